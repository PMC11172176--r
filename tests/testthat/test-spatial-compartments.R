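test_that("stromal band area matches the closed-form annulus", {
  roi <- square_ring(0, 0, 1400)
  tumor <- list(disk_ring(700, 700, 200))
  band <- build_stromal_band(tumor, roi, band_width = 50, resolution = 1)
  truth <- pi * (250^2 - 200^2)
  expect_lt(abs(band$area_um2 - truth) / truth, 0.005)
  # band never intersects the tumor, stays inside the ROI, and respects the
  # width bound (set-difference identities via the membership predicate)
  set.seed(21)
  qx <- runif(4000, 0, 1400)
  qy <- runif(4000, 0, 1400)
  inside <- band_contains(band, qx, qy)
  d <- distance_to_tumor(qx, qy, tumor)
  expect_true(all(d[inside] > 0))
  expect_true(all(d[inside] <= 50))
  expect_true(all(point_in_ring(qx[inside], qy[inside], roi)))
  expect_equal(inside, d > 0 & d <= 50 & point_in_ring(qx, qy, roi))
})

test_that("degenerate and saturated geometries are handled", {
  roi <- square_ring(0, 0, 1400)
  expect_error(build_stromal_band(list(), roi, 50), "degenerate")
  expect_error(distance_to_tumor(1, 1, list()), "degenerate")
  g_empty <- region_geometry("c", "r", roi, list())
  expect_warning(a <- region_areas(g_empty), "no tumor polygon")
  expect_equal(a$tumor_area, 0)
  expect_true(is.na(a$stromal_area))
  # tumor filling the whole ROI: full tumor area, no stromal band
  g_full <- region_geometry("c", "r", roi,
                            list(square_ring(0, 0, 1400)), validate = FALSE)
  a <- region_areas(g_full, resolution = 2)
  expect_equal(a$tumor_area, 1.96)
  expect_equal(a$stromal_area, 0)
})

test_that("distance to tumor matches a brute-force boundary oracle", {
  set.seed(22)
  tumor <- list(random_blob(500, 500, 120), random_blob(950, 300, 80))
  px <- runif(1000, 0, 1400)
  py <- runif(1000, 0, 1400)
  d <- distance_to_tumor(px, py, tumor)
  inside <- point_in_multipolygon(px, py, tumor)
  expect_true(all(d[inside] == 0))
  out <- which(!inside)
  brute <- brute_boundary_distance(px[out], py[out], tumor, step = 0.01)
  expect_lt(max(abs(d[out] - brute)), 0.02)
})

test_that("compartment assignment partitions cells and obeys the band rule", {
  roi <- square_ring(0, 0, 1400)
  tumor <- list(disk_ring(700, 700, 200))
  geom <- region_geometry("c1", "r1", roi, tumor, validate = FALSE)
  cells <- data.frame(
    case_id = "c1", roi_id = "r1", marker = "CD163",
    x_um = c(700, 930, 960, 700, 700 + 200 * cos(2 * pi * 10 / 256)),
    y_um = c(700, 700, 700, 1500, 700 + 200 * sin(2 * pi * 10 / 256)))
  expect_warning(out <- assign_compartment(cells, geom, 50), "outside")
  # centroid -> tumor; 30 um out -> stroma; 60 um out -> excluded;
  # outside ROI -> excluded; exactly on the boundary -> tumor (distance 0)
  expect_equal(out$compartment,
               c("tumor", "stroma", "excluded", "excluded", "tumor"))
  expect_equal(out$distance_to_tumor[1], 0)
  expect_equal(out$distance_to_tumor[2], 30, tolerance = 1e-3)
  # partition: every cell in exactly one class
  expect_equal(sum(table(out$compartment)), nrow(cells))
})

test_that("enlarging the band never shrinks stromal area or count, and scaling is exact", {
  set.seed(23)
  roi <- square_ring(0, 0, 1400)
  tumor <- list(random_blob(700, 700, 150))
  geom <- region_geometry("c", "r", roi, tumor, validate = FALSE)
  widths <- c(25, 50, 100)
  areas <- vapply(widths, function(w)
    build_stromal_band(tumor, roi, w, resolution = 2)$area_um2, numeric(1))
  expect_true(all(diff(areas) > 0))
  cells <- data.frame(case_id = "c", roi_id = "r", marker = "CD163",
                      x_um = runif(400, 0, 1400), y_um = runif(400, 0, 1400))
  counts <- vapply(widths, function(w)
    sum(assign_compartment(cells, geom, w)$compartment == "stroma"),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  # scaling: x k scales distances by k and areas by k^2
  k <- 2.5
  tumor_k <- lapply(tumor, function(r) list(x = r$x * k, y = r$y * k))
  roi_k <- polygon_ring(roi$x * k, roi$y * k)
  d1 <- distance_to_tumor(cells$x_um, cells$y_um, tumor)
  dk <- distance_to_tumor(cells$x_um * k, cells$y_um * k, tumor_k)
  expect_equal(dk, k * d1, tolerance = 1e-12)
  expect_equal(multipolygon_area(tumor_k), k^2 * multipolygon_area(tumor),
               tolerance = 1e-12)
})

test_that("region_geometry validates rings and containment", {
  roi <- square_ring(0, 0, 1000)
  expect_error(
    region_geometry("c", "r", roi,
                    list(list(x = c(0, 100, 0, 100), y = c(0, 100, 100, 0)))),
    "self-intersecting")
  expect_error(
    region_geometry("c", "r", roi, list(square_ring(900, 900, 300))),
    "outside the ROI")
})

test_that("hotspot search finds the densest window with deterministic ties", {
  set.seed(24)
  cluster <- data.frame(x_um = rnorm(60, 2000, 60), y_um = rnorm(60, 2000, 60))
  sparse <- data.frame(x_um = runif(40, 0, 6000), y_um = runif(40, 0, 6000))
  cells <- rbind(cluster, sparse)
  hs <- find_hotspots(cells, window_area = 1.96)
  side <- sqrt(1.96e6)
  expect_true(hs$x <= 2000 && 2000 <= hs$x + side)
  expect_true(hs$y <= 2000 && 2000 <= hs$y + side)
  # on a single tight cluster the grid maximum captures everything, so it
  # is >= the count of any of 10,000 random window placements
  hs_c <- find_hotspots(cluster, window_area = 1.96)
  expect_equal(hs_c$count, nrow(cluster))
  set.seed(25)
  rx <- runif(10000, min(cluster$x_um) - side, max(cluster$x_um))
  ry <- runif(10000, min(cluster$y_um) - side, max(cluster$y_um))
  rand_best <- max(vapply(seq_len(10000), function(i)
    sum(cluster$x_um >= rx[i] & cluster$x_um <= rx[i] + side &
          cluster$y_um >= ry[i] & cluster$y_um <= ry[i] + side), numeric(1)))
  expect_gte(hs_c$count, rand_best)
  # two identical clusters: the smaller-x window wins
  two <- rbind(data.frame(x_um = rep(1000, 5), y_um = rep(1000, 5)),
               data.frame(x_um = rep(9000, 5), y_um = rep(9000, 5)))
  hs2 <- find_hotspots(two, window_area = 1.96)
  expect_lt(hs2$x, 5000)
  expect_error(find_hotspots(two[0, ]), "no detections")
})
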