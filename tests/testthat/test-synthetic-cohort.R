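test_that("configuration invariants are enforced", {
  expect_error(sim_config(roi_area = -1))
  expect_error(sim_config(cross_marker_rho = 1.4))
  expect_error(sim_config(target_event_fraction = 0))
  expect_error(sim_config(tumor_fraction_range = c(0.6, 0.2)))
  expect_error(sim_config(covariate_effects = list(grade = c(bogus = 1))),
               "density variables")
  # copula feasibility: cross-marker correlation cannot exceed the
  # within-marker stromal-tumoral correlation
  expect_error(sim_config(cross_marker_rho = 0.9), "shared-factor")
  cfg <- sim_config()
  expect_equal(cfg$roi_area, 1.96)
  expect_equal(cfg$band_width, 50)
  expect_equal(sqrt(cfg$roi_area * 1e6), 1400)
})

test_that("generated geometries are simple, contained, and in the area range", {
  cfg <- sim_config(seed = 61)
  set.seed(61)
  for (i in 1:8) {
    g <- generate_geometry(cfg, "c", paste0("r", i))
    expect_true(is_simple_ring(g$roi))
    expect_gte(length(g$tumor), 1)
    expect_lte(length(g$tumor), 5)
    for (ring in g$tumor) {
      expect_true(is_simple_ring(ring))
      expect_true(all(point_in_ring(ring$x, ring$y, g$roi)))
      # vertex-list area equals the shoelace oracle
      expect_equal(ring_area(ring), shoelace_oracle(ring),
                   tolerance = 1e-9)
    }
    frac <- multipolygon_area(g$tumor) / ring_area(g$roi)
    expect_gte(frac, cfg$tumor_fraction_range[1] - 1e-9)
    expect_lte(frac, cfg$tumor_fraction_range[2] + 1e-9)
  }
  # zero nests requested: degenerate ROI flagged by a warning, empty tumor
  cfg0 <- sim_config(n_nest_range = c(0, 0), seed = 61)
  expect_warning(g0 <- generate_geometry(cfg0), "degenerate")
  expect_length(g0$tumor, 0)
})

test_that("point counts are Poisson with mean intensity x area", {
  cfg <- sim_config(seed = 62)
  set.seed(62)
  g <- generate_geometry(cfg)
  band <- build_stromal_band(g$tumor, g$roi, 50, resolution = 2)
  a_t <- multipolygon_area(g$tumor) / 1e6
  lam_t <- 400
  # zero intensity -> zero points
  none <- sample_tam_points(g, 0, 0, band = band)
  expect_equal(nrow(none), 0)
  # 500 replicates: mean count within 3 SE of lambda * area, and the
  # chi-square goodness-of-fit against the Poisson law does not reject
  counts <- vapply(1:500, function(i)
    nrow(sample_tam_points(g, lam_t, 0, band = band)), numeric(1))
  mu <- lam_t * a_t
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 500))
  qs <- quantile(counts, c(0.2, 0.4, 0.6, 0.8))
  breaks <- unique(c(-Inf, qs, Inf))
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-Inf, qs, Inf), mu))
  gof <- chisq.test(as.vector(obs), p = pr)
  expect_gt(gof$p.value, 0.01)
  # all stromal points live inside the band; all tumoral points at distance 0
  pts <- sample_tam_points(g, 200, 400, band = band)
  d <- distance_to_tumor(pts$x_um, pts$y_um, g$tumor)
  expect_true(all(d <= 50))
  expect_gt(sum(d == 0), 0)
  expect_error(sample_tam_points(region_geometry("c", "r", g$roi, list()),
                                 100, 100), "degenerate")
})

test_that("identical seed and config give byte-identical cohort outputs", {
  cfg <- sim_config(n_cases = 4, rois_per_case = 2, seed = 63)
  c1 <- generate_cohort(cfg, level = "cells")
  c2 <- generate_cohort(cfg, level = "cells")
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cells_csv(c1$cells, f1)
  write_cells_csv(c2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(fileext = ".geojson")
  g2 <- tempfile(fileext = ".geojson")
  write_regions_geojson(c1$geometries, g1)
  write_regions_geojson(c2$geometries, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$clinical, c2$clinical)
  # a different seed changes the realization
  c3 <- generate_cohort(sim_config(n_cases = 4, rois_per_case = 2,
                                   seed = 64), level = "cells")
  expect_false(identical(c1$cells, c3$cells))
})

test_that("subtype assignment follows the IHC surrogate rules", {
  expect_equal(as.character(assign_subtype(TRUE, 30, FALSE, 10)),
               "luminal A")
  expect_equal(as.character(assign_subtype(TRUE, 10, FALSE, 10)),
               "luminal B")
  expect_equal(as.character(assign_subtype(TRUE, 30, TRUE, 10)),
               "luminal B")
  expect_equal(as.character(assign_subtype(TRUE, 30, FALSE, 40)),
               "luminal B")
  expect_equal(as.character(assign_subtype(FALSE, 0, TRUE, 50)), "HER2-OE")
  expect_equal(as.character(assign_subtype(FALSE, 0, FALSE, 50)), "TNBC")
  expect_equal(as.character(assign_subtype(NA, 0, FALSE, 50)),
               "unclassified")
  expect_error(assign_subtype(TRUE, 150, FALSE, 10), "\\[0, 100\\]")
})

test_that("null hazards give exchangeable survival groups", {
  set.seed(65)
  ps <- vapply(1:40, function(i) {
    coh <- generate_cohort(sim_config(n_cases = 150, seed = 6500 + i,
                                      hazard_log_hr = c(pn_stage = 0)),
                           level = "case")
    s <- coh$survival
    m <- coh$metrics
    g <- m$ratio_sCD163_sTIL_high[match(s$case_id, m$case_id)]
    logrank_test(s$dfs_months, s$dfs_event, g)$p
  }, numeric(1))
  # under the null the log-rank p is uniform: no mass piling near 0
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("configured hazard ratios are recovered by the downstream Cox fit", {
  set.seed(66)
  coh <- generate_cohort(sim_config(n_cases = 2000, seed = 66),
                         level = "case")
  des <- build_survival_design(coh$metrics, coh$clinical)
  fit <- cox_fit(des[c("ratio_sCD163_sTIL_high", "pn_stage")],
                 coh$survival$dfs_months, coh$survival$dfs_event)
  b <- fit$coefficients[fit$coefficients$term == "ratio_sCD163_sTIL_high", ]
  expect_lt(abs(b$coef - log(3.477)), 2 * b$se)
  # realized event fraction lands near the configured target
  expect_lt(abs(mean(coh$survival$dfs_event) - 0.141), 0.05)
  expect_true(all(coh$survival$dfs_months <= coh$survival$os_months + 1e-9))
  expect_true(all(coh$survival$dfs_months > 0))
})

test_that("unknown hazard covariate keys are a configuration error", {
  cfg <- sim_config(n_cases = 30, seed = 67,
                    hazard_log_hr = c(not_a_column = 1))
  expect_error(generate_cohort(cfg, level = "case"), "unknown covariate")
})

test_that("clinical marginals approximate the cohort they emulate", {
  coh <- generate_cohort(sim_config(n_cases = 2000, seed = 68),
                         level = "case")
  cl <- coh$clinical
  expect_equal(mean(cl$grade == 1), 16 / 225, tolerance = 0.35)
  expect_equal(mean(cl$grade == 2), 124 / 225, tolerance = 0.12)
  expect_equal(mean(cl$er_positive), 0.763, tolerance = 0.08)
  expect_equal(median(cl$age), 47, tolerance = 0.08)
  expect_equal(median(cl$size_cm), 1.8, tolerance = 0.15)
  expect_gt(mean(cl$subtype == "luminal B"), 0.3)
  # sTILs correlate positively with stromal TAM density (shared factor)
  m <- coh$metrics
  expect_gt(cor(m$sCD163, cl$til_percent[match(m$case_id, cl$case_id)],
                method = "spearman"), 0.2)
})
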