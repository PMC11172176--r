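## Optional image front-end: synthetic H-DAB tile rendering with known
## ground truth, color deconvolution, and optical-density-based cell
## detection with DAB positivity calls.
##
## Rendering follows the Beer-Lambert model: per channel c the transmitted
## intensity is I_c = background_c * 10^(-sum_s A_s V_{s,c}) where A_s is
## the per-pixel amount of stain s (Gaussian discs around cell centers; DAB
## only for marker-positive cells) and V_s the unit stain vector.
## Deconvolution inverts this exactly in the noise-free case via the
## pseudoinverse of the stain matrix, so detection can be validated against
## rendered ground truth.

#' H-DAB stain model
#'
#' Defaults are the standard published hematoxylin/DAB optical-density
#' vectors; vectors are normalized to unit Euclidean norm.
#'
#' @param hematoxylin,dab Length-3 stain vectors in OD (RGB) space.
#' @param background Background (no-stain) intensity per channel, 0-255.
#' @return Object of class `stain_model` with the 2x3 unit stain matrix.
#' @export
stain_model <- function(hematoxylin = c(0.65, 0.70, 0.29),
                        dab = c(0.27, 0.57, 0.78),
                        background = c(243, 243, 243)) {
  m <- rbind(hematoxylin = hematoxylin / sqrt(sum(hematoxylin^2)),
             dab = dab / sqrt(sum(dab^2)))
  cosang <- abs(sum(m[1, ] * m[2, ]))
  if (cosang > 1 - 1e-6)
    stop("collinear stain vectors: deconvolution system is singular")
  stopifnot(length(background) == 3, all(background > 0),
            all(background <= 255))
  structure(list(matrix = m, background = background), class = "stain_model")
}

#' Detection parameters
#'
#' @param pixel_size Micrometres per pixel (default 0.25, a 400x scan).
#' @param smoothing_um Gaussian smoothing scale in micrometres.
#' @param min_cell_area,max_cell_area Component area limits in um^2.
#' @param dab_od_threshold Mean-DAB-OD positivity threshold (OD units).
#' @param hema_od_threshold Hematoxylin OD detection threshold (OD units).
#' @param cell_sigma_um Gaussian-disc radius parameter used by the renderer.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(pixel_size = 0.25, smoothing_um = 1.0,
                             min_cell_area = 8, max_cell_area = 150,
                             dab_od_threshold = 0.3,
                             hema_od_threshold = 0.15,
                             cell_sigma_um = 1.8) {
  stopifnot(pixel_size > 0, min_cell_area < max_cell_area,
            dab_od_threshold >= 0, hema_od_threshold >= 0,
            smoothing_um > 0, cell_sigma_um > 0)
  structure(list(pixel_size = pixel_size, smoothing_um = smoothing_um,
                 min_cell_area = min_cell_area,
                 max_cell_area = max_cell_area,
                 dab_od_threshold = dab_od_threshold,
                 hema_od_threshold = hema_od_threshold,
                 cell_sigma_um = cell_sigma_um),
            class = "detection_params")
}

#' Render a synthetic H-DAB tile
#'
#' Every cell deposits a hematoxylin Gaussian disc; marker-positive cells
#' additionally deposit DAB. Intensities are kept as floating point unless
#' `quantize = TRUE` (8-bit sensor), so the noise-free render/deconvolve
#' round trip is exact to numerical precision.
#'
#' @param cells Data frame with `x_um`, `y_um`, `marker_positive` (logical).
#' @param tile_um Tile side length in micrometres.
#' @param stain A [stain_model()].
#' @param params A [detection_params()].
#' @param hema_amount,dab_amount Peak stain amount per cell (OD units).
#' @param noise_sd Additive Gaussian sensor noise (intensity units).
#' @param quantize Round to 8-bit integers?
#' @param max_packing Warn when cell density exceeds this packing fraction
#'   (cells x disc area / tile area).
#' @return Array (rows = y, cols = x, 3 channels) of intensities in
#'   (0, 255], with attributes `pixel_size` and `tile_um`.
#' @export
render_tile <- function(cells, tile_um = 128, stain = stain_model(),
                        params = detection_params(), hema_amount = 0.7,
                        dab_amount = 1.0, noise_sd = 0, quantize = FALSE,
                        max_packing = 0.25) {
  px <- params$pixel_size
  npx <- round(tile_um / px)
  sigma <- params$cell_sigma_um
  if (nrow(cells) > 0) {
    stopifnot(all(cells$x_um >= 0 & cells$x_um <= tile_um),
              all(cells$y_um >= 0 & cells$y_um <= tile_um))
    packing <- nrow(cells) * pi * (2 * sigma)^2 / tile_um^2
    if (packing > max_packing)
      warning(sprintf("cell packing fraction %.2f exceeds %.2f: overlaps likely",
                      packing, max_packing))
  }
  amt_h <- matrix(0, npx, npx)
  amt_d <- matrix(0, npx, npx)
  centers_um <- (seq_len(npx) - 0.5) * px
  win <- ceiling(4 * sigma / px)
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]
    cy <- cells$y_um[i]
    ix <- max(1, round(cx / px) - win):min(npx, round(cx / px) + win)
    iy <- max(1, round(cy / px) - win):min(npx, round(cy / px) + win)
    g <- exp(-outer((centers_um[iy] - cy)^2, (centers_um[ix] - cx)^2, "+") /
               (2 * sigma^2))
    amt_h[iy, ix] <- amt_h[iy, ix] + hema_amount * g
    if (isTRUE(cells$marker_positive[i]))
      amt_d[iy, ix] <- amt_d[iy, ix] + dab_amount * g
  }
  img <- array(0, dim = c(npx, npx, 3))
  for (ch in 1:3) {
    od <- amt_h * stain$matrix["hematoxylin", ch] +
      amt_d * stain$matrix["dab", ch]
    I <- stain$background[ch] * 10^(-od)
    if (noise_sd > 0) I <- I + rnorm(length(I), 0, noise_sd)
    img[, , ch] <- pmax(pmin(I, 255), 0)
  }
  if (quantize) img <- round(img)
  attr(img, "pixel_size") <- px
  attr(img, "tile_um") <- tile_um
  img
}

#' Color deconvolution of an H-DAB image
#'
#' Per channel OD_c = -log10(max(I_c, 1) / background_c); per-pixel stain
#' amounts are the least-squares solution (pseudoinverse of the stain
#' matrix) of the OD vector, with negative amounts clipped to zero.
#'
#' @param img RGB intensity array (rows x cols x 3).
#' @param stain A [stain_model()].
#' @return List with `hematoxylin` and `dab` amount matrices and the
#'   carried-over `pixel_size` attribute.
#' @export
color_deconvolve <- function(img, stain = stain_model()) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)[1:2]
  od <- vapply(1:3, function(ch) {
    -log10(pmax(img[, , ch], 1) / stain$background[ch])
  }, matrix(0, d[1], d[2]))
  odm <- matrix(od, ncol = 3)  # pixels x channels
  m <- stain$matrix            # stains x channels
  # least squares: amounts = OD %*% t(M) %*% (M M^T)^{-1}
  amounts <- odm %*% t(m) %*% solve(m %*% t(m))
  amounts[amounts < 0] <- 0
  out <- list(hematoxylin = matrix(amounts[, 1], d[1], d[2]),
              dab = matrix(amounts[, 2], d[1], d[2]))
  attr(out, "pixel_size") <- attr(img, "pixel_size")
  out
}

#' Detect cells and call DAB positivity
#'
#' Smooths the total stain amount, thresholds (a pixel counts as cellular
#' when smoothed hematoxylin or DAB exceeds its threshold), splits touching
#' cells by watershed on the distance map, filters components by area, and
#' calls a detection marker-positive when its mean DAB OD reaches
#' `dab_od_threshold`. Deterministic: repeated runs are identical.
#'
#' @param channels Output of [color_deconvolve()] (or a compatible list).
#' @param params A [detection_params()].
#' @return Data frame: x_um, y_um (centroids), area_um2, mean_dab_od,
#'   marker_positive. Empty (zero rows) for a blank image.
#' @export
detect_cells <- function(channels, params = detection_params()) {
  px <- attr(channels, "pixel_size")
  if (is.null(px)) px <- params$pixel_size
  sigma_px <- params$smoothing_um / px
  sm_h <- EBImage::gblur(channels$hematoxylin, sigma = sigma_px)
  sm_d <- EBImage::gblur(channels$dab, sigma = sigma_px)
  mask <- sm_h > params$hema_od_threshold | sm_d > params$dab_od_threshold
  if (!any(mask)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_dab_od = numeric(0),
                      marker_positive = logical(0)))
  }
  labels <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  lab <- as.integer(labels)
  keep <- lab > 0
  lab <- lab[keep]
  idx <- which(keep)
  nr <- nrow(channels$dab)
  row_i <- (idx - 1L) %% nr + 1L
  col_i <- (idx - 1L) %/% nr + 1L
  area_px <- tabulate(lab)
  area_um2 <- area_px * px^2
  ok <- which(area_um2 >= params$min_cell_area &
                area_um2 <= params$max_cell_area)
  if (length(ok) == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_dab_od = numeric(0),
                      marker_positive = logical(0)))
  }
  cy <- tapply((row_i - 0.5) * px, lab, mean)
  cx <- tapply((col_i - 0.5) * px, lab, mean)
  mean_dab <- tapply(channels$dab[idx], lab, mean)
  comp <- as.integer(names(cy))
  sel <- comp %in% ok
  data.frame(x_um = as.numeric(cx)[sel], y_um = as.numeric(cy)[sel],
             area_um2 = area_um2[comp[sel]],
             mean_dab_od = as.numeric(mean_dab)[sel],
             marker_positive = as.numeric(mean_dab)[sel] >=
               params$dab_od_threshold)
}
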