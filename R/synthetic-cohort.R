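## Synthetic cohort generator.
##
## Emulates the inputs of the TAM spatial-profiling analysis: per-ROI
## tumor-nest geometries inside 1.96 mm^2 square ROIs, compartment-wise
## homogeneous Poisson point patterns for CD163/CD206 cells with case-level
## lognormal intensity heterogeneity and a shared Gaussian-copula factor for
## cross-marker correlation, clinical covariates with cohort-like marginals,
## stromal TIL percentages positively correlated with TAM intensities, and
## exponential proportional-hazards outcomes under uniform administrative
## censoring calibrated to a target event fraction.
##
## Defaults are the study conditions: 225 cases, five 1.96 mm^2 ROIs per
## case, a 50 um stromal band, lognormal intensity medians 354.1 / 210.8 /
## 303.2 / 111.6 cells/mm^2 (sCD163 / tCD163 / sCD206 / tCD206), a 14.1%
## disease-free-survival event fraction and a default hazard ratio of 3.477
## on the high sCD163/sTIL flag.

#' Simulation configuration
#'
#' @param n_cases Number of cases (default 225).
#' @param rois_per_case ROIs per case (default 5).
#' @param roi_area ROI area in mm^2 (default 1.96; square ROI, side
#'   sqrt(area)).
#' @param band_width Stromal band width in micrometres (default 50).
#' @param tumor_fraction_range Admissible tumor area fraction per ROI.
#' @param n_nest_range Range of tumor-nest polygon counts per ROI (1..5).
#' @param intensity_median Case-level lognormal intensity medians
#'   (cells/mm^2) named by sCD163/tCD163/sCD206/tCD206.
#' @param intensity_sdlog Lognormal log-scale standard deviations (same
#'   names).
#' @param marker_st_rho Latent stromal-tumoral log-intensity correlation per
#'   marker.
#' @param cross_marker_rho Latent cross-marker correlation (shared factor);
#'   must not exceed either `marker_st_rho`.
#' @param roi_sdlog Within-case between-ROI lognormal spread of intensities
#'   (a free parameter of the generator; the source analysis reports none).
#' @param covariate_effects Named list: clinical covariate -> named numeric
#'   of log-scale intensity modifiers per density variable (applied centered
#'   so cohort medians stay at `intensity_median`).
#' @param stil_median,stil_sdlog,stil_loading Stromal-TIL lognormal median
#'   (%), spread, and loading on the shared case factor.
#' @param hazard_log_hr Named log hazard ratios over the columns of
#'   [build_survival_design()].
#' @param baseline_hazard Baseline exponential hazard (events/month); when
#'   `NULL` it is calibrated so the expected event fraction equals
#'   `target_event_fraction`.
#' @param target_event_fraction Target disease-free-survival event fraction.
#' @param censor_range Uniform administrative censoring window in months
#'   (follow-up from a closed accrual window).
#' @param os_delay_rate Rate (1/months) of the exponential relapse-to-death
#'   delay used for overall survival.
#' @param seed Integer master seed; every draw derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 225,
                       rois_per_case = 5,
                       roi_area = 1.96,
                       band_width = 50,
                       tumor_fraction_range = c(0.2, 0.6),
                       n_nest_range = c(1, 5),
                       intensity_median = c(sCD163 = 354.1, tCD163 = 210.8,
                                            sCD206 = 303.2, tCD206 = 111.6),
                       intensity_sdlog = c(sCD163 = 0.915, tCD163 = 1.07,
                                           sCD206 = 0.775, tCD206 = 0.96),
                       marker_st_rho = c(CD163 = 0.75, CD206 = 0.55),
                       cross_marker_rho = 0.51,
                       roi_sdlog = 0.25,
                       covariate_effects = list(
                         grade = c(tCD163 = 0.40, sCD163 = 0.35),
                         ln_met = c(sCD206 = 0.35)),
                       stil_median = 10, stil_sdlog = 0.8,
                       stil_loading = 0.6,
                       hazard_log_hr = c(ratio_sCD163_sTIL_high = log(3.477),
                                         pn_stage = log(2.111)),
                       baseline_hazard = NULL,
                       target_event_fraction = 0.141,
                       censor_range = c(95, 143),
                       os_delay_rate = 1 / 24,
                       seed = 1L) {
  stopifnot(n_cases >= 1, rois_per_case >= 1, roi_area > 0, band_width > 0,
            all(intensity_median >= 0), all(intensity_sdlog >= 0),
            cross_marker_rho >= 0, cross_marker_rho <= 1,
            all(marker_st_rho >= 0), all(marker_st_rho <= 1),
            target_event_fraction > 0, target_event_fraction < 1,
            length(tumor_fraction_range) == 2,
            tumor_fraction_range[1] <= tumor_fraction_range[2],
            tumor_fraction_range[1] > 0, tumor_fraction_range[2] < 1,
            censor_range[1] > 0, censor_range[1] < censor_range[2])
  stopifnot(all(DENSITY_VARS %in% names(intensity_median)),
            all(DENSITY_VARS %in% names(intensity_sdlog)),
            all(MARKERS %in% names(marker_st_rho)))
  if (any(marker_st_rho < cross_marker_rho))
    stop("marker_st_rho must be >= cross_marker_rho (shared-factor copula)")
  for (k in names(covariate_effects)) {
    if (!all(names(covariate_effects[[k]]) %in% DENSITY_VARS))
      stop(sprintf("covariate_effects[[%s]] names must be density variables", k))
  }
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic 31-bit substream seed from the master seed and a key, so the
# cohort is reproducible case by case (stable under parallel generation).
seed_for <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(key)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' IHC surrogate molecular subtype
#'
#' luminal A = ER+ and PR >= 20% and HER2- and Ki67 < 20%; luminal B = ER+
#' and (PR < 20% or HER2+ or Ki67 >= 20%); HER2-OE = ER-, PR-, HER2+; TNBC =
#' ER-, PR-, HER2-. PR- means PR < 20%. Any missing input gives
#' "unclassified".
#'
#' @param er_positive,her2_positive Logical (or 0/1) receptor status.
#' @param pr_percent,ki67_percent Percentages in [0, 100].
#' @return Factor with levels luminal A, luminal B, HER2-OE, TNBC,
#'   unclassified.
#' @export
assign_subtype <- function(er_positive, pr_percent, her2_positive,
                           ki67_percent) {
  if (any(pr_percent < 0 | pr_percent > 100, na.rm = TRUE) ||
      any(ki67_percent < 0 | ki67_percent > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  er <- as.logical(er_positive)
  her2 <- as.logical(her2_positive)
  pr_hi <- pr_percent >= 20
  ki_hi <- ki67_percent >= 20
  out <- rep("unclassified", length(er))
  lum_a <- er & pr_hi & !her2 & !ki_hi
  lum_b <- er & (!pr_hi | her2 | ki_hi)
  her2_oe <- !er & !pr_hi & her2
  tnbc <- !er & !pr_hi & !her2
  out[which(lum_a)] <- "luminal A"
  out[which(lum_b)] <- "luminal B"
  out[which(her2_oe)] <- "HER2-OE"
  out[which(tnbc)] <- "TNBC"
  out[is.na(er) | is.na(pr_hi) | is.na(her2) | is.na(ki_hi)] <- "unclassified"
  factor(out, levels = c("luminal A", "luminal B", "HER2-OE", "TNBC",
                         "unclassified"))
}

# One perturbed-ellipse tumor-nest ring with exact target area, centered at
# the origin. Star-shaped by construction, hence simple. Returns the ring
# and its maximal radial extent.
nest_ring <- function(target_area, n_vertices = 96) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  rr <- rep(1, n_vertices)
  for (k in 2:5)
    rr <- rr + (runif(1, 0, 0.15) / k) * cos(k * theta + runif(1, 0, 2 * pi))
  ecc <- runif(1, 0.75, 1)
  phi <- runif(1, 0, pi)
  x <- rr * cos(theta) / sqrt(ecc)
  y <- rr * sin(theta) * sqrt(ecc)
  xr <- x * cos(phi) - y * sin(phi)
  yr <- x * sin(phi) + y * cos(phi)
  ring <- list(x = xr, y = yr)
  s <- sqrt(target_area / ring_area(ring))
  ring <- list(x = xr * s, y = yr * s)
  list(ring = ring, extent = max(sqrt(ring$x^2 + ring$y^2)))
}

#' Generate one synthetic ROI geometry
#'
#' A square ROI of the configured area containing 1-5 disjoint simple
#' tumor-nest polygons (randomly perturbed ellipses) whose total area
#' fraction lies in `tumor_fraction_range`. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param case_id,roi_id Identifiers stored in the geometry.
#' @return A [region_geometry()].
#' @export
generate_geometry <- function(config, case_id = "case1", roi_id = "roi1") {
  stopifnot(inherits(config, "sim_config"))
  side <- sqrt(config$roi_area * 1e6)
  roi <- polygon_ring(c(0, side, side, 0), c(0, 0, side, side))
  n_max <- config$n_nest_range[2]
  if (n_max < 1) {
    warning("zero tumor nests requested: degenerate ROI (empty tumor)")
    return(region_geometry(case_id, roi_id, roi, list()))
  }
  margin <- 0.02 * side
  gap <- 5
  frac <- runif(1, config$tumor_fraction_range[1],
                config$tumor_fraction_range[2])
  n_nests <- if (config$n_nest_range[1] == n_max) n_max else
    sample(seq(config$n_nest_range[1], n_max), 1)
  n_nests <- max(1L, n_nests)
  for (attempt in seq_len(25)) {
    w <- rgamma(n_nests, shape = 3)
    areas <- frac * side^2 * w / sum(w)
    nests <- lapply(areas, nest_ring)
    ext <- vapply(nests, `[[`, numeric(1), "extent")
    ok <- ext + margin < side / 2
    placed_x <- placed_y <- numeric(0)
    success <- all(ok)
    if (success) {
      for (b in seq_len(n_nests)) {
        found <- FALSE
        for (try in seq_len(200)) {
          cx <- runif(1, margin + ext[b], side - margin - ext[b])
          cy <- runif(1, margin + ext[b], side - margin - ext[b])
          if (b == 1 || all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >
                              ext[seq_len(b - 1)] + ext[b] + gap)) {
            placed_x <- c(placed_x, cx)
            placed_y <- c(placed_y, cy)
            found <- TRUE
            break
          }
        }
        if (!found) { success <- FALSE; break }
      }
    }
    if (success) {
      tumor <- lapply(seq_len(n_nests), function(b) {
        list(x = nests[[b]]$ring$x + placed_x[b],
             y = nests[[b]]$ring$y + placed_y[b])
      })
      return(region_geometry(case_id, roi_id, roi, tumor,
                             validate = FALSE))
    }
    # infeasible packing: retry with a smaller fraction and/or fewer nests
    frac <- runif(1, config$tumor_fraction_range[1], frac)
    n_nests <- max(1L, n_nests - 1L)
  }
  stop("infeasible geometry configuration: could not place tumor nests")
}

#' Sample a compartment-wise homogeneous Poisson TAM point pattern
#'
#' Counts are Poisson with mean intensity x compartment area; locations are
#' uniform inside the compartment (tumor nest, or the peritumoral stromal
#' band for the stromal compartment).
#'
#' @param geom A [region_geometry()] with a non-empty tumor.
#' @param tumor_intensity,stroma_intensity Intensities in cells/mm^2.
#' @param marker Marker label stored in the output.
#' @param band_width Band width in micrometres (default 50).
#' @param band Optional precomputed [build_stromal_band()] for `geom`.
#' @param resolution Band quadrature grid step (um) when `band` is NULL.
#' @return Data frame: case_id, roi_id, marker, x_um, y_um.
#' @export
sample_tam_points <- function(geom, tumor_intensity, stroma_intensity,
                              marker = "CD163", band_width = 50,
                              band = NULL, resolution = 2) {
  stopifnot(inherits(geom, "region_geometry"),
            tumor_intensity >= 0, stroma_intensity >= 0)
  if (length(geom$tumor) == 0)
    stop("degenerate ROI: empty tumor multipolygon")
  if (is.null(band))
    band <- build_stromal_band(geom$tumor, geom$roi, band_width, resolution)
  blob_areas <- vapply(geom$tumor, ring_area, numeric(1))
  n_t <- rpois(1, tumor_intensity * sum(blob_areas) / 1e6)
  n_s <- rpois(1, stroma_intensity * band$area_mm2)
  tx <- ty <- numeric(0)
  if (n_t > 0) {
    blob <- sample.int(length(blob_areas), n_t, replace = TRUE,
                       prob = blob_areas)
    for (b in unique(blob)) {
      need <- sum(blob == b)
      ring <- geom$tumor[[b]]
      bb <- ring_bbox(ring)
      got_x <- got_y <- numeric(0)
      while (length(got_x) < need) {
        m <- max(2L * need, 64L)
        qx <- runif(m, bb["xmin"], bb["xmax"])
        qy <- runif(m, bb["ymin"], bb["ymax"])
        keep <- point_in_ring(qx, qy, ring)
        got_x <- c(got_x, qx[keep])
        got_y <- c(got_y, qy[keep])
      }
      tx <- c(tx, got_x[seq_len(need)])
      ty <- c(ty, got_y[seq_len(need)])
    }
  }
  sx <- sy <- numeric(0)
  if (n_s > 0) {
    rb <- ring_bbox(geom$roi)
    tb <- multipolygon_bbox(geom$tumor)
    xmin <- max(tb["xmin"] - band$band_width, rb["xmin"])
    xmax <- min(tb["xmax"] + band$band_width, rb["xmax"])
    ymin <- max(tb["ymin"] - band$band_width, rb["ymin"])
    ymax <- min(tb["ymax"] + band$band_width, rb["ymax"])
    while (length(sx) < n_s) {
      m <- max(4L * n_s, 256L)
      qx <- runif(m, xmin, xmax)
      qy <- runif(m, ymin, ymax)
      keep <- band_contains(band, qx, qy)
      sx <- c(sx, qx[keep])
      sy <- c(sy, qy[keep])
    }
    sx <- sx[seq_len(n_s)]
    sy <- sy[seq_len(n_s)]
  }
  n_pts <- length(tx) + length(sx)
  data.frame(case_id = rep(geom$case_id, n_pts),
             roi_id = rep(geom$roi_id, n_pts),
             marker = rep(marker, n_pts),
             x_um = c(tx, sx), y_um = c(ty, sy), stringsAsFactors = FALSE)
}

# Cohort-like clinical covariate marginals plus the latent Gaussian factors
# that couple TAM intensities and stromal TILs.
generate_clinical <- function(config) {
  n <- config$n_cases
  case_id <- sprintf("case%03d", seq_len(n))
  age <- pmin(pmax(round(rnorm(n, 48.6, 10.1)), 29), 85)
  size_cm <- pmin(pmax(round(rlnorm(n, log(1.8), 0.55), 1), 0.1), 7.6)
  grade <- sample(1:3, n, replace = TRUE, prob = c(16, 124, 85) / 225)
  ln_met <- rbinom(n, 1, 0.458)
  pn_stage <- ifelse(ln_met == 1,
                     sample(1:3, n, replace = TRUE, prob = c(.60, .25, .15)),
                     0L)
  pt_stage <- as.integer(cut(size_cm, c(0, 2, 5, Inf), labels = FALSE))
  er_positive <- rbinom(n, 1, 0.763) == 1
  pr_hi <- ifelse(er_positive, rbinom(n, 1, 0.92), rbinom(n, 1, 0.18)) == 1
  pr_percent <- ifelse(pr_hi, 20 + round(79 * rbeta(n, 1.2, 0.8)),
                       round(19 * rbeta(n, 0.6, 2)))
  her2_positive <- rbinom(n, 1, 0.139) == 1
  ki67_percent <- pmin(pmax(round(rlnorm(n, log(27), 0.73)), 1), 95)
  ki67_high <- ki67_percent >= 20
  # shared case factor F couples the four TAM intensities and the TILs
  f_case <- rnorm(n)
  g_marker <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, MARKERS))
  til_raw <- exp(log(config$stil_median) + config$stil_sdlog *
                   (config$stil_loading * f_case +
                      sqrt(1 - config$stil_loading^2) * rnorm(n)))
  til_percent <- pmin(pmax(round(til_raw), 1), 90)
  clin <- data.frame(
    case_id = case_id, age = age, size_cm = size_cm, grade = grade,
    ln_met = ln_met == 1, pt_stage = pt_stage, pn_stage = pn_stage,
    er_positive = er_positive, pr_percent = pr_percent,
    pr_positive = pr_percent >= 20, her2_positive = her2_positive,
    ki67_percent = ki67_percent, ki67_high = ki67_high,
    til_percent = til_percent, til_high = til_percent > 20,
    necrosis = rbinom(n, 1, 0.27) == 1,
    lvi = rbinom(n, 1, 0.11) == 1,
    fibrotic_focus = rbinom(n, 1, 0.156) == 1,
    apocrine = rbinom(n, 1, 0.10) == 1,
    ck14 = rbinom(n, 1, 0.065) == 1,
    p63 = rbinom(n, 1, 0.097) == 1,
    egfr = rbinom(n, 1, 0.023) == 1,
    ckit = rbinom(n, 1, 0.09) == 1,
    ck56 = rbinom(n, 1, 0.17) == 1,
    pdl1_ic = rbinom(n, 1, 0.33) == 1,
    pdl1_t = rbinom(n, 1, 0.11) == 1,
    stringsAsFactors = FALSE)
  clin$subtype <- assign_subtype(clin$er_positive, clin$pr_percent,
                                 clin$her2_positive, clin$ki67_percent)
  list(clinical = clin, f_case = f_case, g_marker = g_marker)
}

# Case-level true intensities (cells/mm^2): lognormal around the configured
# medians, shared-factor copula across the four variables, plus centered
# covariate modifiers so the cohort medians stay at the configured values.
latent_intensities <- function(config, clin, f_case, g_marker) {
  n <- config$n_cases
  b <- config$cross_marker_rho
  lam <- matrix(NA_real_, n, 4, dimnames = list(NULL, DENSITY_VARS))
  for (v in DENSITY_VARS) {
    m <- ifelse(grepl("163", v), "CD163", "CD206")
    c_m <- config$marker_st_rho[[m]] - b
    z <- sqrt(b) * f_case + sqrt(c_m) * g_marker[, m] +
      sqrt(1 - b - c_m) * rnorm(n)
    eff <- rep(0, n)
    for (k in names(config$covariate_effects)) {
      e_k <- config$covariate_effects[[k]]
      if (!v %in% names(e_k)) next
      x <- as.numeric(clin[[k]])
      if (is.null(x)) stop(sprintf("unknown covariate '%s' in covariate_effects", k))
      eff <- eff + e_k[[v]] * (x - mean(x))
    }
    lam[, v] <- exp(log(config$intensity_median[[v]]) +
                      config$intensity_sdlog[[v]] * z + eff)
  }
  lam
}

#' Survival design matrix
#'
#' Case-level covariates used by the outcome generator and the Cox analyses:
#' continuous age and tumor size, ordinal grade/pT/pN, binary receptor and
#' proliferation status, TIL status, the CD163 four-group dummies (reference
#' sLO-tLO) and the four median-split TAM/sTIL ratio flags.
#'
#' @param metrics Case metric table from [compute_case_metrics()].
#' @param clinical Clinical table.
#' @return Data frame keyed by `case_id` with numeric covariate columns.
#' @export
build_survival_design <- function(metrics, clinical) {
  d <- merge(clinical, metrics, by = "case_id", sort = TRUE)
  out <- data.frame(case_id = d$case_id, age = d$age, size_cm = d$size_cm,
                    grade = d$grade, pt_stage = d$pt_stage,
                    pn_stage = d$pn_stage,
                    er_positive = as.numeric(d$er_positive),
                    pr_positive = as.numeric(d$pr_positive),
                    her2_positive = as.numeric(d$her2_positive),
                    ki67_high = as.numeric(d$ki67_high),
                    til_high = as.numeric(d$til_high),
                    stringsAsFactors = FALSE)
  fg <- d$cd163_four_group
  out$cd163_sLO_tHI <- as.numeric(fg == "sLO-tHI")
  out$cd163_sHI_tLO <- as.numeric(fg == "sHI-tLO")
  out$cd163_sHI_tHI <- as.numeric(fg == "sHI-tHI")
  for (v in DENSITY_VARS) {
    flag <- paste0("ratio_", v, "_sTIL_high")
    if (flag %in% names(d)) out[[flag]] <- as.numeric(d[[flag]])
  }
  out
}

# Expected event fraction under exponential hazards h and U(a, b) censoring.
expected_event_fraction <- function(h, a, b) {
  mean(1 - (exp(-h * a) - exp(-h * b)) / (h * (b - a)))
}

generate_survival <- function(config, metrics, clinical) {
  design <- build_survival_design(metrics, clinical)
  keys <- names(config$hazard_log_hr)
  unknown <- setdiff(keys, names(design))
  if (length(unknown))
    stop(sprintf("unknown covariate key(s) in hazard_log_hr: %s",
                 paste(unknown, collapse = ", ")))
  eta <- rep(0, nrow(design))
  for (k in keys) {
    x <- design[[k]]
    x[is.na(x)] <- 0
    eta <- eta + config$hazard_log_hr[[k]] * x
  }
  a <- config$censor_range[1]
  b <- config$censor_range[2]
  h0 <- config$baseline_hazard
  if (is.null(h0)) {
    h0 <- exp(uniroot(function(lh) {
      expected_event_fraction(exp(lh + eta), a, b) -
        config$target_event_fraction
    }, lower = -14, upper = 3, tol = 1e-10)$root)
  }
  h <- h0 * exp(eta)
  t_event <- rexp(length(h), rate = h)
  censor <- runif(length(h), a, b)
  dfs_event <- t_event <= censor
  dfs_months <- pmax(pmin(t_event, censor), 0.03)
  death <- t_event + rexp(length(h), rate = config$os_delay_rate)
  os_event <- death <= censor
  os_months <- pmax(pmin(death, censor), dfs_months)
  list(survival = data.frame(case_id = design$case_id,
                             dfs_months = dfs_months,
                             dfs_event = as.integer(dfs_event),
                             os_months = os_months,
                             os_event = as.integer(os_event),
                             stringsAsFactors = FALSE),
       baseline_hazard = h0, linear_predictor = eta)
}

#' Generate a complete synthetic cohort
#'
#' Two fidelity levels. `"cells"` generates per-ROI tumor-nest geometries
#' and compartment-wise Poisson point patterns, assigns compartments and
#' recomputes densities from the cells exactly as the analysis pipeline
#' does. `"case"` skips coordinates: per-ROI counts are drawn Poisson on
#' simulated compartment areas (for large-n survival studies). In both, the
#' proportional-hazards linear predictor uses the realized median-split
#' flags computed with the same metric code the downstream analysis runs, so
#' configured hazard ratios are recoverable without measurement-error
#' attenuation.
#'
#' @param config A [sim_config()].
#' @param level `"cells"` or `"case"`.
#' @param resolution Band quadrature grid step (um) for `"cells"` level.
#' @return List: `clinical`, `survival`, `metrics`, `cutoffs`, `roi_table`,
#'   `latent` (true case-level intensities), `baseline_hazard`, and (cells
#'   level) `cells` with compartment assignments plus `geometries`.
#' @export
generate_cohort <- function(config = sim_config(),
                            level = c("cells", "case"), resolution = 2) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  set.seed(seed_for(config$seed, "clinical"))
  cl <- generate_clinical(config)
  clinical <- cl$clinical
  set.seed(seed_for(config$seed, "intensity"))
  lam <- latent_intensities(config, clinical, cl$f_case, cl$g_marker)
  roi_ids <- sprintf("roi%d", seq_len(config$rois_per_case))
  cells <- NULL
  geometries <- NULL
  if (level == "cells") {
    all_cells <- list()
    all_areas <- list()
    geometries <- list()
    for (i in seq_len(config$n_cases)) {
      cid <- clinical$case_id[i]
      set.seed(seed_for(config$seed, cid))
      for (r in roi_ids) {
        geom <- generate_geometry(config, cid, r)
        band <- build_stromal_band(geom$tumor, geom$roi, config$band_width,
                                   resolution)
        roi_mult <- exp(config$roi_sdlog * rnorm(4) - config$roi_sdlog^2 / 2)
        names(roi_mult) <- DENSITY_VARS
        pts <- lapply(MARKERS, function(m) {
          sample_tam_points(geom,
                            tumor_intensity = lam[i, paste0("t", m)] *
                              roi_mult[[paste0("t", m)]],
                            stroma_intensity = lam[i, paste0("s", m)] *
                              roi_mult[[paste0("s", m)]],
                            marker = m, band_width = config$band_width,
                            band = band)
        })
        pts <- do.call(rbind, pts)
        pts <- assign_compartment(pts, geom, config$band_width)
        all_cells[[length(all_cells) + 1L]] <- pts
        all_areas[[length(all_areas) + 1L]] <- data.frame(
          case_id = cid, roi_id = r,
          tumor_area = multipolygon_area(geom$tumor) / 1e6,
          stromal_area = band$area_mm2, stringsAsFactors = FALSE)
        geometries[[paste(cid, r, sep = "/")]] <- geom
      }
    }
    cells <- do.call(rbind, all_cells)
    areas <- do.call(rbind, all_areas)
    roi_table <- summarize_rois(cells, areas)
    cm <- compute_case_metrics(roi_table, cells, clinical)
  } else {
    set.seed(seed_for(config$seed, "rois"))
    nroi <- config$n_cases * config$rois_per_case
    grid <- expand.grid(roi_id = roi_ids, case_id = clinical$case_id,
                        stringsAsFactors = FALSE)[, 2:1]
    grid <- grid[order(grid$case_id, grid$roi_id), ]
    tfrac <- runif(nroi, config$tumor_fraction_range[1],
                   config$tumor_fraction_range[2])
    grid$tumor_area <- tfrac * config$roi_area
    grid$stromal_area <- runif(nroi, 0.12, 0.30) * config$roi_area
    rows <- list()
    for (v in DENSITY_VARS) {
      comp <- if (substr(v, 1, 1) == "s") "stroma" else "tumor"
      marker <- sub("^[st]", "", v)
      area <- if (comp == "tumor") grid$tumor_area else grid$stromal_area
      lam_roi <- lam[match(grid$case_id, clinical$case_id), v] *
        exp(config$roi_sdlog * rnorm(nroi) - config$roi_sdlog^2 / 2)
      count <- rpois(nroi, lam_roi * area)
      rows[[v]] <- data.frame(case_id = grid$case_id, roi_id = grid$roi_id,
                              marker = marker, compartment = comp,
                              count = count, area = area,
                              density = count / area,
                              stringsAsFactors = FALSE)
    }
    roi_table <- do.call(rbind, rows)
    roi_table <- roi_table[order(roi_table$case_id, roi_table$roi_id,
                                 roi_table$marker, roi_table$compartment), ]
    rownames(roi_table) <- NULL
    case_level <- aggregate_case(roi_table, cells = NULL)
    # plausible correlated mean stromal distances (no coordinates at this
    # fidelity level)
    z1 <- rnorm(config$n_cases)
    z2 <- 0.64 * z1 + sqrt(1 - 0.64^2) * rnorm(config$n_cases)
    case_level$dist_sCD163 <- pmin(pmax(23 + 3.0 * z1, 5),
                                   config$band_width - 2)
    case_level$dist_sCD206 <- pmin(pmax(24 + 2.5 * z2, 5),
                                   config$band_width - 2)
    cm <- compute_case_metrics(case_level = case_level, clinical = clinical)
  }
  set.seed(seed_for(config$seed, "survival"))
  sv <- generate_survival(config, cm$metrics, clinical)
  out <- list(config = config, clinical = clinical, survival = sv$survival,
              metrics = cm$metrics, cutoffs = cm$cutoffs,
              roi_table = roi_table, latent = lam,
              baseline_hazard = sv$baseline_hazard)
  if (level == "cells") {
    out$cells <- cells
    out$geometries <- geometries
    out$areas <- areas
  }
  out
}
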