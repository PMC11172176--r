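## Case-level TAM variables.
##
## From compartment-assigned cells and per-ROI areas to the six case-level
## spatial variables (sCD163/tCD163/sCD206/tCD206 densities in cells/mm^2,
## mean stromal CD163/CD206 distance to the tumor nest in um), their
## median-cutoff high/low calls, the joint stromal x tumoral four-group
## label per marker, and the four TAM-density-to-sTIL ratio scores.

MARKERS <- c("CD163", "CD206")
DENSITY_VARS <- c("sCD163", "tCD163", "sCD206", "tCD206")

#' Cell density of an ROI compartment
#'
#' @param count Number of marker-positive cells.
#' @param area_mm2 Compartment area in mm^2.
#' @return `count / area_mm2` in cells/mm^2; `NA` (with a warning) when the
#'   area is zero or missing — a degenerate compartment, not zero density.
#' @export
roi_density <- function(count, area_mm2) {
  stopifnot(length(count) == length(area_mm2))
  bad <- is.na(area_mm2) | area_mm2 <= 0
  if (any(bad & !is.na(count) & count > 0))
    warning("positive cell count with zero/missing area: density set to NA")
  d <- ifelse(bad, NA_real_, count / area_mm2)
  as.numeric(d)
}

#' Tabulate per-ROI compartment counts, areas and densities
#'
#' @param cells Compartment-assigned cells (from [assign_compartment()]),
#'   with `case_id`, `roi_id`, `marker`, `compartment` columns.
#' @param areas Data frame with `case_id`, `roi_id`, `tumor_area`,
#'   `stromal_area` (mm^2), one row per ROI.
#' @return Data frame with one row per (case, ROI, marker, compartment) over
#'   compartments `tumor` and `stroma`, including ROIs where the marker has
#'   zero cells.
#' @export
summarize_rois <- function(cells, areas) {
  stopifnot(all(c("case_id", "roi_id", "marker", "compartment") %in%
                  names(cells)),
            all(c("case_id", "roi_id", "tumor_area", "stromal_area") %in%
                  names(areas)))
  grid <- merge(areas[c("case_id", "roi_id", "tumor_area", "stromal_area")],
                expand.grid(marker = MARKERS,
                            compartment = c("tumor", "stroma"),
                            stringsAsFactors = FALSE))
  kept <- cells[cells$compartment %in% c("tumor", "stroma"), ]
  if (nrow(kept)) {
    cnt <- aggregate(list(count = rep(1L, nrow(kept))),
                     kept[c("case_id", "roi_id", "marker", "compartment")],
                     FUN = sum)
  } else {
    cnt <- data.frame(case_id = character(0), roi_id = character(0),
                      marker = character(0), compartment = character(0),
                      count = integer(0))
  }
  out <- merge(grid, cnt, all.x = TRUE,
               by = c("case_id", "roi_id", "marker", "compartment"))
  out$count[is.na(out$count)] <- 0L
  out$area <- ifelse(out$compartment == "tumor",
                     out$tumor_area, out$stromal_area)
  out$density <- suppressWarnings(roi_density(out$count, out$area))
  out <- out[order(out$case_id, out$roi_id, out$marker, out$compartment),
             c("case_id", "roi_id", "marker", "compartment",
               "count", "area", "density")]
  rownames(out) <- NULL
  out
}

#' Aggregate ROI-level quantities to case level
#'
#' Densities are the unweighted mean of per-ROI densities over the ROIs where
#' the compartment exists (`weighting = "roi"`), or the area-weighted pooled
#' density (`weighting = "area"`). Mean stromal distances are cell-weighted:
#' pooled over every stromal cell of the marker across the case's ROIs
#' (`distance = "pooled"`), with a per-ROI-mean alternative.
#'
#' @param roi_table Output of [summarize_rois()].
#' @param cells Compartment-assigned cells (for the distance columns); may be
#'   `NULL`, in which case distances are `NA`.
#' @param weighting `"roi"` (default) or `"area"`.
#' @param distance `"pooled"` (default) or `"roi"`.
#' @return Data frame with one row per case: the four densities and the two
#'   mean distances (missing when no ROI/cell contributes).
#' @export
aggregate_case <- function(roi_table, cells = NULL,
                           weighting = c("roi", "area"),
                           distance = c("pooled", "roi")) {
  weighting <- match.arg(weighting)
  distance <- match.arg(distance)
  case_ids <- sort(unique(roi_table$case_id))
  out <- data.frame(case_id = case_ids, stringsAsFactors = FALSE)
  for (m in MARKERS) {
    for (comp in c("stroma", "tumor")) {
      var <- paste0(substr(comp, 1, 1), m)
      sub <- roi_table[roi_table$marker == m &
                         roi_table$compartment == comp &
                         !is.na(roi_table$density), ]
      val <- if (weighting == "roi") {
        tapply(sub$density, sub$case_id, mean)
      } else {
        tapply(sub$count, sub$case_id, sum) /
          tapply(sub$area, sub$case_id, sum)
      }
      out[[var]] <- as.numeric(val[match(case_ids, names(val))])
    }
  }
  for (m in MARKERS) {
    var <- paste0("dist_s", m)
    if (is.null(cells)) {
      out[[var]] <- NA_real_
      next
    }
    sub <- cells[cells$marker == m & cells$compartment == "stroma", ]
    val <- if (distance == "pooled") {
      tapply(sub$distance_to_tumor, sub$case_id, mean)
    } else {
      roi_means <- aggregate(list(d = sub$distance_to_tumor),
                             sub[c("case_id", "roi_id")], FUN = mean)
      tapply(roi_means$d, roi_means$case_id, mean)
    }
    out[[var]] <- as.numeric(val[match(case_ids, names(val))])
  }
  out
}

#' Median-cutoff dichotomization
#'
#' The cutoff is the sample median of the non-missing values (midpoint
#' convention for even n). High means strictly greater than the cutoff; ties
#' at the median go to low. Missing values stay missing.
#'
#' @param values Numeric vector of per-case values.
#' @return List with `cutoff`, `n` (non-missing count) and `high`, a logical
#'   vector aligned with `values`.
#' @export
dichotomize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to dichotomize")
  cutoff <- median(values[ok])
  high <- values > cutoff
  if (all(!high[ok]))
    warning("all values at or below the median cutoff: everyone low")
  list(cutoff = cutoff, n = sum(ok), high = high)
}

#' Joint stromal x tumoral four-group label
#'
#' @param s_high,t_high Logical high flags for the stromal and tumoral
#'   density of one marker.
#' @return Factor with levels `sLO-tLO`, `sLO-tHI`, `sHI-tLO`, `sHI-tHI`;
#'   missing when either flag is missing.
#' @export
four_group <- function(s_high, t_high) {
  lv <- c("sLO-tLO", "sLO-tHI", "sHI-tLO", "sHI-tHI")
  lab <- ifelse(is.na(s_high) | is.na(t_high), NA_character_,
                paste0(ifelse(s_high, "sHI", "sLO"), "-",
                       ifelse(t_high, "tHI", "tLO")))
  factor(lab, levels = lv)
}

#' TAM-density-to-sTIL ratio score
#'
#' @param density TAM density in cells/mm^2.
#' @param stil Stromal TIL percentage.
#' @return `density / stil` in (cells/mm^2)/%; `NA` (with a warning) when
#'   sTIL is zero; an error on negative inputs. The score is dichotomized at
#'   the cohort median downstream via [dichotomize()].
#' @export
tam_til_ratio <- function(density, stil) {
  if (any(density < 0, na.rm = TRUE) || any(stil < 0, na.rm = TRUE))
    stop("negative density or sTIL value")
  zero <- !is.na(stil) & stil == 0
  if (any(zero))
    warning(sprintf("%d case(s) with sTIL = 0: ratio set to NA", sum(zero)))
  out <- density / stil
  out[zero] <- NA_real_
  out
}

#' Compute the full case-level metric table
#'
#' Runs [aggregate_case()] and derives every dichotomized variable: high/low
#' flags for the four densities and two distances, the per-marker four-group
#' labels, and the four TAM/sTIL ratio scores with their flags. Median
#' cutoffs are computed on all assessable cases in the input (the full-cohort
#' convention; restrict the input first to change it).
#'
#' @param roi_table Output of [summarize_rois()].
#' @param cells Compartment-assigned cells, or `NULL` (no distance metrics).
#' @param clinical Data frame with `case_id` and `til_percent` (needed for
#'   ratio scores; may be `NULL`).
#' @param case_level Optional pre-aggregated case table (one row per case,
#'   densities + distances); used instead of `roi_table`/`cells` when given.
#' @param weighting,distance Passed to [aggregate_case()].
#' @return List with `metrics` (one row per case) and `cutoffs` (named list
#'   of `value`/`n` per dichotomized variable).
#' @export
compute_case_metrics <- function(roi_table = NULL, cells = NULL,
                                 clinical = NULL, case_level = NULL,
                                 weighting = "roi", distance = "pooled") {
  metrics <- if (is.null(case_level)) {
    aggregate_case(roi_table, cells, weighting, distance)
  } else {
    case_level
  }
  cutoffs <- list()
  cut_var <- function(values, name) {
    d <- dichotomize(values)
    cutoffs[[name]] <<- list(value = d$cutoff, n = d$n)
    d$high
  }
  for (v in c(DENSITY_VARS, "dist_sCD163", "dist_sCD206")) {
    flag <- paste0(v, "_high")
    metrics[[flag]] <- if (all(is.na(metrics[[v]]))) NA else
      cut_var(metrics[[v]], v)
  }
  for (m in MARKERS) {
    metrics[[paste0("cd", substr(m, 3, 5), "_four_group")]] <-
      four_group(metrics[[paste0("s", m, "_high")]],
                 metrics[[paste0("t", m, "_high")]])
  }
  if (!is.null(clinical)) {
    stil <- clinical$til_percent[match(metrics$case_id, clinical$case_id)]
    for (v in DENSITY_VARS) {
      rv <- paste0("ratio_", v, "_sTIL")
      metrics[[rv]] <- tam_til_ratio(metrics[[v]], stil)
      metrics[[paste0(rv, "_high")]] <- if (all(is.na(metrics[[rv]]))) NA else
        cut_var(metrics[[rv]], rv)
    }
  }
  list(metrics = metrics, cutoffs = cutoffs)
}
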