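## End-to-end orchestration: input validation, quantify (compartments +
## areas) -> metrics -> associations -> survival, with a run manifest that
## makes case attrition and exclusions auditable.

default_features <- function() {
  list(
    age = list(var = "age", type = "continuous"),
    size = list(var = "size_cm", type = "continuous"),
    til = list(var = "til_high", type = "binary"),
    fibrotic_focus = list(var = "fibrotic_focus", type = "binary"),
    necrosis = list(var = "necrosis", type = "binary"),
    apocrine = list(var = "apocrine", type = "binary"),
    grade = list(var = "grade", type = "ordered"),
    lvi = list(var = "lvi", type = "binary"),
    ln_met = list(var = "ln_met", type = "binary"),
    subtype = list(var = "subtype", type = "nominal"),
    ki67 = list(var = "ki67_high", type = "binary"),
    her2 = list(var = "her2_positive", type = "binary"),
    er = list(var = "er_positive", type = "binary"),
    pr = list(var = "pr_positive", type = "binary"),
    ck14 = list(var = "ck14", type = "binary"),
    p63 = list(var = "p63", type = "binary"),
    pdl1_ic = list(var = "pdl1_ic", type = "binary"))
}

#' Validate pipeline inputs
#'
#' Schema checks on the cell, clinical and survival tables and validity
#' checks on the region geometries (simple rings, tumor inside ROI). Each
#' check yields a machine-readable pass/fail row.
#'
#' @param cells Cell table (or `NULL` to skip).
#' @param geometries Named list of [region_geometry()] (or `NULL`).
#' @param clinical,survival Data frames (or `NULL`).
#' @return Data frame: check, pass, detail.
#' @export
validate_inputs <- function(cells = NULL, geometries = NULL,
                            clinical = NULL, survival = NULL) {
  rows <- list()
  add <- function(check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(check = check, pass = pass,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(cells)) {
    need <- c("case_id", "roi_id", "marker", "x_um", "y_um")
    miss <- setdiff(need, names(cells))
    add("cells: required columns", length(miss) == 0,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
    if (length(miss) == 0) {
      add("cells: known markers", all(cells$marker %in% MARKERS),
          paste(setdiff(unique(cells$marker), MARKERS), collapse = ", "))
      add("cells: finite coordinates",
          all(is.finite(cells$x_um)) && all(is.finite(cells$y_um)))
    }
  }
  if (!is.null(geometries)) {
    for (key in names(geometries)) {
      g <- geometries[[key]]
      simple <- is_simple_ring(g$roi) &&
        all(vapply(g$tumor, is_simple_ring, logical(1)))
      add(sprintf("geometry %s: simple polygons", key), simple)
      inside <- all(vapply(g$tumor, function(ring)
        all(point_in_ring(ring$x, ring$y, g$roi)), logical(1)))
      add(sprintf("geometry %s: tumor inside ROI", key), inside)
      add(sprintf("geometry %s: non-degenerate", key), length(g$tumor) > 0,
          if (length(g$tumor) == 0) "no tumor polygon (excluded from stromal metrics)" else "")
    }
  }
  if (!is.null(clinical)) {
    need <- c("case_id", "til_percent")
    miss <- setdiff(need, names(clinical))
    add("clinical: required columns", length(miss) == 0,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
  }
  if (!is.null(survival)) {
    need <- c("case_id", "dfs_months", "dfs_event", "os_months", "os_event")
    miss <- setdiff(need, names(survival))
    add("survival: required columns", length(miss) == 0,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
    if (length(miss) == 0) {
      add("survival: positive times",
          all(survival$dfs_months > 0) && all(survival$os_months > 0))
      add("survival: DFS <= OS",
          all(survival$dfs_months <= survival$os_months + 1e-9))
    }
  }
  do.call(rbind, rows)
}

#' Run the full spatial-profiling analysis
#'
#' quantify -> metrics -> associate -> survive. Cases present in the cell
#' data but missing from the survival table are analyzed for associations
#' and dropped (with a logged warning) from the survival stage. Case ids in
#' clinical/survival not present in the cell data are a hard error.
#'
#' @param cells Cell table (case_id, roi_id, marker, x_um, y_um).
#' @param geometries Named list of [region_geometry()] keyed
#'   `case_id/roi_id`.
#' @param clinical Clinical covariate table.
#' @param survival Survival table (may omit cases; `NULL` skips the stage).
#' @param band_width Stromal band width in micrometres (default 50).
#' @param p_remove Backward-Wald removal threshold (default 0.10).
#' @param resolution Band quadrature grid step in micrometres.
#' @param out_dir Output directory for stage CSV/JSON files (`NULL`: no
#'   files written).
#' @param stepwise_covariates Covariates for the backward-Wald model
#'   (default: every column of [build_survival_design()] available).
#' @return List of stage outputs plus a `manifest` with config hash and
#'   row counts per stage.
#' @export
run_pipeline <- function(cells, geometries, clinical, survival = NULL,
                         band_width = 50, p_remove = 0.10, resolution = 1,
                         out_dir = NULL, stepwise_covariates = NULL) {
  t0 <- Sys.time()
  config <- list(band_width = band_width, p_remove = p_remove,
                 resolution = resolution)
  extra <- setdiff(clinical$case_id, cells$case_id)
  if (length(extra))
    stop(sprintf("case id(s) in clinical but absent from cells: %s",
                 paste(extra, collapse = ", ")))
  # ---- quantify: compartments + areas ----
  assigned <- list()
  areas <- list()
  excluded_rois <- character(0)
  for (key in names(geometries)) {
    g <- geometries[[key]]
    sub <- cells[cells$case_id == g$case_id & cells$roi_id == g$roi_id, ]
    if (length(g$tumor) == 0) {
      excluded_rois <- c(excluded_rois, key)
      next
    }
    assigned[[key]] <- assign_compartment(sub, g, band_width)
    ar <- region_areas(g, band_width, resolution)
    areas[[key]] <- data.frame(case_id = g$case_id, roi_id = g$roi_id,
                               tumor_area = ar$tumor_area,
                               stromal_area = ar$stromal_area,
                               stringsAsFactors = FALSE)
  }
  if (length(excluded_rois))
    warning(sprintf("degenerate ROI(s) excluded: %s",
                    paste(excluded_rois, collapse = ", ")))
  cells_out <- do.call(rbind, assigned)
  rownames(cells_out) <- NULL
  areas <- do.call(rbind, areas)
  rownames(areas) <- NULL
  # ---- metrics ----
  roi_table <- summarize_rois(cells_out, areas)
  cm <- compute_case_metrics(roi_table, cells_out, clinical)
  metrics <- cm$metrics
  # ---- associations ----
  assoc_data <- merge(clinical, metrics, by = "case_id")
  groups <- intersect(
    c("sCD163_high", "tCD163_high", "sCD206_high", "tCD206_high",
      "dist_sCD163_high", "dist_sCD206_high"), names(assoc_data))
  groups <- groups[vapply(groups, function(g) !all(is.na(assoc_data[[g]])),
                          logical(1))]
  associations <- association_battery(assoc_data, default_features(), groups)
  # ---- survival ----
  surv_out <- NULL
  if (!is.null(survival)) {
    missing_cases <- setdiff(metrics$case_id, survival$case_id)
    if (length(missing_cases))
      warning(sprintf("%d case(s) lack survival data and are dropped from the survival stage: %s",
                      length(missing_cases),
                      paste(missing_cases, collapse = ", ")))
    sd <- merge(survival, merge(metrics, clinical, by = "case_id"),
                by = "case_id")
    ok4 <- !is.na(sd$cd163_four_group)
    km <- km_estimate(sd$dfs_months[ok4], sd$dfs_event[ok4],
                      sd$cd163_four_group[ok4])
    tests <- list()
    for (gvar in c("cd163_four_group", "cd206_four_group")) {
      okg <- !is.na(sd[[gvar]])
      if (sum(sd$dfs_event[okg]) == 0) break
      lr <- tryCatch(logrank_test(sd$dfs_months[okg], sd$dfs_event[okg],
                                  sd[[gvar]][okg]),
                     error = function(e) NULL)
      if (is.null(lr)) next
      tests[[length(tests) + 1L]] <- data.frame(
        endpoint = "DFS", grouping = gvar, test = lr$test,
        statistic = lr$statistic, df = lr$df, p = lr$p,
        stringsAsFactors = FALSE)
    }
    for (rv in grep("^ratio_.*_high$", names(sd), value = TRUE)) {
      for (ep in c("dfs", "os")) {
        if (sum(sd[[paste0(ep, "_event")]]) == 0) next
        lr <- tryCatch(logrank_test(sd[[paste0(ep, "_months")]],
                                    sd[[paste0(ep, "_event")]], sd[[rv]]),
                       error = function(e) NULL)
        if (is.null(lr)) next
        tests[[length(tests) + 1L]] <- data.frame(
          endpoint = toupper(ep), grouping = rv, test = lr$test,
          statistic = lr$statistic, df = lr$df, p = lr$p,
          stringsAsFactors = FALSE)
      }
    }
    design <- build_survival_design(metrics, clinical)
    design <- design[design$case_id %in% sd$case_id, ]
    design <- design[match(sd$case_id, design$case_id), ]
    covs <- stepwise_covariates %||%
      setdiff(names(design), "case_id")
    covs <- covs[vapply(covs, function(v) {
      x <- design[[v]]
      !anyNA(x) && sd(x) > 0
    }, logical(1))]
    cox <- tryCatch(
      backward_stepwise_wald(design[covs], sd$os_months, sd$os_event,
                             p_remove = p_remove),
      error = function(e) {
        warning(sprintf("stepwise Cox failed: %s", conditionMessage(e)))
        NULL
      })
    surv_out <- list(km = km, tests = do.call(rbind, tests), cox = cox)
  }
  manifest <- list(
    config = config, config_hash = config_hash(config),
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    r_version = as.character(getRversion()),
    counts = list(
      cells_in = nrow(cells),
      cells_tumor = sum(cells_out$compartment == "tumor"),
      cells_stroma = sum(cells_out$compartment == "stroma"),
      cells_excluded = sum(cells_out$compartment == "excluded"),
      rois = length(geometries), rois_degenerate = length(excluded_rois),
      cases_metrics = nrow(metrics),
      cases_survival = if (is.null(survival)) 0L else
        length(intersect(metrics$case_id, survival$case_id)),
      associations = nrow(associations)),
    excluded_rois = excluded_rois)
  out <- list(cells = cells_out, areas = areas, roi_table = roi_table,
              metrics = metrics, cutoffs = cm$cutoffs,
              associations = associations, survival = surv_out,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cells_csv(cells_out, file.path(out_dir, "cells.csv"))
    write.csv(areas, file.path(out_dir, "areas.csv"), row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "case_metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(cm$cutoffs, file.path(out_dir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(associations, file.path(out_dir, "associations.csv"),
              row.names = FALSE)
    if (!is.null(surv_out)) {
      write.csv(surv_out$km, file.path(out_dir, "km_curves.csv"),
                row.names = FALSE)
      if (!is.null(surv_out$tests))
        write.csv(surv_out$tests, file.path(out_dir, "survival_tests.csv"),
                  row.names = FALSE)
      if (!is.null(surv_out$cox))
        jsonlite::write_json(
          list(coefficients = surv_out$cox$coefficients,
               trace = surv_out$cox$trace,
               retained = surv_out$cox$retained,
               p_remove = surv_out$cox$p_remove),
          file.path(out_dir, "cox_model.json"), auto_unbox = TRUE,
          digits = NA, dataframe = "rows")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
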