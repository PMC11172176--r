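## Association statistics for the clinico-pathological tables.
##
## Conventions reproduce the cohort analysis they validate against:
## - Pearson chi-square WITHOUT continuity correction for unordered tables;
## - the linear-by-linear (Mantel-Haenszel trend) statistic M^2 = (n-1) r^2,
##   df = 1, for ordered >=3-level rows (tumor grade) against a binary group;
## - Fisher's exact test (probability-mass two-sided rule) for 2x2 tables
##   with any expected count below 5;
## - Spearman rank correlation (t approximation), Mann-Whitney U and
##   Wilcoxon signed-rank with tie-corrected normal approximations.
## No multiplicity adjustment is applied anywhere; every p is reported raw
## with its test name.

#' Statistic container
#'
#' @param test Test name.
#' @param statistic Statistic value.
#' @param df Degrees of freedom (`NA` for exact/rank tests).
#' @param p Two-sided p-value.
#' @param effect Optional effect descriptor (e.g. Spearman rs, odds ratio).
#' @param n Number of observations.
#' @return Object of class `tam_stat`.
#' @export
tam_stat <- function(test, statistic, df = NA_real_, p, effect = NULL,
                     n = NA_integer_) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), effect = effect, n = n),
            class = "tam_stat")
}

#' @export
print.tam_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %s)\n", x$test,
              x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p, x$n))
  if (!is.null(x$effect))
    cat(sprintf("  effect: %s = %.4g\n", names(x$effect)[1], x$effect[[1]]))
  invisible(x)
}

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2x2")
  tab
}

#' Expected counts under independence
#' @param tab Contingency table (matrix of counts).
#' @export
expected_counts <- function(tab) {
  tab <- check_table(tab)
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Pearson chi-square test (no continuity correction)
#'
#' @param tab r x c contingency table with all margins positive.
#' @return A [tam_stat()].
#' @export
pearson_chi2 <- function(tab) {
  tab <- check_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: collapse the level or use fisher_exact()")
  # the small-expected-count caveat is handled by the test-choice rule, so
  # the generic approximation warning is not re-raised here
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tam_stat("pearson_chi2", ct$statistic, ct$parameter, ct$p.value,
           n = sum(tab))
}

#' Linear-by-linear association (chi-square trend) test
#'
#' M^2 = (n - 1) r^2 where r is the Pearson correlation between the row
#' scores and the column indicator over the n subjects; df = 1.
#'
#' @param tab Ordered r x 2 table (r >= 3), rows in score order.
#' @param scores Row scores (default 1, 2, ..., r).
#' @return A [tam_stat()].
#' @export
trend_chi2 <- function(tab, scores = seq_len(nrow(tab))) {
  tab <- check_table(tab)
  if (nrow(tab) < 3) stop("trend test expects >= 3 ordered row levels")
  if (ncol(tab) != 2) stop("trend test expects 2 columns")
  stopifnot(length(scores) == nrow(tab))
  n <- sum(tab)
  w <- as.vector(tab)
  x <- rep(scores, 2)
  y <- rep(c(0, 1), each = nrow(tab))
  mx <- sum(w * x) / n
  my <- sum(w * y) / n
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0)
    stop("degenerate table: no variance in rows or columns")
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  m2 <- (n - 1) * r^2
  tam_stat("trend_chi2", m2, 1, pchisq(m2, 1, lower.tail = FALSE),
           effect = list(r = r), n = n)
}

#' Fisher's exact test (two-sided, probability-mass rule)
#'
#' @param tab 2x2 contingency table.
#' @return A [tam_stat()]. A zero row or column margin gives p = 1.
#' @export
fisher_exact <- function(tab) {
  tab <- check_table(tab)
  if (nrow(tab) != 2 || ncol(tab) != 2) stop("fisher_exact expects 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(tam_stat("fisher_exact", NA_real_, p = 1, n = sum(tab)))
  ft <- fisher.test(tab)
  tam_stat("fisher_exact", NA_real_, p = ft$p.value,
           effect = list(odds_ratio = unname(ft$estimate)), n = sum(tab))
}

#' Deterministic test choice for a contingency table
#'
#' Ordered rows with >= 3 levels use the trend test; a 2x2 table with any
#' expected count below 5 uses Fisher's exact test; everything else uses the
#' uncorrected Pearson chi-square.
#'
#' @param tab Contingency table.
#' @param row_ordered Are the row levels ordered (e.g. tumor grade)?
#' @return Test name: `"trend_chi2"`, `"fisher_exact"` or `"pearson_chi2"`.
#' @export
choose_test <- function(tab, row_ordered = FALSE) {
  tab <- check_table(tab)
  if (row_ordered && nrow(tab) >= 3 && ncol(tab) == 2) return("trend_chi2")
  if (nrow(tab) == 2 && ncol(tab) == 2 && any(expected_counts(tab) < 5))
    return("fisher_exact")
  "pearson_chi2"
}

#' Run the chosen contingency test
#' @inheritParams choose_test
#' @return A [tam_stat()].
#' @export
run_contingency_test <- function(tab, row_ordered = FALSE) {
  switch(choose_test(tab, row_ordered),
         trend_chi2 = trend_chi2(tab),
         fisher_exact = fisher_exact(tab),
         pearson_chi2 = pearson_chi2(tab))
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties; two-sided p by the t approximation.
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return A [tam_stat()] with `effect$rs`.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tam_stat("spearman", ct$statistic, p = ct$p.value,
           effect = list(rs = unname(ct$estimate)), n = length(x))
}

#' Mann-Whitney U test
#'
#' Tie-corrected normal approximation, two-sided, no continuity correction.
#' @param a,b Numeric samples.
#' @return A [tam_stat()]; `statistic` is U for the first sample.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  tam_stat("mann_whitney", wt$statistic, p = wt$p.value,
           n = length(a) + length(b))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; tie-corrected normal approximation,
#' two-sided, no continuity correction.
#' @param a,b Paired numeric vectors.
#' @return A [tam_stat()].
#' @export
wilcoxon_signed_rank <- function(a, b) {
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (all(a == b)) stop("all paired differences are zero: no information")
  wt <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  tam_stat("wilcoxon_signed_rank", wt$statistic, p = wt$p.value,
           n = length(a))
}

#' McNemar test for a paired shift between two dichotomized variables
#'
#' Compares paired high/low calls of two variables on the same cases (e.g.
#' whether stromal-high is more frequent than tumoral-high for one marker).
#' Uncorrected; the convention behind the source cohort's paired comparison
#' is not fully specified, so this implementation is flagged unvalidated.
#'
#' @param flag_a,flag_b Paired logical vectors.
#' @return A [tam_stat()].
#' @export
paired_flag_shift <- function(flag_a, flag_b) {
  ok <- complete.cases(flag_a, flag_b)
  tab <- table(factor(flag_a[ok], levels = c(FALSE, TRUE)),
               factor(flag_b[ok], levels = c(FALSE, TRUE)))
  mt <- mcnemar.test(tab, correct = FALSE)
  tam_stat("mcnemar", mt$statistic, mt$parameter, mt$p.value, n = sum(ok))
}

#' Run the clinico-pathological association battery
#'
#' Cross-tabulates each feature against each high/low grouping variable and
#' applies the test-choice rule ([choose_test()]); continuous features use
#' the Mann-Whitney U test between the two groups.
#'
#' @param data Data frame holding feature and group columns (cases as rows).
#' @param features Named list describing the features: each element is
#'   `list(var = <column>, type = "binary"|"nominal"|"ordered"|"continuous")`.
#' @param groups Character vector of logical (high/low) group columns.
#' @return Tidy data frame: feature, group, test, statistic, df, p, n.
#' @export
association_battery <- function(data, features, groups) {
  rows <- list()
  for (g in groups) {
    gv <- factor(ifelse(data[[g]], "high", "low"), levels = c("low", "high"))
    for (fname in names(features)) {
      f <- features[[fname]]
      fv <- data[[f$var]]
      res <- tryCatch({
        if (f$type == "continuous") {
          mann_whitney(fv[gv == "low"], fv[gv == "high"])
        } else {
          tab <- table(fv, gv)
          tab <- tab[rowSums(tab) > 0, , drop = FALSE]
          run_contingency_test(tab, row_ordered = f$type == "ordered")
        }
      }, error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fname, group = g, test = res$test,
        statistic = if (is.null(res$statistic)) NA_real_ else res$statistic,
        df = res$df, p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
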