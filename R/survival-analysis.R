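## Survival stratification: Kaplan-Meier curves, k-group log-rank tests,
## multivariate Cox proportional-hazards regression (Breslow ties) and
## backward-stepwise-Wald covariate selection. The survival package provides
## the estimators behind this surface; the stepwise procedure (term-wise
## Wald statistics, removal while max p > p_remove, full elimination trace)
## is implemented here.

#' Kaplan-Meier product-limit estimate per group
#'
#' @param time Follow-up times in months (> 0).
#' @param event Event indicator (0/1 or logical).
#' @param group Optional group labels (single group when `NULL`).
#' @return Data frame of step coordinates: group, time, n_risk, n_event,
#'   n_censor, surv. The step function is right-continuous, starts at 1, and
#'   censored subjects leave the risk set after their time.
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(all(time > 0), length(event) == length(time))
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)  # empty factor levels carry no subjects
  if (length(time) == 0 || anyNA(group))
    stop("every group needs at least one subject")
  d <- data.frame(time = time, event = as.integer(event),
                  group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(unique(d$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Log-rank (Mantel-Haenszel) test over k groups
#'
#' @inheritParams km_estimate
#' @param group Group labels, k >= 2 non-empty groups.
#' @return A [tam_stat()] with the chi-square statistic and df = k - 1.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(all(time > 0))
  group <- as.character(group)
  k <- length(unique(group))
  if (k < 2) stop("log-rank needs at least 2 groups")
  if (sum(event) == 0) stop("no events: log-rank statistic undefined")
  d <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- k - 1
  tam_stat("logrank", sd$chisq, df,
           pchisq(sd$chisq, df, lower.tail = FALSE), n = length(time))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling (Efron behind
#' the `ties` flag). Wald confidence intervals and p-values per coefficient.
#'
#' @param data Data frame of covariates (numeric, logical or factor).
#' @param time,event Follow-up times and event indicators.
#' @param covariates Covariate columns to include (default: all columns).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `cox_result`: `coefficients` data frame (term,
#'   coef, hr, ci bounds, wald z, p), `loglik`, `n`, `n_event`, `converged`.
#' @export
cox_fit <- function(data, time, event, covariates = NULL, ties = "breslow",
                    conf_level = 0.95) {
  if (is.null(covariates)) covariates <- names(data)
  stopifnot(length(covariates) >= 1, nrow(data) == length(time))
  if (sum(event) == 0) stop("no events: Cox model undefined")
  for (v in covariates) {
    x <- data[[v]]
    if (is.numeric(x) && sd(x, na.rm = TRUE) == 0)
      stop(sprintf("constant covariate '%s'", v))
  }
  d <- data[covariates]
  d$.time <- time
  d$.event <- as.integer(event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = names(beta), coef = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    ci_lower = exp(unname(beta) - z * unname(se)),
    ci_upper = exp(unname(beta) + z * unname(se)),
    wald_z = unname(beta / se),
    p = 2 * pnorm(-abs(unname(beta / se))),
    stringsAsFactors = FALSE)
  structure(
    list(coefficients = coefs, loglik = fit$loglik[2], n = fit$n,
         n_event = fit$nevent, converged = converged, ties = ties,
         assign = fit$assign, var = fit$var, fit = fit),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_event,
              if (x$converged) "" else " [NON-CONVERGED]"))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  if (!is.null(x$trace) && nrow(x$trace))
    cat(sprintf("Eliminated: %s\n",
                paste(sprintf("%s (p=%.3f)", x$trace$removed,
                              x$trace$p_at_removal), collapse = ", ")))
  invisible(x)
}

# Wald chi-square per model term (multi-df for factor terms) from a fitted
# cox_result, using the coefficient-block mapping in $assign.
term_wald <- function(res) {
  terms <- names(res$assign)
  out <- data.frame(term = terms, wald = NA_real_, df = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  beta <- res$coefficients$coef
  for (i in seq_along(terms)) {
    idx <- res$assign[[i]]
    b <- beta[idx]
    W <- tryCatch(drop(t(b) %*% solve(res$var[idx, idx, drop = FALSE], b)),
                  error = function(e) NA_real_)
    out$wald[i] <- W
    out$df[i] <- length(idx)
    out$p[i] <- pchisq(W, length(idx), lower.tail = FALSE)
  }
  out
}

#' Backward-stepwise covariate selection by Wald statistic
#'
#' Starts from the full multivariate Cox model and iteratively removes the
#' term with the largest Wald p-value while that p exceeds `p_remove`
#' (default 0.10); a term whose final-step p is, say, 0.058 is therefore
#' retained. There is no re-entry step. Factor terms are removed as a block
#' using the multi-df Wald statistic.
#'
#' @inheritParams cox_fit
#' @param p_remove Removal threshold on the Wald p-value (default 0.10).
#' @return A `cox_result` for the final model, with `trace` (data frame of
#'   step, removed term, p at removal) and `retained` attached.
#' @export
backward_stepwise_wald <- function(data, time, event, covariates = NULL,
                                   p_remove = 0.10, ties = "breslow") {
  if (is.null(covariates)) covariates <- names(data)
  current <- covariates
  res <- cox_fit(data, time, event, current, ties = ties)
  if (!res$converged)
    stop("full model did not converge; selection not started")
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_at_removal = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    tw <- term_wald(res)
    worst <- which.max(tw$p)
    if (length(current) == 1 || tw$p[worst] <= p_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = tw$term[worst],
                                     p_at_removal = tw$p[worst],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, tw$term[worst])
    res <- cox_fit(data, time, event, current, ties = ties)
  }
  res$trace <- trace
  res$retained <- current
  res$term_wald <- term_wald(res)
  res$p_remove <- p_remove
  res
}
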