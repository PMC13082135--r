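#' Fit a time-varying Cox model on counting-process intervals
#'
#' Fits `Surv(start, stop, event_interval)` on the given predictor and forced
#' covariate columns with Breslow tie handling, optional site stratification,
#' and cluster-robust (sandwich) variance aggregating score residuals within
#' participant. Constant (zero-variance) columns are non-identifiable and are
#' dropped with a warning rather than returned as NaN; non-convergence and
#' infinite-coefficient warnings are surfaced via the `converged` attribute,
#' never silently.
#'
#' @param intervals interval table (`id,start,stop,event_interval,...`).
#' @param predictor_cols predictor columns of interest.
#' @param forced_cols always-adjusted covariate columns.
#' @param strata_col optional stratification column (baseline hazard varies
#'   by its levels and it is excluded from the linear predictor).
#' @param id_col cluster identifier for the robust variance.
#' @return data frame of class `cox_fit_result`, one row per coefficient:
#'   `predictor, beta, HR, robust_se, ci_low, ci_high, p`, with attributes
#'   `n_subjects`, `n_events`, `converged`, `dropped` (non-identifiable
#'   columns) and `fit` (the underlying model).
#' @export
fit_tv_cox <- function(intervals, predictor_cols, forced_cols = character(0),
                       strata_col = NULL, id_col = "id") {
  n_events <- sum(intervals$event_interval)
  if (n_events == 0) stop("no events in the interval data", call. = FALSE)
  cols <- c(predictor_cols, forced_cols)
  const <- cols[vapply(cols, function(cc) {
    v <- intervals[[cc]]
    all(is.na(v)) || stats::var(v, na.rm = TRUE) == 0
  }, TRUE)]
  if (length(const)) {
    warning(sprintf("non-identifiable constant column(s) dropped: %s",
                    paste(const, collapse = ", ")), call. = FALSE)
    cols <- setdiff(cols, const)
  }
  if (!length(cols)) stop("no identifiable covariates to fit", call. = FALSE)
  rhs <- paste0("`", cols, "`")
  if (!is.null(strata_col)) {
    rhs <- c(rhs, sprintf("survival::strata(`%s`)", strata_col))
  }
  f <- stats::as.formula(paste(
    "survival::Surv(start, stop, event_interval) ~",
    paste(rhs, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = intervals,
                    cluster = intervals[[id_col]],
                    ties = "breslow", x = FALSE, y = FALSE,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  rse <- sqrt(diag(fit$var))       # robust variance (cluster= supplied)
  converged <- all(is.finite(beta)) &&
    !any(grepl("converge|infinite|out of iterations|singular", warns,
               ignore.case = TRUE))
  z <- beta / rse
  res <- data.frame(
    predictor = gsub("`", "", names(beta)),
    beta = unname(beta), HR = exp(unname(beta)),
    robust_se = unname(rse),
    ci_low = exp(unname(beta - 1.959964 * rse)),
    ci_high = exp(unname(beta + 1.959964 * rse)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE)
  attr(res, "n_subjects") <- length(unique(intervals[[id_col]]))
  attr(res, "n_events") <- n_events
  attr(res, "converged") <- converged
  attr(res, "dropped") <- const
  attr(res, "warnings") <- warns
  attr(res, "fit") <- fit
  class(res) <- c("cox_fit_result", class(res))
  res
}

#' Univariate screening with multiple-testing control
#'
#' Fits one time-varying Cox model per candidate predictor (predictor plus
#' the forced covariates), extracts the predictor's own coefficient, and
#' computes Benjamini-Hochberg q-values and Bonferroni-adjusted p-values
#' across the converged fits. Non-converging predictors are recorded with
#' `converged = FALSE`, excluded from the multiplicity family `m`, and their
#' count is reported via a message.
#'
#' @inheritParams fit_tv_cox
#' @param candidates candidate predictor columns, screened one at a time.
#' @param domain_map optional named character vector predictor -> domain.
#' @return data frame of class `screen_result`: one row per candidate with
#'   `beta, HR, robust_se, ci_low, ci_high, p, q, p_bonf, n_subjects,
#'   n_events, converged, domain`.
#' @export
screen_univariate <- function(intervals, candidates,
                              forced_cols = character(0),
                              strata_col = NULL, id_col = "id",
                              domain_map = NULL) {
  rows <- lapply(candidates, function(cc) {
    r <- tryCatch(
      fit_tv_cox(intervals, cc, forced_cols, strata_col, id_col),
      error = function(e) NULL)
    if (is.null(r) || !cc %in% r$predictor) {
      return(data.frame(predictor = cc, beta = NA_real_, HR = NA_real_,
                        robust_se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n_subjects = NA_integer_, n_events = NA_integer_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    row <- r[r$predictor == cc, , drop = FALSE]
    row$n_subjects <- attr(r, "n_subjects")
    row$n_events <- attr(r, "n_events")
    row$converged <- attr(r, "converged")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$converged & !is.na(out$p)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf(
      "screen_univariate: %d predictor(s) did not converge; excluded from the multiplicity family",
      n_bad))
  }
  out$q <- NA_real_
  out$p_bonf <- NA_real_
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$p_bonf[ok] <- stats::p.adjust(out$p[ok], method = "bonferroni")
  out$domain <- if (is.null(domain_map)) NA_character_ else
    unname(domain_map[out$predictor])
  class(out) <- c("screen_result", class(out))
  out
}

#' Pre-selection: univariate evidence plus participant coverage
#'
#' Keeps predictors whose univariate screening p-value is at most `p_enter`
#' and that pass the participant-coverage filter on pre-imputation values.
#'
#' @param screen a [screen_univariate()] result.
#' @param coverage_table long table with raw (pre-imputation) predictor
#'   values, used by [coverage_filter()].
#' @param p_enter screening p-value threshold (default 0.05).
#' @param min_frac minimum coverage fraction (default 0.5).
#' @param id_col participant identifier column.
#' @return character vector of retained predictor names.
#' @export
prescreen <- function(screen, coverage_table, p_enter = 0.05,
                      min_frac = 0.5, id_col = "id") {
  hits <- screen$predictor[!is.na(screen$p) & screen$p <= p_enter &
                             screen$converged]
  hits <- hits[hits %in% names(coverage_table)]
  coverage_filter(coverage_table, hits, min_frac, id_col)
}

#' LASSO screening of prescreened predictors
#'
#' L1-penalized Cox regression used as a screening step. By default each
#' interval's end time is treated as an independent right-censored
#' observation (ignoring late entry) -- an approximation that makes standard
#' coordinate-descent LASSO applicable to start-stop data; set
#' `use_start_stop = TRUE` for exact (start, stop] risk sets. Forced
#' covariates are unpenalized. The penalty is chosen by k-fold
#' cross-validation with whole participants assigned to folds (respecting
#' clustering); `one_se = TRUE` selects the 1-SE penalty instead of the
#' deviance minimizer. A fixed `lambda` bypasses cross-validation.
#'
#' @inheritParams fit_tv_cox
#' @param predictors penalized candidate columns.
#' @param k_folds number of CV folds (default 10).
#' @param seed seed for fold assignment.
#' @param lambda optional fixed penalty (skips CV); `0` reduces to the
#'   unpenalized fit, very large values select nothing.
#' @param use_start_stop use exact counting-process risk sets.
#' @param one_se use the 1-SE rule.
#' @return character vector of predictors with nonzero coefficients at the
#'   selected penalty (possibly empty, with a warning).
#' @export
lasso_screen <- function(intervals, predictors, forced_cols = character(0),
                         k_folds = 10, seed = NULL, lambda = NULL,
                         use_start_stop = FALSE, one_se = FALSE,
                         id_col = "id") {
  cols <- c(predictors, forced_cols)
  x <- as.matrix(intervals[cols])
  if (any(is.na(x))) stop("predictors must be complete (impute first)")
  y <- if (use_start_stop) {
    survival::Surv(intervals$start, intervals$stop, intervals$event_interval)
  } else {
    survival::Surv(intervals$stop, intervals$event_interval)
  }
  pf <- c(rep(1, length(predictors)), rep(0, length(forced_cols)))
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", penalty.factor = pf,
                          lambda = lambda, standardize = TRUE)
    b <- as.matrix(stats::coef(fit))[, 1]
  } else {
    if (!is.null(seed)) set.seed(seed)
    ids <- unique(intervals[[id_col]])
    fold_of_id <- sample(rep_len(seq_len(k_folds), length(ids)))
    foldid <- fold_of_id[match(intervals[[id_col]], ids)]
    cv <- glmnet::cv.glmnet(x, y, family = "cox", penalty.factor = pf,
                            foldid = foldid, standardize = TRUE)
    s <- if (one_se) cv$lambda.1se else cv$lambda.min
    b <- as.matrix(stats::coef(cv, s = s))[, 1]
  }
  sel <- intersect(names(b)[b != 0], predictors)
  if (!length(sel)) {
    warning("LASSO selected no predictors; the multivariable model will contain forced covariates only",
            call. = FALSE)
  }
  sel
}

#' Final site-stratified multivariable Cox model
#'
#' Fits the selected predictors (plus any `<X>_obs` availability companions
#' present in the data) together with the forced covariates in a single
#' counting-process Cox model, stratified by site, with cluster-robust
#' standard errors. BH q-values and Bonferroni-adjusted p-values are computed
#' across the non-forced coefficients.
#'
#' @inheritParams fit_tv_cox
#' @param selected selected predictor columns.
#' @param include_obs also include `<X>_obs` companions when present.
#' @return a `screen_result` data frame over the selected (non-forced)
#'   coefficients, with the full `cox_fit_result` in `attr(, "fit_result")`.
#' @export
fit_multivariable <- function(intervals, selected,
                              forced_cols = character(0),
                              strata_col = "site", id_col = "id",
                              include_obs = TRUE) {
  preds <- selected
  if (include_obs) {
    obs <- paste0(selected, "_obs")
    preds <- c(selected, obs[obs %in% names(intervals)])
  }
  r <- fit_tv_cox(intervals, preds, forced_cols, strata_col, id_col)
  out <- r[r$predictor %in% preds, , drop = FALSE]
  out$n_subjects <- rep(attr(r, "n_subjects"), nrow(out))
  out$n_events <- rep(attr(r, "n_events"), nrow(out))
  out$converged <- rep(attr(r, "converged"), nrow(out))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$p_bonf <- stats::p.adjust(out$p, method = "bonferroni")
  out$domain <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", class(out))
  attr(out, "fit_result") <- r
  out
}

#' Write a screening or multivariable result table as TSV
#'
#' @param result a `screen_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(result, path) {
  cols <- intersect(c("predictor", "beta", "HR", "ci_low", "ci_high",
                      "robust_se", "p", "q", "p_bonf", "n_subjects",
                      "n_events", "converged", "domain"), names(result))
  utils::write.table(result[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
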