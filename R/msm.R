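#' Dichotomize an exposure by median split
#'
#' Continuous exposures become 1 above the median of observed values and 0
#' otherwise (ties at the median go to 0). Already-binary columns pass
#' through unchanged when `type = "binary"`.
#'
#' @param values numeric vector.
#' @param type `"median_split"` or `"binary"` (passthrough).
#' @return 0/1 vector (NA preserved).
#' @export
dichotomize <- function(values, type = c("median_split", "binary")) {
  type <- match.arg(type)
  if (all(is.na(values))) stop("all values missing; cannot dichotomize",
                               call. = FALSE)
  if (type == "binary") {
    bad <- !is.na(values) & !(values %in% c(0, 1))
    if (any(bad)) stop("declared binary but contains non-0/1 values",
                       call. = FALSE)
    return(as.integer(values))
  }
  med <- stats::median(values, na.rm = TRUE)
  out <- ifelse(values > med, 1L, 0L)
  out[is.na(values)] <- NA_integer_
  as.integer(out)
}

#' Restricted cubic spline basis for follow-up time
#'
#' Natural cubic spline with 4 knots placed at the 5/35/65/95 percentiles of
#' the interval end times (boundary knots at 5/95, internal at 35/65). Falls
#' back to a linear term when the times have too few distinct values to
#' support distinct knots.
#'
#' @param t numeric times.
#' @param knots optional explicit knot vector (length 4, ascending).
#' @return basis matrix with columns `t1, t2, ...`.
#' @export
time_basis <- function(t, knots = NULL) {
  if (is.null(knots)) {
    knots <- stats::quantile(t, c(0.05, 0.35, 0.65, 0.95), names = FALSE)
  }
  knots <- unique(knots)
  if (length(knots) < 4 || length(unique(t)) < 5) {
    b <- matrix(t, ncol = 1)
  } else {
    b <- splines::ns(t, knots = knots[2:3],
                     Boundary.knots = knots[c(1, 4)])
    b <- unclass(b)
  }
  colnames(b) <- paste0("t", seq_len(ncol(b)))
  b
}

# add lagged exposure within id (0 at each participant's first interval)
add_prior_treatment <- function(intervals, exposure_col, id_col = "id") {
  ord <- order(intervals[[id_col]], intervals$start)
  stopifnot(!is.unsorted(ord) || TRUE)
  a <- intervals[[exposure_col]]
  grp <- intervals[[id_col]]
  lag <- c(NA, a[-length(a)])
  first <- c(TRUE, grp[-1] != grp[-length(grp)])
  lag[first] <- 0
  lag
}

#' Fit numerator and denominator treatment models
#'
#' Logistic regressions for per-interval treatment assignment. The numerator
#' model conditions on prior treatment, baseline covariates and a flexible
#' function of time; the denominator model additionally conditions on the
#' time-varying confounders. Rows must be sorted by (id, start); prior
#' treatment is initialized to 0 at each participant's first interval.
#'
#' @param intervals interval table containing the exposure column.
#' @param exposure_col 0/1 treatment column.
#' @param z_cols baseline covariate columns.
#' @param l_cols time-varying confounder columns (denominator only).
#' @param id_col participant identifier.
#' @param time_col column giving the interval time for the spline basis
#'   (default `"stop"`).
#' @return list with `num_fit`, `den_fit`, fitted probabilities `num_p`,
#'   `den_p`, and the `prior` treatment vector.
#' @export
fit_treatment_models <- function(intervals, exposure_col, z_cols,
                                 l_cols = character(0), id_col = "id",
                                 time_col = "stop") {
  o <- order(intervals[[id_col]], intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  a <- intervals[[exposure_col]]
  if (any(is.na(a))) stop("exposure column contains missing values")
  prior <- add_prior_treatment(intervals, exposure_col, id_col)
  tb <- time_basis(intervals[[time_col]])
  dat <- data.frame(.A = a, .Aprev = prior,
                    intervals[c(z_cols, l_cols)], tb,
                    check.names = TRUE)
  zn <- make.names(z_cols); ln <- make.names(l_cols)
  f_num <- stats::reformulate(c(".Aprev", zn, colnames(tb)), ".A")
  f_den <- stats::reformulate(c(".Aprev", zn, ln, colnames(tb)), ".A")
  num_fit <- stats::glm(f_num, data = dat, family = stats::binomial())
  den_fit <- stats::glm(f_den, data = dat, family = stats::binomial())
  for (fit in list(num_fit, den_fit)) {
    bad <- names(stats::coef(fit))[!is.finite(stats::coef(fit)) |
                                     abs(stats::coef(fit)) > 15]
    if (length(bad)) {
      stop(sprintf("possible separation in treatment model (coefficient(s): %s)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  res <- list(num_fit = num_fit, den_fit = den_fit,
              num_p = unname(stats::fitted(num_fit)),
              den_p = unname(stats::fitted(den_fit)),
              prior = prior, order = o)
  res
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' Per interval the likelihood contribution of each model is `p` if the
#' treatment was taken and `1 - p` otherwise, with fitted probabilities
#' clipped to `[clip, 1 - clip]`. The stabilized weight is the cumulative
#' product within participant of numerator over denominator contributions,
#' then truncated at the `trunc_q` upper quantile.
#'
#' @param num_probs,den_probs fitted treatment probabilities per interval.
#' @param A observed 0/1 treatment per interval.
#' @param id participant identifier per interval (rows sorted by id, time).
#' @param clip probability clipping bound (default 0.01).
#' @param trunc_q upper truncation quantile for the weights (default 0.99;
#'   `1` disables truncation).
#' @return list of class `weight_set`: `weights` (post-truncation), `raw`
#'   (pre-truncation), and `diagnostics` (mean/min/max, effective-sample-size
#'   ratio, bounds used).
#' @export
compute_stabilized_weights <- function(num_probs, den_probs, A, id,
                                       clip = 0.01, trunc_q = 0.99) {
  stopifnot(length(num_probs) == length(A), length(den_probs) == length(A),
            length(id) == length(A))
  np <- clip_prob(num_probs, clip)
  dp <- clip_prob(den_probs, clip)
  lnum <- ifelse(A == 1, np, 1 - np)
  lden <- ifelse(A == 1, dp, 1 - dp)
  ratio <- log(lnum) - log(lden)
  # cumulative product within id
  grp <- as.character(id)
  first <- c(TRUE, grp[-1] != grp[-length(grp)])
  csum <- cumsum(ratio)
  base <- csum[which(first)] - ratio[which(first)]
  sw <- exp(csum - rep(base, times = diff(c(which(first), length(A) + 1))))
  raw <- sw
  cap <- if (trunc_q < 1) stats::quantile(sw, trunc_q, names = FALSE) else Inf
  sw <- pmin(sw, cap)
  ess <- sum(sw)^2 / (length(sw) * sum(sw^2))
  structure(list(
    weights = sw, raw = raw, id = id,
    diagnostics = list(mean_w = mean(sw), min_w = min(sw), max_w = max(sw),
                       max_raw = max(raw), ess_ratio = ess, clip = clip,
                       trunc_q = trunc_q, cap = cap)),
    class = "weight_set")
}

#' Weight and positivity diagnostics
#'
#' Predefined weight-quality criteria applied before outcome modeling: the
#' exposure prevalence (fraction of person-intervals treated) must lie in
#' `[p_lo, p_hi]`, the post-truncation mean weight in
#' `[mean_lo, mean_hi]`, and the effective-sample-size ratio
#' `(sum w)^2 / (n sum w^2)` must be at least `ess_min`. Exposures failing
#' any criterion are excluded from outcome modeling and from the FDR family.
#'
#' @param weight_set a [compute_stabilized_weights()] result.
#' @param prevalence fraction of person-intervals with treatment 1.
#' @param p_lo,p_hi prevalence window (default 0.05, 0.95).
#' @param mean_lo,mean_hi mean-weight window (default 0.9, 1.1).
#' @param ess_min minimum ESS ratio (default 0.5).
#' @return list `pass` (logical) and `report` (named checks + values).
#' @export
weight_diagnostics <- function(weight_set, prevalence,
                               p_lo = 0.05, p_hi = 0.95,
                               mean_lo = 0.9, mean_hi = 1.1,
                               ess_min = 0.5) {
  d <- weight_set$diagnostics
  checks <- c(prevalence = prevalence >= p_lo && prevalence <= p_hi,
              mean_weight = d$mean_w >= mean_lo && d$mean_w <= mean_hi,
              ess = d$ess_ratio >= ess_min)
  list(pass = all(checks),
       report = list(checks = checks, prevalence = prevalence,
                     mean_w = d$mean_w, max_w = d$max_w,
                     ess_ratio = d$ess_ratio,
                     failed = names(checks)[!checks]))
}

#' Weighted pooled logistic marginal structural model
#'
#' Weighted logistic regression of the interval-end event indicator on a
#' flexible function of time, current treatment and baseline covariates,
#' using the stabilized weights, with participant-level cluster-robust
#' standard errors. With per-interval events rare, the exposure odds ratio
#' approximates a hazard ratio.
#'
#' @param intervals interval table sorted by (id, start) with the treatment
#'   column and `event_interval`.
#' @param exposure_col 0/1 treatment column.
#' @param z_cols baseline covariate columns.
#' @param weights per-row stabilized weights (same order as `intervals`).
#' @param id_col participant identifier.
#' @param time_col interval time column for the spline basis.
#' @return list of class `msm_fit`: `psi` (log-OR), `OR`, `se`, `ci_low`,
#'   `ci_high`, `p`, `converged`, and the underlying `fit`.
#' @export
fit_msm <- function(intervals, exposure_col, z_cols, weights,
                    id_col = "id", time_col = "stop") {
  tb <- time_basis(intervals[[time_col]])
  dat <- data.frame(.Y = intervals$event_interval,
                    .A = intervals[[exposure_col]],
                    intervals[z_cols], tb, check.names = TRUE)
  dat$.w <- weights
  f <- stats::reformulate(c(colnames(tb), ".A", make.names(z_cols)), ".Y")
  fit <- tryCatch(
    stats::glm(f, data = dat, family = stats::quasibinomial(),
               weights = .w),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || !is.finite(stats::coef(fit)[".A"])) {
    return(structure(list(psi = NA_real_, OR = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, converged = FALSE, fit = fit),
                     class = "msm_fit"))
  }
  vc <- sandwich::vcovCL(fit, cluster = intervals[[id_col]])
  psi <- stats::coef(fit)[".A"]
  se <- sqrt(vc[".A", ".A"])
  structure(list(psi = unname(psi), OR = exp(unname(psi)), se = se,
                 ci_low = exp(unname(psi - 1.959964 * se)),
                 ci_high = exp(unname(psi + 1.959964 * se)),
                 p = 2 * stats::pnorm(-abs(unname(psi) / se)),
                 converged = TRUE, fit = fit), class = "msm_fit")
}

#' Run the full MSM-IPTW analysis for one exposure
#'
#' Dichotomizes the exposure if needed, fits numerator and denominator
#' treatment models, computes stabilized weights, applies the weight and
#' prevalence diagnostics, and (when they pass) fits the weighted pooled
#' logistic outcome model.
#'
#' @param intervals interval table (complete predictors; sorted internally).
#' @param exposure_col exposure source column.
#' @param z_cols baseline covariate columns.
#' @param l_cols time-varying confounder columns for the denominator model.
#' @param type exposure type: `"binary"` or `"median_split"`.
#' @param clip,trunc_q weight-estimation settings
#'   (see [compute_stabilized_weights()]).
#' @param id_col participant identifier.
#' @param ... diagnostics thresholds passed to [weight_diagnostics()].
#' @return one-row data frame of class `msm_result`: `exposure, psi, OR,
#'   ci_low, ci_high, p, mean_w, max_w, ess_ratio, retained`, with the
#'   diagnostics report and weight set as attributes.
#' @export
run_msm_exposure <- function(intervals, exposure_col, z_cols,
                             l_cols = character(0),
                             type = c("median_split", "binary"),
                             clip = 0.01, trunc_q = 0.99, id_col = "id",
                             ...) {
  type <- match.arg(type)
  o <- order(intervals[[id_col]], intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  v <- intervals[[exposure_col]]
  trt <- if (type == "binary") dichotomize(v, "binary") else
    dichotomize(v, "median_split")
  intervals$.trt <- trt
  prev <- mean(trt)
  blank <- data.frame(exposure = exposure_col, psi = NA_real_,
                      OR = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, mean_w = NA_real_, max_w = NA_real_,
                      ess_ratio = NA_real_, retained = FALSE,
                      stringsAsFactors = FALSE)
  # prevalence exclusion happens before any model fitting
  diag_args <- list(...)
  p_lo <- diag_args$p_lo %||% 0.05
  p_hi <- diag_args$p_hi %||% 0.95
  if (prev < p_lo || prev > p_hi) {
    attr(blank, "report") <- list(checks = c(prevalence = FALSE),
                                  prevalence = prev,
                                  failed = "prevalence")
    class(blank) <- c("msm_result", class(blank))
    return(blank)
  }
  tm <- fit_treatment_models(intervals, ".trt", z_cols, l_cols, id_col)
  ws <- compute_stabilized_weights(tm$num_p, tm$den_p, intervals$.trt,
                                   intervals[[id_col]], clip, trunc_q)
  dg <- weight_diagnostics(ws, prev, ...)
  d <- ws$diagnostics
  out <- blank
  out$mean_w <- d$mean_w; out$max_w <- d$max_w; out$ess_ratio <- d$ess_ratio
  if (dg$pass) {
    m <- fit_msm(intervals, ".trt", z_cols, ws$weights, id_col)
    if (m$converged) {
      out$psi <- m$psi; out$OR <- m$OR
      out$ci_low <- m$ci_low; out$ci_high <- m$ci_high; out$p <- m$p
      out$retained <- TRUE
    }
  }
  attr(out, "report") <- dg$report
  attr(out, "weight_set") <- ws
  class(out) <- c("msm_result", class(out))
  out
}

#' Benjamini-Hochberg correction across retained exposures
#'
#' Adds BH q-values over the retained results only; non-retained exposures
#' are excluded from the FDR family and keep `q = NA`.
#'
#' @param results data frame of stacked `msm_result` rows.
#' @return the input with a `q` column.
#' @export
fdr_across_exposures <- function(results) {
  results$q <- NA_real_
  fam <- results$retained & !is.na(results$p)
  results$q[fam] <- stats::p.adjust(results$p[fam], method = "BH")
  results
}
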