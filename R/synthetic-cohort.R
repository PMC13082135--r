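#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate an ABCD-like design: ~4 years of follow-up with annual
#' in-person visits and mid-year phone contacts (visits every 6 months),
#' baseline age drawn as 12 x (9.91 +/- 0.62) months, 20 ancestry principal
#' components and 4 polygenic risk scores, a time-varying confounder with
#' AR(1) structure and exposure feedback, and per-substance discrete-time
#' initiation processes whose intercepts are calibrated so that cumulative
#' incidence over follow-up is roughly 36.5% (alcohol-like), 5.44%
#' (nicotine-like) and 3.42% (cannabis-like).
#'
#' @param n_participants number of participants.
#' @param visit_months strictly increasing visit times in months, starting at 0.
#' @param n_sites number of recruitment sites.
#' @param n_pcs number of ancestry principal components.
#' @param n_prs number of polygenic risk score columns.
#' @param rho_L AR(1) coefficient of the time-varying confounder L.
#' @param kappa_feedback effect of prior exposure A on the next confounder
#'   value (treatment-confounder feedback; set 0 for no feedback).
#' @param a_coefs list with elements `intercept`, `confounder`,
#'   `prior_exposure` and `baseline` (length-3 vector for sex, standardized
#'   baseline age, first PRS) defining the exposure assignment model
#'   `P(A_k = 1) = expit(a0 + a1 L_k + a2 A_{k-1} + a3' Z)`.
#' @param psi_true causal log odds ratio of exposure on the per-interval
#'   event probability.
#' @param delta_L confounder effect on the event logit.
#' @param eta_Z length-3 vector of baseline-covariate effects (sex,
#'   standardized baseline age, first PRS) on the event logit.
#' @param base_hazard named list of per-outcome `c(intercept, slope)` for the
#'   event logit `alpha0 + alpha1 * t`; one latent initiation process per
#'   entry. The first entry is the primary outcome used for causal ground
#'   truth.
#' @param miss_rate_visit per-visit MCAR dropout probability (baseline visit
#'   is always retained so every participant has a time origin).
#' @param miss_rate_cell per-cell MCAR missingness probability applied to
#'   measurement columns.
#' @param relig_rate probability that a participant's first alcohol (or
#'   nicotine) endorsement is flagged as occurring exclusively in a religious
#'   context.
#' @param monotone_dropout if `TRUE`, visit dropout is monotone (once missed,
#'   all later visits are missed).
#' @param n_mc_truth Monte-Carlo sample size for the counterfactual marginal
#'   odds ratio reported in the ground-truth object.
#' @param compute_truth compute the counterfactual marginal OR (set `FALSE`
#'   to skip the extra simulation).
#' @param seed integer seed; the truth simulation uses `seed + 1`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       visit_months = seq(0, 48, by = 6),
                       n_sites = 20,
                       n_pcs = 20,
                       n_prs = 4,
                       rho_L = 0.6,
                       kappa_feedback = 0.4,
                       a_coefs = list(intercept = -0.4, confounder = 0.6,
                                      prior_exposure = 0.8,
                                      baseline = c(0, 0, 0.2)),
                       psi_true = log(2),
                       delta_L = 0.3,
                       eta_Z = c(0.1, 0, 0.3),
                       base_hazard = default_base_hazard(),
                       miss_rate_visit = 0.1,
                       miss_rate_cell = 0.1,
                       relig_rate = 0.05,
                       monotone_dropout = FALSE,
                       n_mc_truth = 1e5,
                       compute_truth = TRUE,
                       seed = 1L) {
  if (!is_count(n_participants)) stop_config("n_participants", "must be a count >= 1")
  if (length(visit_months) < 2 || visit_months[1] != 0 ||
      any(diff(visit_months) <= 0)) {
    stop_config("visit_months", "must be strictly increasing and start at 0")
  }
  if (!is_count(n_sites)) stop_config("n_sites", "must be a count >= 1")
  if (!is_count(n_pcs)) stop_config("n_pcs", "must be a count >= 1")
  if (!is_count(n_prs)) stop_config("n_prs", "must be a count >= 1")
  for (f in c("miss_rate_visit", "miss_rate_cell", "relig_rate")) {
    if (!is_prob(get(f))) stop_config(f, "must be a probability in [0, 1]")
  }
  need <- c("intercept", "confounder", "prior_exposure", "baseline")
  if (!is.list(a_coefs) || !all(need %in% names(a_coefs))) {
    stop_config("a_coefs", sprintf("must be a list with elements %s",
                                   paste(need, collapse = ", ")))
  }
  if (length(a_coefs$baseline) != 3L) stop_config("a_coefs", "baseline must have length 3")
  if (length(eta_Z) != 3L) stop_config("eta_Z", "must have length 3")
  if (!is.list(base_hazard) || is.null(names(base_hazard)) ||
      any(!nzchar(names(base_hazard))) ||
      !all(vapply(base_hazard, function(b) is.numeric(b) && length(b) == 2L, TRUE))) {
    stop_config("base_hazard", "must be a named list of c(intercept, slope)")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed", "must be a single integer")
  }
  structure(list(
    n_participants = as.integer(n_participants), visit_months = visit_months,
    n_sites = as.integer(n_sites), n_pcs = as.integer(n_pcs),
    n_prs = as.integer(n_prs), rho_L = rho_L,
    kappa_feedback = kappa_feedback, a_coefs = a_coefs, psi_true = psi_true,
    delta_L = delta_L, eta_Z = eta_Z, base_hazard = base_hazard,
    miss_rate_visit = miss_rate_visit, miss_rate_cell = miss_rate_cell,
    relig_rate = relig_rate, monotone_dropout = monotone_dropout,
    n_mc_truth = n_mc_truth, compute_truth = compute_truth,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default per-outcome baseline event logits
#'
#' Intercepts of the per-interval event logit, calibrated by Monte Carlo under
#' the default causal parameters so that cumulative incidence over the default
#' 8 half-year intervals is approximately 0.365 (alcohol-like), 0.0544
#' (nicotine-like), 0.0342 (cannabis-like) and ~1% (other substances). Slopes
#' default to 0 (flat discrete-time baseline hazard).
#'
#' @return named list of `c(intercept, slope)`.
#' @export
default_base_hazard <- function() {
  list(alcohol  = c(-3.5425, 0),
       nicotine = c(-5.7326, 0),
       cannabis = c(-6.2257, 0),
       other    = c(-7.4495, 0))
}

#' Default visit labels for the synthetic schedule
#'
#' Annual in-person visits (baseline, FU1..FU4) interleaved with mid-year
#' phone contacts, in chronological order. These are also the visit-order key
#' used when harmonizing endorsement sources.
#'
#' @param n_visits number of visits (default 9: months 0, 6, ..., 48).
#' @return character vector of ordered visit labels.
#' @export
default_visit_levels <- function(n_visits = 9L) {
  ann <- c("baseline", paste0("FU", 1:4))
  pho <- paste0("phone_", sprintf("%02d", seq(6, 42, by = 12)))
  lab <- character(2L * length(ann) - 1L)
  lab[seq(1, length(lab), by = 2)] <- ann
  lab[seq(2, length(lab), by = 2)] <- pho
  lab[seq_len(n_visits)]
}

#' Simulate a binary exposure sequence given a confounder path
#'
#' Draws `A_k ~ Bernoulli(expit(a0 + a1 L_k + a2 A_{k-1} + a3' Z))` with the
#' exposure history initialized to 0 before the first visit. Uses the current
#' RNG state.
#'
#' @param L_path numeric vector (one participant) or matrix (participants x
#'   visits) of confounder values.
#' @param Z numeric vector (length 3) or matrix (participants x 3) of baseline
#'   covariates entering the exposure model.
#' @param a_coefs coefficient list as in [sim_config()].
#' @return 0/1 vector or matrix matching `L_path`.
#' @export
simulate_exposure_history <- function(L_path, Z, a_coefs) {
  vec <- is.null(dim(L_path))
  L <- if (vec) matrix(L_path, nrow = 1) else as.matrix(L_path)
  Zm <- if (is.null(dim(Z))) matrix(Z, nrow = nrow(L), ncol = length(Z),
                                    byrow = TRUE) else as.matrix(Z)
  if (nrow(Zm) != nrow(L)) stop("dimension error: Z rows must match L_path rows")
  if (ncol(Zm) != length(a_coefs$baseline)) {
    stop("dimension error: ncol(Z) must match length(a_coefs$baseline)")
  }
  n <- nrow(L); K <- ncol(L)
  zlin <- drop(Zm %*% a_coefs$baseline)
  A <- matrix(0L, n, K)
  prev <- numeric(n)
  for (k in seq_len(K)) {
    p <- expit(a_coefs$intercept + a_coefs$confounder * L[, k] +
                 a_coefs$prior_exposure * prev + zlin)
    A[, k] <- stats::rbinom(n, 1L, p)
    prev <- A[, k]
  }
  if (vec) drop(A) else A
}

# joint simulation of confounder (AR(1) + exposure feedback) and exposure
simulate_confounder_exposure <- function(n, K, rho_L, kappa, a_coefs, Z) {
  L <- matrix(0, n, K)
  A <- matrix(0L, n, K)
  zlin <- drop(Z %*% a_coefs$baseline)
  prevA <- numeric(n); prevL <- numeric(n)
  for (k in seq_len(K)) {
    L[, k] <- if (k == 1) stats::rnorm(n) else
      rho_L * prevL + kappa * prevA + stats::rnorm(n)
    p <- expit(a_coefs$intercept + a_coefs$confounder * L[, k] +
                 a_coefs$prior_exposure * prevA + zlin)
    A[, k] <- stats::rbinom(n, 1L, p)
    prevL <- L[, k]; prevA <- A[, k]
  }
  list(L = L, A = A)
}

#' Simulate discrete-time initiation events
#'
#' Per interval k (from visit k to visit k+1) the event probability is
#' `expit(alpha0 + alpha1 * t_k + psi * A_k + delta_L * L_k + eta_Z' Z)` with
#' `t_k` the interval start in months. The first success sets the event time
#' to the interval's end visit; participants with no success are censored at
#' the last visit. Uses the current RNG state.
#'
#' @param A,L participants x visits exposure and confounder matrices (or
#'   vectors for one participant).
#' @param Z baseline covariate vector/matrix (3 columns).
#' @param psi_true,delta_L,eta_Z event-model coefficients.
#' @param base_hazard numeric `c(intercept, slope)`.
#' @param visit_months visit times in months.
#' @return list with `time` (months) and `event` (0/1) per participant.
#' @export
simulate_events <- function(A, L, Z, psi_true, delta_L, eta_Z, base_hazard,
                            visit_months) {
  vec <- is.null(dim(A))
  Am <- if (vec) matrix(A, nrow = 1) else as.matrix(A)
  Lm <- if (vec) matrix(L, nrow = 1) else as.matrix(L)
  Zm <- if (is.null(dim(Z))) matrix(Z, nrow = nrow(Am), ncol = length(Z),
                                    byrow = TRUE) else as.matrix(Z)
  if (!all(dim(Am) == dim(Lm)) || nrow(Zm) != nrow(Am)) {
    stop("dimension error: A, L, Z must be aligned")
  }
  K <- length(visit_months)
  if (ncol(Am) < K - 1L) stop("dimension error: need exposure at each interval start")
  n <- nrow(Am)
  zlin <- drop(Zm %*% eta_Z)
  tim <- rep(visit_months[K], n)
  ev <- integer(n)
  alive <- rep(TRUE, n)
  for (k in seq_len(K - 1L)) {
    p <- expit(base_hazard[1] + base_hazard[2] * visit_months[k] +
                 psi_true * Am[, k] + delta_L * Lm[, k] + zlin)
    hit <- alive & (stats::runif(n) < p)
    tim[hit] <- visit_months[k + 1L]
    ev[hit] <- 1L
    alive <- alive & !hit
  }
  list(time = tim, event = ev)
}

# substance item sets produced by the generator; religious flags exist for
# the first alcohol and nicotine items only
cohort_item_sets <- function() {
  list(alcohol  = c("su_alc_sip", "su_alc_drink"),
       nicotine = c("su_nic_cig", "su_nic_ecig"),
       cannabis = c("su_can_puff", "su_can_edible"),
       other    = "su_oth_any")
}

#' Generate a synthetic ABCD-like longitudinal cohort
#'
#' Simulates baseline covariates, a time-varying confounder with exposure
#' feedback, a binary time-varying exposure, auxiliary time-varying
#' predictors, per-substance latent initiation events and their visit-level
#' first-endorsement items (with religious-context flags for alcohol and
#' nicotine), then applies MCAR visit dropout and cell-level missingness.
#' Output is deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{long}{visit-level long table: `id`, `visit`,
#'       `interview_age_months`, confounder `conf_ar`, exposure `expo_bin`,
#'       auxiliary predictors (`beh_x1..beh_x5`, `par_monitor`), endorsement
#'       items and religious flags.}
#'     \item{baseline}{one row per participant: `id`, `sex`, `site`,
#'       `baseline_age_months`, `pc_1..pc_k`, `prs_1..prs_m`.}
#'     \item{truth}{class `sim_truth`: `psi_true`, counterfactual
#'       `marginal_or_mc` for the primary outcome, per-outcome latent
#'       cumulative incidence, latent event times/indicators.}
#'   }
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  vm <- config$visit_months
  K <- length(vm)
  labels <- default_visit_levels(K)

  baseline <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    sex = stats::rbinom(n, 1L, 0.5),
    site = sample.int(config$n_sites, n, replace = TRUE),
    baseline_age_months = round(stats::rnorm(n, 118.92, 7.44), 1),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n)
  colnames(pcs) <- paste0("pc_", seq_len(config$n_pcs))
  prs <- matrix(stats::rnorm(n * config$n_prs), n)
  colnames(prs) <- paste0("prs_", seq_len(config$n_prs))
  baseline <- cbind(baseline, as.data.frame(pcs), as.data.frame(prs))

  Z <- cbind(baseline$sex,
             (baseline$baseline_age_months - 118.92) / 7.44,
             baseline$prs_1)

  le <- simulate_confounder_exposure(n, K, config$rho_L,
                                     config$kappa_feedback, config$a_coefs, Z)

  outcomes <- lapply(config$base_hazard, function(bh) {
    simulate_events(le$A, le$L, Z, config$psi_true, config$delta_L,
                    config$eta_Z, bh, vm)
  })

  # auxiliary time-varying predictors: AR(1) noise plus a monitoring-like
  # score negatively tied to the confounder
  aux <- lapply(1:5, function(j) {
    x <- matrix(0, n, K)
    x[, 1] <- stats::rnorm(n)
    for (k in 2:K) x[, k] <- 0.5 * x[, k - 1] + stats::rnorm(n)
    x
  })
  names(aux) <- paste0("beh_x", 1:5)
  aux$par_monitor <- -0.6 * le$L + matrix(stats::rnorm(n * K, sd = 0.8), n)

  items <- cohort_item_sets()
  item_cols <- unlist(items, use.names = FALSE)
  flag_cols <- c("su_alc_sip_religious", "su_nic_cig_religious")

  long <- data.frame(
    id = rep(baseline$id, each = K),
    visit = rep(labels, n),
    interview_age_months = round(rep(baseline$baseline_age_months, each = K) +
                                   rep(vm, n), 1),
    stringsAsFactors = FALSE
  )
  for (nm in names(aux)) long[[nm]] <- as.vector(t(aux[[nm]]))
  long$conf_ar <- as.vector(t(le$L))
  long$expo_bin <- as.vector(t(le$A))

  # endorsement items: primary item turns 1 at the event visit and stays 1
  # ("have you ever..." style); secondary items endorsed with prob 0.3
  month_mat <- matrix(vm, n, K, byrow = TRUE)
  for (s in names(items)) {
    if (is.null(outcomes[[s]])) next
    o <- outcomes[[s]]
    endorsed <- (o$event == 1L) & (month_mat >= o$time)  # n x K logical
    primary <- items[[s]][1]
    long[[primary]] <- as.integer(as.vector(t(endorsed)))
    for (extra in items[[s]][-1]) {
      sec <- endorsed & matrix(stats::runif(n * K) < 0.3, n, K)
      long[[extra]] <- as.integer(as.vector(t(sec)))
    }
  }
  # religious-context flags on the first endorsement of alcohol/nicotine
  for (fs in list(c("alcohol", "su_alc_sip", "su_alc_sip_religious"),
                  c("nicotine", "su_nic_cig", "su_nic_cig_religious"))) {
    o <- outcomes[[fs[1]]]
    flag <- matrix(0L, n, K)
    if (!is.null(o)) {
      relig <- stats::runif(n) < config$relig_rate
      first_k <- match(o$time, vm)
      sel <- which(o$event == 1L & relig)
      flag[cbind(sel, first_k[sel])] <- 1L
    }
    long[[fs[3]]] <- as.vector(t(flag))
  }

  meas_cols <- c(names(aux), "conf_ar", "expo_bin", item_cols, flag_cols)

  # MCAR cell missingness on measurement columns
  if (config$miss_rate_cell > 0) {
    for (cc in meas_cols) {
      long[[cc]][stats::runif(nrow(long)) < config$miss_rate_cell] <- NA
    }
  }
  # MCAR visit dropout (baseline always retained)
  if (config$miss_rate_visit > 0) {
    nonbase <- long$visit != "baseline"
    drop <- stats::runif(nrow(long)) < config$miss_rate_visit
    if (config$monotone_dropout) {
      dm <- matrix(drop, n, K, byrow = TRUE)
      dm[, 1] <- FALSE
      dm <- t(apply(dm, 1, cummax)) > 0
      drop <- as.vector(t(dm))
    }
    long <- long[!(nonbase & drop), , drop = FALSE]
    rownames(long) <- NULL
  }

  truth <- structure(list(
    psi_true = config$psi_true,
    marginal_or_mc = NA_real_,
    cumulative_incidence = vapply(outcomes, function(o) mean(o$event), 0),
    primary_outcome = names(config$base_hazard)[1],
    event_time = outcomes[[1]]$time,
    event = outcomes[[1]]$event
  ), class = "sim_truth")
  if (isTRUE(config$compute_truth)) {
    truth$marginal_or_mc <- counterfactual_marginal_or(config)
  }

  structure(list(long = long, baseline = baseline, truth = truth,
                 config = config), class = "synthetic_cohort")
}

# counterfactual marginal OR for the primary outcome via re-simulation with
# exposure forced to 1 vs 0 (confounder feedback follows the forced regime)
counterfactual_marginal_or <- function(config) {
  set.seed(config$seed + 1L)
  n <- as.integer(config$n_mc_truth)
  K <- length(config$visit_months)
  Z <- cbind(stats::rbinom(n, 1L, 0.5), stats::rnorm(n), stats::rnorm(n))
  bh <- config$base_hazard[[1]]
  p_do <- vapply(c(1L, 0L), function(a) {
    L <- matrix(0, n, K)
    A <- matrix(a, n, K)
    for (k in seq_len(K)) {
      L[, k] <- if (k == 1) stats::rnorm(n) else
        config$rho_L * L[, k - 1] + config$kappa_feedback * a + stats::rnorm(n)
    }
    ev <- simulate_events(A, L, Z, config$psi_true, config$delta_L,
                          config$eta_Z, bh, config$visit_months)
    mean(ev$event)
  }, 0)
  (p_do[1] / (1 - p_do[1])) / (p_do[2] / (1 - p_do[2]))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants, %d visit rows, %d visits scheduled\n",
              nrow(x$baseline), nrow(x$long), length(x$config$visit_months)))
  ci <- x$truth$cumulative_incidence
  cat("latent cumulative incidence:\n")
  for (nm in names(ci)) cat(sprintf("  %-9s %.4f\n", nm, ci[[nm]]))
  if (!is.na(x$truth$marginal_or_mc)) {
    cat(sprintf("counterfactual marginal OR (%s): %.3f (psi_true = %.3f)\n",
                x$truth$primary_outcome, x$truth$marginal_or_mc, x$truth$psi_true))
  }
  invisible(x)
}

#' Split the long table into annual and phone-interview sources
#'
#' Mirrors the two instruments of the study design: annual in-person
#' interviews (baseline, FU1..FU4) and mid-year phone interviews.
#'
#' @param long the visit-level long table from [generate_cohort()].
#' @return list with `annual` and `phone` data frames.
#' @export
split_sources <- function(long) {
  phone <- startsWith(long$visit, "phone_")
  list(annual = long[!phone, , drop = FALSE],
       phone = long[phone, , drop = FALSE])
}

#' Write a synthetic cohort to disk
#'
#' Writes `long.csv`, `baseline.csv` and a `truth.json` sidecar.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$long, file.path(dir, "long.csv"), row.names = FALSE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(psi_true = tr$psi_true, marginal_or_mc = tr$marginal_or_mc,
         cumulative_incidence = as.list(tr$cumulative_incidence),
         primary_outcome = tr$primary_outcome),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reference feedback simulation at the interval level
#'
#' Generates counting-process interval data directly from the structural
#' model -- baseline covariates Z, AR(1) confounder L with exposure feedback,
#' binary exposure A depending on (L, prior A, Z), and a rare discrete-time
#' event process depending on (A, L, Z) -- bypassing item-level endorsement
#' derivation. This is the reference scenario for causal-recovery studies:
#' the confounder both responds to prior exposure and predicts later
#' exposure and outcome, so conditioning on it post-baseline is biased while
#' IPTW is not. Defaults create substantial treatment-confounder feedback in
#' the rare-event regime where the marginal OR is close to exp(psi_true).
#'
#' @param n participants.
#' @param psi_true causal log-OR of exposure on the per-interval event odds.
#' @param delta_L confounder effect on the event logit.
#' @param kappa_feedback prior-exposure effect on the confounder.
#' @param rho_L confounder AR(1) coefficient.
#' @param a_coefs exposure-model coefficients (as in [sim_config()]).
#' @param eta_Z baseline-covariate effects on the event logit.
#' @param base_hazard event logit `c(intercept, slope)`; default gives
#'   per-interval event probabilities well under 0.05.
#' @param visit_months interval grid.
#' @param seed optional seed.
#' @return interval data frame: `id, start, stop, event_interval, A, L,
#'   sex, agez, prs`.
#' @export
simulate_msm_intervals <- function(n, psi_true = log(2), delta_L = 0.4,
                                   kappa_feedback = 0.2, rho_L = 0.6,
                                   a_coefs = list(intercept = -0.3,
                                                  confounder = 0.7,
                                                  prior_exposure = 0.2,
                                                  baseline = c(0.2, 0, 0.2)),
                                   eta_Z = c(0.2, 0, 0.2),
                                   base_hazard = c(-5.0, 0),
                                   visit_months = seq(0, 48, by = 6),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(visit_months)
  Z <- cbind(stats::rbinom(n, 1L, 0.5), stats::rnorm(n), stats::rnorm(n))
  le <- simulate_confounder_exposure(n, K, rho_L, kappa_feedback, a_coefs, Z)
  ev <- simulate_events(le$A, le$L, Z, psi_true, delta_L, eta_Z,
                        base_hazard, visit_months)
  first_k <- match(ev$time, visit_months) - 1L     # event interval index
  rows <- rep(seq_len(n), times = first_k)
  kk <- unlist(lapply(first_k, seq_len), use.names = FALSE)
  data.frame(
    id = sprintf("S%05d", rows),
    start = visit_months[kk], stop = visit_months[kk + 1L],
    event_interval = as.integer(ev$event[rows] == 1L &
                                  kk == first_k[rows]),
    A = le$A[cbind(rows, kk)], L = le$L[cbind(rows, kk)],
    sex = Z[rows, 1], agez = Z[rows, 2], prs = Z[rows, 3],
    stringsAsFactors = FALSE)
}
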