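# Independent oracle: the Breslow counting-process partial likelihood written
# out explicitly as a product over event times, maximized numerically. Kept
# deliberately separate from the package's fitting path (survival::coxph).

breslow_loglik <- function(beta, d) {
  x <- as.matrix(d[, grep("^x", names(d)), drop = FALSE])
  eta <- drop(x %*% beta)
  ev_times <- sort(unique(d$stop[d$event_interval == 1]))
  ll <- 0
  for (t in ev_times) {
    dead <- d$event_interval == 1 & d$stop == t
    risk <- d$start < t & t <= d$stop
    ll <- ll + sum(eta[dead]) - sum(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

oracle_fit_1d <- function(d, lower = -8, upper = 8) {
  stats::optimize(function(b) breslow_loglik(b, d),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# small random counting-process datasets (<= 10 subjects, time-varying
# binary covariate); regenerates until the partial likelihood has an
# interior maximum so the MLE is finite and comparable
random_small_coxdata <- function(seed, n_subj = 6) {
  set.seed(seed)
  repeat {
    rows <- lapply(seq_len(n_subj), function(i) {
      k <- sample(1:3, 1)
      cuts <- sort(sample(1:9, k))
      start <- c(0, cuts[-k]); stop <- cuts
      data.frame(id = i, start = start, stop = stop,
                 event_interval = 0L, x = rbinom(k, 1, 0.5))
    })
    d <- do.call(rbind, rows)
    # events on a random subset of subjects' final intervals
    last <- cumsum(rle(d$id)$lengths)
    ev <- sample(last, max(2, rbinom(1, n_subj, 0.5)))
    d$event_interval[ev] <- 1L
    ok <- length(unique(d$x)) == 2 &&
      sum(d$event_interval) >= 2 &&
      abs(bmax <- oracle_fit_1d(d)) < 5
    if (ok) return(d)
  }
}

# one-interval-per-subject proportional hazards data with known log-HR
simulate_ph_data <- function(n, beta, seed = NULL, cens = 10) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  t <- stats::rexp(n, rate = 0.1 * exp(beta * x))
  event <- as.integer(t <= cens)
  data.frame(id = seq_len(n), start = 0, stop = pmin(t, cens),
             event_interval = event, x = x)
}

# closed-form Benjamini-Hochberg step-up q-values (independent of p.adjust)
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
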