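test_that("the fitted log-HR matches the explicit Breslow partial likelihood on a toy dataset", {
  # 6 subjects, 3 events, one binary time-varying covariate
  d <- random_small_coxdata(seed = 101, n_subj = 6)
  fit <- fit_tv_cox(d, "x")
  expect_true(attr(fit, "converged"))
  expect_lt(abs(fit$beta - oracle_fit_1d(d)), 1e-6)
})

test_that("cloning every subject leaves beta and the cluster-robust SE unchanged", {
  d <- simulate_ph_data(150, beta = 0.5, seed = 4)
  base <- fit_tv_cox(d, "x")
  clones <- rbind(d, transform(d, id = id + 1000))   # distinct row ids
  clones$cluster <- rep(d$id, 2)                     # clones share a cluster
  dup_naive <- fit_tv_cox(transform(clones, id = seq_len(nrow(clones))), "x")
  dup_clust <- fit_tv_cox(clones, "x", id_col = "cluster")
  expect_equal(dup_clust$beta, base$beta, tolerance = 1e-8)
  # treating clones as independent halves the variance...
  expect_lt(dup_naive$robust_se, 0.8 * base$robust_se)
  # ...but clustering on the original subject restores it
  expect_equal(dup_clust$robust_se, base$robust_se, tolerance = 0.05)
})

test_that("zero events and all-constant covariates are hard errors, never NaN", {
  d <- simulate_ph_data(30, beta = 0, seed = 2)
  d0 <- transform(d, event_interval = 0L)
  expect_error(fit_tv_cox(d0, "x"), "no events")
  d$ones <- 1
  expect_warning(r <- fit_tv_cox(d, c("x", "ones")), "non-identifiable")
  expect_false("ones" %in% r$predictor)
  expect_true(all(is.finite(r$beta)))
})

test_that("shifting times and scaling predictors transform beta as expected", {
  d <- simulate_ph_data(300, beta = 0.6, seed = 9)
  b0 <- fit_tv_cox(d, "x")$beta
  shifted <- transform(d, start = start + 7, stop = stop + 7)
  expect_equal(fit_tv_cox(shifted, "x")$beta, b0, tolerance = 1e-8)
  scaled <- transform(d, x = 10 * x)
  expect_equal(fit_tv_cox(scaled, "x")$beta, b0 / 10, tolerance = 1e-8)
})

test_that("univariate screening reports BH and Bonferroni over the converged family", {
  set.seed(12)
  d <- simulate_ph_data(250, beta = 0.7, seed = 12)
  d$noise1 <- rnorm(nrow(d)); d$noise2 <- rnorm(nrow(d))
  d$sex <- rbinom(nrow(d), 1, 0.5)
  scr <- screen_univariate(d, c("x", "noise1", "noise2"),
                           forced_cols = "sex")
  expect_equal(nrow(scr), 3)
  expect_true(all(scr$converged))
  ok <- !is.na(scr$p)
  expect_equal(scr$q[ok], bh_stepup(scr$p[ok]), tolerance = 1e-12)
  expect_equal(scr$p_bonf[ok], pmin(1, scr$p[ok] * sum(ok)),
               tolerance = 1e-12)
  expect_lt(scr$p[scr$predictor == "x"], 0.001)
  # single predictor: q = p = p_bonf
  one <- screen_univariate(d, "x", forced_cols = "sex")
  expect_equal(one$q, one$p)
  expect_equal(one$p_bonf, one$p)
})

test_that("prescreen requires both univariate evidence and coverage", {
  scr <- data.frame(predictor = c("good", "sparse", "weak"),
                    p = c(0.01, 0.02, 0.5), converged = TRUE)
  cov_tab <- data.frame(id = rep(1:100, 2))
  cov_tab$good <- 1
  cov_tab$sparse <- ifelse(cov_tab$id <= 40, 1, NA)   # 40% coverage
  cov_tab$weak <- 1
  kept <- prescreen(scr, cov_tab, p_enter = 0.05, min_frac = 0.5)
  expect_true("good" %in% kept)
  expect_false("sparse" %in% kept)
  expect_false("weak" %in% kept)
})

test_that("LASSO screening honors penalty limits and unpenalized forced covariates", {
  set.seed(3)
  d <- simulate_ph_data(400, beta = log(2), seed = 3)
  for (j in 1:6) d[[paste0("noise", j)]] <- rnorm(nrow(d))
  preds <- c("x", paste0("noise", 1:6))
  d$sex <- rbinom(nrow(d), 1, 0.5)
  expect_equal(suppressWarnings(
    lasso_screen(d, preds, forced_cols = "sex", lambda = 1e6)),
    character(0))
  expect_warning(lasso_screen(d, preds, lambda = 1e6), "no predictors")
  expect_setequal(lasso_screen(d, preds, forced_cols = "sex", lambda = 0),
                  preds)
  sel <- lasso_screen(d, preds, forced_cols = "sex", k_folds = 5, seed = 1)
  expect_true("x" %in% sel)
})

test_that("a strong predictor survives cross-validated LASSO selection consistently", {
  hits <- vapply(1:8, function(s) {
    d <- simulate_ph_data(500, beta = log(2), seed = 700 + s)
    set.seed(700 + s)
    for (j in 1:10) d[[paste0("noise", j)]] <- rnorm(nrow(d))
    sel <- lasso_screen(d, c("x", paste0("noise", 1:10)),
                        k_folds = 5, seed = s)
    "x" %in% sel
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("site stratification recovers the effect under site-specific baseline hazards", {
  est <- vapply(1:6, function(s) {
    set.seed(400 + s)
    n <- 1200
    site <- sample(1:3, n, replace = TRUE)
    x <- rnorm(n)
    rate <- c(0.03, 0.09, 0.27)[site] * exp(log(1.5) * x)  # 3-fold hazards
    t <- rexp(n, rate)
    d <- data.frame(id = 1:n, start = 0, stop = pmin(t, 15),
                    event_interval = as.integer(t <= 15), x = x,
                    site = site)
    fit_tv_cox(d, "x", strata_col = "site")$beta
  }, 0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(1.5)), 3 * mc_se + 0.02)
})

test_that("the multivariable fit includes availability indicators and adjusts over the selected set", {
  co <- generate_cohort(sim_config(n_participants = 400, seed = 15,
                                   compute_truth = FALSE))
  out <- derive_outcome(harmonize_sources(co$long),
                        default_outcome_specs()$alcohol)
  long <- forward_fill(co$long, c("conf_ar", "beh_x1"))
  iv <- build_interval_table(long, out,
                             covariate_cols = c("conf_ar", "beh_x1"))
  iv <- attach_baseline(iv, co$baseline)
  iv <- encode_value_availability(iv, c("conf_ar", "beh_x1"))
  m <- fit_multivariable(iv, c("conf_ar", "beh_x1"),
                         forced_cols = c("sex", "baseline_age_months"),
                         strata_col = "site")
  expect_true(all(c("conf_ar", "conf_ar_obs", "beh_x1", "beh_x1_obs")
                  %in% m$predictor))
  expect_false(any(c("sex", "baseline_age_months") %in% m$predictor))
  expect_equal(m$q, bh_stepup(m$p), tolerance = 1e-12)
  # zero selected predictors: forced-covariates-only model runs cleanly
  m0 <- fit_multivariable(iv, character(0),
                          forced_cols = c("sex", "baseline_age_months"),
                          strata_col = "site")
  expect_equal(nrow(m0), 0)
  expect_true(attr(attr(m0, "fit_result"), "converged"))
})
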