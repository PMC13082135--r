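test_that("median split dichotomizes with ties at the median going to 0", {
  expect_equal(dichotomize(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize(c(5, 5, 5, 9)), c(0L, 0L, 0L, 1L))
  expect_equal(dichotomize(c(0, 1, 1, 0), type = "binary"),
               c(0L, 1L, 1L, 0L))
  expect_error(dichotomize(c(0, 2), type = "binary"), "binary")
  expect_error(dichotomize(c(NA_real_, NA_real_)), "missing")
  expect_equal(dichotomize(c(1, NA, 4)), c(0L, NA, 1L))
})

test_that("the two-interval stabilized-weight example is exact", {
  # single id, A = (1, 0), numerator p = (0.5, 0.5), denominator (0.8, 0.4)
  ws <- compute_stabilized_weights(c(0.5, 0.5), c(0.8, 0.4), c(1, 0),
                                   id = c("a", "a"), clip = 0.001,
                                   trunc_q = 1)
  expect_equal(ws$weights[1], 0.625, tolerance = 1e-12)
  expect_equal(ws$weights[2], 0.625 * (0.5 / 0.6), tolerance = 1e-12)
})

test_that("identical numerator and denominator probabilities give unit weights", {
  set.seed(2)
  p <- runif(50, 0.2, 0.8)
  A <- rbinom(50, 1, p)
  ws <- compute_stabilized_weights(p, p, A, id = rep(1:10, each = 5))
  expect_equal(ws$weights, rep(1, 50), tolerance = 1e-12)
})

test_that("cumulative products restart at each participant", {
  ws <- compute_stabilized_weights(c(0.5, 0.5), c(0.8, 0.8), c(1, 1),
                                   id = c("a", "b"), trunc_q = 1)
  expect_equal(ws$weights, c(0.625, 0.625), tolerance = 1e-12)
})

test_that("truncation caps weights at the requested quantile", {
  set.seed(4)
  n <- 200
  num <- rep(0.5, n); den <- runif(n, 0.4, 0.6); A <- rbinom(n, 1, 0.5)
  den[1] <- 1e-6   # a positivity violation
  A[1] <- 1
  ws <- compute_stabilized_weights(num, den, A, id = seq_len(n),
                                   clip = 0.01, trunc_q = 0.99)
  expect_lte(ws$diagnostics$max_w, ws$diagnostics$max_raw)
  expect_equal(ws$diagnostics$max_w,
               unname(quantile(ws$raw, 0.99)), tolerance = 1e-10)
  # clipping already bounds the raw weight for the degenerate probability
  expect_lte(ws$diagnostics$max_raw, 0.5 / 0.01 + 1e-9)
})

test_that("weight diagnostics implement the predefined quality criteria", {
  good <- compute_stabilized_weights(rep(0.5, 20), rep(0.5, 20),
                                     rbinom(20, 1, 0.5), id = 1:20)
  expect_true(weight_diagnostics(good, prevalence = 0.5)$pass)
  d1 <- weight_diagnostics(good, prevalence = 0.01)
  expect_false(d1$pass)
  expect_equal(d1$report$failed, "prevalence")
  bad <- good
  bad$weights <- c(rep(0.1, 19), 30)
  bad$diagnostics$mean_w <- mean(bad$weights)
  bad$diagnostics$ess_ratio <- sum(bad$weights)^2 /
    (20 * sum(bad$weights^2))
  d2 <- weight_diagnostics(bad, prevalence = 0.5)
  expect_false(d2$pass)
})

test_that("treatment models recover known assignment coefficients", {
  set.seed(6)
  n <- 1000; K <- 6
  iv <- simulate_msm_intervals(n, seed = 6)
  tm <- fit_treatment_models(iv[order(iv$id, iv$start), ], "A",
                             z_cols = c("sex", "agez", "prs"),
                             l_cols = "L")
  cf <- coef(tm$den_fit)
  se <- sqrt(diag(vcov(tm$den_fit)))
  # true denominator model: intercept -0.3, L 0.7, prior A 0.2,
  # sex 0.2, agez 0, prs 0.2
  truth <- c("(Intercept)" = -0.3, L = 0.7, .Aprev = 0.2, sex = 0.2,
             agez = 0, prs = 0.2)
  for (nm in names(truth)) {
    expect_lt(abs(cf[[nm]] - truth[[nm]]), 3 * se[[nm]] + 0.05)
  }
})

test_that("no-confounding data give stabilized weights near one and a no-op weighting", {
  iv <- simulate_msm_intervals(1500, kappa_feedback = 0,
                               a_coefs = list(intercept = -0.3,
                                              confounder = 0,
                                              prior_exposure = 0.2,
                                              baseline = c(0.2, 0, 0.2)),
                               seed = 10)
  iv <- iv[order(iv$id, iv$start), ]
  tm <- fit_treatment_models(iv, "A", z_cols = c("sex", "agez", "prs"),
                             l_cols = "L")
  expect_lt(mean(abs(tm$num_p - tm$den_p)), 0.02)
  ws <- compute_stabilized_weights(tm$num_p, tm$den_p, iv$A, iv$id)
  expect_lt(abs(ws$diagnostics$mean_w - 1), 0.05)

  m_w <- fit_msm(iv, "A", c("sex", "agez", "prs"), ws$weights)
  m_1 <- fit_msm(iv, "A", c("sex", "agez", "prs"),
                 rep(1, nrow(iv)))
  expect_equal(m_w$psi, m_1$psi, tolerance = 0.05)
})

test_that("exposure prevalence outside the window triggers exclusion before fitting", {
  iv <- simulate_msm_intervals(300, seed = 20)
  iv$always <- 1
  r <- run_msm_exposure(iv, "always", z_cols = c("sex", "agez", "prs"),
                        l_cols = "L", type = "binary")
  expect_false(r$retained)
  expect_equal(attr(r, "report")$failed, "prevalence")
  expect_true(is.na(r$psi))
})

test_that("BH across retained exposures matches the step-up closed form", {
  res <- data.frame(exposure = c("e1", "e2", "e3", "e4"),
                    p = c(0.005, 0.03, 0.8, 0.001),
                    retained = c(TRUE, TRUE, TRUE, FALSE))
  out <- fdr_across_exposures(res)
  expect_equal(out$q[1:3], bh_stepup(c(0.005, 0.03, 0.8)),
               tolerance = 1e-12)
  expect_true(is.na(out$q[4]))                   # excluded from the family
  one <- fdr_across_exposures(data.frame(exposure = "e", p = 0.2,
                                         retained = TRUE))
  expect_equal(one$q, one$p)
  allone <- fdr_across_exposures(data.frame(exposure = c("a", "b"),
                                            p = c(1, 1),
                                            retained = TRUE))
  expect_equal(allone$q, c(1, 1))
})

test_that("spec'd BH example [.01,.02,.03,.04] yields q = .04 everywhere", {
  res <- data.frame(exposure = letters[1:4], p = c(0.01, 0.02, 0.03, 0.04),
                    retained = TRUE)
  expect_equal(fdr_across_exposures(res)$q, rep(0.04, 4),
               tolerance = 1e-12)
})

test_that("the time basis degrades gracefully with few distinct times", {
  b1 <- time_basis(rep(c(1, 2), 10))
  expect_equal(ncol(b1), 1)
  b2 <- time_basis(seq(0, 48, by = 6))
  expect_gt(ncol(b2), 1)
})
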