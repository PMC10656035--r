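test_that("ground-truth beta follows the calibrated sigmoid difference", {
  expect_equal(ground_truth_beta(0), 0)
  expect_equal(ground_truth_beta(7), 0.9477 * (plogis(2) - plogis(-5)))
  expect_equal(ground_truth_beta(7), 0.8283, tolerance = 1e-3)
  w <- seq(-5, 8, by = 0.5)
  expect_true(all(diff(ground_truth_beta(w)) > 0))
  m <- matrix(c(0, 2, -3, 0), 2, 2)
  b <- ground_truth_beta(m)
  expect_equal(dim(b), c(2, 2))
  expect_true(all(sign(b) == sign(m)))
})

test_that("calibration rejects degenerate weight grids", {
  expect_error(calibrate_alpha(c(1, 1, 1)), class = "refractiv_config_error")
  expect_error(calibrate_alpha(c(0, 0, 0)), class = "refractiv_config_error")
})

test_that("pair errors and their summaries follow hand arithmetic", {
  e <- pair_errors(c(0.5, 0.1), c(0.3, 0.5), weights = c(2, -1))
  expect_equal(e$error, c(0.2, -0.4))
  s <- summarize_errors(e)
  expect_equal(s$mae, 0.3)
  expect_equal(s$mae_pos_w, 0.2)
  expect_equal(s$mae_neg_w, 0.4)
  expect_equal(s$n_excluded, 0)
  t <- pair_errors(c(1, NA), c(1, 0))
  expect_equal(summarize_errors(t)$mae, 0)
  expect_equal(summarize_errors(t)$n_excluded, 1)
  expect_equal(summarize_errors(pair_errors(c(1, 2), c(0.9, 1.9)))$mae, 0.1)
})

test_that("condition number tracks covariance anisotropy", {
  # two independent neurons with very different rates
  r <- withr::with_seed(51, {
    t1 <- sort(sample.int(2e4, 4000))  # p ~ 0.2
    t2 <- sort(sample.int(2e4, 200))   # p ~ 0.01
    refractiv:::new_spike_raster(list(t1, t2), 2, 2e4L)
  })
  kappa <- condition_number(r)
  oracle <- (0.2 * 0.8) / (0.01 * 0.99)
  expect_equal(as.numeric(kappa), oracle, tolerance = 0.15)
  expect_false(attr(kappa, "degenerate"))

  # equal-rate independent neurons approach the isotropic limit
  r2 <- withr::with_seed(52, {
    trains <- lapply(1:4, function(i) sort(sample.int(1e5, 5000)))
    refractiv:::new_spike_raster(trains, 4, 1e5L)
  })
  expect_lt(as.numeric(condition_number(r2)), 1.2)

  # a duplicated spike train makes the covariance rank-deficient
  t1 <- sort(sample.int(1e4, 800))
  r3 <- refractiv:::new_spike_raster(list(t1, t1), 2, 1e4L)
  k3 <- condition_number(r3)
  expect_true(attr(k3, "degenerate"))
  expect_true(is.infinite(as.numeric(k3)))

  r4 <- refractiv:::new_spike_raster(list(integer(0), integer(0)), 2, 100L)
  expect_true(attr(condition_number(r4), "degenerate"))
  expect_error(condition_number(refractiv:::new_spike_raster(list(1L), 1, 10L)),
               class = "refractiv_config_error")
})

test_that("condition number is invariant to neuron order and time reversal", {
  cond <- cached_fig1()
  r <- cond$raster
  sub <- refractiv:::new_spike_raster(r$times, r$n_neurons, r$n_steps)
  k0 <- as.numeric(condition_number(sub))
  perm <- refractiv:::new_spike_raster(r$times[c(3, 1, 2)], 3, r$n_steps)
  expect_equal(as.numeric(condition_number(perm)), k0, tolerance = 1e-8)
  rev_times <- lapply(r$times, function(tt) sort(r$n_steps - tt + 1L))
  revr <- refractiv:::new_spike_raster(rev_times, 3, r$n_steps)
  expect_equal(as.numeric(condition_number(revr)), k0, tolerance = 1e-8)
})

test_that("auroc matches the printed examples and a brute-force oracle", {
  expect_equal(auroc(c(3, 2, 1, 0), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(auroc(rep(1, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  expect_true(is.na(auroc(1:4, rep(1, 4))))
  brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  withr::with_seed(53, {
    for (k in 1:100) {
      s <- sample(rnorm(20) * sample(c(1, 10), 20, TRUE))
      s <- round(s, 1)  # provoke ties
      l <- rbinom(20, 1, 0.4)
      if (sum(l) %in% c(0, 20)) next
      expect_equal(auroc(s, l), brute(s, l), tolerance = 1e-12)
    }
  })
})

test_that("estimates recover ground truth on a sparse unconfounded network", {
  res <- cached("recovery", {
    cond <- simulate_condition(50, sigma = 10, n_stimulated = 5, gamma_s = 6,
                               sparsity = 0.9, n_steps = 1e6, seed = 77)
    pair_results(cond)
  })
  fit <- lm(iv_did ~ 0 + beta, data = res)
  expect_gt(coef(fit)[1], 0.8)
  expect_lt(coef(fit)[1], 1.2)
  # near-unbiased on null pairs, and the DiD correction beats plain IV
  expect_lt(abs(mean(res$iv_did[res$beta == 0])), 0.005)
  long <- results_long(res)
  s <- summarize_results(long)
  expect_lt(s$mae[s$estimator == "iv_did"], s$mae[s$estimator == "iv"])
})
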