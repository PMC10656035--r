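tt <- function(...) tibble::tibble(...)

test_that("the OLS conditional difference matches hand arithmetic", {
  expect_equal(ols_estimate(tt(x = c(1, 1, 0, 0), y = c(1, 1, 0, 0))), 1)
  expect_equal(ols_estimate(tt(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0))), 0)
  expect_equal(ols_estimate(tt(x = c(1, 1, 1, 0, 0), y = c(1, 1, 0, 1, 0))),
               2 / 3 - 1 / 2)
  expect_true(is.na(ols_estimate(tt(x = c(1, 1), y = c(1, 0)))))
})

test_that("the Wald estimator matches hand arithmetic and handles degeneracy", {
  expect_equal(iv_estimate(tt(z = c(1, 1, 0, 0), x = c(0, 0, 1, 1),
                              y = c(0, 0, 1, 1))), 1)
  expect_equal(iv_estimate(tt(z = c(1, 0, 1, 0), x = c(0, 1, 0, 1),
                              y = c(1, 1, 1, 1))), 0)
  expect_equal(iv_estimate(tt(z = c(1, 1, 0, 0, 0, 0), x = c(0, 0, 1, 1, 0, 1),
                              y = c(1, 0, 1, 1, 0, 1))),
               (0.75 - 0.5) / 0.75)
  expect_true(is.na(iv_estimate(tt(z = c(1, 0), x = c(1, 1), y = c(0, 1)))))
})

test_that("DiD estimators match hand arithmetic and reduce correctly", {
  t1 <- tt(x = c(1, 1, 0, 0), y = c(1, 1, 1, 0), y_star = c(0, 1, 1, 0))
  expect_equal(ols_did(t1), (1 - 0.5) - (0.5 - 0.5))
  t2 <- tt(x = c(1, 0, 1, 0), y = c(1, 0, 0, 1), y_star = c(1, 0, 0, 1))
  expect_equal(ols_did(t2), 0)
  t3 <- tt(x = c(1, 1, 0, 0), y = c(1, 1, 0, 1), y_star = rep(0, 4))
  expect_equal(ols_did(t3), ols_estimate(t3))

  t4 <- tt(z = c(1, 1, 0, 0, 0, 0), x = c(0, 0, 1, 1, 0, 1),
           x_star = c(1, 1, 0, 0, 0, 0), y = c(1, 1, 1, 1, 0, 1),
           y_star = c(0, 0, 0, 1, 0, 0))
  expect_equal(iv_did(t4, xstar_in_denominator = TRUE), 0.5 / -1.75)
  # with no starred history the DiD form collapses onto the plain Wald
  t5 <- tt(z = c(1, 1, 0, 0), x = c(0, 0, 1, 1), x_star = rep(0, 4),
           y = c(0, 0, 1, 1), y_star = rep(0, 4))
  expect_equal(iv_did(t5, xstar_in_denominator = TRUE), iv_estimate(t5))
  expect_equal(iv_did(t5, xstar_in_denominator = FALSE), iv_estimate(t5))
  # constant outcomes across strata zero the numerator
  t6 <- tt(z = c(1, 0), x = c(0, 1), x_star = c(1, 0), y = c(1, 1),
           y_star = c(1, 1))
  expect_equal(iv_did(t6), 0)
})

test_that("hit rate is the mean of the treatment indicator", {
  expect_equal(hit_rate(tt(x = rep(1, 4))), 1)
  expect_equal(hit_rate(tt(x = rep(0, 4))), 0)
  expect_equal(hit_rate(tt(x = c(1, 0, 1, 0))), 0.5)
  expect_true(is.na(hit_rate(tt(x = numeric(0)))))
})

test_that("OLS equals the least-squares slope on random binary tables", {
  withr::with_seed(10, {
    for (k in 1:100) {
      d <- random_trial_table()
      if (length(unique(d$x)) < 2) next
      slope <- unname(coef(lm(y ~ x, data = d))[2])
      expect_equal(ols_estimate(d), slope, tolerance = 1e-12)
    }
  })
})

test_that("the Wald estimator equals the covariance-ratio oracle", {
  withr::with_seed(11, {
    for (k in 1:100) {
      d <- random_trial_table()
      den <- cov(d$x, 1 - d$z)
      if (length(unique(d$z)) < 2 || den == 0) next
      expect_equal(iv_estimate(d), cov(d$y, 1 - d$z) / den, tolerance = 1e-12)
    }
  })
})

test_that("DiD numerators are exactly invariant to additive common trends", {
  withr::with_seed(12, {
    for (k in 1:20) {
      d <- random_trial_table()
      shift <- d
      cshift <- rnorm(1)
      shift$y <- shift$y + cshift
      shift$y_star <- shift$y_star + cshift
      if (length(unique(d$x)) < 2 || length(unique(d$z)) < 2) next
      expect_equal(ols_did(shift), ols_did(d), tolerance = 1e-12)
      expect_equal(iv_did(shift), iv_did(d), tolerance = 1e-12)
    }
  })
})

test_that("estimate_pairs assembles one labelled row per pair", {
  r <- two_neuron_raster(5, n_steps = 5e4, seed = 20)
  onsets <- seq(50, 5e4 - 50, by = 50)
  out <- estimate_pairs(r, onsets, tt(upstream = 2L, downstream = 1L))
  expect_equal(nrow(out), 1)
  expect_named(out, c("upstream", "downstream", "n_trials", "hit_rate",
                      "ols", "ols_did", "iv", "iv_did"))
  expect_gt(out$n_trials, 900)
})
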