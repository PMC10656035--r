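test_that("correlogram counts match pair enumeration", {
  cc <- cross_correlogram(c(0, 10), c(3, 13, 14), max_lag = 5)
  expect_equal(cc$counts[cc$lag == 3], 2L)
  expect_equal(cc$counts[cc$lag == 4], 1L)
  expect_equal(sum(cc$counts), 3L)

  k <- 7
  train <- cumsum(rep(200L, k))
  same <- cross_correlogram(train, train, max_lag = 50)
  expect_equal(same$counts[same$lag == 0], k)
  expect_equal(sum(same$counts), k)
  shifted <- cross_correlogram(train, train + 3L, max_lag = 50)
  expect_equal(shifted$counts[shifted$lag == 3], k)
  expect_equal(sum(shifted$counts), k)
})

test_that("correlogram totals equal the brute-force pair count", {
  withr::with_seed(21, {
    for (k in 1:20) {
      pre <- sort(sample.int(2000, 80))
      post <- sort(sample.int(2000, 120))
      cc <- cross_correlogram(pre, post, max_lag = 30)
      brute <- sum(abs(outer(post, pre, `-`)) <= 30)
      expect_identical(sum(cc$counts), brute)
    }
  })
})

test_that("hollow gaussian baseline matches a direct convolution oracle", {
  counts <- rep(5L, 101)
  cc <- list(lag = -50:50, counts = counts, n_presyn = 100)
  bl <- hollow_gaussian_baseline(cc, kernel_sd = 10, hollow_fraction = 0.6)
  expect_equal(bl, rep(5, 101), tolerance = 1e-9)

  impulse <- integer(101); impulse[51] <- 1L
  cc2 <- list(lag = -50:50, counts = impulse, n_presyn = 10)
  bl2 <- hollow_gaussian_baseline(cc2, kernel_sd = 10, hollow_fraction = 0.6)
  g <- dnorm(-50:50, sd = 10); g[51] <- g[51] * 0.4; g <- g / sum(g)
  # direct convolution with reflection padding
  pad <- c(rev(impulse[1:50]), impulse, rev(impulse[52:101]))
  oracle <- vapply(1:101, function(i) sum(pad[i:(i + 100)] * rev(g)), 1)
  expect_equal(bl2, oracle, tolerance = 1e-10)
  expect_equal(bl2[51], g[51], tolerance = 1e-10)  # hollowed self-contribution

  bl3 <- hollow_gaussian_baseline(cc2, kernel_sd = 10, hollow_fraction = 0)
  g3 <- dnorm(-50:50, sd = 10); g3 <- g3 / sum(g3)
  expect_equal(bl3[51], g3[51], tolerance = 1e-6)
})

test_that("the continuity-corrected Poisson p-value matches direct summation", {
  expect_equal(poisson_continuity_pvalue(0, 0), 0.5)
  expect_equal(poisson_continuity_pvalue(1, 0), 0)
  # oracle: direct tail summation in log space (absolutely convergent)
  direct <- function(n, lam) {
    k <- n:(n + 2000)
    sum(exp(k * log(lam) - lam - lgamma(k + 1))) -
      exp(n * log(lam) - lam - lgamma(n + 1)) / 2
  }
  expect_equal(poisson_continuity_pvalue(10, 1), direct(10, 1), tolerance = 1e-10)
  expect_lt(poisson_continuity_pvalue(10, 1), 2e-7)
  withr::with_seed(31, {
    for (k in 1:50) {
      n <- sample(0:100, 1); lam <- runif(1, 0.01, 50)
      o <- direct(n, lam)
      expect_equal(poisson_continuity_pvalue(n, lam), min(max(o, 0), 1),
                   tolerance = 1e-10)
    }
  })
  expect_error(poisson_continuity_pvalue(-1, 1), class = "refractiv_domain_error")
})

test_that("significance screens behave on degenerate and symmetric correlograms", {
  zero <- list(lag = -50:50, counts = integer(101), n_presyn = 0)
  bl <- rep(0, 101)
  sig <- cch_significance(zero, bl)
  expect_equal(sig$p_fast, 1)
  expect_equal(sig$p_diff, 1)
  expect_false(sig$significant)

  sym <- list(lag = -50:50, counts = rep(c(2L, 3L), length.out = 101),
              n_presyn = 100)
  sym$counts <- sym$counts + rev(sym$counts)  # force symmetry
  sbl <- hollow_gaussian_baseline(sym, 10, 0.6)
  ssig <- cch_significance(sym, sbl)
  expect_gte(ssig$p_diff, 0.4)   # peak equals its mirror: no causal asymmetry

  peaky <- list(lag = -50:50, counts = integer(101), n_presyn = 100)
  peaky$counts[51 + 4] <- 50L
  pbl <- rep(5, 101)
  psig <- cch_significance(peaky, pbl)
  expect_lt(psig$p_fast, 1e-15)
  expect_true(psig$significant)
})

test_that("transmission probability is the normalized short-latency excess", {
  cc <- list(lag = -50:50, counts = integer(101), n_presyn = 100)
  bl <- rep(2, 101)
  cc$counts[] <- 2L
  expect_equal(transmission_probability(cc, bl), 0)
  cc$counts[51 + 3:6] <- 7L   # excess of 5 in each of 4 bins
  expect_equal(transmission_probability(cc, bl), 4 * 5 / 100)
  cc2 <- cc; cc2$counts[51 + 3:6] <- 12L; cc2$n_presyn <- 200
  expect_equal(transmission_probability(cc2, rep(2, 101)), 4 * 10 / 200)
  # invariant to a common additive offset of counts and baseline
  cc3 <- cc; cc3$counts <- cc$counts + 9L
  expect_equal(transmission_probability(cc3, bl + 9),
               transmission_probability(cc, bl), tolerance = 1e-10)
  cc$n_presyn <- 0
  expect_true(is.na(transmission_probability(cc, bl)))
})

test_that("the significance gate holds its false-positive rate on null pairs", {
  fp <- withr::with_seed(41, {
    mean(vapply(1:400, function(k) {
      pre <- sort(sample.int(6e4, 400))
      post <- sort(sample.int(6e4, 400))
      cc <- cross_correlogram(pre, post, max_lag = 50)
      bl <- hollow_gaussian_baseline(cc, 10, 0.6)
      cch_significance(cc, bl)$significant
    }, logical(1)))
  })
  expect_lt(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / 400))
})

test_that("cch_estimate recovers a strong synapse and rejects a null pair", {
  r <- cached_fig1()$raster
  res <- cch_estimate(r, tibble::tibble(upstream = c(2L, 1L),
                                        downstream = c(3L, 3L)))
  expect_gt(res$cch[1], 0.1)       # true B -> C synapse
  expect_true(res$significant[1])
})
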