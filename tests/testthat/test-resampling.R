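test_that("bootstrap on noise-free linear data collapses to a point", {
  cfg <- fix_cfg()
  fr <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  B0 <- matrix(c(0.7, 0.01, -0.2, -0.05), 2, 2)
  pm <- fix_exact_pairs(B0, n = 60L, seed = 1)
  bm <- bootstrap_model(pm, fr, n_iter = 200L, seed = 1)
  expect_equal(bm$lambda_w$ci_low, bm$lambda_w$ci_high, tolerance = 1e-9)
  m <- eigenanalysis(B0, fr)
  expect_equal(bm$lambda_w$mean, m$lambda_w, tolerance = 1e-9)
  expect_equal(bm$theta_s_deg$mean, m$theta_s_deg, tolerance = 1e-7)
})

test_that("bootstrap is deterministic under a fixed seed", {
  ts <- simulate_series(fix_spec(seed = 41))
  fl <- fluctuations(ts)
  fr <- gem_frame(operating_point(ts), ts$cfg)
  b1 <- bootstrap_model(fl, fr, n_iter = 50L, seed = 7)
  b2 <- bootstrap_model(fl, fr, n_iter = 50L, seed = 7)
  expect_identical(b1$lambda_w$samples, b2$lambda_w$samples)
  b3 <- bootstrap_model(fl, fr, n_iter = 50L, seed = 8)
  expect_false(identical(b1$lambda_w$samples, b3$lambda_w$samples))
})

test_that("bootstrap mean tracks ground truth on simulated data", {
  means <- vapply(1:30, function(s) {
    ts <- simulate_series(fix_spec(seed = 300 + s))
    fl <- fluctuations(ts)
    fr <- gem_frame(operating_point(ts), ts$cfg)
    bootstrap_model(fl, fr, n_iter = 200L, seed = s)$lambda_w$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.76), 0.05)
})

test_that("resampling engine reproduces the closed-form CI of a mean", {
  # sanity oracle: percentile CI of the mean of N(0,1), n = 450
  set.seed(9)
  x <- rnorm(450)
  n_iter <- 4000L
  set.seed(10)
  boots <- replicate(n_iter, mean(x[sample.int(450, 450, replace = TRUE)]))
  width <- diff(quantile(boots, c(0.025, 0.975), names = FALSE))
  expect_equal(width, 2 * 1.96 * sd(x) / sqrt(450), tolerance = 0.1)
})

test_that("bootstrap_dfa transforms the whole series per iterate", {
  ts <- simulate_series(fix_spec(seed = 23))
  fl <- fluctuations(ts)
  fr <- gem_frame(operating_point(ts), ts$cfg)
  bd <- bootstrap_dfa(fl, fr, n_iter = 100L, seed = 2)
  # weak direction more persistent than strong in the simulated regime
  expect_gt(bd$alpha_w$mean, bd$alpha_s$mean)
  expect_lt(abs(bd$alpha_s$mean - 0.5), 0.12)
  # the alpha distribution varies only through eigenvector re-estimation,
  # so its spread is far smaller than the white-noise sampling spread
  expect_lt(bd$alpha_w$ci_high - bd$alpha_w$ci_low, 0.2)
  # ordering robust across seeds
  orderings <- vapply(1:10, function(s) {
    ts <- simulate_series(fix_spec(seed = 400 + s))
    fl <- fluctuations(ts)
    fr <- gem_frame(operating_point(ts), ts$cfg)
    bd <- bootstrap_dfa(fl, fr, n_iter = 40L, seed = s)
    bd$alpha_w$mean > bd$alpha_s$mean
  }, logical(1))
  expect_true(all(orderings))
})

test_that("pooling concatenates samples and takes pooled percentiles", {
  d1 <- bootstrap_model(fix_exact_pairs(diag(c(0.5, -0.1)), n = 30L, seed = 1),
                        gem_frame(c(1, 0.4), fix_cfg()), n_iter = 10L, seed = 1)
  expect_equal(pool(list(d1$lambda_w))$mean, d1$lambda_w$mean)
  # two point-masses at 0 and 1 pool to mean 0.5
  mk <- function(v) structure(
    list(name = "q", samples = rep(v, 100), mean = v, ci_low = v, ci_high = v,
         n_iter = 100L, seed = 1L, n_dropped = 0L),
    class = "bootstrap_distribution")
  pooled <- pool(list(mk(0), mk(1)))
  expect_equal(pooled$mean, 0.5)
  # percentile oracle on standard normal samples
  set.seed(11)
  g <- mk(0); g$samples <- rnorm(20000)
  pooled_g <- pool(list(g))
  expect_equal(pooled_g$ci_low, -1.96, tolerance = 0.05)
  expect_equal(pooled_g$ci_high, 1.96, tolerance = 0.05)
  expect_error(pool(list()), "no distributions")
})

test_that("CI endpoints are stable in n_iter", {
  ts <- simulate_series(fix_spec(seed = 55))
  fl <- fluctuations(ts)
  fr <- gem_frame(operating_point(ts), ts$cfg)
  b_small <- bootstrap_model(fl, fr, n_iter = 2000L, seed = 3)$lambda_w
  b_large <- bootstrap_model(fl, fr, n_iter = 10000L, seed = 4)$lambda_w
  w <- b_large$ci_high - b_large$ci_low
  expect_lt(abs(b_small$ci_low - b_large$ci_low), 0.05 * w)
  expect_lt(abs(b_small$ci_high - b_large$ci_high), 0.05 * w)
})
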