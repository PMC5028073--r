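test_that("build_update_matrix realizes the prescribed eigenstructure", {
  cfg <- fix_cfg()
  fr <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  # orthogonal case: eigenbasis = (tangent, normal)
  spec <- fix_spec(lambda_w = 0.76, lambda_s = -0.03,
                   theta_w_deg = 0, theta_s_deg = 90)
  bm <- build_update_matrix(spec, fr)
  B_expect <- 0.76 * fr$e_t %o% fr$e_t - 0.03 * fr$e_n %o% fr$e_n
  expect_equal(bm$B, B_expect, tolerance = 1e-12)
  # zero map
  spec0 <- fix_spec(lambda_w = 0, lambda_s = 0,
                    theta_w_deg = 0, theta_s_deg = 90)
  expect_equal(build_update_matrix(spec0, fr)$B, matrix(0, 2, 2),
               tolerance = 1e-15)
  # round-trip: eigenanalysis recovers the generating parameters
  spec2 <- fix_spec(lambda_w = 0.7, lambda_s = 0,
                    theta_w_deg = 2, theta_s_deg = 75)
  m <- eigenanalysis(build_update_matrix(spec2, fr)$B, fr)
  expect_equal(m$lambda_w, 0.7, tolerance = 1e-9)
  expect_equal(m$lambda_s, 0, tolerance = 1e-9)
  expect_equal(m$theta_w_deg, 2, tolerance = 1e-7)
  expect_equal(m$theta_s_deg, 75, tolerance = 1e-7)
  # parallel eigenvectors rejected
  expect_error(fix_spec(theta_w_deg = 30, theta_s_deg = 210),
               "parallel|coincide")
})

test_that("simulate_series: fixed point, determinism, block structure", {
  # noise-free: every trial sits exactly at the operating point
  spec <- fix_spec(sigma_nw = 0, sigma_ns = 0)
  ts <- simulate_series(spec)
  expect_equal(nrow(ts$records), 500L)
  expect_equal(unname(table(ts$records$block)), rep(50L, 10L),
               ignore_attr = TRUE)
  expect_equal(max(abs(ts$records$x - spec$op_point[1L])), 0)
  expect_equal(max(abs(ts$records$v - spec$op_point[2L])), 0)
  expect_equal(ts$records$e,
               rep(goal_function(spec$op_point[1L], spec$op_point[2L],
                                 spec$cfg), 500L))
  # recorded error equals the goal function of the recorded state
  ts2 <- simulate_series(fix_spec(seed = 9))
  expect_equal(ts2$records$e,
               goal_function(ts2$records$x, ts2$records$v, ts2$cfg),
               tolerance = 1e-10)
  # identical seed => identical output; different seed differs
  expect_identical(simulate_series(fix_spec(seed = 5))$records,
                   simulate_series(fix_spec(seed = 5))$records)
  expect_false(identical(simulate_series(fix_spec(seed = 6))$records,
                         ts2$records))
  # unstable spec rejected before simulation
  expect_error(fix_spec(lambda_w = 1.0), "unstable|< 1")
})

test_that("zero-memory dynamics produce white output fluctuations", {
  spec <- fix_spec(lambda_w = 0, lambda_s = 0.001, seed = 3,
                   n_blocks = 20L, block_len = 500L)
  ts <- simulate_series(spec)
  for (col in c("x", "v")) {
    z <- ts$records[[col]]
    r1 <- lag1_autocorrelation(z)
    expect_lt(abs(r1), 3 / sqrt(length(z)))
  }
})

test_that("stationary_covariance solves the Lyapunov equation", {
  expect_equal(stationary_covariance(matrix(0, 2, 2), diag(2)), diag(2))
  expect_equal(stationary_covariance(diag(c(0.5, 0)), diag(2)),
               diag(c(1 / 0.75, 1)), tolerance = 1e-12)
  expect_error(stationary_covariance(diag(c(1, 0)), diag(2)),
               "spectral radius")
  # defining fixed point holds for a random stable matrix
  set.seed(8)
  B <- matrix(rnorm(4, sd = 0.4), 2, 2)
  Q <- crossprod(matrix(rnorm(4), 2, 2))
  S <- stationary_covariance(B, Q)
  expect_equal(S, B %*% S %*% t(B) + Q, tolerance = 1e-12)
})

test_that("long-run sample moments match the stationary covariance", {
  spec <- fix_spec(seed = 21, n_blocks = 200L, block_len = 500L)
  fr <- gem_frame(spec$op_point, spec$cfg)
  bm <- build_update_matrix(spec, fr)
  Q <- bm$E %*% diag(c(spec$sigma_nw, spec$sigma_ns)^2) %*% t(bm$E)
  S <- stationary_covariance(bm$B, Q)
  ts <- simulate_series(spec)
  u <- cbind(ts$records$x - spec$op_point[1L],
             ts$records$v - spec$op_point[2L])
  expect_equal(cov(u), S, tolerance = 0.02)
  # weak-direction steady-state sd matches the scalar closed form
  z <- to_eigencoordinates(u, bm$E)
  expect_equal(sd(z[, 1L]),
               steady_state_std(spec$lambda_w, spec$sigma_nw),
               tolerance = 0.02)
})

test_that("simulated goal error is the linearized projection at small noise", {
  spec <- fix_spec(seed = 13, sigma_nw = 0.002, sigma_ns = 0.002)
  ts <- simulate_series(spec)
  fr <- gem_frame(spec$op_point, spec$cfg)
  u <- cbind(ts$records$x - spec$op_point[1L],
             ts$records$v - spec$op_point[2L])
  e_lin <- as.numeric(u %*% t(fr$A))
  expect_equal(sd(ts$records$e - e_lin) / sd(ts$records$e), 0,
               tolerance = 0.05)
})

test_that("simulate_experiment spans sensitivities and is reproducible", {
  exp8 <- simulate_experiment(seed = 2)
  expect_length(exp8, 8L)
  expect_true(all(vapply(exp8, function(ts) nrow(ts$records), numeric(1)) == 500))
  # lower friction (longer stop time) => higher passive sensitivity
  s_vals <- vapply(exp8, function(ts) {
    gem_frame(operating_point(ts), ts$cfg)$s
  }, numeric(1))
  expect_lt(s_vals[1L], s_vals[8L])   # t=3s condition vs t=5s condition
  expect_true(all(diff(s_vals) > 0))
  # master-seed determinism, bit for bit
  exp8b <- simulate_experiment(seed = 2)
  expect_identical(lapply(exp8, `[[`, "records"),
                   lapply(exp8b, `[[`, "records"))
})

test_that("measurement noise perturbs records at the requested scale", {
  clean <- simulate_series(fix_spec(seed = 4))
  noisy <- simulate_series(fix_spec(seed = 4, measurement_noise_frac = 0.02))
  dx <- noisy$records$x - clean$records$x
  expect_gt(sd(dx), 0)
  expect_equal(sd(dx) / sd(clean$records$x), 0.02, tolerance = 0.25)
})

test_that("OLS recovers generating parameters at experiment scale", {
  # bias of each entry of the update matrix, averaged over seeds, is small
  spec_args <- list(lambda_w = 0.7, lambda_s = 0.0,
                    theta_w_deg = 2, theta_s_deg = 75)
  cfg <- fix_cfg()
  fr_true <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  B_true <- build_update_matrix(do.call(fix_spec, spec_args), fr_true)$B
  n_seeds <- 100L
  Bs <- array(NA_real_, c(2, 2, n_seeds))
  for (s in seq_len(n_seeds)) {
    ts <- simulate_series(do.call(fix_spec, c(spec_args, list(seed = s))))
    fl <- fluctuations(ts)
    Bs[, , s] <- fit_update_matrix(fl)
  }
  bias <- apply(Bs, c(1, 2), mean) - B_true
  expect_lt(max(abs(bias)), 0.05)
})
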