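test_that("operating_point is the component-wise trial mean", {
  mk <- function(x, v) {
    structure(list(records = data.frame(block = 1L, trial = seq_along(x),
                                        x = x, v = v, e = 0),
                   cfg = fix_cfg(), provenance = list(kind = "synthetic")),
              class = "trial_series")
  }
  expect_equal(operating_point(mk(c(0, 2), c(0, 2))), c(1, 1))
  expect_equal(operating_point(mk(rep(3, 5), rep(0.4, 5))), c(3, 0.4))
  # noise-free simulation sits exactly at the spec operating point
  spec <- fix_spec(sigma_nw = 0, sigma_ns = 0)
  expect_equal(operating_point(simulate_series(spec)), spec$op_point,
               tolerance = 1e-12)
})

test_that("fluctuations implements the blockwise trimming rule", {
  ts <- simulate_series(fix_spec(seed = 2))
  fl <- fluctuations(ts)
  expect_equal(nrow(fl$pairs), 450L)
  # current states are trials 5..49 of each block, successors 6..50
  within_block <- ts$records$trial[fl$pairs[, 1L]]
  expect_equal(sort(unique(within_block)), 5:49)
  expect_true(all(ts$records$block[fl$pairs[, 1L]] ==
                  ts$records$block[fl$pairs[, 2L]]))
  expect_equal(nrow(fluctuations(ts, trim_head = 0L)$pairs), 490L)
  # boundary case: 6-trial block leaves a single pair
  short <- ts
  short$records <- ts$records[ts$records$block == 1L, ][1:6, ]
  expect_equal(nrow(fluctuations(short, trim_head = 4L)$pairs), 1L)
  short$records <- short$records[1:5, ]
  expect_error(fluctuations(short, trim_head = 4L), "too short")
})

test_that("fit_update_matrix solves exact linear systems and is consistent", {
  set.seed(10)
  for (i in 1:5) {
    B0 <- matrix(rnorm(4, sd = 0.5), 2, 2)
    pm <- fix_exact_pairs(B0, n = 20L, seed = i)
    expect_equal(fit_update_matrix(pm), B0, tolerance = 1e-10)
  }
  # degenerate input: all current states identical
  pm_bad <- list(cur = matrix(1, 10, 2), nxt = matrix(1, 10, 2))
  expect_error(fit_update_matrix(pm_bad), "rank-deficient")
  # consistency: white-noise series (B = 0) shrinks the estimate with N
  set.seed(11)
  cur <- matrix(rnorm(2e4), ncol = 2L)
  nxt <- matrix(rnorm(2e4), ncol = 2L)
  expect_lt(max(abs(fit_update_matrix(list(cur = cur, nxt = nxt)))), 0.1)
})

test_that("eigenanalysis labels, normalizes and errors as specified", {
  cfg <- fix_cfg()
  fr <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  # the aggregate-mean consistency check: printed matrix rounds to 0.76, -0.03
  B <- matrix(c(0.76, -0.01, -0.26, -0.03), 2, 2)
  m <- eigenanalysis(B, fr)
  expect_equal(round(m$lambda_w, 2), 0.76)
  expect_equal(round(m$lambda_s, 2), -0.03)
  expect_equal(m$B %*% m$e_w, m$lambda_w * cbind(m$e_w), tolerance = 1e-9)
  expect_equal(m$B %*% m$e_s, m$lambda_s * cbind(m$e_s), tolerance = 1e-9)
  expect_gte(sum(m$e_w * fr$e_t), 0)
  expect_gte(sum(m$e_s * fr$e_n), 0)
  expect_gte(m$beta, 0)
  expect_true(m$theta_s_deg >= 0 && m$theta_s_deg < 180)
  # degenerate and complex cases are errors
  expect_error(eigenanalysis(0.5 * diag(2), fr), "repeated|degenerate")
  rot <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2) * 0.5
  expect_error(eigenanalysis(rot, fr), "complex")
  # invariance under positive rescaling of the data: refit on scaled pairs
  pm <- fix_exact_pairs(B, n = 30L, seed = 3)
  noisy <- list(cur = pm$cur, nxt = pm$nxt + 0.05 * matrix(rnorm(60), 30, 2))
  B1 <- fit_update_matrix(noisy)
  B2 <- fit_update_matrix(list(cur = 7.3 * noisy$cur, nxt = 7.3 * noisy$nxt))
  m1 <- eigenanalysis(B1, fr); m2 <- eigenanalysis(B2, fr)
  expect_equal(m1$lambda_w, m2$lambda_w, tolerance = 1e-10)
  expect_equal(m1$theta_s_deg, m2$theta_s_deg, tolerance = 1e-8)
})

test_that("eigencoordinate transform is the exact inverse of the basis", {
  cfg <- fix_cfg()
  fr <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  m <- eigenanalysis(matrix(c(0.76, -0.01, -0.26, -0.03), 2, 2), fr)
  expect_equal(unname(to_eigencoordinates(m$e_w, m$E)), c(1, 0),
               tolerance = 1e-10)
  expect_equal(unname(to_eigencoordinates(m$e_s, m$E)), c(0, 1),
               tolerance = 1e-10)
  set.seed(5)
  U <- matrix(rnorm(100), ncol = 2)
  Z <- to_eigencoordinates(U, m$E)
  expect_equal(Z %*% t(m$E), U, tolerance = 1e-10)
})

test_that("residual noise scales recover the generating noise", {
  # exact linear data: residuals identically zero
  B0 <- matrix(c(0.7, 0, 0.1, -0.1), 2, 2)
  pm <- fix_exact_pairs(B0, n = 40L, seed = 2)
  cfg <- fix_cfg()
  fr <- gem_frame(c(1, gem_speed(1, cfg)), cfg)
  m <- eigenanalysis(B0, fr)
  rn <- residual_noise(pm, B0, m$E)
  expect_equal(rn$sigma_nw, 0, tolerance = 1e-12)
  expect_equal(rn$sigma_ns, 0, tolerance = 1e-12)
  # long simulation: estimated sigma_ns within 3% of truth
  spec <- fix_spec(seed = 17, sigma_nw = 0.01, sigma_ns = 0.005,
                   n_blocks = 40L, block_len = 250L)
  ts <- simulate_series(spec)
  fl <- fluctuations(ts, use_first = 249L)
  fr2 <- gem_frame(operating_point(ts), ts$cfg)
  m2 <- eigenanalysis(fit_update_matrix(fl), fr2)
  rn2 <- residual_noise(fl, m2$B, m2$E)
  expect_equal(rn2$sigma_ns, 0.005, tolerance = 0.03)
  expect_equal(rn2$sigma_nw, 0.01, tolerance = 0.03)
  # permutation invariance of the RMS
  perm <- sample(nrow(fl$pairs))
  pm2 <- list(cur = fl$u[fl$pairs[perm, 1L], ], nxt = fl$u[fl$pairs[perm, 2L], ])
  rn3 <- residual_noise(pm2, m2$B, m2$E)
  expect_equal(rn3$sigma_ns, rn2$sigma_ns, tolerance = 1e-12)
})

test_that("steady_state_std implements the AR(1) stationary scale", {
  expect_equal(steady_state_std(0, 1), 1)
  expect_equal(steady_state_std(0.76, 1), 1 / sqrt(1 - 0.76^2))
  expect_error(steady_state_std(1, 1), "unbounded|random-walk")
})

test_that("full pipeline recovers eigen-quantities and matches steady state", {
  spec_args <- list(lambda_w = 0.76, lambda_s = -0.03,
                    theta_w_deg = 1, theta_s_deg = 80)
  n_seeds <- 60L
  est <- matrix(NA_real_, n_seeds, 6L)
  for (s in seq_len(n_seeds)) {
    ts <- simulate_series(do.call(fix_spec, c(spec_args, list(seed = 100 + s))))
    fl <- fluctuations(ts)
    fr <- gem_frame(operating_point(ts), ts$cfg)
    m <- eigenanalysis(fit_update_matrix(fl), fr, warn_alignment = FALSE)
    rn <- residual_noise(fl, m$B, m$E)
    est[s, ] <- c(m$lambda_w, m$lambda_s, m$theta_w_deg, m$theta_s_deg,
                  rn$sigma_nw, rn$sigma_ns)
  }
  mu <- colMeans(est)
  expect_lt(abs(mu[1L] - 0.76), 0.05)
  expect_lt(abs(mu[2L] - (-0.03)), 0.05)
  expect_lt(abs(mu[3L] - 1), 5)
  expect_lt(abs(mu[4L] - 80), 5)
  expect_lt(abs(mu[5L] / 0.01 - 1), 0.05)
  expect_lt(abs(mu[6L] / 0.01 - 1), 0.05)
  # eigencoordinate sample scale vs fitted steady-state prediction
  spec <- do.call(fix_spec, c(spec_args,
                              list(seed = 3, n_blocks = 40L, block_len = 250L)))
  ts <- simulate_series(spec)
  fl <- fluctuations(ts, use_first = 249L)
  fr <- gem_frame(operating_point(ts), ts$cfg)
  m <- eigenanalysis(fit_update_matrix(fl), fr, warn_alignment = FALSE)
  rn <- residual_noise(fl, m$B, m$E)
  z <- to_eigencoordinates(fl$u, m$E)
  expect_equal(sd(z[, 1L]), steady_state_std(m$lambda_w, rn$sigma_nw),
               tolerance = 0.1)
  expect_equal(sd(z[, 2L]), steady_state_std(m$lambda_s, rn$sigma_ns),
               tolerance = 0.1)
})
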