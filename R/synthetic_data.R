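#' Specification of a simulated shuffleboard experiment condition
#'
#' Defines the ground truth for one participant/condition: an operating point
#' on (or near) the GEM, a linear inter-trial update map with prescribed
#' eigenstructure, and additive Gaussian noise in the eigendirections. The
#' simulated trial-to-trial dynamics are
#' \deqn{u_{k+1} = B u_k + \nu_k, \qquad \nu_k = E n_k,}
#' where \code{u_k} is the fluctuation of the release state about the
#' operating point, \code{B} has eigenvalues \code{(lambda_w, lambda_s)} with
#' eigenvectors at angles \code{theta_w_deg}, \code{theta_s_deg} from the GEM
#' tangent, and \code{n_k} has independent zero-mean Gaussian components with
#' standard deviations \code{(sigma_nw, sigma_ns)}.
#'
#' Defaults are the study conditions emulated throughout the package:
#' a weakly stable eigendirection nearly tangent to the GEM
#' (\code{lambda_w = 0.76}, \code{theta_w_deg = 1}) and a strongly stable
#' transverse direction (\code{lambda_s = -0.03}, \code{theta_s_deg = 80}),
#' 10 blocks of 50 trials.
#'
#' @param cfg A \code{task_config}.
#' @param op_point Operating point \code{c(x, v)}; default on-GEM at
#'   \code{x = 1} with \code{v = gem_speed(1, cfg)}.
#' @param lambda_w,lambda_s Real eigenvalues, both with |.| < 1.
#' @param theta_w_deg Signed angle (degrees) of the weak eigenvector from the
#'   GEM tangent.
#' @param theta_s_deg Angle (degrees) of the strong eigenvector from the
#'   tangent, in (0, 180), distinct from \code{theta_w_deg} mod 180.
#' @param sigma_nw,sigma_ns Noise standard deviations in the weak/strong
#'   eigendirections (dimensionless).
#' @param n_blocks,block_len Block structure (default 10 x 50 trials).
#' @param burn_in Initial iterates discarded before recording (default 200).
#' @param measurement_noise_frac If > 0, adds independent Gaussian measurement
#'   noise to recorded x and v with sd equal to this fraction of each
#'   component's fluctuation sd (0.02 emulates ~2% apparatus precision).
#' @param seed Integer RNG seed for [simulate_series()].
#' @return Object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(cfg,
                            op_point = NULL,
                            lambda_w = 0.76, lambda_s = -0.03,
                            theta_w_deg = 1, theta_s_deg = 80,
                            sigma_nw = 0.01, sigma_ns = 0.01,
                            n_blocks = 10L, block_len = 50L,
                            burn_in = 200L,
                            measurement_noise_frac = 0,
                            seed = 1L) {
  stopifnot(inherits(cfg, "task_config"))
  if (abs(lambda_w) >= 1 || abs(lambda_s) >= 1)
    stop("unstable update map: both eigenvalue magnitudes must be < 1")
  if (abs((theta_w_deg - theta_s_deg) %% 180) < 1e-9)
    stop("eigenvector angles coincide mod 180 degrees: eigenvectors parallel")
  if (sigma_nw < 0 || sigma_ns < 0) stop("noise sd must be non-negative")
  if (is.null(op_point)) op_point <- c(1, gem_speed(1, cfg))
  structure(
    list(cfg = cfg, op_point = as.numeric(op_point),
         lambda_w = lambda_w, lambda_s = lambda_s,
         theta_w_deg = theta_w_deg, theta_s_deg = theta_s_deg,
         sigma_nw = sigma_nw, sigma_ns = sigma_ns,
         n_blocks = as.integer(n_blocks), block_len = as.integer(block_len),
         burn_in = as.integer(burn_in),
         measurement_noise_frac = measurement_noise_frac,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Build an update matrix with prescribed eigenstructure
#'
#' Constructs \code{B = E diag(lambda_w, lambda_s) E^-1} where the columns of
#' \code{E} are unit eigenvectors at angles \code{theta_w_deg},
#' \code{theta_s_deg} from the GEM tangent (measured toward the normal).
#'
#' @param spec A \code{simulation_spec}.
#' @param frame A \code{gem_frame} (defaults to the frame at the spec's
#'   operating point).
#' @return List with \code{B} (2 x 2), \code{E} (eigenvector columns
#'   \code{e_w}, \code{e_s}).
#' @export
build_update_matrix <- function(spec, frame = gem_frame(spec$op_point, spec$cfg)) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(frame, "gem_frame"))
  ang_w <- spec$theta_w_deg * pi / 180
  ang_s <- spec$theta_s_deg * pi / 180
  e_w <- cos(ang_w) * frame$e_t + sin(ang_w) * frame$e_n
  e_s <- cos(ang_s) * frame$e_t + sin(ang_s) * frame$e_n
  E <- cbind(e_w, e_s)
  if (abs(det(E)) < 1e-12) stop("eigenvector matrix singular")
  B <- E %*% diag(c(spec$lambda_w, spec$lambda_s)) %*% solve(E)
  list(B = B, E = E)
}

#' Simulate one blocked trial series
#'
#' Iterates the linear inter-trial map from \code{u_0 = 0}, discards the
#' burn-in, and records release states \code{x_k = op_point + u_k} together
#' with the exact nonlinear goal-level error \code{e_k = f(x_k, v_k)}. With
#' \code{measurement_noise_frac > 0}, independent Gaussian perturbations are
#' added to the recorded x and v (errors then recomputed from the noisy
#' state, as an apparatus would report them). Identical seed gives identical
#' output.
#'
#' @param spec A \code{simulation_spec}.
#' @return A \code{trial_series}: list with \code{records} (data.frame with
#'   columns block, trial, x, v, e), \code{cfg}, \code{provenance}.
#' @export
#' @examples
#' cfg <- task_config(mu = 0.016)
#' ts <- simulate_series(simulation_spec(cfg, seed = 7))
#' nrow(ts$records)  # 500
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  bm <- build_update_matrix(spec)
  n_rec <- spec$n_blocks * spec$block_len
  n_tot <- spec$burn_in + n_rec
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  nk <- cbind(stats::rnorm(n_tot, 0, spec$sigma_nw),
              stats::rnorm(n_tot, 0, spec$sigma_ns))
  nu <- nk %*% t(bm$E)
  u <- matrix(0, n_tot + 1L, 2L)
  tB <- t(bm$B)
  for (k in seq_len(n_tot)) {
    u[k + 1L, ] <- u[k, , drop = FALSE] %*% tB + nu[k, ]
  }
  u <- u[(spec$burn_in + 2L):(n_tot + 1L), , drop = FALSE]
  x <- spec$op_point[1L] + u[, 1L]
  v <- spec$op_point[2L] + u[, 2L]
  if (spec$measurement_noise_frac > 0) {
    x <- x + stats::rnorm(n_rec, 0, spec$measurement_noise_frac * stats::sd(x))
    v <- v + stats::rnorm(n_rec, 0, spec$measurement_noise_frac * stats::sd(v))
  }
  records <- data.frame(
    block = rep(seq_len(spec$n_blocks), each = spec$block_len),
    trial = rep(seq_len(spec$block_len), times = spec$n_blocks),
    x = x, v = v,
    e = goal_function(x, v, spec$cfg)
  )
  structure(
    list(records = records, cfg = spec$cfg,
         provenance = list(kind = "simulated", spec = spec)),
    class = "trial_series"
  )
}

#' @export
print.trial_series <- function(x, ...) {
  blk <- table(x$records$block)
  cat(sprintf("Trial series: %d trials in %d blocks (%s), %s\n",
              nrow(x$records), length(blk),
              paste(range(blk), collapse = "-"),
              x$provenance$kind %||% "unknown origin"))
  invisible(x)
}

# Save/restore the global RNG state so simulation seeds do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Stationary covariance of the linear inter-trial map
#'
#' Solves the discrete Lyapunov equation \code{Sigma = B Sigma B' + Q} by the
#' vectorized direct solve \code{vec(Sigma) = (I - B (x) B)^-1 vec(Q)}.
#' Projections onto the eigendirections reproduce the closed-form
#' steady-state variances \code{sigma_n^2 / (1 - lambda^2)} when the noise is
#' constructed in eigencoordinates.
#'
#' @param B 2 x 2 (or d x d) update matrix with spectral radius < 1.
#' @param noise_cov Noise covariance \code{Q}, same dimension.
#' @return The stationary covariance matrix.
#' @export
stationary_covariance <- function(B, noise_cov) {
  stopifnot(is.matrix(B), is.matrix(noise_cov),
            all(dim(B) == dim(noise_cov)))
  if (max(Mod(eigen(B, only.values = TRUE)$values)) >= 1)
    stop("spectral radius >= 1: no stationary covariance exists")
  d <- nrow(B)
  M <- diag(d * d) - kronecker(B, B)
  matrix(solve(M, as.vector(noise_cov)), d, d)
}

#' Simulate the full eight-condition experiment
#'
#' Builds one condition per ideal stop-time (friction via [friction_set()]),
#' places the operating point on the GEM, and simulates one blocked trial
#' series per condition with deterministic per-condition sub-seeds spawned
#' from the master seed. Passive sensitivity varies across conditions through
#' the friction coefficient.
#'
#' @param times Ideal stop-times in seconds, one per condition (default 8
#'   uniform on [3, 5] s).
#' @param base_spec_args List of overrides passed to [simulation_spec()]
#'   (e.g. eigenvalues, noise scales); \code{cfg} and \code{seed} are set per
#'   condition.
#' @param seed Master seed.
#' @param L_cm,R_cm,g Task constants shared by all conditions.
#' @return Named list of \code{trial_series}, names \code{"t3.00"} etc.
#' @export
simulate_experiment <- function(times = seq(3, 5, length.out = 8),
                                base_spec_args = list(),
                                seed = 1L,
                                L_cm = 200, R_cm = 20, g = 981) {
  stopifnot(length(times) >= 1L)
  mus <- friction_set(times, task_config(mu = 1, L_cm = L_cm, R_cm = R_cm, g = g))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(times))
  out <- vector("list", length(times))
  names(out) <- sprintf("t%.2f", times)
  for (i in seq_along(times)) {
    cfg <- task_config(mu = mus[i], L_cm = L_cm, R_cm = R_cm, g = g)
    args <- utils::modifyList(list(cfg = cfg, seed = sub_seeds[i]),
                              base_spec_args)
    out[[i]] <- simulate_series(do.call(simulation_spec, args))
  }
  out
}
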