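#' Mean operating point of a trial series
#'
#' Component-wise mean of (x, v) over all trials. For skilled performers this
#' sample mean is assumed to lie near the GEM; it is computed once on the
#' full series and held fixed by all downstream analyses (including the
#' bootstrap).
#'
#' @param series A \code{trial_series}.
#' @return Numeric \code{c(x, v)}.
#' @export
operating_point <- function(series) {
  stopifnot(inherits(series, "trial_series"))
  if (nrow(series$records) < 2L) stop("need at least 2 trials")
  c(mean(series$records$x), mean(series$records$v))
}

#' Fluctuations about the operating point with blockwise trimming
#'
#' Subtracts the operating point from every trial and selects the
#' trial-to-trial transition pairs valid for regression: within each block,
#' the first \code{trim_head} trials are dropped (possible retraining
#' transients) and only the first \code{use_first} trials may serve as
#' current states, so no pair spans a block boundary. With 50-trial blocks
#' and the defaults this keeps trials 5-49 as current states: 45 pairs per
#' block, 450 pairs over 10 blocks.
#'
#' @param series A \code{trial_series}.
#' @param op_point Operating point; default [operating_point()] of the series.
#' @param trim_head Trials removed from the start of each block (default 4).
#' @param use_first Last within-block index allowed as a current state
#'   (default 49).
#' @return Object of class \code{"fluctuation_series"}: list with \code{u}
#'   (n x 2 matrix of fluctuations, all trials), \code{block} (block index per
#'   trial), \code{pairs} (m x 2 matrix of row indices (k, k+1) into
#'   \code{u}), \code{op_point}.
#' @export
fluctuations <- function(series, op_point = operating_point(series),
                         trim_head = 4L, use_first = 49L) {
  stopifnot(inherits(series, "trial_series"))
  rec <- series$records
  u <- cbind(rec$x - op_point[1L], rec$v - op_point[2L])
  blocks <- unique(rec$block)
  pair_list <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    idx <- which(rec$block == blocks[i])
    len <- length(idx)
    if (len < trim_head + 2L)
      stop(sprintf("block %s too short (%d trials) for trim_head = %d",
                   blocks[i], len, trim_head))
    cur <- seq.int(trim_head + 1L, min(use_first, len - 1L))
    pair_list[[i]] <- cbind(idx[cur], idx[cur + 1L])
  }
  pairs <- do.call(rbind, pair_list)
  structure(
    list(u = u, block = rec$block, pairs = pairs,
         op_point = as.numeric(op_point)),
    class = "fluctuation_series"
  )
}

#' Least-squares estimate of the inter-trial update matrix
#'
#' Ordinary least squares minimizing the single-step mean-square prediction
#' error over the valid transition pairs, with no intercept (fluctuations
#' are mean-removed by construction):
#' \deqn{\hat B = \Big(\sum_k u_{k+1} u_k^T\Big)\Big(\sum_k u_k u_k^T\Big)^{-1}.}
#'
#' @param flucts A \code{fluctuation_series}, or a list with matrices
#'   \code{cur} and \code{nxt} (m x 2 each) of current/next fluctuations.
#' @return Estimated 2 x 2 matrix B.
#' @export
fit_update_matrix <- function(flucts) {
  pm <- .pair_matrices(flucts)
  if (nrow(pm$cur) < 2L) stop("need at least 2 transition pairs")
  S0 <- crossprod(pm$cur)                 # sum u_k u_k'
  if (abs(det(S0)) < 1e-14 * max(1, sum(diag(S0))^2))
    stop("rank-deficient current-state covariance: cannot fit update matrix")
  S1 <- crossprod(pm$nxt, pm$cur)         # sum u_{k+1} u_k'
  S1 %*% solve(S0)
}

.pair_matrices <- function(flucts) {
  if (inherits(flucts, "fluctuation_series")) {
    list(cur = flucts$u[flucts$pairs[, 1L], , drop = FALSE],
         nxt = flucts$u[flucts$pairs[, 2L], , drop = FALSE])
  } else if (is.list(flucts) && !is.null(flucts$cur) && !is.null(flucts$nxt)) {
    list(cur = as.matrix(flucts$cur), nxt = as.matrix(flucts$nxt))
  } else stop("'flucts' must be a fluctuation_series or list(cur, nxt)")
}

#' Labeled eigenanalysis of the update matrix relative to the GEM
#'
#' Solves \code{B e = lambda e} and labels the eigenpairs: "weak" is the
#' eigenvalue of larger magnitude (expected near 1, direction near the GEM
#' tangent), "strong" the smaller (expected near 0, transverse). Eigenvector
#' signs are normalized so \code{e_w . e_t >= 0} and \code{e_s . e_n >= 0};
#' angles from the tangent are then \code{theta_w} signed in (-90, 90] and
#' \code{theta_s} in [0, 180). \code{beta = sin(theta_s)} is the geometric
#' factor coupling strong-direction fluctuations to goal-relevant deviations.
#' Complex or (numerically) repeated eigenvalues are an error: the analysis
#' is restricted to real, distinct eigenvalues.
#'
#' @param B 2 x 2 update matrix.
#' @param frame A \code{gem_frame}.
#' @param warn_alignment If TRUE (default), warn when magnitude-based
#'   labeling disagrees with labeling by alignment of eigenvectors with the
#'   tangent (diagnostic cross-check).
#' @return Object of class \code{"linear_model_fit"}: list with \code{B},
#'   \code{lambda_w}, \code{lambda_s}, \code{e_w}, \code{e_s}, \code{E}
#'   (columns e_w, e_s), \code{theta_w_deg}, \code{theta_s_deg}, \code{beta}.
#' @export
eigenanalysis <- function(B, frame, warn_alignment = TRUE) {
  stopifnot(is.matrix(B), all(dim(B) == 2L), inherits(frame, "gem_frame"))
  eg <- eigen(B)
  lam <- eg$values
  if (any(abs(Im(lam)) > 1e-9 * pmax(1, Mod(lam))))
    stop("complex eigenvalue pair: inter-trial map outside the real, distinct regime")
  lam <- Re(lam)
  if (abs(lam[1L] - lam[2L]) < 1e-9)
    stop("repeated eigenvalue (within 1e-9): degenerate eigenstructure")
  vec <- Re(eg$vectors)
  # weak = larger |lambda|; tie broken toward larger algebraic value
  ord <- order(-abs(lam), -lam)
  i_w <- ord[1L]; i_s <- ord[2L]
  e_w <- vec[, i_w] / sqrt(sum(vec[, i_w]^2))
  e_s <- vec[, i_s] / sqrt(sum(vec[, i_s]^2))
  if (sum(e_w * frame$e_t) < 0) e_w <- -e_w
  if (sum(e_s * frame$e_n) < 0) e_s <- -e_s
  theta_w <- atan2(sum(e_w * frame$e_n), sum(e_w * frame$e_t)) * 180 / pi
  theta_s <- atan2(sum(e_s * frame$e_n), sum(e_s * frame$e_t)) * 180 / pi
  theta_s <- theta_s %% 180
  if (warn_alignment) {
    # alignment-based labeling: weak = eigenvector closer to the tangent
    al_w <- abs(sum(e_w * frame$e_t))
    al_s <- abs(sum(e_s * frame$e_t))
    if (al_s > al_w)
      warning("magnitude-based weak/strong labeling disagrees with tangent alignment")
  }
  structure(
    list(B = B,
         lambda_w = lam[i_w], lambda_s = lam[i_s],
         e_w = e_w, e_s = e_s, E = cbind(e_w = e_w, e_s = e_s),
         theta_w_deg = theta_w, theta_s_deg = theta_s,
         beta = sin(theta_s * pi / 180)),
    class = "linear_model_fit"
  )
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf(
    "Inter-trial linear model: lambda_w = %.3f, lambda_s = %.3f, theta_w = %.2f deg, theta_s = %.2f deg, beta = %.3f\n",
    x$lambda_w, x$lambda_s, x$theta_w_deg, x$theta_s_deg, x$beta))
  invisible(x)
}

#' Transform fluctuations into eigencoordinates
#'
#' \code{z_k = E^-1 u_k}: components along the weak and strong eigenvectors,
#' in which the linear dynamics decouple into two scalar AR(1)-like maps.
#'
#' @param u n x 2 matrix of fluctuations (or length-2 vector).
#' @param E 2 x 2 eigenvector matrix (columns e_w, e_s), nonsingular.
#' @return n x 2 matrix with columns \code{z_w}, \code{z_s} (or length-2
#'   vector).
#' @export
to_eigencoordinates <- function(u, E) {
  stopifnot(is.matrix(E), all(dim(E) == 2L))
  if (abs(det(E)) < 1e-14) stop("singular eigenvector matrix")
  Einv <- solve(E)
  if (is.matrix(u)) {
    z <- u %*% t(Einv)
    colnames(z) <- c("z_w", "z_s")
    z
  } else {
    stats::setNames(as.numeric(Einv %*% u), c("z_w", "z_s"))
  }
}

#' Regression residuals in eigencoordinates and noise scales
#'
#' \code{r_k = E^-1 (u_{k+1} - B u_k)} per transition pair; the noise scales
#' are the RMS of each component, \code{sigma_nw = sqrt(mean(r_w^2))} and
#' \code{sigma_ns = sqrt(mean(r_s^2))}. \code{sigma_ns} estimates the
#' intrinsic body-level noise feeding the goal-relevant direction.
#'
#' @param flucts A \code{fluctuation_series} or list(cur, nxt).
#' @param B Fitted update matrix.
#' @param E Eigenvector matrix of \code{B}.
#' @return List with \code{residuals} (m x 2, columns r_w, r_s),
#'   \code{sigma_nw}, \code{sigma_ns}.
#' @export
residual_noise <- function(flucts, B, E) {
  pm <- .pair_matrices(flucts)
  res_lab <- pm$nxt - pm$cur %*% t(B)
  r <- res_lab %*% t(solve(E))
  colnames(r) <- c("r_w", "r_s")
  list(residuals = r,
       sigma_nw = sqrt(mean(r[, 1L]^2)),
       sigma_ns = sqrt(mean(r[, 2L]^2)))
}

#' Steady-state fluctuation scale of a scalar AR(1) direction
#'
#' For \code{z_{k+1} = lambda z_k + n_k} with noise sd \code{sigma_n}, the
#' stationary sd is \code{sigma_n / sqrt(1 - lambda^2)}; it approaches the
#' input noise level as \code{lambda -> 0} and diverges at the random-walk
#' boundary \code{|lambda| = 1}.
#'
#' @param lambda AR coefficient, |lambda| < 1.
#' @param sigma_n Input noise standard deviation, >= 0.
#' @return Stationary standard deviation.
#' @export
steady_state_std <- function(lambda, sigma_n) {
  stopifnot(sigma_n >= 0)
  if (any(abs(lambda) >= 1))
    stop("|lambda| >= 1: output variance unbounded (random-walk boundary)")
  sigma_n / sqrt(1 - lambda^2)
}
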