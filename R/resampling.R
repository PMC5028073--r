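# Internal: label the eigenstructure of a 2x2 matrix relative to a GEM frame.
# Returns NULL when the eigenvalues are complex or numerically repeated, so
# bootstrap loops can drop such iterates cheaply.
.label_eigen <- function(B, e_t, e_n) {
  eg <- eigen(B)
  lam <- eg$values
  if (is.complex(lam)) {
    if (any(abs(Im(lam)) > 1e-9 * pmax(1, Mod(lam)))) return(NULL)
    lam <- Re(lam)
    vec <- Re(eg$vectors)
  } else vec <- eg$vectors
  if (abs(lam[1L] - lam[2L]) < 1e-9) return(NULL)
  ord <- order(-abs(lam), -lam)
  i_w <- ord[1L]; i_s <- ord[2L]
  e_w <- vec[, i_w]; e_w <- e_w / sqrt(sum(e_w^2))
  e_s <- vec[, i_s]; e_s <- e_s / sqrt(sum(e_s^2))
  if (sum(e_w * e_t) < 0) e_w <- -e_w
  if (sum(e_s * e_n) < 0) e_s <- -e_s
  theta_w <- atan2(sum(e_w * e_n), sum(e_w * e_t)) * 180 / pi
  theta_s <- (atan2(sum(e_s * e_n), sum(e_s * e_t)) * 180 / pi) %% 180
  list(lambda_w = lam[i_w], lambda_s = lam[i_s],
       e_w = e_w, e_s = e_s, E = cbind(e_w, e_s),
       theta_w_deg = theta_w, theta_s_deg = theta_s,
       beta = sin(theta_s * pi / 180))
}

# Internal: constructor for an empirical bootstrap distribution.
.boot_dist <- function(name, samples, n_iter, seed, n_dropped = 0L) {
  qs <- stats::quantile(samples, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(name = name, samples = samples, mean = mean(samples),
         ci_low = qs[1L], ci_high = qs[2L],
         n_iter = n_iter, seed = seed, n_dropped = n_dropped),
    class = "bootstrap_distribution"
  )
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("%s: %.4f [%.4f, %.4f] (%d samples%s)\n",
              x$name, x$mean, x$ci_low, x$ci_high, length(x$samples),
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Bootstrap the linear model and its derived quantities
#'
#' Each iterate draws the transition pairs with replacement (the resampling
#' unit is the (current, next) pair; operating point and valid-pair set are
#' fixed), refits the update matrix by least squares, re-labels the
#' eigenstructure against the GEM frame, computes lag-1 autocorrelations of
#' the resampled pairs in that iterate's eigencoordinates, and the residual
#' noise scales. Iterates whose eigenvalues come out complex or repeated are
#' dropped and counted; more than \code{max_dropped_frac} dropped is an
#' error. Deterministic under a fixed seed.
#'
#' @param flucts A \code{fluctuation_series}.
#' @param frame A \code{gem_frame}.
#' @param n_iter Bootstrap iterates (default 10000).
#' @param seed Integer seed.
#' @param max_dropped_frac Tolerated fraction of degenerate iterates
#'   (default 0.2).
#' @return Named list of \code{bootstrap_distribution} for lambda_w,
#'   lambda_s, theta_w_deg, theta_s_deg, beta, R_w1, R_s1, sigma_nw,
#'   sigma_ns, B11, B12, B21, B22.
#' @export
bootstrap_model <- function(flucts, frame, n_iter = 10000L, seed = 1L,
                            max_dropped_frac = 0.2) {
  pm <- .pair_matrices(flucts)
  m <- nrow(pm$cur)
  n_iter <- as.integer(n_iter)
  if (m < 2L) stop("need at least 2 transition pairs")
  e_t <- frame$e_t; e_n <- frame$e_n
  keys <- c("lambda_w", "lambda_s", "theta_w_deg", "theta_s_deg", "beta",
            "R_w1", "R_s1", "sigma_nw", "sigma_ns",
            "B11", "B12", "B21", "B22")
  acc <- matrix(NA_real_, n_iter, length(keys),
                dimnames = list(NULL, keys))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(m, m, replace = TRUE)
    cur <- pm$cur[idx, , drop = FALSE]
    nxt <- pm$nxt[idx, , drop = FALSE]
    S0 <- crossprod(cur)
    if (abs(det(S0)) < 1e-14) next
    B <- crossprod(nxt, cur) %*% solve(S0)
    lab <- .label_eigen(B, e_t, e_n)
    if (is.null(lab)) next
    Einv_t <- t(solve(lab$E))
    zc <- cur %*% Einv_t
    zn <- nxt %*% Einv_t
    den <- colMeans(zc^2)
    R1 <- colMeans(zn * zc) / den
    r <- (nxt - cur %*% t(B)) %*% Einv_t
    sig <- sqrt(colMeans(r^2))
    acc[it, ] <- c(lab$lambda_w, lab$lambda_s, lab$theta_w_deg,
                   lab$theta_s_deg, lab$beta, R1[1L], R1[2L],
                   sig[1L], sig[2L], B[1, 1], B[1, 2], B[2, 1], B[2, 2])
  }
  ok <- stats::complete.cases(acc)
  n_dropped <- n_iter - sum(ok)
  if (n_dropped > max_dropped_frac * n_iter)
    stop(sprintf("bootstrap diagnostic failure: %d/%d iterates degenerate",
                 n_dropped, n_iter))
  if (n_dropped > 0)
    message(sprintf("bootstrap_model: dropped %d/%d degenerate iterates",
                    n_dropped, n_iter))
  out <- lapply(keys, function(k)
    .boot_dist(k, acc[ok, k], n_iter, seed, n_dropped))
  names(out) <- keys
  out
}

#' Bootstrap the DFA persistence exponents
#'
#' DFA needs a long, properly ordered series, so the resampling enters only
#' through the eigenvector estimate: each iterate resamples pairs, refits the
#' update matrix and its eigenvectors, then transforms the ENTIRE
#' concatenated fluctuation series (first \code{trim_head} trials of each
#' block removed) into that iterate's eigencoordinates and runs DFA in each
#' direction.
#'
#' @inheritParams bootstrap_model
#' @param trim_head Trials dropped at the start of each block for the
#'   concatenated series (default 4).
#' @return List of \code{bootstrap_distribution} for \code{alpha_w},
#'   \code{alpha_s}.
#' @export
bootstrap_dfa <- function(flucts, frame, n_iter = 10000L, seed = 1L,
                          trim_head = 4L, max_dropped_frac = 0.2) {
  stopifnot(inherits(flucts, "fluctuation_series"))
  pm <- .pair_matrices(flucts)
  m <- nrow(pm$cur)
  n_iter <- as.integer(n_iter)
  keep <- unlist(lapply(split(seq_along(flucts$block), flucts$block),
                        function(idx) idx[-seq_len(min(trim_head, length(idx)))]),
                 use.names = FALSE)
  u_cat <- flucts$u[sort(keep), , drop = FALSE]
  if (nrow(u_cat) < 100L) stop("concatenated series too short for DFA bootstrap")
  boxes <- dfa_box_sizes(nrow(u_cat))
  a_w <- rep(NA_real_, n_iter)
  a_s <- rep(NA_real_, n_iter)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(m, m, replace = TRUE)
    cur <- pm$cur[idx, , drop = FALSE]
    nxt <- pm$nxt[idx, , drop = FALSE]
    S0 <- crossprod(cur)
    if (abs(det(S0)) < 1e-14) next
    B <- crossprod(nxt, cur) %*% solve(S0)
    lab <- .label_eigen(B, frame$e_t, frame$e_n)
    if (is.null(lab)) next
    z <- u_cat %*% t(solve(lab$E))
    a_w[it] <- dfa(z[, 1L], boxes)$alpha
    a_s[it] <- dfa(z[, 2L], boxes)$alpha
  }
  ok <- !is.na(a_w)
  n_dropped <- n_iter - sum(ok)
  if (n_dropped > max_dropped_frac * n_iter)
    stop(sprintf("bootstrap diagnostic failure: %d/%d iterates degenerate",
                 n_dropped, n_iter))
  list(alpha_w = .boot_dist("alpha_w", a_w[ok], n_iter, seed, n_dropped),
       alpha_s = .boot_dist("alpha_s", a_s[ok], n_iter, seed, n_dropped))
}

#' Pool bootstrap distributions across conditions
#'
#' Concatenates the raw bootstrap samples of the same quantity across
#' participants/conditions; the aggregate estimate is the pooled mean and the
#' aggregate 95% CI the pooled 2.5/97.5 percentiles.
#'
#' @param distributions List of \code{bootstrap_distribution} (same quantity).
#' @return A pooled \code{bootstrap_distribution}.
#' @export
pool <- function(distributions) {
  if (length(distributions) == 0L) stop("no distributions to pool")
  stopifnot(all(vapply(distributions, inherits, logical(1L),
                       "bootstrap_distribution")))
  samples <- unlist(lapply(distributions, `[[`, "samples"), use.names = FALSE)
  .boot_dist(distributions[[1L]]$name, samples,
             n_iter = sum(vapply(distributions, `[[`, numeric(1L), "n_iter")),
             seed = distributions[[1L]]$seed,
             n_dropped = sum(vapply(distributions,
                                    function(d) as.numeric(d$n_dropped),
                                    numeric(1L))))
}
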