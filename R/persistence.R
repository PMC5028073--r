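#' Normalized lag-1 autocorrelation
#'
#' \code{R(1) = mean(z_{k+1} z_k) / mean(z_k^2)} on the mean-removed series
#' (biased-variance convention, matching the population form). When
#' \code{pairs} is supplied only those lag-1 products enter the numerator,
#' so no product spans a block boundary; the denominator uses all samples.
#' For a linear AR(1) direction this statistic equals the eigenvalue in
#' expectation, making it an independent consistency check on the
#' eigenanalysis.
#'
#' @param z Numeric series, length >= 3.
#' @param pairs Optional m x 2 index matrix of valid (k, k+1) lag pairs;
#'   default all consecutive pairs.
#' @return R(1), in [-1, 1] up to sampling noise.
#' @export
lag1_autocorrelation <- function(z, pairs = NULL) {
  z <- as.numeric(z)
  if (length(z) < 3L) stop("series too short for lag-1 autocorrelation")
  z <- z - mean(z)
  denom <- mean(z^2)
  if (denom == 0) stop("zero variance: autocorrelation undefined")
  if (is.null(pairs)) {
    n <- length(z)
    num <- mean(z[-n] * z[-1L])
  } else {
    num <- mean(z[pairs[, 1L]] * z[pairs[, 2L]])
  }
  num / denom
}

#' Default DFA box sizes
#'
#' About 12 log-spaced integer box sizes in [4, N/4].
#'
#' @param n Series length.
#' @param n_sizes Number of sizes requested (default 12).
#' @return Strictly increasing integer vector.
#' @export
dfa_box_sizes <- function(n, n_sizes = 12L) {
  lo <- 4L
  hi <- max(lo + 1L, floor(n / 4))
  sizes <- unique(round(exp(seq(log(lo), log(hi), length.out = n_sizes))))
  sizes[sizes >= lo & sizes <= hi]
}

#' Detrended fluctuation analysis with linear detrending
#'
#' Integrates the mean-removed series into a profile, partitions it into
#' non-overlapping boxes of size n (forward segmentation, tail remainder
#' discarded), removes a least-squares line within each box, and takes
#' \code{F(n)} as the RMS of the residuals over all boxes. The exponent
#' \code{alpha} is the least-squares slope of \code{log10 F} on
#' \code{log10 n}: 0.5 for uncorrelated noise, > 0.5 for persistent series,
#' < 0.5 antipersistent, ~1.5 for integrated white noise. Used here as an
#' overall persistence measure, not as evidence of long-range correlation.
#'
#' @param z Numeric series.
#' @param box_sizes Integer box sizes (default [dfa_box_sizes()]); each box
#'   must hold >= 4 samples.
#' @return List with \code{alpha} and \code{profile} (data.frame n, F).
#' @export
#' @examples
#' set.seed(1)
#' dfa(rnorm(460))$alpha  # ~0.5
dfa <- function(z, box_sizes = dfa_box_sizes(length(z))) {
  z <- as.numeric(z)
  n_len <- length(z)
  if (length(box_sizes) < 2L) stop("need at least 2 box sizes")
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (min(box_sizes) < 4L) stop("boxes must hold at least 4 samples")
  if (n_len < 4L * min(box_sizes)) stop("series too short for DFA")
  y <- cumsum(z - mean(z))
  Fn <- vapply(box_sizes, function(n) {
    m <- n_len %/% n
    Y <- matrix(y[seq_len(m * n)], nrow = n)
    tc <- seq_len(n) - (n + 1) / 2
    stt <- sum(tc^2)
    slope <- colSums(Y * tc) / stt
    res <- sweep(Y, 2L, colMeans(Y)) - outer(tc, slope)
    sqrt(mean(res^2))
  }, numeric(1L))
  if (any(Fn <= 0)) stop("degenerate series: zero detrended fluctuation")
  lx <- log10(box_sizes); ly <- log10(Fn)
  alpha <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  list(alpha = alpha, profile = data.frame(n = box_sizes, F = Fn))
}

#' Concatenated eigencoordinate series for DFA
#'
#' DFA needs the proper temporal ordering of a long series, so instead of the
#' regression-pair convention the blocks are concatenated with only the first
#' \code{trim_head} trials of each block removed (10 x 46 = 460 trials for
#' full-length data).
#'
#' @param flucts A \code{fluctuation_series}.
#' @param E Eigenvector matrix.
#' @param trim_head Trials dropped at the start of each block (default 4).
#' @return n x 2 matrix of eigencoordinates (columns z_w, z_s).
#' @export
concatenated_eigenseries <- function(flucts, E, trim_head = 4L) {
  stopifnot(inherits(flucts, "fluctuation_series"))
  keep <- unlist(lapply(split(seq_along(flucts$block), flucts$block),
                        function(idx) idx[-seq_len(min(trim_head, length(idx)))]),
                 use.names = FALSE)
  keep <- sort(keep)
  to_eigencoordinates(flucts$u[keep, , drop = FALSE], E)
}

#' Persistence summary in both eigendirections
#'
#' Lag-1 autocorrelations on the regression-pair convention (no cross-block
#' products) and DFA exponents on the concatenated series with the first
#' trials of each block removed.
#'
#' @param flucts A \code{fluctuation_series}.
#' @param model A \code{linear_model_fit} (supplies the eigenvector basis).
#' @param trim_head Trials dropped per block for the DFA concatenation.
#' @return List with \code{R_w1}, \code{R_s1}, \code{alpha_w}, \code{alpha_s},
#'   \code{dfa_profile_w}, \code{dfa_profile_s}.
#' @export
persistence_summary <- function(flucts, model, trim_head = 4L) {
  stopifnot(inherits(flucts, "fluctuation_series"),
            inherits(model, "linear_model_fit"))
  z_all <- to_eigencoordinates(flucts$u, model$E)
  R_w1 <- lag1_autocorrelation(z_all[, 1L], flucts$pairs)
  R_s1 <- lag1_autocorrelation(z_all[, 2L], flucts$pairs)
  z_cat <- concatenated_eigenseries(flucts, model$E, trim_head)
  d_w <- dfa(z_cat[, 1L])
  d_s <- dfa(z_cat[, 2L])
  list(R_w1 = R_w1, R_s1 = R_s1,
       alpha_w = d_w$alpha, alpha_s = d_s$alpha,
       dfa_profile_w = d_w$profile, dfa_profile_s = d_s$profile)
}
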