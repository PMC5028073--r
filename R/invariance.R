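#' A coordinate transformation of the body state
#'
#' Represents an invertible change of body-state coordinates x = g(y) through
#' its Jacobian \code{T} at the operating point: small fluctuations map as
#' \code{u = T v}. Only the Jacobian matters for the fluctuation analysis, so
#' differentiable nonlinear maps are admitted via their linearization.
#'
#' @param T 2 x 2 invertible Jacobian matrix.
#' @param kind "linear" (default) or "differentiable-nonlinear".
#' @param description Free-text description stored for reproducibility.
#' @return Object of class \code{"coordinate_transform"} with fields
#'   \code{T}, \code{T_inv}, \code{kind}, \code{description}, \code{kappa}
#'   (condition number).
#' @export
coordinate_transform <- function(T, kind = "linear", description = "") {
  stopifnot(is.matrix(T), all(dim(T) == 2L), all(is.finite(T)))
  sv <- svd(T)$d
  if (sv[2L] < 1e-12 * max(1, sv[1L]))
    stop("transformation Jacobian is singular")
  structure(
    list(T = T, T_inv = solve(T), kind = kind,
         description = description, kappa = sv[1L] / sv[2L]),
    class = "coordinate_transform"
  )
}

#' Express fluctuations in new coordinates
#'
#' With \code{u = T v}, the new-coordinate fluctuations are
#' \code{v_k = T^-1 u_k}; the update matrix estimated from the transformed
#' pairs equals \code{T^-1 B T}, which has the same eigenvalues as \code{B}.
#'
#' @param flucts A \code{fluctuation_series}.
#' @param transform A \code{coordinate_transform}.
#' @return A \code{fluctuation_series} in the new coordinates (same pair
#'   index and block structure).
#' @export
transform_fluctuations <- function(flucts, transform) {
  stopifnot(inherits(flucts, "fluctuation_series"),
            inherits(transform, "coordinate_transform"))
  out <- flucts
  out$u <- flucts$u %*% t(transform$T_inv)
  out
}

#' GEM frame in transformed coordinates
#'
#' The body-goal row becomes \code{A' = A T} (since \code{A u = A T v}), so
#' the transformed GEM tangent spans its null space and the normal its row
#' space; the passive sensitivity in the new coordinates is \code{|A'|}.
#' Tangent sign is chosen to align with the mapped original tangent
#' \code{T^-1 e_t}.
#'
#' @param frame Original \code{gem_frame}.
#' @param transform A \code{coordinate_transform}.
#' @return A \code{gem_frame} in the new coordinates.
#' @export
transform_frame <- function(frame, transform) {
  stopifnot(inherits(frame, "gem_frame"),
            inherits(transform, "coordinate_transform"))
  A2 <- frame$A %*% transform$T
  nrm <- sqrt(sum(A2^2))
  e_n <- as.numeric(A2) / nrm
  e_t <- c(-e_n[2L], e_n[1L])
  mapped_t <- transform$T_inv %*% frame$e_t
  if (sum(e_t * mapped_t) < 0) e_t <- -e_t
  structure(
    list(operating_point = as.numeric(transform$T_inv %*% frame$operating_point),
         A = A2, e_t = e_t, e_n = e_n, s = nrm),
    class = "gem_frame"
  )
}

#' PCA-whitening transform of the fluctuation cloud
#'
#' Builds the worst-case coordinates for variance-based GEM detection: with
#' sample covariance \code{Sigma = C Lambda C'} (eigenvector columns
#' \code{C}, principal values \code{Lambda}), the whitening map
#' \code{P = S C'} with \code{S = diag(Lambda^-1/2)} turns the variance
#' ellipse into a circle. The returned transform has Jacobian
#' \code{T = P^-1}, so the new-coordinate fluctuations
#' \code{v = T^-1 u = P u} have identity sample covariance and the
#' variance-anisotropy signature of the GEM is destroyed — while the
#' eigenvalues of the update map are untouched.
#'
#' @param flucts A \code{fluctuation_series}.
#' @return A \code{coordinate_transform}.
#' @export
pca_whitening_transform <- function(flucts) {
  stopifnot(inherits(flucts, "fluctuation_series"))
  Sigma <- stats::cov(flucts$u)
  eg <- eigen(Sigma, symmetric = TRUE)
  if (min(eg$values) < 1e-14 * max(eg$values))
    stop("rank-deficient fluctuation covariance: cannot whiten")
  P <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  coordinate_transform(solve(P), kind = "linear",
                       description = "PCA whitening (identity sample covariance)")
}

#' Check coordinate invariance of the dynamical analysis
#'
#' Refits the update matrix on the same transition pairs expressed in new
#' coordinates and reports: the maximum eigenvalue discrepancy (exactly ~0
#' for a deterministic linear change of the same pairs), the GEM-relative
#' angles in both coordinate systems (the weak direction should stay nearly
#' tangent to the transformed GEM and the strong direction transverse), and
#' the tangent/normal variance ratio before and after (which whitening
#' collapses to ~1 even though the dynamics are unchanged).
#'
#' @param flucts A \code{fluctuation_series}.
#' @param frame A \code{gem_frame}.
#' @param transform A \code{coordinate_transform}.
#' @return List with \code{eig_original}, \code{eig_transformed},
#'   \code{max_eigenvalue_diff}, \code{theta_w_deg}, \code{theta_s_deg}
#'   (both coordinate systems), \code{variance_ratio} (tangent/normal, both
#'   systems), \code{transform_description}.
#' @export
invariance_check <- function(flucts, frame, transform) {
  B0 <- fit_update_matrix(flucts)
  fl2 <- transform_fluctuations(flucts, transform)
  fr2 <- transform_frame(frame, transform)
  B2 <- fit_update_matrix(fl2)
  ev0 <- sort(Re(eigen(B0, only.values = TRUE)$values))
  ev2 <- sort(Re(eigen(B2, only.values = TRUE)$values))
  m0 <- eigenanalysis(B0, frame, warn_alignment = FALSE)
  m2 <- eigenanalysis(B2, fr2, warn_alignment = FALSE)
  vr <- function(fl, fr) {
    comp <- decompose_fluctuation(fl$u, fr)
    stats::sd(comp[, 2L]) / stats::sd(comp[, 1L])   # tangent / normal
  }
  list(
    eig_original = ev0,
    eig_transformed = ev2,
    max_eigenvalue_diff = max(abs(ev0 - ev2)),
    theta_w_deg = c(original = m0$theta_w_deg, transformed = m2$theta_w_deg),
    theta_s_deg = c(original = m0$theta_s_deg, transformed = m2$theta_s_deg),
    variance_ratio = c(original = vr(flucts, frame),
                       transformed = vr(fl2, fr2)),
    transform_description = transform$description
  )
}
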