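#' Per-condition performance quantities and total body-goal sensitivity
#'
#' Computes, for one participant/condition: the RMS goal-level error
#' \code{sigma_e} (sample sd of e about its mean; the mean-e offset is
#' returned separately as a skill diagnostic), the sample sds of
#' goal-relevant/goal-equivalent fluctuation components (\code{sigma_R},
#' \code{sigma_N}), the strong-direction residual noise \code{sigma_ns}, the
#' passive sensitivity \code{s}, and the total body-goal sensitivity
#' \deqn{s_{TOT} = \beta s / \sqrt{1 - \lambda_s^2},}
#' the predicted gain between intrinsic strong-direction noise and goal-level
#' variability, so that \code{sigma_e / sigma_ns ~ s_TOT}.
#'
#' @param series A \code{trial_series}.
#' @param frame A \code{gem_frame} at the condition's operating point.
#' @param model A \code{linear_model_fit}.
#' @param flucts The \code{fluctuation_series} the model was fitted on
#'   (default recomputed from the series).
#' @param condition Optional condition label.
#' @return List of class \code{"scaling_point"} with fields condition,
#'   sigma_e, mean_e, sigma_R, sigma_N, sigma_ns, s, beta, lambda_s, s_tot,
#'   ratio.
#' @export
scaling_point <- function(series, frame, model,
                          flucts = fluctuations(series), condition = NA) {
  stopifnot(inherits(series, "trial_series"), inherits(frame, "gem_frame"),
            inherits(model, "linear_model_fit"))
  e <- series$records$e
  comp <- decompose_fluctuation(flucts$u, frame)
  rn <- residual_noise(flucts, model$B, model$E)
  if (rn$sigma_ns == 0) stop("sigma_ns = 0: variability ratio undefined")
  s_tot <- model$beta * frame$s / sqrt(1 - model$lambda_s^2)
  structure(
    list(condition = condition,
         sigma_e = stats::sd(e), mean_e = mean(e),
         sigma_R = stats::sd(comp[, 1L]), sigma_N = stats::sd(comp[, 2L]),
         sigma_ns = rn$sigma_ns,
         s = frame$s, beta = model$beta, lambda_s = model$lambda_s,
         s_tot = s_tot, ratio = stats::sd(e) / rn$sigma_ns),
    class = "scaling_point"
  )
}

#' Linear fit of the variability ratio against total sensitivity
#'
#' Ordinary least squares of \code{sigma_e / sigma_ns} on \code{s_TOT}
#' across conditions. Under the fluctuation model the points fall on the
#' identity line: slope ~ 1, intercept ~ 0.
#'
#' @param points List of \code{scaling_point} (>= 2, distinct s_tot), or a
#'   data.frame with columns \code{s_tot} and \code{ratio}.
#' @return List of class \code{"scaling_fit"}: \code{a} (slope), \code{b}
#'   (intercept), \code{r_squared}, \code{points} (data.frame).
#' @export
fit_scaling <- function(points) {
  df <- if (is.data.frame(points)) points else
    data.frame(s_tot = vapply(points, `[[`, numeric(1L), "s_tot"),
               ratio = vapply(points, `[[`, numeric(1L), "ratio"))
  if (nrow(df) < 2L) stop("need at least 2 conditions for the scaling fit")
  if (diff(range(df$s_tot)) < 1e-12)
    stop("identical s_tot across conditions: scaling fit rank-deficient")
  fit <- stats::lm(ratio ~ s_tot, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$ratio - mean(df$ratio))^2)
  structure(
    list(a = unname(stats::coef(fit)[2L]),
         b = unname(stats::coef(fit)[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         points = df),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit: sigma_e/sigma_ns = %.3f * s_TOT + %.3f (R^2 = %.4f, %d conditions)\n",
              x$a, x$b, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Bootstrap the scaling law across conditions
#'
#' Per iterate: each condition's transition pairs are resampled with
#' replacement and used to re-estimate sigma_e, sigma_ns, beta and lambda_s
#' (s and the operating point are held fixed, computed once per condition);
#' a linear fit of the variability ratio on s_TOT across conditions then
#' yields one (a, b) sample. Also returns the single fit using all
#' iterate-points at once as a cross-check, and the fit through the
#' per-condition bootstrap-mean points.
#'
#' @param series_list Named list of \code{trial_series} (>= 3 conditions for
#'   a meaningful fit).
#' @param n_iter Bootstrap iterates (default 10000).
#' @param seed Integer seed.
#' @param trim_head,use_first Blockwise trimming passed to [fluctuations()].
#' @return List of class \code{"scaling_boot"}: \code{fit} (scaling_fit
#'   through bootstrap-mean points), \code{a}, \code{b}
#'   (bootstrap_distribution), \code{all_points_fit} (scaling_fit over all
#'   iterate-points), \code{per_condition} (data.frame of bootstrap-mean
#'   s_tot/ratio with CIs).
#' @export
bootstrap_scaling <- function(series_list, n_iter = 10000L, seed = 1L,
                              trim_head = 4L, use_first = 49L) {
  stopifnot(length(series_list) >= 2L)
  n_iter <- as.integer(n_iter)
  n_cond <- length(series_list)
  prep <- lapply(series_list, function(ts) {
    op <- operating_point(ts)
    fl <- fluctuations(ts, op, trim_head, use_first)
    fr <- gem_frame(op, ts$cfg)
    pm <- .pair_matrices(fl)
    list(frame = fr, cur = pm$cur, nxt = pm$nxt,
         e_cur = ts$records$e[fl$pairs[, 1L]])
  })
  a_s <- rep(NA_real_, n_iter)
  b_s <- rep(NA_real_, n_iter)
  stot_acc <- matrix(NA_real_, n_iter, n_cond)
  ratio_acc <- matrix(NA_real_, n_iter, n_cond)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    ok <- TRUE
    for (j in seq_len(n_cond)) {
      p <- prep[[j]]
      m <- nrow(p$cur)
      idx <- sample.int(m, m, replace = TRUE)
      cur <- p$cur[idx, , drop = FALSE]
      nxt <- p$nxt[idx, , drop = FALSE]
      S0 <- crossprod(cur)
      if (abs(det(S0)) < 1e-14) { ok <- FALSE; break }
      B <- crossprod(nxt, cur) %*% solve(S0)
      lab <- .label_eigen(B, p$frame$e_t, p$frame$e_n)
      if (is.null(lab)) { ok <- FALSE; break }
      r <- (nxt - cur %*% t(B)) %*% t(solve(lab$E))
      sigma_ns <- sqrt(mean(r[, 2L]^2))
      if (sigma_ns == 0) { ok <- FALSE; break }
      sigma_e <- stats::sd(p$e_cur[idx])
      stot_acc[it, j] <- lab$beta * p$frame$s / sqrt(1 - lab$lambda_s^2)
      ratio_acc[it, j] <- sigma_e / sigma_ns
    }
    if (!ok) next
    x <- stot_acc[it, ]; y <- ratio_acc[it, ]
    xc <- x - mean(x)
    a_s[it] <- sum(xc * y) / sum(xc^2)
    b_s[it] <- mean(y) - a_s[it] * mean(x)
  }
  keep <- !is.na(a_s)
  if (sum(keep) < 2L) stop("too few valid bootstrap iterates for scaling fit")
  per_cond <- data.frame(
    condition = names(series_list) %||% as.character(seq_len(n_cond)),
    s_tot = colMeans(stot_acc, na.rm = TRUE),
    ratio = colMeans(ratio_acc, na.rm = TRUE),
    s_tot_lo = apply(stot_acc, 2L, stats::quantile, 0.025, na.rm = TRUE),
    s_tot_hi = apply(stot_acc, 2L, stats::quantile, 0.975, na.rm = TRUE),
    ratio_lo = apply(ratio_acc, 2L, stats::quantile, 0.025, na.rm = TRUE),
    ratio_hi = apply(ratio_acc, 2L, stats::quantile, 0.975, na.rm = TRUE)
  )
  all_pts <- data.frame(s_tot = as.vector(stot_acc[keep, ]),
                        ratio = as.vector(ratio_acc[keep, ]))
  structure(
    list(fit = fit_scaling(per_cond[, c("s_tot", "ratio")]),
         a = .boot_dist("a", a_s[keep], n_iter, seed, n_iter - sum(keep)),
         b = .boot_dist("b", b_s[keep], n_iter, seed, n_iter - sum(keep)),
         all_points_fit = fit_scaling(all_pts),
         per_condition = per_cond),
    class = "scaling_boot"
  )
}

#' Hypothesis report for the four structural predictions
#'
#' Evaluates the package's standing predictions about skilled performance
#' near a GEM against pooled bootstrap distributions:
#' \itemize{
#'   \item H1 (weak control along the GEM): CI(lambda_w) inside (0, 1), weak
#'     eigenvector nearly tangent (|mean theta_w| < \code{theta_w_max} and CI
#'     overlapping [-theta_w_max, theta_w_max]).
#'   \item H2 (strong control transverse): |mean lambda_s| <
#'     \code{lambda_s_max}, strong direction well separated from the weak
#'     (mean theta_s - |mean theta_w| > \code{angle_sep_min}).
#'   \item H3 (persistence structure): CI(R_w1) excludes 0, CI(R_s1)
#'     contains 0, CI(alpha_s) contains 0.5, mean alpha_w - mean alpha_s >
#'     \code{alpha_gap_min}.
#'   \item H4 (scaling law): CI of the slope a contains 1.
#' }
#' Raw values are always reported alongside verdicts; all thresholds are
#' configurable and echoed in the output.
#'
#' @param dists Named list of pooled \code{bootstrap_distribution}s with
#'   elements lambda_w, lambda_s, theta_w_deg, theta_s_deg, R_w1, R_s1,
#'   alpha_w, alpha_s.
#' @param scaling A \code{scaling_boot} (supplies the slope distribution).
#' @param theta_w_max,lambda_s_max,angle_sep_min,alpha_gap_min Thresholds
#'   (degrees / unitless; defaults 10, 0.2, 15, 0.2).
#' @return List of class \code{"hypothesis_report"}: per-hypothesis verdict,
#'   the values used, and the thresholds.
#' @export
hypothesis_report <- function(dists, scaling,
                              theta_w_max = 10, lambda_s_max = 0.2,
                              angle_sep_min = 15, alpha_gap_min = 0.2) {
  need <- c("lambda_w", "lambda_s", "theta_w_deg", "theta_s_deg",
            "R_w1", "R_s1", "alpha_w", "alpha_s")
  missing <- setdiff(need, names(dists))
  if (length(missing) > 0)
    stop("missing distributions for hypothesis report: ",
         paste(missing, collapse = ", "))
  ci <- function(d) c(d$ci_low, d$ci_high)
  contains <- function(d, v) d$ci_low <= v && v <= d$ci_high
  lw <- dists$lambda_w; ls <- dists$lambda_s
  tw <- dists$theta_w_deg; ts <- dists$theta_s_deg
  h1 <- (lw$ci_low > 0 && lw$ci_high < 1) &&
    (tw$ci_low <= theta_w_max && tw$ci_high >= -theta_w_max) &&
    abs(tw$mean) < theta_w_max
  h2 <- abs(ls$mean) < lambda_s_max &&
    (ts$mean - abs(tw$mean)) > angle_sep_min
  h3 <- !contains(dists$R_w1, 0) && contains(dists$R_s1, 0) &&
    contains(dists$alpha_s, 0.5) &&
    (dists$alpha_w$mean - dists$alpha_s$mean) > alpha_gap_min
  h4 <- contains(scaling$a, 1)
  structure(
    list(
      H1 = list(pass = h1, lambda_w = lw$mean, lambda_w_ci = ci(lw),
                theta_w = tw$mean, theta_w_ci = ci(tw)),
      H2 = list(pass = h2, lambda_s = ls$mean, lambda_s_ci = ci(ls),
                theta_s = ts$mean, theta_s_ci = ci(ts)),
      H3 = list(pass = h3,
                R_w1 = dists$R_w1$mean, R_w1_ci = ci(dists$R_w1),
                R_s1 = dists$R_s1$mean, R_s1_ci = ci(dists$R_s1),
                alpha_w = dists$alpha_w$mean, alpha_w_ci = ci(dists$alpha_w),
                alpha_s = dists$alpha_s$mean, alpha_s_ci = ci(dists$alpha_s)),
      H4 = list(pass = h4, a = scaling$a$mean, a_ci = ci(scaling$a),
                b = scaling$b$mean, b_ci = ci(scaling$b),
                r_squared = scaling$fit$r_squared),
      thresholds = list(theta_w_max = theta_w_max,
                        lambda_s_max = lambda_s_max,
                        angle_sep_min = angle_sep_min,
                        alpha_gap_min = alpha_gap_min)
    ),
    class = "hypothesis_report"
  )
}

#' @export
print.hypothesis_report <- function(x, ...) {
  for (h in c("H1", "H2", "H3", "H4")) {
    cat(sprintf("%s: %s\n", h, if (x[[h]]$pass) "PASS" else "FAIL"))
  }
  invisible(x)
}
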