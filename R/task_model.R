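#' Task configuration for the virtual shuffleboard
#'
#' Physical and dimensionless parameters defining the shuffleboard goal
#' function. After release at position \code{x} (cm) with speed \code{v}
#' (cm/s), the puck decelerates under Coulomb friction \code{mu} and stops at
#' \code{x_f = x + v^2/(2 mu g)}; the goal-level error is \code{x_f - L}.
#' Positions are rescaled by \code{R_cm}, speeds by \code{sqrt(2 g R_cm)},
#' so the dimensionless target distance is \code{L_tilde = L_cm / R_cm}.
#'
#' @param mu Coulomb friction coefficient (dimensionless), > 0.
#' @param L_cm Target distance in cm (default 200).
#' @param R_cm Length scale used for nondimensionalization, cm (default 20).
#' @param g Gravitational acceleration, cm/s^2 (default 981).
#' @return An object of class \code{"task_config"}: list with fields
#'   \code{mu}, \code{L_cm}, \code{R_cm}, \code{g}, \code{L_tilde}.
#' @export
#' @examples
#' cfg <- task_config(mu = 0.016)
#' cfg$L_tilde  # 10
task_config <- function(mu, L_cm = 200, R_cm = 20, g = 981) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu <= 0) stop("friction coefficient 'mu' must be positive")
  if (L_cm <= 0 || R_cm <= 0 || g <= 0)
    stop("'L_cm', 'R_cm' and 'g' must all be positive")
  structure(
    list(mu = mu, L_cm = L_cm, R_cm = R_cm, g = g, L_tilde = L_cm / R_cm),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Shuffleboard task: mu = %.5f, L = %g cm, R = %g cm, g = %g cm/s^2 (L~ = %g)\n",
    x$mu, x$L_cm, x$R_cm, x$g, x$L_tilde))
  invisible(x)
}

#' Read a task configuration from a YAML or JSON file
#'
#' Keys: \code{mu}, and optionally \code{L_cm}, \code{R_cm}, \code{g_cm_s2}.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A \code{task_config}.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$mu)) stop("config file must define 'mu'")
  task_config(
    mu = raw$mu,
    L_cm = raw$L_cm %||% 200,
    R_cm = raw$R_cm %||% 20,
    g = raw$g_cm_s2 %||% 981
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dimensionless goal function
#'
#' \code{f(x, v) = v^2/mu + x - L_tilde} for dimensionless release state
#' (x, v). Its zeros are all perfect trials and form the goal equivalent
#' manifold (GEM); its value equals the dimensionless goal-level error
#' \code{e = (x_f - L)/R}.
#'
#' @param x,v Dimensionless release position and speed (vectorized).
#' @param cfg A \code{task_config}.
#' @return Dimensionless goal-level error, same length as \code{x}.
#' @export
#' @examples
#' cfg <- task_config(mu = 0.016)
#' goal_function(0, 0.4, cfg)  # 0: on the GEM
goal_function <- function(x, v, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!all(is.finite(x)) || !all(is.finite(v)))
    stop("non-finite release state passed to goal_function")
  v^2 / cfg$mu + x - cfg$L_tilde
}

#' Nondimensionalize dimensional release data
#'
#' \code{x~ = x/R}, \code{v~ = v/sqrt(2 g R)}, \code{e~ = e/R}.
#'
#' @param x_cm Release position, cm.
#' @param v_cm_s Release speed, cm/s.
#' @param e_cm Goal-level error, cm.
#' @param cfg A \code{task_config}.
#' @return List with dimensionless \code{x}, \code{v}, \code{e}.
#' @seealso [dimensionalize()] for the exact inverse.
#' @export
nondimensionalize <- function(x_cm, v_cm_s, e_cm, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  list(
    x = x_cm / cfg$R_cm,
    v = v_cm_s / sqrt(2 * cfg$g * cfg$R_cm),
    e = e_cm / cfg$R_cm
  )
}

#' Inverse of [nondimensionalize()]
#' @param x,v,e Dimensionless position, speed, error.
#' @param cfg A \code{task_config}.
#' @return List with \code{x_cm}, \code{v_cm_s}, \code{e_cm}.
#' @export
dimensionalize <- function(x, v, e, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  list(
    x_cm = x * cfg$R_cm,
    v_cm_s = v * sqrt(2 * cfg$g * cfg$R_cm),
    e_cm = e * cfg$R_cm
  )
}

#' On-GEM release speed for a given release position
#'
#' Solves \code{goal_function(x, v) = 0} for \code{v >= 0}:
#' \code{v = sqrt(mu (L_tilde - x))}. The GEM is the parabola traced by this
#' map for \code{x < L_tilde}.
#'
#' @param x Dimensionless release position (vectorized), < \code{L_tilde}.
#' @param cfg A \code{task_config}.
#' @return Dimensionless on-GEM speed.
#' @export
gem_speed <- function(x, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (any(x > cfg$L_tilde))
    stop("no real on-GEM speed for release position at or past the target")
  sqrt(cfg$mu * (cfg$L_tilde - x))
}

#' GEM geometry at an operating point
#'
#' Linearizes the goal function about the operating point
#' \code{x* = (x*, v*)}: the 1 x 2 body-goal matrix is
#' \code{A = (1, 2 v*/mu)}, the unit tangent to the GEM spans its null space,
#' the unit normal spans its row space, and the passive sensitivity \code{s}
#' is the single singular value \code{s = sqrt(1 + (2 v*/mu)^2)}. \code{s}
#' measures how much body-level deviations are amplified into goal-level
#' error, independent of any control. The operating point need not lie
#' exactly on the GEM; \code{A} is evaluated at the given point regardless.
#'
#' @param op_point Numeric length-2, \code{c(x, v)} (dimensionless);
#'   \code{v > 0} unless \code{mu} keeps the ratio finite.
#' @param cfg A \code{task_config}.
#' @return Object of class \code{"gem_frame"}: list with
#'   \code{operating_point}, \code{A} (1 x 2 matrix), \code{e_t}, \code{e_n}
#'   (unit 2-vectors), \code{s}.
#' @export
#' @examples
#' cfg <- task_config(mu = 0.016)
#' fr <- gem_frame(c(0, 0.4), cfg)
#' fr$s  # sqrt(2501) ~ 50.01
gem_frame <- function(op_point, cfg) {
  stopifnot(inherits(cfg, "task_config"),
            is.numeric(op_point), length(op_point) == 2L,
            all(is.finite(op_point)))
  v_star <- op_point[2L]
  r <- 2 * v_star / cfg$mu
  if (!is.finite(r)) stop("degenerate operating point: 2 v*/mu not finite")
  nrm <- sqrt(1 + r^2)
  structure(
    list(
      operating_point = as.numeric(op_point),
      A = matrix(c(1, r), nrow = 1L),
      e_t = c(-r, 1) / nrm,
      e_n = c(1, r) / nrm,
      s = nrm
    ),
    class = "gem_frame"
  )
}

#' @export
print.gem_frame <- function(x, ...) {
  cat(sprintf(
    "GEM frame at (x*, v*) = (%.4f, %.4f): s = %.3f, e_t = (%.4f, %.4f)\n",
    x$operating_point[1L], x$operating_point[2L], x$s, x$e_t[1L], x$e_t[2L]))
  invisible(x)
}

#' Decompose a fluctuation into goal-relevant / goal-equivalent components
#'
#' Projects the body-level fluctuation \code{u} onto the GEM normal
#' (goal-relevant, produces error to leading order) and tangent
#' (goal-equivalent, error-free to leading order).
#'
#' @param u Numeric length-2 fluctuation, or an n x 2 matrix of fluctuations.
#' @param frame A \code{gem_frame}.
#' @return For a single vector, \code{c(u_R, u_N)}; for a matrix, an n x 2
#'   matrix with columns \code{u_R}, \code{u_N}.
#' @export
decompose_fluctuation <- function(u, frame) {
  stopifnot(inherits(frame, "gem_frame"))
  if (is.matrix(u)) {
    stopifnot(ncol(u) == 2L)
    out <- cbind(u %*% frame$e_n, u %*% frame$e_t)
    colnames(out) <- c("u_R", "u_N")
    out
  } else {
    stopifnot(length(u) == 2L)
    c(u_R = sum(u * frame$e_n), u_N = sum(u * frame$e_t))
  }
}

#' Friction coefficients from ideal stop-times
#'
#' For an ideal trial released at dimensional \code{x = 0} with the speed
#' that stops the puck exactly on the target, the stop time is
#' \code{t = sqrt(2 L / (mu g))}, so \code{mu = 2 L / (g t^2)}. Longer stop
#' times therefore give lower friction. With 8 stop-times uniform on
#' [3, 5] s, the four largest times give the "low friction" conditions and
#' the four smallest the "high friction" ones.
#'
#' @param times Ideal trial stop-times in seconds, all > 0.
#' @param cfg A \code{task_config} supplying \code{L_cm} and \code{g}
#'   (the \code{mu} field is ignored here).
#' @return Numeric vector of friction coefficients, one per time.
#' @export
#' @examples
#' cfg <- task_config(mu = 1)  # mu unused
#' friction_set(5, cfg)  # ~0.0163
friction_set <- function(times, cfg = task_config(mu = 1)) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  if (any(times <= 0)) stop("stop-times must be positive")
  2 * cfg$L_cm / (cfg$g * times^2)
}
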