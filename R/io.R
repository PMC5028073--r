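#' Write a trial series to CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal; columns participant,
#' condition, block, trial, x, v, e (dimensionless).
#'
#' @param series A \code{trial_series}.
#' @param path Output path.
#' @param participant,condition Labels written to every row.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(series, path, participant = "sim", condition = "c1") {
  stopifnot(inherits(series, "trial_series"))
  df <- cbind(participant = participant, condition = condition,
              series$records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial series from CSV
#'
#' Accepts dimensionless columns \code{x, v, e} or dimensional
#' \code{x_cm, v_cm_s, e_cm} (auto-nondimensionalized via \code{cfg});
#' requires \code{block} and \code{trial} columns and a single
#' participant/condition per file. Validates the block structure (ragged
#' blocks are retained with a warning: partial blocks occur in real data) and
#' recomputes the error from (x, v), warning when the recorded error
#' disagrees by more than \code{tol}.
#'
#' @param path CSV path.
#' @param cfg A \code{task_config} for the condition in the file.
#' @param tol Error-mismatch warning threshold, dimensionless (default 1e-6).
#' @return A \code{trial_series}.
#' @export
read_trials <- function(path, cfg, tol = 1e-6) {
  stopifnot(inherits(cfg, "task_config"))
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need_any <- c("block", "trial")
  for (col in need_any)
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  if (all(c("x_cm", "v_cm_s") %in% names(df))) {
    nd <- nondimensionalize(df$x_cm, df$v_cm_s,
                            df$e_cm %||% rep(NA_real_, nrow(df)), cfg)
    df$x <- nd$x; df$v <- nd$v
    if ("e_cm" %in% names(df)) df$e <- nd$e
  }
  for (col in c("x", "v"))
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  for (col in c("x", "v", "block", "trial")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                   col, bad[1L], path))
  }
  if ("participant" %in% names(df) && length(unique(df$participant)) > 1L)
    stop("multiple participants in one file; split per participant/condition")
  if ("condition" %in% names(df) && length(unique(df$condition)) > 1L)
    stop("multiple conditions in one file; split per participant/condition")
  e_calc <- goal_function(df$x, df$v, cfg)
  if ("e" %in% names(df)) {
    mism <- max(abs(df$e - e_calc), na.rm = TRUE)
    if (is.finite(mism) && mism > tol)
      warning(sprintf(
        "recorded error disagrees with goal function by up to %.3g in %s; using recomputed values",
        mism, path))
  }
  blk <- table(df$block)
  if (length(unique(blk)) > 1L)
    warning(sprintf("ragged blocks in %s (lengths %s); blocks retained",
                    path, paste(sort(unique(as.integer(blk))), collapse = ", ")))
  structure(
    list(records = data.frame(block = df$block, trial = df$trial,
                              x = df$x, v = df$v, e = e_calc),
         cfg = cfg,
         provenance = list(kind = "file", path = path)),
    class = "trial_series"
  )
}

# Internal: FNV-1a hash of a serialized R object, as a provenance fingerprint.
.config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full inter-trial fluctuation pipeline
#'
#' Orchestrates the complete analysis over one or more conditions: operating
#' point, blockwise-trimmed fluctuations, GEM frame, least-squares update
#' matrix with labeled eigenanalysis, persistence summary, bootstrap of all
#' eigen/correlation quantities and DFA exponents, per-condition scaling
#' points, cross-condition pooling, the bootstrapped scaling fit, and the
#' four-hypothesis report. Fully deterministic given (data, configuration,
#' seed).
#'
#' @param series_list Named list of \code{trial_series} (one per
#'   participant/condition).
#' @param n_iter Bootstrap iterates (default 10000; the paper-scale setting).
#' @param fast If TRUE, use 2000 iterates and flag reduced CI precision.
#' @param seed Master seed; per-condition sub-seeds are spawned
#'   deterministically.
#' @param trim_head,use_first Blockwise trimming (defaults 4 and 49).
#' @return Nested list of class \code{"analysis_report"}; see
#'   [write_report()] for serialization.
#' @export
run_pipeline <- function(series_list, n_iter = 10000L, fast = FALSE,
                         seed = 1L, trim_head = 4L, use_first = 49L) {
  stopifnot(length(series_list) >= 1L)
  if (is.null(names(series_list)))
    names(series_list) <- sprintf("condition%02d", seq_along(series_list))
  if (fast) n_iter <- 2000L
  n_iter <- as.integer(n_iter)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub <- matrix(sample.int(.Machine$integer.max - 1L,
                           2L * length(series_list) + 1L),
                ncol = 1L)
  per_condition <- vector("list", length(series_list))
  names(per_condition) <- names(series_list)
  pooled_src <- list()
  for (i in seq_along(series_list)) {
    ts <- series_list[[i]]
    op <- operating_point(ts)
    fl <- fluctuations(ts, op, trim_head, use_first)
    fr <- gem_frame(op, ts$cfg)
    B <- fit_update_matrix(fl)
    model <- eigenanalysis(B, fr, warn_alignment = FALSE)
    pers <- persistence_summary(fl, model, trim_head)
    bm <- bootstrap_model(fl, fr, n_iter = n_iter, seed = sub[2L * i - 1L])
    bd <- bootstrap_dfa(fl, fr, n_iter = n_iter, seed = sub[2L * i],
                        trim_head = trim_head)
    sp <- scaling_point(ts, fr, model, fl, condition = names(series_list)[i])
    dists <- c(bm, bd)
    pooled_src[[i]] <- dists
    per_condition[[i]] <- list(
      n_trials = nrow(ts$records),
      n_pairs = nrow(fl$pairs),
      operating_point = op,
      gem = list(s = fr$s, e_t = fr$e_t, e_n = fr$e_n),
      B = as.vector(t(B)),   # row-major: B11 B12 B21 B22
      point_estimates = list(
        lambda_w = model$lambda_w, lambda_s = model$lambda_s,
        theta_w_deg = model$theta_w_deg, theta_s_deg = model$theta_s_deg,
        beta = model$beta,
        R_w1 = pers$R_w1, R_s1 = pers$R_s1,
        alpha_w = pers$alpha_w, alpha_s = pers$alpha_s),
      bootstrap = lapply(dists, function(d)
        list(mean = d$mean, ci = c(d$ci_low, d$ci_high),
             n_dropped = d$n_dropped)),
      scaling_point = unclass(sp)[c("sigma_e", "mean_e", "sigma_R", "sigma_N",
                                    "sigma_ns", "s", "beta", "lambda_s",
                                    "s_tot", "ratio")]
    )
  }
  keys <- c("lambda_w", "lambda_s", "theta_w_deg", "theta_s_deg", "beta",
            "R_w1", "R_s1", "sigma_nw", "sigma_ns", "alpha_w", "alpha_s")
  pooled <- lapply(keys, function(k)
    pool(lapply(pooled_src, `[[`, k)))
  names(pooled) <- keys
  scaling <- if (length(series_list) >= 3L) {
    bootstrap_scaling(series_list, n_iter = n_iter,
                      seed = sub[2L * length(series_list) + 1L],
                      trim_head = trim_head, use_first = use_first)
  } else NULL
  hyp <- if (!is.null(scaling)) hypothesis_report(pooled, scaling) else NULL
  cfgs <- lapply(series_list, function(ts) unclass(ts$cfg))
  structure(
    list(
      per_condition = per_condition,
      aggregate = list(
        pooled = lapply(pooled, function(d)
          list(mean = d$mean, ci = c(d$ci_low, d$ci_high))),
        scaling = if (!is.null(scaling)) list(
          a = scaling$a$mean, a_ci = c(scaling$a$ci_low, scaling$a$ci_high),
          b = scaling$b$mean, b_ci = c(scaling$b$ci_low, scaling$b$ci_high),
          r_squared = scaling$fit$r_squared,
          all_points_a = scaling$all_points_fit$a,
          all_points_b = scaling$all_points_fit$b,
          per_condition = scaling$per_condition) else NULL,
        hypotheses = if (!is.null(hyp)) unclass(hyp) else NULL
      ),
      provenance = list(
        seed = seed, n_iter = n_iter, fast = fast,
        trim_head = trim_head, use_first = use_first,
        n_conditions = length(series_list),
        package_version = as.character(utils::packageVersion("gemfluct")),
        config_hash = .config_hash(cfgs)
      ),
      distributions = list(pooled = pooled, scaling = scaling)
    ),
    class = "analysis_report"
  )
}

#' Serialize an analysis report to JSON
#'
#' Writes scalar results with stable key ordering and full numeric precision
#' (identical inputs and seed give byte-identical files). The raw bootstrap
#' sample vectors are omitted from the JSON; pass
#' \code{samples_dir} to dump them as per-quantity CSV files.
#'
#' @param report An \code{analysis_report}.
#' @param path Output JSON path.
#' @param samples_dir Optional directory for per-sample CSV dumps.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, samples_dir = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  out <- report[c("per_condition", "aggregate", "provenance")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(samples_dir)) {
    dir.create(samples_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in names(report$distributions$pooled)) {
      utils::write.csv(
        data.frame(sample = report$distributions$pooled[[k]]$samples),
        file.path(samples_dir, paste0(k, ".csv")), row.names = FALSE)
    }
  }
  invisible(path)
}
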