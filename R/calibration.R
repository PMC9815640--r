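# Calibration curves: growth-rate-conditioned timer distributions.
#
# A calibration curve summarises, for one growth condition, the conditional
# distribution of (tau_i, tau_C, tau_d, k_next) given the single-cell
# exponential growth rate k of the current cycle. It is estimated by binning
# cycles on k (equal-count bins by default) and keeping both per-bin moments
# and the raw tuples, so sampling can either resample whole tuples
# (preserving within-cycle correlations) or draw independent normals from
# the per-bin moments.

timer_vars <- c("tau_i", "tau_C", "tau_d", "k_next")

#' Derive timers from event times in a cycle table
#'
#' Fills the three timers of each cycle from its recorded event times:
#' `tau_i` is the time from this cycle's initiation to the next initiation
#' in the same lineage, `tau_C = t_term - t_init`, and
#' `tau_d = t_div - t_init`. The last cycle of each lineage has no observed
#' next initiation; its `tau_i` is set to `NA` and the row is flagged
#' `terminal`, not dropped.
#'
#' @param records Data frame with columns `lineage_id`, `cycle_index`,
#'   `t_init`, `t_term`, `t_div` (minutes).
#' @return The data frame with columns `tau_i`, `tau_C`, `tau_d` and logical
#'   `terminal` filled in.
#' @export
derive_timers <- function(records) {
  req <- c("lineage_id", "cycle_index", "t_init", "t_term", "t_div")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  records <- records[order(records$lineage_id, records$cycle_index), ,
                     drop = FALSE]
  parts <- split(records, records$lineage_id)
  parts <- lapply(parts, function(d) {
    if (nrow(d) > 1L && any(diff(d$t_init) <= 0)) {
      bad <- which(diff(d$t_init) <= 0)[1] + 1L
      stop("non-monotone initiation times in lineage '", d$lineage_id[1],
           "' at cycle ", d$cycle_index[bad], call. = FALSE)
    }
    d$tau_i <- c(diff(d$t_init), NA_real_)
    d$tau_C <- d$t_term - d$t_init
    d$tau_d <- d$t_div - d$t_init
    d$terminal <- c(rep(FALSE, nrow(d) - 1L), TRUE)
    bad <- which(d$tau_C <= 0 | d$tau_d <= 0)
    if (length(bad))
      stop("non-positive timer in lineage '", d$lineage_id[1],
           "' at cycle ", d$cycle_index[bad[1]], call. = FALSE)
    bad <- which(d$tau_d <= d$tau_C)
    if (length(bad))
      stop("t_div precedes t_term (tau_d <= tau_C) in lineage '",
           d$lineage_id[1], "' at cycle ", d$cycle_index[bad[1]],
           call. = FALSE)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# k_next = growth rate of the subsequent cycle in the same lineage.
add_k_next <- function(records) {
  records <- records[order(records$lineage_id, records$cycle_index), ,
                     drop = FALSE]
  parts <- split(records, records$lineage_id)
  parts <- lapply(parts, function(d) {
    d$k_next <- c(d$k[-1], NA_real_)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Estimate a calibration curve from a single-cell cycle table
#'
#' Bins cycles on single-cell growth rate `k` using equal-count (quantile)
#' bins and computes, per bin, the count, mean and SD of each timer and of
#' the next cycle's growth rate, along with the retained raw tuples. Timer
#' statistics use every cycle with the timer observed; `k_next` statistics
#' and the retained tuples use only cycles whose successor was observed.
#'
#' @param records Data frame with columns `lineage_id`, `cycle_index`, `k`,
#'   `tau_i`, `tau_C`, `tau_d` (event-time columns are ignored here; use
#'   [derive_timers()] first if the timers are absent).
#' @param condition Name stored with the curve.
#' @param n_bins Target number of growth-rate bins (default 8). Reduced
#'   automatically when the data cannot fill them at `min_per_bin`.
#' @param min_per_bin Minimum cycles per bin (default 20).
#' @return An object of class `"calibration_curve"`: a list with elements
#'   `condition`, `bin_edges`, `k_range`, `stats` (per-bin data frame),
#'   `tuples` (raw draws with their bin), and `default_mode`.
#' @seealso [sample_cycle()], [evaluate_curve()], [write_calibration()]
#' @export
estimate_calibration <- function(records, condition = "data",
                                 n_bins = 8L, min_per_bin = 20L) {
  req <- c("lineage_id", "cycle_index", "k", "tau_i", "tau_C", "tau_d")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  check_timers(records$tau_i, records$tau_C, records$tau_d)
  if (any(!is.finite(records$k) | records$k <= 0))
    stop("growth rates k must be positive and finite", call. = FALSE)
  records <- add_k_next(records)

  usable <- records[is.finite(records$k), , drop = FALSE]
  if (nrow(usable) < 2L * min_per_bin)
    stop("too few usable cycles (", nrow(usable), ") for calibration; need ",
         2L * min_per_bin, call. = FALSE)

  nb <- max(1L, min(as.integer(n_bins), nrow(usable) %/% min_per_bin))
  edges <- unique(stats::quantile(usable$k, probs = seq(0, 1, length.out = nb + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < nb + 1L) {
    warning("tied growth rates: merged ", nb + 1L - length(edges),
            " empty bin(s)", call. = FALSE)
  }
  if (length(edges) < 2L) edges <- c(edges, edges) + c(-1e-12, 1e-12)
  bin <- findInterval(usable$k, edges, all.inside = TRUE)

  stats_df <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    d <- usable[bin == b, , drop = FALSE]
    row <- data.frame(bin = b, k_lo = edges[b], k_hi = edges[b + 1L],
                      center = if (nrow(d)) mean(d$k) else
                        (edges[b] + edges[b + 1L]) / 2,
                      n = nrow(d))
    for (v in timer_vars) {
      x <- d[[v]]; x <- x[is.finite(x)]
      row[[paste0("mean_", v)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("sd_", v)]] <- if (length(x) > 1L) stats::sd(x) else 0
      row[[paste0("n_", v)]] <- length(x)
    }
    row
  }))
  low <- stats_df$n < min_per_bin
  if (any(low))
    warning(sum(low), " bin(s) below min_per_bin = ", min_per_bin,
            call. = FALSE)

  complete <- stats::complete.cases(usable[, c("k", timer_vars)])
  tuples <- usable[complete, c("k", timer_vars), drop = FALSE]
  tuples$bin <- bin[complete]
  rownames(tuples) <- NULL

  structure(list(condition = condition,
                 bin_edges = as.numeric(edges),
                 k_range = range(usable$k),
                 stats = stats_df,
                 tuples = tuples,
                 default_mode = "empirical_joint"),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve '%s': %d k bin(s), %d retained tuples\n",
              x$condition, nrow(x$stats), nrow(x$tuples)))
  cat(sprintf("  k range: %.4g .. %.4g /min; default sampling: %s\n",
              x$k_range[1], x$k_range[2], x$default_mode))
  invisible(x)
}

# Locate the k bin of a value, optionally clamping to the observed range.
curve_bin <- function(curve, k, clamp = TRUE) {
  if (k < curve$k_range[1] || k > curve$k_range[2]) {
    if (!clamp)
      stop(sprintf("k = %g outside calibrated range [%g, %g]",
                   k, curve$k_range[1], curve$k_range[2]), call. = FALSE)
    k <- min(max(k, curve$k_range[1]), curve$k_range[2])
  }
  findInterval(k, curve$bin_edges, all.inside = TRUE)
}

#' Sample the next cycle's timers from a calibration curve
#'
#' Draws `(tau_i, tau_C, tau_d, k_next)` conditional on the current
#' single-cell growth rate `k`. In `"empirical_joint"` mode one retained
#' tuple is drawn uniformly from `k`'s bin, preserving within-cycle
#' correlations. In `"parametric_independent"` mode the four quantities are
#' drawn as independent normals from the bin's mean/SD, rejecting draws with
#' non-positive values or `tau_d <= tau_C` (after `max_reject` rejections an
#' error is raised).
#'
#' @param curve A `"calibration_curve"`.
#' @param k Current growth rate (1/min).
#' @param n Number of draws.
#' @param mode Sampling mode; defaults to the curve's `default_mode`.
#' @param clamp Clamp out-of-range `k` to the calibrated range (default);
#'   with `clamp = FALSE` an out-of-range `k` is an error.
#' @param max_reject Rejection budget per draw in parametric mode.
#' @return Data frame with `n` rows and columns
#'   `tau_i, tau_C, tau_d, k_next`.
#' @export
sample_cycle <- function(curve, k, n = 1L, mode = NULL, clamp = TRUE,
                         max_reject = 1000L) {
  stopifnot(inherits(curve, "calibration_curve"))
  mode <- match.arg(mode %||% curve$default_mode,
                    c("empirical_joint", "parametric_independent"))
  b <- curve_bin(curve, k, clamp = clamp)
  if (mode == "empirical_joint") {
    pool <- curve$tuples[curve$tuples$bin == b, timer_vars, drop = FALSE]
    if (nrow(pool) == 0L)
      stop("no retained tuples in bin ", b,
           "; use parametric_independent mode", call. = FALSE)
    out <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  s <- curve$stats[b, ]
  mu <- c(s$mean_tau_i, s$mean_tau_C, s$mean_tau_d, s$mean_k_next)
  sd <- c(s$sd_tau_i, s$sd_tau_C, s$sd_tau_d, s$sd_k_next)
  if (any(!is.finite(mu)))
    stop("bin ", b, " has undefined moments; cannot sample parametrically",
         call. = FALSE)
  draw_one <- function() {
    for (i in seq_len(max_reject)) {
      x <- stats::rnorm(4L, mu, sd)
      if (all(x > 0) && x[3] > x[2]) return(x)
    }
    stop("rejection budget exhausted in bin ", b,
         " (tau_d <= tau_C or non-positive draws)", call. = FALSE)
  }
  m <- t(vapply(seq_len(n), function(i) draw_one(), numeric(4L)))
  out <- as.data.frame(m)
  names(out) <- timer_vars
  out
}

#' Evaluate interpolated per-timer moments of a calibration curve
#'
#' Linearly interpolates the per-bin means and SDs between bin centers;
#' beyond the outermost centers the nearest bin's values are used
#' (constant extrapolation).
#'
#' @param curve A `"calibration_curve"`.
#' @param k Growth rates at which to evaluate (vector).
#' @return Data frame with one row per `k` and columns `k`, `mean_*`,
#'   `sd_*` for each of `tau_i`, `tau_C`, `tau_d`, `k_next`.
#' @export
evaluate_curve <- function(curve, k) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- data.frame(k = k)
  centers <- curve$stats$center
  for (v in paste0(rep(c("mean_", "sd_"), each = length(timer_vars)),
                   timer_vars)) {
    y <- curve$stats[[v]]
    out[[v]] <- if (length(centers) < 2L) rep(y[1], length(k)) else
      stats::approx(centers, y, xout = k, rule = 2)$y
  }
  out
}

#' Write a calibration curve to JSON
#'
#' Numbers are serialized with 17 significant digits so that
#' `read_calibration(write_calibration(curve))` reproduces the curve
#' bit-exactly.
#'
#' @param curve A `"calibration_curve"`.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- unclass(curve)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path Path to a JSON document written by [write_calibration()].
#' @return A `"calibration_curve"`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("stats", "tuples")) obj[[nm]] <- as.data.frame(obj[[nm]])
  obj$bin_edges <- as.numeric(obj$bin_edges)
  obj$k_range <- as.numeric(obj$k_range)
  if (nrow(obj$tuples)) obj$tuples$bin <- as.integer(obj$tuples$bin)
  obj$stats$bin <- as.integer(obj$stats$bin)
  for (nm in grep("^n(_|$)", names(obj$stats), value = TRUE))
    obj$stats[[nm]] <- as.integer(obj$stats[[nm]])
  structure(obj, class = "calibration_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
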