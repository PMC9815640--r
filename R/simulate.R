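# Chained replication-cycle simulation.
#
# Starting from an initiation event, each cycle draws (tau_i, tau_C, tau_d,
# k_next) from the calibration curve conditional on the cycle's growth rate,
# advances the initiation clock by tau_i, and hands k_next to the next
# cycle. No parameter is fitted: the calibration curve is the entire model.

#' Simulation configuration
#'
#' @param n_lineages Number of independent lineages.
#' @param n_cycles Cycles per lineage (must exceed `burn_in`).
#' @param burn_in Initial cycles per lineage flagged and excluded from
#'   summaries (>= 1; the first cycle has no preceding round to overlap).
#' @param seed Integer seed; identical configurations give identical output.
#' @param mode Sampling mode passed to [sample_cycle()].
#' @param k_init `"marginal"` draws each lineage's starting growth rate from
#'   the calibration's marginal `k` distribution; `"fixed"` uses `k0`.
#' @param k0 Starting growth rate when `k_init = "fixed"`.
#' @param clamp Clamp out-of-range growth rates to the calibrated range.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_lineages, n_cycles, burn_in = 10L, seed = 1L,
                       mode = c("empirical_joint", "parametric_independent"),
                       k_init = c("marginal", "fixed"), k0 = NULL,
                       clamp = TRUE) {
  mode <- match.arg(mode)
  k_init <- match.arg(k_init)
  n_lineages <- as.integer(n_lineages); n_cycles <- as.integer(n_cycles)
  burn_in <- as.integer(burn_in)
  if (n_lineages < 0L) stop("n_lineages must be >= 0", call. = FALSE)
  if (burn_in < 1L) stop("burn_in must be >= 1", call. = FALSE)
  if (n_cycles <= burn_in)
    stop("n_cycles must exceed burn_in", call. = FALSE)
  if (k_init == "fixed" && (is.null(k0) || k0 <= 0))
    stop("k_init = \"fixed\" requires a positive k0", call. = FALSE)
  structure(list(n_lineages = n_lineages, n_cycles = n_cycles,
                 burn_in = burn_in, seed = as.integer(seed), mode = mode,
                 k_init = k_init, k0 = k0, clamp = clamp),
            class = "sim_config")
}

# Draw a starting growth rate from the calibration's marginal k.
draw_k_init <- function(curve) {
  if (nrow(curve$tuples)) return(sample(curve$tuples$k, 1L))
  # parametric curve: pick a bin by its weight, use its center
  w <- curve$stats$n
  if (all(w == 0)) w <- rep(1, length(w))
  curve$stats$center[sample.int(nrow(curve$stats), 1L, prob = w)]
}

#' Simulate one lineage of chained replication cycles
#'
#' Uses the current RNG state (callers wanting reproducibility should
#' `set.seed()` first or use [simulate_population()]). Each cycle's division
#' time must exceed the previous cycle's; a draw violating this order is
#' resampled (up to `max_resample` attempts, then an error names the k bin).
#'
#' @param curve A `"calibration_curve"`.
#' @param n_cycles,burn_in,mode,clamp See [sim_config()].
#' @param k0 Starting growth rate; `NULL` draws from the marginal.
#' @param lineage_id Identifier stored in the output rows.
#' @param max_resample Resampling budget per cycle for division-order
#'   consistency.
#' @return Data frame with one row per cycle: `lineage_id`, `cycle_index`,
#'   `k`, `tau_i`, `tau_C`, `tau_d`, `t_init`, `t_term`, `t_div`,
#'   `fork_class`, `burn_in` (logical flag).
#' @export
simulate_lineage <- function(curve, n_cycles, burn_in = 10L, k0 = NULL,
                             mode = NULL, clamp = TRUE, lineage_id = "L1",
                             max_resample = 1000L) {
  stopifnot(inherits(curve, "calibration_curve"))
  n_cycles <- as.integer(n_cycles)
  k <- if (is.null(k0)) draw_k_init(curve) else k0
  tau <- matrix(NA_real_, n_cycles, 4L,
                dimnames = list(NULL, timer_vars))
  ks <- numeric(n_cycles)
  t_init <- numeric(n_cycles)
  t_prev_div <- -Inf
  t_now <- 0
  for (i in seq_len(n_cycles)) {
    ok <- FALSE
    for (attempt in seq_len(max_resample)) {
      d <- sample_cycle(curve, k, n = 1L, mode = mode, clamp = clamp)
      if (t_now + d$tau_d > t_prev_div) { ok <- TRUE; break }
    }
    if (!ok)
      stop("persistent division-order violation in k bin ",
           curve_bin(curve, k, clamp = TRUE), " (k = ", signif(k, 4), ")",
           call. = FALSE)
    tau[i, ] <- as.numeric(d[1, timer_vars])
    ks[i] <- k
    t_init[i] <- t_now
    t_prev_div <- t_now + d$tau_d
    t_now <- t_now + d$tau_i
    k <- d$k_next
  }
  out <- data.frame(lineage_id = lineage_id,
                    cycle_index = seq_len(n_cycles) - 1L,
                    k = ks,
                    tau_i = tau[, "tau_i"], tau_C = tau[, "tau_C"],
                    tau_d = tau[, "tau_d"],
                    t_init = t_init,
                    t_term = t_init + tau[, "tau_C"],
                    t_div = t_init + tau[, "tau_d"],
                    stringsAsFactors = FALSE)
  out$fork_class <- classify_cycle(out$tau_i, out$tau_C, out$tau_d)
  out$burn_in <- out$cycle_index < burn_in
  out
}

#' Simulate a population of independent lineages
#'
#' Expands the configuration seed into one substream per lineage, simulates
#' each lineage independently with [simulate_lineage()], and concatenates
#' the results. Identical `(curve, config)` pairs give byte-identical
#' output.
#'
#' @param curve A `"calibration_curve"`.
#' @param config A `"sim_config"`.
#' @return An object of class `"sim_result"`: list with `cycles` (the
#'   combined cycle table) and `provenance` (curve condition, configuration,
#'   seed, package version).
#' @export
simulate_population <- function(curve, config) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(config, "sim_config"))
  set.seed(config$seed)
  lineage_seeds <- sample.int(.Machine$integer.max - 1L,
                              max(config$n_lineages, 1L))
  rows <- vector("list", config$n_lineages)
  for (i in seq_len(config$n_lineages)) {
    set.seed(lineage_seeds[i])
    k0 <- if (config$k_init == "fixed") config$k0 else NULL
    rows[[i]] <- simulate_lineage(curve, config$n_cycles, config$burn_in,
                                  k0 = k0, mode = config$mode,
                                  clamp = config$clamp,
                                  lineage_id = sprintf("L%04d", i))
  }
  cycles <- if (config$n_lineages)
    do.call(rbind, rows)
  else {
    tmpl <- simulate_lineage(curve, 2L, 1L, lineage_id = "L0000")
    tmpl[0L, , drop = FALSE]
  }
  rownames(cycles) <- NULL
  structure(list(cycles = cycles,
                 provenance = list(condition = curve$condition,
                                   config = unclass(config),
                                   package_version =
                                     as.character(utils::packageVersion("forktimer")))),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- nrow(x$cycles)
  cat(sprintf("sim_result: %d cycles (%d post-burn-in) from condition '%s'\n",
              n, sum(!x$cycles$burn_in), x$provenance$condition))
  invisible(x)
}

# Accept either a sim_result or a plain cycle table.
as_cycle_table <- function(x, post_burn_in = TRUE) {
  cycles <- if (inherits(x, "sim_result")) x$cycles else x
  if (post_burn_in && "burn_in" %in% names(cycles))
    cycles <- cycles[!cycles$burn_in, , drop = FALSE]
  cycles
}

#' Population fork-class distribution versus growth rate
#'
#' For each growth-rate bin, the fraction of post-burn-in cycles in each
#' fork-cycle class. Bins with no cycles report `NA` probabilities rather
#' than zeros.
#'
#' @param x A `"sim_result"` or a cycle table carrying a `fork_class`
#'   column (any table lacking it is classified from its timers).
#' @param k_bin_edges Growth-rate bin edges (vector, length >= 2).
#' @return Data frame with one row per bin: `bin`, `k_lo`, `k_hi`, `n`, and
#'   probability columns `p_2`, `p_4`, `p_6`, `p_8plus` summing to 1 in
#'   every occupied bin.
#' @export
fork_distribution_vs_k <- function(x, k_bin_edges) {
  cycles <- as_cycle_table(x)
  if (nrow(cycles) == 0L) stop("no post-burn-in cycles", call. = FALSE)
  if (!"fork_class" %in% names(cycles))
    cycles$fork_class <- classify_cycle(cycles$tau_i, cycles$tau_C,
                                        cycles$tau_d)
  cycles$fork_class <- factor(cycles$fork_class, levels = fork_class_levels())
  cycles <- cycles[!is.na(cycles$fork_class), , drop = FALSE]
  nb <- length(k_bin_edges) - 1L
  bin <- findInterval(cycles$k, k_bin_edges, all.inside = TRUE)
  out_of_range <- cycles$k < k_bin_edges[1] | cycles$k > k_bin_edges[nb + 1L]
  bin[out_of_range] <- NA_integer_
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    cl <- cycles$fork_class[!is.na(bin) & bin == b]
    n <- length(cl)
    p <- if (n) as.numeric(table(cl)) / n else rep(NA_real_, 4L)
    data.frame(bin = b, k_lo = k_bin_edges[b], k_hi = k_bin_edges[b + 1L],
               n = n, p_2 = p[1], p_4 = p[2], p_6 = p[3], p_8plus = p[4])
  }))
  rownames(out) <- NULL
  out
}

#' Steady-state population summaries of a simulation
#'
#' Arithmetic means of the timers over post-burn-in cycles, plus the mean
#' inter-division time computed from consecutive division epochs within each
#' lineage. In steady state the mean inter-division time equals the mean
#' inter-initiation time (every division is preceded by a corresponding
#' initiation), which in turn equals the effective mass doubling time.
#'
#' @param x A `"sim_result"` or cycle table.
#' @return A list of class `"steady_state_summary"`: `n_cycles`,
#'   `mean_tau_i`, `mean_tau_C`, `mean_tau_d`, `mean_interdivision`,
#'   `se_interdivision`, `mdt_effective`, `se_tau_i`.
#' @export
steady_state_summaries <- function(x) {
  cycles <- as_cycle_table(x)
  if (nrow(cycles) == 0L) stop("no post-burn-in cycles", call. = FALSE)
  interdiv <- unlist(lapply(split(cycles$t_div, cycles$lineage_id),
                            function(td) if (length(td) > 1L) diff(sort(td))
                            else numeric(0)), use.names = FALSE)
  tau_i <- cycles$tau_i[is.finite(cycles$tau_i)]
  res <- list(n_cycles = nrow(cycles),
              mean_tau_i = mean(tau_i),
              mean_tau_C = mean(cycles$tau_C, na.rm = TRUE),
              mean_tau_d = mean(cycles$tau_d, na.rm = TRUE),
              se_tau_i = stats::sd(tau_i) / sqrt(length(tau_i)),
              mean_interdivision = mean(interdiv),
              se_interdivision = stats::sd(interdiv) / sqrt(length(interdiv)))
  res$mdt_effective <- res$mean_interdivision
  structure(res, class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf(paste0("steady state over %d cycles:\n",
                     "  mean tau_i          %8.2f min\n",
                     "  mean tau_C          %8.2f min\n",
                     "  mean tau_d          %8.2f min\n",
                     "  mean inter-division %8.2f min (effective MDT)\n"),
              x$n_cycles, x$mean_tau_i, x$mean_tau_C, x$mean_tau_d,
              x$mean_interdivision))
  invisible(x)
}
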