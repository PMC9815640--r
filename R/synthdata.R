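# Ground-truth synthetic data generator.
#
# Emulates single-cell lineage tables with the statistical structure the
# framework assumes: per-cycle tuples (k, tau_i, tau_C, tau_d, k_next) whose
# conditional means vary smoothly with the single-cell growth rate k,
# mother-daughter growth-rate correlation via a stationary AR(1) on log k,
# lognormal timer noise, and the hard constraint tau_d > tau_C. Presets are
# anchored to population mass doubling times of 195 min (slow), 52 and 63
# min (intermediate), plus a fast condition constructed to sit in the
# 8-plus-fork mean regime.

#' Specify a ground-truth growth condition
#'
#' The conditional mean functions are
#' `tau_C(k) = c0 + c1 / k` (diminishing returns as `k` grows),
#' `tau_d(k) = tau_C(k) + d0` (a constant termination-to-division offset),
#' and `tau_i(k)` proportional to `ln(2) / k`, rescaled so that the
#' *population* mean inter-initiation time equals the mass doubling time
#' exactly: in steady state every division is preceded by one initiation,
#' so the population mean of `tau_i` must equal the MDT, and because
#' `E[1/k] > 1/E[k]` for a dispersed `k`, the naive `ln(2)/k` would
#' overshoot by the factor `E[k] * E[1/k] = 1 + CV_k^2` (lognormal `k`).
#'
#' @param name Condition name.
#' @param mdt Population mass doubling time, minutes.
#' @param c0,c1 C-period coefficients: `tau_C(k) = c0 + c1 / k`
#'   (`c0` minutes, `c1` dimensionless).
#' @param d0 Termination-to-division offset, minutes (`tau_d - tau_C`).
#' @param timer_cv Coefficient of variation of the lognormal noise on each
#'   timer (default 0.15).
#' @param k_cv Coefficient of variation of the stationary growth-rate
#'   marginal (default 0.15).
#' @param rho Mother-daughter (lag-1) autocorrelation of `log k`
#'   (default 0.3).
#' @return An object of class `"truth_spec"` with the coefficients plus the
#'   derived log-normal parameters of the `k` chain.
#' @export
truth_spec <- function(name, mdt, c0, c1, d0, timer_cv = 0.15,
                       k_cv = 0.15, rho = 0.3) {
  if (mdt <= 0) stop("mdt must be positive", call. = FALSE)
  if (d0 <= 0) stop("d0 must be positive (tau_d > tau_C)", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  if (timer_cv < 0 || k_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  k_mean <- log(2) / mdt
  sigma_log <- sqrt(log1p(k_cv^2))
  mu_log <- log(k_mean) - sigma_log^2 / 2
  spec <- structure(list(name = name, mdt = mdt, c0 = c0, c1 = c1, d0 = d0,
                         timer_cv = timer_cv, k_cv = k_cv, rho = rho,
                         k_mean = k_mean, mu_log = mu_log,
                         sigma_log = sigma_log,
                         # population-mean identity: E[tau_i] = MDT
                         tau_i_scale = exp(-sigma_log^2)),
                    class = "truth_spec")
  ks <- truth_k_support(spec)
  if (any(truth_mean(spec, "tau_C", ks) <= 0) ||
      any(truth_mean(spec, "tau_i", ks) <= 0))
    stop("mean timer functions must be positive over the k support",
         call. = FALSE)
  spec
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf(paste0("truth spec '%s': MDT = %g min (mean k = %.4g /min)\n",
                     "  tau_C(k) = %g + %g/k, tau_d = tau_C + %g; ",
                     "timer CV %g, k CV %g, rho %g\n"),
              x$name, x$mdt, x$k_mean, x$c0, x$c1, x$d0,
              x$timer_cv, x$k_cv, x$rho))
  invisible(x)
}

# k support used for validation and truth-curve discretization:
# mean +/- 3 SD, floored at a small positive rate.
truth_k_support <- function(spec, n = 50L) {
  sd_k <- spec$k_mean * spec$k_cv
  lo <- max(spec$k_mean - 3 * sd_k, spec$k_mean / 20)
  hi <- spec$k_mean + 3 * sd_k
  if (spec$k_cv == 0) { lo <- spec$k_mean * 0.999; hi <- spec$k_mean * 1.001 }
  seq(lo, hi, length.out = n)
}

#' Conditional mean timer functions of a truth specification
#'
#' @param spec A `"truth_spec"`.
#' @param what One of `"tau_i"`, `"tau_C"`, `"tau_d"`.
#' @param k Growth rates (1/min).
#' @return Mean timer values at `k`, minutes.
#' @export
truth_mean <- function(spec, what = c("tau_i", "tau_C", "tau_d"), k) {
  what <- match.arg(what)
  switch(what,
         tau_i = log(2) / k * spec$tau_i_scale,
         tau_C = spec$c0 + spec$c1 / k,
         tau_d = spec$c0 + spec$c1 / k + spec$d0)
}

#' Built-in growth-condition presets
#'
#' Four documented conditions anchored to population mass doubling times:
#'
#' * `"slow"` — MDT 195 min (acetate-like minimal medium); mostly 2-fork
#'   cycles with occasional 4-fork cycles.
#' * `"intermediate_glucose"` — MDT 52 min; mixture of 4- and 6-fork cycles.
#' * `"intermediate_glycerol11aa"` — MDT 63 min; 4/6 mixture tilted to
#'   4-fork.
#' * `"fast"` — MDT 25 min, constructed so the mean timers satisfy the
#'   8-plus-fork inequality chain `tau_i < tau_C < 2 tau_i < tau_d < 3
#'   tau_i`.
#'
#' Noise levels (timer CV 0.15, growth-rate CV 0.15, lag-1 autocorrelation
#' 0.3) are documented placeholders at realistic single-cell magnitudes, not
#' fits to any particular dataset.
#'
#' @param name Preset name.
#' @return A `"truth_spec"`.
#' @examples
#' preset("slow")$mdt  # 195
#' @export
preset <- function(name = c("slow", "intermediate_glucose",
                            "intermediate_glycerol11aa", "fast")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% eval(formals(preset)$name))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: ", paste(eval(formals(preset)$name), collapse = ", "),
         call. = FALSE)
  switch(name,
    slow = truth_spec("slow", mdt = 195, c0 = 50, c1 = 0.30, d0 = 30),
    intermediate_glucose =
      truth_spec("intermediate_glucose", mdt = 52, c0 = 30, c1 = 0.30,
                 d0 = 25),
    intermediate_glycerol11aa =
      truth_spec("intermediate_glycerol11aa", mdt = 63, c0 = 30, c1 = 0.30,
                 d0 = 25),
    fast = truth_spec("fast", mdt = 25, c0 = 30, c1 = 0.30, d0 = 25))
}

#' Discretize a truth specification into a parametric calibration curve
#'
#' Evaluates the analytic mean functions on equal-width growth-rate bins
#' spanning the mean `k` plus/minus three SD and populates the per-bin
#' moments (`sd = CV * mean`); bin counts are proportional to the lognormal
#' mass of each bin, so marginal draws of `k` follow the specified
#' distribution. The curve has no retained tuples and defaults to
#' parametric sampling.
#'
#' @param spec A `"truth_spec"`.
#' @param n_bins Number of bins (default 25).
#' @param n_virtual Total virtual count distributed over bins (default
#'   1000).
#' @return A `"calibration_curve"`.
#' @export
make_truth_calibration <- function(spec, n_bins = 25L, n_virtual = 1000L) {
  stopifnot(inherits(spec, "truth_spec"))
  ks <- truth_k_support(spec, n = 2L)
  edges <- seq(ks[1], ks[length(ks)], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mass <- if (spec$k_cv == 0) rep(1 / n_bins, n_bins) else
    diff(stats::plnorm(edges, spec$mu_log, spec$sigma_log))
  n <- pmax(1L, as.integer(round(n_virtual * mass / sum(mass))))

  m_i <- truth_mean(spec, "tau_i", centers)
  m_C <- truth_mean(spec, "tau_C", centers)
  m_d <- truth_mean(spec, "tau_d", centers)
  # conditional lognormal k_next given k = center under the AR(1) on log k
  m2 <- spec$mu_log + spec$rho * (log(centers) - spec$mu_log)
  s2 <- spec$sigma_log^2 * (1 - spec$rho^2)
  mean_kn <- exp(m2 + s2 / 2)
  sd_kn <- mean_kn * sqrt(expm1(s2))

  stats_df <- data.frame(bin = seq_len(n_bins), k_lo = edges[-length(edges)],
                         k_hi = edges[-1], center = centers, n = n,
                         mean_tau_i = m_i, sd_tau_i = spec$timer_cv * m_i,
                         n_tau_i = n,
                         mean_tau_C = m_C, sd_tau_C = spec$timer_cv * m_C,
                         n_tau_C = n,
                         mean_tau_d = m_d,
                         sd_tau_d = spec$timer_cv * sqrt(m_C^2 + spec$d0^2),
                         n_tau_d = n,
                         mean_k_next = mean_kn, sd_k_next = sd_kn,
                         n_k_next = n)
  tuples <- data.frame(k = numeric(0), tau_i = numeric(0),
                       tau_C = numeric(0), tau_d = numeric(0),
                       k_next = numeric(0), bin = integer(0))
  structure(list(condition = spec$name, bin_edges = as.numeric(edges),
                 k_range = range(edges), stats = stats_df, tuples = tuples,
                 default_mode = "parametric_independent"),
            class = "calibration_curve")
}

# Lognormal draw with mean m and coefficient of variation cv.
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, length.out = n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

#' Generate a synthetic single-cell lineage table
#'
#' Simulates `n_lineages` lineages of `n_cycles` replication cycles each.
#' The growth rate follows a stationary AR(1) on `log k` with the
#' specification's marginal and lag-1 autocorrelation. `tau_i` and `tau_C`
#' are drawn per cycle as lognormals with `k`-dependent means at the
#' specified CV; `tau_d` is `tau_C` plus an independent lognormal
#' termination-to-division increment with mean `d0`, so `tau_d > tau_C`
#' holds by construction and every stated conditional mean is exact. Draws
#' that would put a cycle's division before its predecessor's are rejected
#' and redrawn. The last cycle of each lineage has `tau_i = NA` (its next
#' initiation is unobserved), matching real lineage tables.
#'
#' @param spec A `"truth_spec"`.
#' @param n_lineages,n_cycles Table dimensions.
#' @param seed Integer seed; fixed seed gives an identical table.
#' @param max_resample Per-cycle rejection budget; exhausting it signals an
#'   infeasible specification.
#' @return A cycle table: `lineage_id`, `cycle_index`, `k`, `tau_i`,
#'   `tau_C`, `tau_d`, `t_init`, `t_term`, `t_div`.
#' @export
generate_lineage_table <- function(spec, n_lineages, n_cycles, seed = 1L,
                                   max_resample = 1000L) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(as.integer(seed))
  rows <- vector("list", n_lineages)
  for (l in seq_len(n_lineages)) {
    # stationary AR(1) chain on log k
    logk <- numeric(n_cycles)
    logk[1] <- stats::rnorm(1L, spec$mu_log, spec$sigma_log)
    if (n_cycles > 1L) {
      innov_sd <- spec$sigma_log * sqrt(1 - spec$rho^2)
      for (i in 2L:n_cycles)
        logk[i] <- spec$mu_log + spec$rho * (logk[i - 1L] - spec$mu_log) +
          stats::rnorm(1L, 0, innov_sd)
    }
    k <- exp(logk)

    tau_i <- tau_C <- tau_d <- numeric(n_cycles)
    t_init <- numeric(n_cycles); t_prev_div <- -Inf
    for (i in seq_len(n_cycles)) {
      m_i <- truth_mean(spec, "tau_i", k[i])
      m_C <- truth_mean(spec, "tau_C", k[i])
      ok <- FALSE
      for (a in seq_len(max_resample)) {
        ti <- rlnorm_mean_cv(1L, m_i, spec$timer_cv)
        tc <- rlnorm_mean_cv(1L, m_C, spec$timer_cv)
        # tau_d = tau_C + a positive termination-to-division increment, so
        # tau_d > tau_C holds by construction and the conditional means are
        # exact (an accept-reject step here would truncate the joint
        # distribution and bias the realized mean tau_C low)
        td <- tc + rlnorm_mean_cv(1L, spec$d0, spec$timer_cv)
        if (t_init[i] + td > t_prev_div) { ok <- TRUE; break }
      }
      if (!ok)
        stop("infeasible truth spec '", spec$name,
             "': rejection budget exhausted at lineage ", l, ", cycle ",
             i - 1L, call. = FALSE)
      tau_i[i] <- ti; tau_C[i] <- tc; tau_d[i] <- td
      t_prev_div <- t_init[i] + td
      if (i < n_cycles) t_init[i + 1L] <- t_init[i] + ti
    }
    tau_i[n_cycles] <- NA_real_   # next initiation unobserved
    rows[[l]] <- data.frame(lineage_id = sprintf("L%04d", l),
                            cycle_index = seq_len(n_cycles) - 1L,
                            k = k, tau_i = tau_i, tau_C = tau_C,
                            tau_d = tau_d, t_init = t_init,
                            t_term = t_init + tau_C, t_div = t_init + tau_d,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a truth specification as JSON
#'
#' @param spec A `"truth_spec"`.
#' @param path JSON path.
#' @return `path` invisibly (write) or the restored spec (read).
#' @export
write_truth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "truth_spec"))
  core <- spec[c("name", "mdt", "c0", "c1", "d0", "timer_cv", "k_cv", "rho")]
  jsonlite::write_json(core, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_spec
#' @export
read_truth_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(truth_spec, obj)
}
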