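# Fork-stratified analyses.
#
# Tools for asking whether timer trends versus growth rate depend on the
# fork configuration of the cycle: stratification by fork class, binned
# summary statistics, total-variation comparison of fork-class
# distributions, and a within-bin permutation test that formalizes the
# visual "independent of fork number" comparison.

#' Partition cycles by fork-cycle class
#'
#' @param cycles A cycle table (or `"sim_result"`) with a `fork_class`
#'   column; tables lacking it are classified from their timers.
#' @return A list with `strata` (named list of data frames, one per
#'   non-empty class) and `counts` (named integer vector over all classes).
#' @export
stratify_by_fork_class <- function(cycles) {
  cycles <- as_cycle_table(cycles)
  if (!"fork_class" %in% names(cycles))
    cycles$fork_class <- classify_cycle(cycles$tau_i, cycles$tau_C,
                                        cycles$tau_d)
  cl <- factor(cycles$fork_class, levels = fork_class_levels())
  counts <- table(cl)
  strata <- split(cycles, cl, drop = TRUE)
  list(strata = strata,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Binned mean and SD of a quantity versus growth rate
#'
#' @param x Growth rates (or any binning variable).
#' @param y Values to summarize; same length as `x`.
#' @param bin_edges Bin edges (length >= 2); values outside the edges are
#'   dropped.
#' @return Data frame of class `"binned_stat"` with one row per non-empty
#'   bin: `bin`, `lo`, `hi`, `center` (edge midpoint), `mean_x`, `n`,
#'   `mean`, `sd` (population SD, divisor `n`).
#' @export
binned_stat <- function(x, y, bin_edges) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y) &
    x >= bin_edges[1] & x <= bin_edges[length(bin_edges)]
  x <- x[keep]; y <- y[keep]
  bin <- findInterval(x, bin_edges, all.inside = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    yy <- y[bin == b]
    data.frame(bin = b, lo = bin_edges[b], hi = bin_edges[b + 1L],
               center = (bin_edges[b] + bin_edges[b + 1L]) / 2,
               mean_x = mean(x[bin == b]), n = length(yy), mean = mean(yy),
               sd = sqrt(mean((yy - mean(yy))^2)))
  }))
  rownames(out) <- NULL
  class(out) <- c("binned_stat", "data.frame")
  out
}

# Per-bin class proportions as a matrix (bins x classes) plus counts.
class_props_by_bin <- function(cycles, bin_edges) {
  d <- fork_distribution_vs_k(cycles, bin_edges)
  p <- as.matrix(d[, c("p_2", "p_4", "p_6", "p_8plus")])
  list(p = p, n = d$n, bins = d$bin)
}

#' Compare two fork-class distributions across growth-rate bins
#'
#' Computes, per growth-rate bin, the total-variation (TV) distance between
#' the fork-class distributions of two cycle tables,
#' `TV = 0.5 * sum_c |P_sim(c) - P_emp(c)|`, and an overall distance that
#' weights bins by the reference table's cycle counts. A TV of 0 means the
#' distributions agree exactly; 1 means disjoint support.
#'
#' @param simulated,empirical Cycle tables (or `"sim_result"` objects); the
#'   second table provides the weights for the overall distance.
#' @param bin_edges Shared growth-rate bin edges.
#' @return A list of class `"distribution_comparison"`: `per_bin` (data
#'   frame with `bin`, `k_lo`, `k_hi`, `n_sim`, `n_emp`, `tv`) and
#'   `overall_tv`.
#' @export
compare_fork_distributions <- function(simulated, empirical, bin_edges) {
  sim <- as_cycle_table(simulated); emp <- as_cycle_table(empirical)
  if (min(sim$k) > max(emp$k) || max(sim$k) < min(emp$k))
    stop("growth-rate ranges of the two tables are disjoint", call. = FALSE)
  a <- class_props_by_bin(sim, bin_edges)
  b <- class_props_by_bin(emp, bin_edges)
  tv <- 0.5 * rowSums(abs(a$p - b$p))
  per_bin <- data.frame(bin = a$bins,
                        k_lo = bin_edges[a$bins], k_hi = bin_edges[a$bins + 1L],
                        n_sim = a$n, n_emp = b$n, tv = tv)
  occ <- a$n > 0 & b$n > 0
  if (!any(occ))
    stop("no growth-rate bin occupied by both tables", call. = FALSE)
  overall <- sum(per_bin$tv[occ] * b$n[occ]) / sum(b$n[occ])
  structure(list(per_bin = per_bin, overall_tv = overall),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("fork-class distribution comparison: overall TV = %.4f\n",
              x$overall_tv))
  print(x$per_bin)
  invisible(x)
}

#' Permutation test for fork-number dependence of a timer
#'
#' Tests whether a timer's trend against growth rate differs between two
#' fork-class strata (by default the 4- and 6-fork cycles). Within each
#' growth-rate bin occupied by both strata, the difference of stratum means
#' is computed; the global statistic is the count-weighted mean absolute
#' difference. The null distribution is obtained by permuting fork-class
#' labels *within* bins, which controls for the different growth-rate ranges
#' of the strata (multifork cycles concentrate at high k). A large p-value
#' is consistent with titration of limiting replication substrates (effect
#' independent of fork number); a small one supports fork-number-dependent
#' interference (fork spacing).
#'
#' @param cycles Cycle table (or `"sim_result"`) with `fork_class`.
#' @param quantity Timer to test: `"tau_C"` (default) or `"tau_i"`.
#' @param classes The two fork classes to compare (default `c("4", "6")`).
#' @param bin_edges Growth-rate bin edges; default: 8 equal-count bins of
#'   the pooled `k`.
#' @param min_per_stratum Minimum cycles per stratum for a bin to count as
#'   common (default 5).
#' @param n_perm Number of label permutations (default 1999).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A list of class `"fork_dependence_test"`: `per_bin` (data frame
#'   of common bins with stratum means and their difference), `statistic`
#'   (weighted mean absolute difference, minutes), `p_value`, `verdict`
#'   (`"fork-independent"` when `p >= alpha`, `"fork-dependent"`
#'   otherwise), `n_perm`, `alpha`, and `stratum_sizes`.
#' @export
fork_dependence_test <- function(cycles, quantity = c("tau_C", "tau_i"),
                                 classes = c("4", "6"), bin_edges = NULL,
                                 min_per_stratum = 5L, n_perm = 1999L,
                                 alpha = 0.05) {
  quantity <- match.arg(quantity)
  cycles <- as_cycle_table(cycles)
  if (!"fork_class" %in% names(cycles))
    cycles$fork_class <- classify_cycle(cycles$tau_i, cycles$tau_C,
                                        cycles$tau_d)
  if (length(classes) != 2L) stop("exactly two classes required", call. = FALSE)
  d <- cycles[cycles$fork_class %in% classes &
                is.finite(cycles[[quantity]]) & is.finite(cycles$k), ,
              drop = FALSE]
  if (is.null(bin_edges))
    bin_edges <- unique(stats::quantile(d$k, seq(0, 1, length.out = 9L),
                                        names = FALSE))
  bin <- findInterval(d$k, bin_edges, all.inside = TRUE)
  is_a <- d$fork_class == classes[1]
  tab <- table(bin, factor(is_a, levels = c(TRUE, FALSE)))
  common <- as.integer(rownames(tab))[tab[, 1] >= min_per_stratum &
                                        tab[, 2] >= min_per_stratum]
  if (length(common) < 2L)
    stop("strata share fewer than 2 growth-rate bins (",
         length(common), " common)", call. = FALSE)

  vals <- lapply(common, function(b) d[[quantity]][bin == b])
  laba <- lapply(common, function(b) is_a[bin == b])
  nb_tot <- vapply(vals, length, 0L)
  na_b <- vapply(laba, sum, 0L)

  obs_diffs <- mapply(function(v, l) mean(v[l]) - mean(v[!l]), vals, laba)
  obs <- sum(nb_tot * abs(obs_diffs)) / sum(nb_tot)

  perm <- vapply(seq_len(n_perm), function(i) {
    s <- vapply(seq_along(vals), function(b) {
      v <- vals[[b]]; n <- nb_tot[b]; na <- na_b[b]
      sa <- sum(v[sample.int(n, na)])
      abs(sa / na - (sum(v) - sa) / (n - na)) * n
    }, numeric(1))
    sum(s) / sum(nb_tot)
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)

  per_bin <- data.frame(bin = common,
                        k_lo = bin_edges[common], k_hi = bin_edges[common + 1L],
                        n_a = na_b, n_b = nb_tot - na_b,
                        mean_a = vapply(seq_along(vals), function(b)
                          mean(vals[[b]][laba[[b]]]), numeric(1)),
                        mean_b = vapply(seq_along(vals), function(b)
                          mean(vals[[b]][!laba[[b]]]), numeric(1)))
  per_bin$diff <- per_bin$mean_a - per_bin$mean_b
  structure(list(quantity = quantity, classes = classes, per_bin = per_bin,
                 statistic = obs, p_value = p,
                 verdict = if (p >= alpha) "fork-independent" else
                   "fork-dependent",
                 n_perm = n_perm, alpha = alpha,
                 stratum_sizes = stats::setNames(c(sum(na_b),
                                                   sum(nb_tot - na_b)),
                                                 classes)),
            class = "fork_dependence_test")
}

#' @export
print.fork_dependence_test <- function(x, ...) {
  cat(sprintf(paste0("fork-dependence permutation test on %s ",
                     "(%s- vs %s-fork cycles)\n",
                     "  common bins: %d, stratum sizes: %d / %d\n",
                     "  weighted mean |difference| = %.3f min, ",
                     "p = %.4f (%d permutations)\n  verdict: %s\n"),
              x$quantity, x$classes[1], x$classes[2], nrow(x$per_bin),
              x$stratum_sizes[1], x$stratum_sizes[2], x$statistic,
              x$p_value, x$n_perm, x$verdict))
  invisible(x)
}
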