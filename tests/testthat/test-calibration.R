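test_that("timers derive from event times by subtraction within lineages", {
  rec <- data.frame(lineage_id = "L1", cycle_index = 0:1,
                    t_init = c(0, 100), t_term = c(50, 160),
                    t_div = c(70, 185))
  out <- derive_timers(rec)
  expect_equal(out$tau_i, c(100, NA))
  expect_equal(out$tau_C, c(50, 60))
  expect_equal(out$tau_d, c(70, 85))
  expect_equal(out$terminal, c(FALSE, TRUE))
})

test_that("derive_timers rejects inconsistent event times, naming the cycle", {
  bad <- data.frame(lineage_id = "L7", cycle_index = 0:1,
                    t_init = c(0, 100), t_term = c(80, 160),
                    t_div = c(70, 185))
  expect_error(derive_timers(bad), "L7.*cycle 0")
  nonmono <- data.frame(lineage_id = "L9", cycle_index = 0:1,
                        t_init = c(100, 50), t_term = c(150, 90),
                        t_div = c(170, 120))
  expect_error(derive_timers(nonmono), "non-monotone.*L9")
})

test_that("single-cycle lineages are flagged terminal, not dropped", {
  rec <- data.frame(lineage_id = "solo", cycle_index = 0L,
                    t_init = 0, t_term = 50, t_div = 70)
  out <- derive_timers(rec)
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$tau_i))
  expect_true(out$terminal)
})

test_that("identical growth rates collapse to a single bin with sample means", {
  set.seed(5)
  tab <- table_from_timers(tau_i = rnorm(80, 100, 5),
                           tau_C = rnorm(80, 50, 3),
                           tau_d = rnorm(80, 80, 4), k = 0.007)
  curve <- suppressWarnings(estimate_calibration(tab, min_per_bin = 20))
  expect_equal(nrow(curve$stats), 1L)
  expect_equal(curve$stats$mean_tau_C, mean(tab$tau_C))
  expect_equal(curve$stats$mean_tau_d, mean(tab$tau_d))
  expect_equal(curve$stats$mean_tau_i, mean(tab$tau_i))
})

test_that("calibration rejects invalid inputs", {
  tab <- table_from_timers(rep(100, 50), rep(50, 50), rep(80, 50))
  tab$tau_d[3] <- 40                       # violates tau_d > tau_C
  expect_error(estimate_calibration(tab), "tau_d must exceed tau_C")
  small <- table_from_timers(rep(100, 10), rep(50, 10), rep(80, 10))
  expect_error(estimate_calibration(small), "too few")
})

test_that("per-bin mean estimates tighten as the table grows", {
  spec <- preset("intermediate_glucose")
  err_for <- function(n_lineages) {
    tab <- generate_lineage_table(spec, n_lineages, 20, seed = 101)
    curve <- estimate_calibration(tab, n_bins = 5)
    truth <- vapply(seq_len(nrow(curve$stats)), function(b) {
      kk <- curve$tuples$k[curve$tuples$bin == b]
      mean(truth_mean(spec, "tau_C", kk))
    }, numeric(1))
    mean(abs(curve$stats$mean_tau_C - truth))
  }
  expect_lt(err_for(100), err_for(10))
})

test_that("zero-variance parametric sampling returns exactly the bin means", {
  curve <- zero_var_curve(100, 50, 70)
  d <- sample_cycle(curve, 0.01, n = 5)
  expect_equal(d$tau_i, rep(100, 5))
  expect_equal(d$tau_C, rep(50, 5))
  expect_equal(d$tau_d, rep(70, 5))
})

test_that("empirical sampling with a single retained tuple always returns it", {
  tab <- table_from_timers(rep(100, 41), rep(50, 41), rep(80, 41))
  curve <- suppressWarnings(estimate_calibration(tab, n_bins = 1))
  one <- curve
  one$tuples <- one$tuples[1, ]
  d <- sample_cycle(one, 0.01, n = 10, mode = "empirical_joint")
  expect_true(all(d$tau_i == one$tuples$tau_i))
  expect_true(all(d$k_next == one$tuples$k_next))
})

test_that("parametric Monte-Carlo moments match the bin parameters", {
  curve <- two_bin_curve()
  set.seed(7)
  n <- 2e4
  d <- sample_cycle(curve, 0.01, n = n, mode = "parametric_independent")
  s <- curve$stats[1, ]
  for (v in c("tau_i", "tau_C", "tau_d")) {
    se <- s[[paste0("sd_", v)]] / sqrt(n)
    expect_lt(abs(mean(d[[v]]) - s[[paste0("mean_", v)]]), 3 * se)
  }
  # every draw satisfies the timer invariants
  expect_true(all(d$tau_i > 0 & d$tau_C > 0 & d$tau_d > d$tau_C))
})

test_that("empirical resampling is uniform over a bin's retained tuples", {
  set.seed(11)
  tab <- table_from_timers(tau_i = rnorm(21, 100, 5),
                           tau_C = rnorm(21, 50, 3),
                           tau_d = rnorm(21, 80, 4))
  curve <- suppressWarnings(estimate_calibration(tab, n_bins = 1,
                                                 min_per_bin = 10))
  n_tuples <- nrow(curve$tuples)
  draws <- sample_cycle(curve, 0.01, n = 4000, mode = "empirical_joint")
  counts <- table(factor(match(draws$tau_i, curve$tuples$tau_i),
                         levels = seq_len(n_tuples)))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("curve evaluation interpolates linearly and clamps beyond the centers", {
  curve <- two_bin_curve(centers = c(0.01, 0.02), mean_tau_C = c(40, 60))
  ev <- evaluate_curve(curve, c(0.01, 0.015, 0.02, 0.005, 0.05))
  expect_equal(ev$mean_tau_C, c(40, 50, 60, 40, 60))
  expect_equal(ev$sd_tau_C, rep(4, 5))
})

test_that("out-of-range growth rates clamp by default and error on request", {
  curve <- zero_var_curve(100, 50, 70, k = 0.01)
  expect_silent(sample_cycle(curve, 1, clamp = TRUE))
  expect_error(sample_cycle(curve, 1, clamp = FALSE), "outside")
})

test_that("calibration curves survive a JSON round trip bit-exactly", {
  spec <- preset("slow")
  tab <- generate_lineage_table(spec, 40, 15, seed = 3)
  curve <- estimate_calibration(tab, condition = "slow-check", n_bins = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(curve, path)
  back <- read_calibration(path)
  expect_identical(back$bin_edges, curve$bin_edges)
  expect_identical(back$k_range, curve$k_range)
  for (v in names(curve$stats))
    expect_identical(back$stats[[v]], curve$stats[[v]], label = v)
  for (v in names(curve$tuples))
    expect_identical(back$tuples[[v]], curve$tuples[[v]], label = v)
  expect_identical(back$condition, curve$condition)
})
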