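test_that("zero-variance curves put every post-burn-in cycle in one class", {
  cfg <- sim_config(n_lineages = 3, n_cycles = 12, burn_in = 2, seed = 1,
                    mode = "parametric_independent")
  res2 <- simulate_population(zero_var_curve(100, 50, 70), cfg)
  expect_true(all(res2$cycles$fork_class[!res2$cycles$burn_in] == "2"))
  res6 <- simulate_population(zero_var_curve(40, 60, 75), cfg)
  expect_true(all(res6$cycles$fork_class[!res6$cycles$burn_in] == "6"))
})

test_that("identical configuration and seed give byte-identical tables", {
  spec <- preset("intermediate_glycerol11aa")
  curve <- estimate_calibration(
    generate_lineage_table(spec, 40, 15, seed = 2), n_bins = 4)
  cfg <- sim_config(n_lineages = 10, n_cycles = 15, burn_in = 3, seed = 99)
  a <- simulate_population(curve, cfg)
  b <- simulate_population(curve, cfg)
  expect_identical(a$cycles, b$cycles)
})

test_that("an empty population is an empty table, not an error", {
  cfg <- sim_config(n_lineages = 0, n_cycles = 5, burn_in = 1, seed = 1)
  res <- simulate_population(zero_var_curve(100, 50, 70), cfg)
  expect_equal(nrow(res$cycles), 0L)
  expect_true(all(c("k", "tau_i", "fork_class") %in% names(res$cycles)))
})

test_that("simulated lineages satisfy the timer and division-order invariants", {
  spec <- preset("intermediate_glucose")
  curve <- estimate_calibration(
    generate_lineage_table(spec, 50, 20, seed = 4))
  cfg <- sim_config(n_lineages = 20, n_cycles = 20, burn_in = 2, seed = 31)
  cyc <- simulate_population(curve, cfg)$cycles
  expect_true(all(cyc$tau_d > cyc$tau_C))
  expect_true(all(cyc$tau_i > 0))
  for (d in split(cyc, cyc$lineage_id))
    expect_true(all(diff(d$t_div) > 0))
})

test_that("fork-class fractions are a probability distribution per occupied bin", {
  spec <- preset("intermediate_glucose")
  tab <- generate_lineage_table(spec, 60, 20, seed = 8)
  curve <- estimate_calibration(tab)
  cfg <- sim_config(n_lineages = 30, n_cycles = 20, burn_in = 2, seed = 5)
  res <- simulate_population(curve, cfg)
  fd <- fork_distribution_vs_k(res, curve$bin_edges)
  occ <- fd$n > 0
  sums <- rowSums(fd[occ, c("p_2", "p_4", "p_6", "p_8plus")])
  expect_true(all(abs(sums - 1) < 1e-12))
  # degenerate all-2 table
  fd2 <- fork_distribution_vs_k(
    simulate_population(zero_var_curve(100, 50, 70),
                        sim_config(3, 10, 2, 1,
                                   mode = "parametric_independent")),
    c(0.005, 0.015))
  expect_equal(fd2$p_2[fd2$n > 0], 1)
})

test_that("deterministic curves give summaries equal to the configured means", {
  res <- simulate_population(zero_var_curve(100, 50, 70),
                             sim_config(3, 10, 2, 1,
                                        mode = "parametric_independent"))
  s <- steady_state_summaries(res)
  expect_equal(s$mean_tau_i, 100)
  expect_equal(s$mean_tau_C, 50)
  expect_equal(s$mean_tau_d, 70)
  expect_equal(s$mean_interdivision, 100)
})

test_that("mean inter-division time telescopes to the mean inter-initiation time", {
  spec <- preset("slow")
  curve <- estimate_calibration(generate_lineage_table(spec, 60, 25, seed = 12))
  res <- simulate_population(curve, sim_config(40, 40, 5, seed = 21))
  s <- steady_state_summaries(res)
  se <- sqrt(s$se_tau_i^2 + s$se_interdivision^2)
  expect_lt(abs(s$mean_interdivision - s$mean_tau_i), 3 * se)
  expect_gt(s$mean_tau_d, s$mean_tau_C)
})

test_that("shortening the inter-initiation timer never lowers the fork number", {
  spec <- preset("intermediate_glycerol11aa")
  base <- make_truth_calibration(spec)
  shorter <- base
  shorter$stats$mean_tau_i <- 0.7 * shorter$stats$mean_tau_i
  shorter$stats$sd_tau_i <- 0.7 * shorter$stats$sd_tau_i
  cfg <- sim_config(n_lineages = 25, n_cycles = 25, burn_in = 5, seed = 14,
                    mode = "parametric_independent")
  fork_number <- c("2" = 2, "4" = 4, "6" = 6, "8+" = 8)
  mean_forks <- function(curve) {
    cyc <- simulate_population(curve, cfg)$cycles
    cyc <- cyc[!cyc$burn_in, ]
    mean(fork_number[as.character(cyc$fork_class)])
  }
  expect_gte(mean_forks(shorter), mean_forks(base))
})

test_that("two independent seeds give matching fork distributions", {
  spec <- preset("intermediate_glucose")
  curve <- estimate_calibration(generate_lineage_table(spec, 80, 25, seed = 6))
  # >= 5000 post-burn-in cycles per replicate
  mk <- function(seed) simulate_population(
    curve, sim_config(150, 45, 10, seed = seed))
  cmp <- compare_fork_distributions(mk(1001), mk(2002), curve$bin_edges)
  expect_lt(cmp$overall_tv, 0.05)
})
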