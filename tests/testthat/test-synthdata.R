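test_that("presets are anchored to their mass doubling times", {
  expect_equal(preset("slow")$mdt, 195)
  expect_equal(preset("intermediate_glucose")$mdt, 52)
  expect_equal(preset("intermediate_glycerol11aa")$mdt, 63)
  expect_error(preset("broth"), "available: slow")
})

test_that("preset mean timers sit in the intended fork regimes", {
  regime_at_mean <- function(spec) {
    k <- spec$k_mean
    classify_mean_regime(truth_mean(spec, "tau_i", k),
                         truth_mean(spec, "tau_C", k),
                         truth_mean(spec, "tau_d", k))
  }
  expect_equal(regime_at_mean(preset("slow")), "2")
  expect_equal(regime_at_mean(preset("intermediate_glucose")), "6")
  expect_equal(regime_at_mean(preset("intermediate_glycerol11aa")), "4")
  expect_equal(regime_at_mean(preset("fast")), "8+")
})

test_that("generation is deterministic under a fixed seed", {
  spec <- preset("slow")
  a <- generate_lineage_table(spec, 5, 10, seed = 42)
  b <- generate_lineage_table(spec, 5, 10, seed = 42)
  expect_identical(a, b)
  c_ <- generate_lineage_table(spec, 5, 10, seed = 43)
  expect_false(identical(a, c_))
})

test_that("growth-rate chains carry the configured lag-1 autocorrelation", {
  spec <- preset("intermediate_glucose")
  tab <- generate_lineage_table(spec, 25, 400, seed = 15)
  ac <- unlist(lapply(split(log(tab$k), tab$lineage_id), function(lk) {
    stats::cor(lk[-length(lk)], lk[-1])
  }))
  # pooled estimate over 10^4 cycles
  expect_lt(abs(mean(ac) - spec$rho), 0.05)
})

test_that("mean inter-initiation time equals the mass doubling time", {
  for (name in c("slow", "intermediate_glucose")) {
    spec <- preset(name)
    tab <- generate_lineage_table(spec, 40, 250, seed = 16)
    ti <- tab$tau_i[!is.na(tab$tau_i)]
    se <- stats::sd(ti) / sqrt(length(ti))
    expect_lt(abs(mean(ti) - spec$mdt), 3 * se)
  }
})

test_that("slow growth yields mostly 2-fork cycles with a 4-fork tail rising in k", {
  spec <- preset("slow")
  tab <- generate_lineage_table(spec, 80, 25, seed = 17)
  cls <- classify_cycle(tab$tau_i[!is.na(tab$tau_i)],
                        tab$tau_C[!is.na(tab$tau_i)],
                        tab$tau_d[!is.na(tab$tau_i)])
  frac <- prop.table(table(cls))
  expect_gt(frac[["2"]], 0.5)
  expect_gt(frac[["4"]], 0.02)
  fd <- fork_distribution_vs_k(tab, stats::quantile(tab$k, c(0, .25, .5, .75, 1)))
  expect_true(all(diff(fd$p_4) > 0))
})

test_that("zero-variance generation reproduces the deterministic engine classes", {
  for (mdt in c(195, 63, 52)) {
    spec <- truth_spec("deterministic", mdt = mdt, c0 = 30, c1 = 0.30,
                       d0 = 25, timer_cv = 0, k_cv = 0, rho = 0)
    tab <- generate_lineage_table(spec, 1, 8, seed = 1)
    keep <- !is.na(tab$tau_i)
    cls <- unique(as.character(classify_cycle(tab$tau_i[keep],
                                              tab$tau_C[keep],
                                              tab$tau_d[keep])))
    engine <- attr(run_deterministic_cycle(tab$tau_i[1], tab$tau_C[1],
                                           tab$tau_d[1]),
                   "forks_after")[["initiation"]]
    expect_equal(cls, as.character(engine))
  }
})

test_that("generated tables are valid calibration input end to end", {
  spec <- preset("intermediate_glycerol11aa")
  tab <- generate_lineage_table(spec, 50, 20, seed = 18)
  expect_true(all(tab$tau_d > tab$tau_C))
  expect_true(all(diff(tab$t_div[tab$lineage_id == "L0001"]) > 0))
  curve <- estimate_calibration(tab, condition = spec$name)
  res <- simulate_population(curve, sim_config(5, 10, 2, seed = 1))
  expect_equal(nrow(res$cycles), 50L)
})

test_that("truth calibration curves expose the analytic moments", {
  spec <- preset("intermediate_glucose")
  curve <- make_truth_calibration(spec)
  k <- curve$stats$center
  expect_equal(curve$stats$mean_tau_C, truth_mean(spec, "tau_C", k))
  expect_equal(curve$stats$sd_tau_C, 0.15 * truth_mean(spec, "tau_C", k))
  # zero-CV spec gives a curve whose draws are deterministic
  det <- truth_spec("flat", mdt = 52, c0 = 30, c1 = 0.30, d0 = 25,
                    timer_cv = 0, k_cv = 0)
  dcurve <- make_truth_calibration(det, n_bins = 3)
  d1 <- sample_cycle(dcurve, det$k_mean)
  d2 <- sample_cycle(dcurve, det$k_mean)
  expect_equal(d1[, c("tau_i", "tau_C", "tau_d")],
               d2[, c("tau_i", "tau_C", "tau_d")])
})

test_that("truth specs survive a JSON round trip", {
  spec <- preset("fast")
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_spec(spec, path)
  back <- read_truth_spec(path)
  expect_equal(back, spec)
})
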