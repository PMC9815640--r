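# Shared fixtures: built in code, no files.

# A degenerate (zero-variance) parametric calibration curve whose every draw
# returns exactly the given timer means, with k held at a fixed value.
zero_var_curve <- function(tau_i, tau_C, tau_d, k = 0.01) {
  stats <- data.frame(bin = 1L, k_lo = k * 0.5, k_hi = k * 1.5, center = k,
                      n = 100L,
                      mean_tau_i = tau_i, sd_tau_i = 0, n_tau_i = 100L,
                      mean_tau_C = tau_C, sd_tau_C = 0, n_tau_C = 100L,
                      mean_tau_d = tau_d, sd_tau_d = 0, n_tau_d = 100L,
                      mean_k_next = k, sd_k_next = 0, n_k_next = 100L)
  structure(list(condition = "degenerate",
                 bin_edges = c(k * 0.5, k * 1.5), k_range = c(k * 0.5, k * 1.5),
                 stats = stats,
                 tuples = data.frame(k = numeric(0), tau_i = numeric(0),
                                     tau_C = numeric(0), tau_d = numeric(0),
                                     k_next = numeric(0), bin = integer(0)),
                 default_mode = "parametric_independent"),
            class = "calibration_curve")
}

# A small two-bin curve with hand-set moments, for interpolation tests.
two_bin_curve <- function(centers = c(0.01, 0.02),
                          mean_tau_C = c(40, 60)) {
  edges <- c(centers[1] - 0.0025, mean(centers), centers[2] + 0.0025)
  stats <- do.call(rbind, lapply(1:2, function(b) {
    data.frame(bin = b, k_lo = edges[b], k_hi = edges[b + 1], center = centers[b],
               n = 50L,
               mean_tau_i = 100 - 10 * b, sd_tau_i = 5, n_tau_i = 50L,
               mean_tau_C = mean_tau_C[b], sd_tau_C = 4, n_tau_C = 50L,
               mean_tau_d = mean_tau_C[b] + 30, sd_tau_d = 6, n_tau_d = 50L,
               mean_k_next = centers[b], sd_k_next = 0.001, n_k_next = 50L)
  }))
  structure(list(condition = "two-bin", bin_edges = edges,
                 k_range = range(edges), stats = stats,
                 tuples = data.frame(k = numeric(0), tau_i = numeric(0),
                                     tau_C = numeric(0), tau_d = numeric(0),
                                     k_next = numeric(0), bin = integer(0)),
                 default_mode = "parametric_independent"),
            class = "calibration_curve")
}

# Independent brute-force oracle for the steady-state fork count after
# initiation: naive event enumeration driven entirely through the exported
# state-machine operations (a separate code path from the engine's internal
# loop).
oracle_forks_after_init <- function(tau_i, tau_C, tau_d, n_cycles = 20L) {
  j <- seq_len(n_cycles) - 1L
  ev <- data.frame(time = round(c(j * tau_i + tau_C, j * tau_i + tau_d,
                                  j * tau_i), 9),
                   prio = rep(1:3, each = n_cycles))
  ev <- ev[ev$time <= round((n_cycles - 1L) * tau_i, 9), ]
  ev <- ev[order(ev$time, ev$prio), ]
  st <- chromosome_state()
  forks_after_init <- NA_integer_
  for (i in seq_len(nrow(ev))) {
    st <- switch(ev$prio[i],
                 apply_termination(st), apply_division(st),
                 apply_initiation(st))
    if (ev$prio[i] == 3L) forks_after_init <- n_forks(st)
  }
  forks_after_init
}

# Cycle table with prescribed per-cycle timers at a common growth rate.
table_from_timers <- function(tau_i, tau_C, tau_d, k = 0.01,
                              lineage_id = "L1") {
  n <- length(tau_i)
  t_init <- cumsum(c(0, tau_i[-n]))
  data.frame(lineage_id = lineage_id, cycle_index = seq_len(n) - 1L,
             k = k, tau_i = tau_i, tau_C = tau_C, tau_d = tau_d,
             t_init = t_init, t_term = t_init + tau_C,
             t_div = t_init + tau_d, stringsAsFactors = FALSE)
}
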