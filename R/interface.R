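# Formats and pipeline orchestration.
#
# Cycle tables travel as tab-separated UTF-8 text with '.' decimals and
# 'NA' for the undefined inter-initiation time of lineage-terminal cycles.
# File headers carry units (k_per_min, tau_i_min, ...); in-memory columns
# drop them (k, tau_i, ...). Growth rates are 1/min throughout; convert
# doubling times with k = ln(2) / MDT at the boundary only.

cycle_col_map <- c(lineage_id = "lineage_id", cycle_index = "cycle_index",
                   k = "k_per_min", tau_i = "tau_i_min", tau_C = "tau_C_min",
                   tau_d = "tau_d_min", t_init = "t_init_min",
                   t_term = "t_term_min", t_div = "t_div_min",
                   fork_class = "fork_class")

#' Read a single-cell cycle table
#'
#' Reads a tab-separated cycle table with header columns `lineage_id`,
#' `cycle_index`, `k_per_min` and either the timer columns (`tau_i_min`,
#' `tau_C_min`, `tau_d_min`) or the event-time columns (`t_init_min`,
#' `t_term_min`, `t_div_min`); with event times only, the timers are
#' derived via [derive_timers()]. Rows violating `tau_d > tau_C`, with
#' non-positive durations, or with non-numeric fields are reported with
#' their file row number.
#'
#' @param path Path to the TSV file.
#' @return A validated cycle table with in-memory column names
#'   (`k`, `tau_i`, ...) and an attached `row` column giving the originating
#'   file row.
#' @export
read_cycle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  names(raw) <- trimws(names(raw))
  need <- c("lineage_id", "cycle_index", "k_per_min")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  have_timers <- all(c("tau_i_min", "tau_C_min", "tau_d_min") %in% names(raw))
  have_events <- all(c("t_init_min", "t_term_min", "t_div_min") %in% names(raw))
  if (!have_timers && !have_events)
    stop("need either timer columns (tau_i_min, tau_C_min, tau_d_min) or ",
         "event-time columns (t_init_min, t_term_min, t_div_min)",
         call. = FALSE)

  out <- data.frame(lineage_id = raw$lineage_id, stringsAsFactors = FALSE)
  out$row <- seq_len(nrow(raw)) + 1L        # header is file row 1
  num_col <- function(file_name) {
    x <- raw[[file_name]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "NA" & x != "")
    if (length(bad))
      stop("non-numeric value '", x[bad[1]], "' in column ", file_name,
           ", file row ", bad[1] + 1L, call. = FALSE)
    v
  }
  out$cycle_index <- as.integer(num_col("cycle_index"))
  out$k <- num_col("k_per_min")
  for (v in c("tau_i", "tau_C", "tau_d", "t_init", "t_term", "t_div")) {
    fn <- cycle_col_map[[v]]
    if (fn %in% names(raw)) out[[v]] <- num_col(fn)
  }
  if (!have_timers) out <- derive_timers(out)
  if ("fork_class" %in% names(raw))
    out$fork_class <- factor(raw$fork_class, levels = fork_class_levels())

  bad <- which(!is.na(out$k) & out$k <= 0)
  if (length(bad))
    stop("non-positive growth rate in file row ", out$row[bad[1]],
         call. = FALSE)
  bad <- which(!is.na(out$tau_d) & !is.na(out$tau_C) & out$tau_d <= out$tau_C)
  if (length(bad))
    stop("tau_d <= tau_C in file row ", out$row[bad[1]], call. = FALSE)
  bad <- which((!is.na(out$tau_i) & out$tau_i <= 0) |
                 (!is.na(out$tau_C) & out$tau_C <= 0) |
                 (!is.na(out$tau_d) & out$tau_d <= 0))
  if (length(bad))
    stop("non-positive timer in file row ", out$row[bad[1]], call. = FALSE)
  out
}

#' Write a cycle table
#'
#' Inverse of [read_cycle_table()]: writes tab-separated text with the
#' unit-suffixed header names. Numeric columns are rendered with 17
#' significant digits so that reading the file back reproduces the doubles
#' exactly.
#'
#' @param table Cycle table (or `"sim_result"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycle_table <- function(table, path) {
  table <- as_cycle_table(table, post_burn_in = FALSE)
  cols <- intersect(names(cycle_col_map), names(table))
  out <- table[, cols, drop = FALSE]
  for (v in cols) {
    if (is.numeric(out[[v]]) && !is.integer(out[[v]]))
      out[[v]] <- ifelse(is.na(out[[v]]), "NA", sprintf("%.17g", out[[v]]))
  }
  names(out) <- cycle_col_map[cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Command orchestration (shared by the CLI wrapper in inst/scripts).

command_keys <- list(
  synth = c("preset", "n_lineages", "n_cycles", "seed", "out"),
  calibrate = c("input", "condition", "n_bins", "min_per_bin", "out"),
  simulate = c("curve", "n_lineages", "n_cycles", "burn_in", "seed", "mode",
               "out"),
  analyze = c("input", "quantity", "n_bins", "n_perm", "alpha", "seed",
              "out"),
  compare = c("simulated", "empirical", "n_bins", "out"))

check_config <- function(name, config) {
  unknown <- setdiff(names(config), command_keys[[name]])
  if (length(unknown))
    stop("unknown configuration key(s) for '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  config
}

write_provenance <- function(path, name, config) {
  prov <- list(command = name, config = config,
               seed = config$seed %||% NA,
               package_version =
                 as.character(utils::packageVersion("forktimer")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
}

#' Run a pipeline command
#'
#' Orchestrates one step of the synth / calibrate / simulate / analyze /
#' compare pipeline from a named configuration list (the same structure the
#' command-line wrapper assembles from its flags). Unknown keys are
#' rejected. Every run writes a provenance JSON (`<out>.provenance.json`)
#' recording the command, the full configuration, the seed, and package and
#' R versions. Output is deterministic given the configuration.
#'
#' @param name One of `"synth"`, `"calibrate"`, `"simulate"`, `"analyze"`,
#'   `"compare"`.
#' @param config Named list of parameters; see `forktimer:::command_keys`
#'   for the keys each command accepts.
#' @param quiet Suppress progress messages.
#' @return The primary artifact path, invisibly.
#' @examples
#' \donttest{
#' td <- tempfile(); dir.create(td)
#' run_command("synth", list(preset = "slow", n_lineages = 30,
#'                           n_cycles = 12, seed = 7,
#'                           out = file.path(td, "truth.tsv")))
#' }
#' @export
run_command <- function(name = c("synth", "calibrate", "simulate", "analyze",
                                 "compare"),
                        config, quiet = FALSE) {
  name <- match.arg(name)
  config <- check_config(name, config)
  say <- function(...) if (!quiet) message(...)
  out <- config$out
  if (is.null(out)) stop("configuration needs an 'out' path", call. = FALSE)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)

  if (name == "synth") {
    spec <- preset(config$preset)
    tab <- generate_lineage_table(spec, config$n_lineages, config$n_cycles,
                                  seed = config$seed %||% 1L)
    write_cycle_table(tab, out)
    say(sprintf("synth: wrote %d cycles (%d lineages, preset '%s') to %s",
                nrow(tab), config$n_lineages, config$preset, out))
  } else if (name == "calibrate") {
    rec <- read_cycle_table(config$input)
    curve <- estimate_calibration(rec,
                                  condition = config$condition %||% "data",
                                  n_bins = config$n_bins %||% 8L,
                                  min_per_bin = config$min_per_bin %||% 20L)
    write_calibration(curve, out)
    say(sprintf("calibrate: %d cycles -> %d bins, curve written to %s",
                nrow(rec), nrow(curve$stats), out))
  } else if (name == "simulate") {
    curve <- read_calibration(config$curve)
    cfg <- sim_config(n_lineages = config$n_lineages,
                      n_cycles = config$n_cycles,
                      burn_in = config$burn_in %||% 10L,
                      seed = config$seed %||% 1L,
                      mode = config$mode %||% "empirical_joint")
    res <- simulate_population(curve, cfg)
    write_cycle_table(res, out)
    say(sprintf("simulate: %d cycles (%d post-burn-in) written to %s",
                nrow(res$cycles), sum(!res$cycles$burn_in), out))
  } else if (name == "analyze") {
    rec <- read_cycle_table(config$input)
    if (!"fork_class" %in% names(rec))
      rec$fork_class <- classify_cycle(rec$tau_i, rec$tau_C, rec$tau_d)
    strata <- stratify_by_fork_class(rec)
    set.seed(config$seed %||% 1L)
    nb <- config$n_bins %||% 8L
    edges <- unique(stats::quantile(rec$k, seq(0, 1, length.out = nb + 1L),
                                    names = FALSE))
    quantity <- config$quantity %||% "tau_C"
    bs <- lapply(strata$strata, function(d)
      binned_stat(d$k, d[[quantity]], edges))
    test <- fork_dependence_test(rec, quantity = quantity,
                                 bin_edges = edges,
                                 n_perm = config$n_perm %||% 1999L,
                                 alpha = config$alpha %||% 0.05)
    summary <- list(quantity = quantity,
                    stratum_sizes = as.list(strata$counts),
                    binned = lapply(bs, function(d) as.list(d)),
                    statistic = test$statistic, p_value = test$p_value,
                    verdict = test$verdict, n_perm = test$n_perm,
                    alpha = test$alpha)
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    say(sprintf("analyze: %s by fork class, p = %.4f (%s); summary in %s",
                quantity, test$p_value, test$verdict, out))
  } else if (name == "compare") {
    sim <- read_cycle_table(config$simulated)
    emp <- read_cycle_table(config$empirical)
    nb <- config$n_bins %||% 8L
    edges <- unique(stats::quantile(emp$k, seq(0, 1, length.out = nb + 1L),
                                    names = FALSE))
    cmp <- compare_fork_distributions(sim, emp, edges)
    jsonlite::write_json(list(overall_tv = cmp$overall_tv,
                              per_bin = as.list(cmp$per_bin)),
                         out, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    say(sprintf("compare: overall TV distance %.4f; report in %s",
                cmp$overall_tv, out))
  }
  write_provenance(paste0(out, ".provenance.json"), name, config)
  invisible(out)
}
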