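# Stochastic timers and fork-cycle classification.
#
# A replication cycle is anchored at an initiation event. Three timers start
# ticking at that instant:
#   tau_i  inter-initiation time: time until the next initiation event
#   tau_C  C period: time until this round of replication terminates
#   tau_d  time until the division event that corresponds to this initiation
# All are in minutes. tau_d > tau_C always: a division associated with a
# round of replication cannot precede the completion of that round.

#' Fork-cycle class labels
#'
#' The four configurations a cell can be in just after a replication
#' initiation event, labelled by the number of active replication forks:
#' `"2"`, `"4"`, `"6"`, and `"8+"`.
#'
#' @return Character vector of the four class labels, in increasing order.
#' @export
fork_class_levels <- function() c("2", "4", "6", "8+")

#' Construct and validate a timer triple
#'
#' Bundles the three cell-cycle timers of one initiation-anchored replication
#' cycle and checks their invariants: all durations strictly positive and
#' `tau_d > tau_C` (a round's division cannot precede its termination).
#'
#' @param tau_i Inter-initiation time, minutes (time from this initiation to
#'   the next one).
#' @param tau_C C period, minutes (time from initiation to termination of the
#'   same round).
#' @param tau_d Time from this initiation to its corresponding division,
#'   minutes.
#' @return An object of class `"timers"`: a named list with elements
#'   `tau_i`, `tau_C`, `tau_d`.
#' @examples
#' timers(tau_i = 100, tau_C = 50, tau_d = 70)
#' @export
timers <- function(tau_i, tau_C, tau_d) {
  check_timers(tau_i, tau_C, tau_d)
  structure(list(tau_i = tau_i, tau_C = tau_C, tau_d = tau_d),
            class = "timers")
}

#' @export
print.timers <- function(x, ...) {
  cat(sprintf("timers: tau_i = %g, tau_C = %g, tau_d = %g min\n",
              x$tau_i, x$tau_C, x$tau_d))
  invisible(x)
}

# Vectorised validation shared by the classifiers and the engine.
check_timers <- function(tau_i, tau_C, tau_d, require_tau_i = TRUE) {
  if (length(tau_i) != length(tau_C) || length(tau_C) != length(tau_d))
    stop("tau_i, tau_C and tau_d must have equal length", call. = FALSE)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x) | is.na(x))
  if (!num_ok(tau_i) || !num_ok(tau_C) || !num_ok(tau_d))
    stop("timers must be finite numeric values", call. = FALSE)
  bad_pos <- (if (require_tau_i) !is.na(tau_i) & tau_i <= 0 else FALSE) |
    (!is.na(tau_C) & tau_C <= 0) | (!is.na(tau_d) & tau_d <= 0)
  if (any(bad_pos))
    stop("all timers must be strictly positive (first bad index: ",
         which(bad_pos)[1], ")", call. = FALSE)
  bad_ord <- !is.na(tau_C) & !is.na(tau_d) & tau_d <= tau_C
  if (any(bad_ord))
    stop("tau_d must exceed tau_C (first bad index: ",
         which(bad_ord)[1], ")", call. = FALSE)
  invisible(TRUE)
}

#' Classify a replication cycle by its timer ordering
#'
#' The relative order in which the three timers of a cycle run out determines
#' how many replication forks are active just after the *next* initiation
#' event, provided at most one round of replication overlaps the next
#' (single-overlap regime, `tau_C` shorter than two consecutive
#' inter-initiation intervals):
#'
#' * `tau_i >= tau_d`: the round terminates and the cell divides before the
#'   next initiation; the next cycle starts with 2 forks.
#' * `tau_C <= tau_i < tau_d`: the round terminates but re-initiation occurs
#'   before division; 4 forks across two chromosome copies.
#' * `tau_i < tau_C`: re-initiation occurs while the previous round is still
#'   running (multifork replication); 6 forks.
#'
#' Boundary equalities are assigned to the lower fork class, consistent with
#' the discrete-event engine's tie-break order
#' (termination, then division, then initiation; see
#' [run_deterministic_cycle()]).
#'
#' @param tau_i,tau_C,tau_d Numeric vectors of equal length: the timers of
#'   each cycle, in minutes. A `"timers"` object may be given as the first
#'   argument instead.
#' @return A factor with levels `fork_class_levels()` (the `"8+"` level is
#'   never produced by this per-cycle classifier; it is reachable only via
#'   the discrete-event engine).
#' @seealso [classify_mean_regime()] for population-mean timer orderings,
#'   [run_deterministic_cycle()] for the event-bookkeeping equivalent.
#' @examples
#' classify_cycle(tau_i = c(100, 60, 40),
#'                tau_C = c(50, 50, 60),
#'                tau_d = c(70, 90, 75))
#' @export
classify_cycle <- function(tau_i, tau_C, tau_d) {
  if (inherits(tau_i, "timers")) {
    tau_C <- tau_i$tau_C; tau_d <- tau_i$tau_d; tau_i <- tau_i$tau_i
  }
  check_timers(tau_i, tau_C, tau_d)
  cls <- ifelse(tau_i >= tau_d, "2", ifelse(tau_i >= tau_C, "4", "6"))
  factor(cls, levels = fork_class_levels())
}

#' Classify the fork regime implied by population-mean timers
#'
#' Applies the inequality chains that delimit the fork regimes at the
#' population level, using the population means of the three timers:
#'
#' * 2-fork: `tau_d < tau_i`
#' * 4-fork: `tau_C < tau_i < tau_d < 2 tau_i`
#' * 6-fork: `tau_i < tau_C < tau_d < 2 tau_i`
#' * 8-plus: `tau_i < tau_C < 2 tau_i < tau_d < 3 tau_i`
#'
#' Mean orderings falling outside all four chains (including exact
#' boundaries) return `"indeterminate"` rather than a forced label. Note the
#' 8-plus label names the regime; the discrete-event engine may count more
#' than 8 forks for such orderings when divisions lag several generations
#' (see [run_deterministic_cycle()]).
#'
#' @param tau_i,tau_C,tau_d Population-mean timers, minutes (scalars). A
#'   `"timers"` object may be given as the first argument instead.
#' @return A single character string: `"2"`, `"4"`, `"6"`, `"8+"`, or
#'   `"indeterminate"`.
#' @examples
#' classify_mean_regime(60, 50, 90)  # "4"
#' classify_mean_regime(40, 60, 75)  # "6"
#' classify_mean_regime(30, 45, 80)  # "8+"
#' @export
classify_mean_regime <- function(tau_i, tau_C, tau_d) {
  if (inherits(tau_i, "timers")) {
    tau_C <- tau_i$tau_C; tau_d <- tau_i$tau_d; tau_i <- tau_i$tau_i
  }
  if (length(tau_i) != 1L || length(tau_C) != 1L || length(tau_d) != 1L)
    stop("classify_mean_regime takes scalar mean timers", call. = FALSE)
  check_timers(tau_i, tau_C, tau_d)
  if (tau_d < tau_i) return("2")
  if (tau_C < tau_i && tau_i < tau_d && tau_d < 2 * tau_i) return("4")
  if (tau_i < tau_C && tau_C < tau_d && tau_d < 2 * tau_i) return("6")
  if (tau_i < tau_C && tau_C < 2 * tau_i &&
      2 * tau_i < tau_d && tau_d < 3 * tau_i) return("8+")
  "indeterminate"
}
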