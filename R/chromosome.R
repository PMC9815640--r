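# Chromosome-configuration state machine.
#
# A cell's replication state is a forest of chromosome units. Each unit is a
# binary tree whose internal nodes are active replication bubbles and whose
# leaves carry one oriC each. Because initiation is synchronous (every oriC
# fires at each initiation event) and division splits the cell exactly in
# half, the forest is fully described by counts: origin copies, terminus
# copies (= chromosome units), and the number of bubbles per open round of
# replication, oldest round first. Each bubble contributes two forks.

#' Construct a chromosome replication state
#'
#' @param n_ori Number of oriC copies (default 1: a single non-replicating
#'   chromosome).
#' @param n_ter Number of terminus copies, equal to the number of chromosome
#'   units in the cell.
#' @return An object of class `"chromosome_state"` with fields `n_ori`,
#'   `n_ter`, `rounds` (named integer vector of bubbles per open round,
#'   oldest first) and `next_round` (counter for round identifiers).
#' @examples
#' s <- chromosome_state()
#' n_forks(s)
#' @export
chromosome_state <- function(n_ori = 1L, n_ter = 1L) {
  n_ori <- as.integer(n_ori); n_ter <- as.integer(n_ter)
  if (n_ter < 1L) stop("n_ter must be >= 1", call. = FALSE)
  if (n_ori < n_ter) stop("n_ori must be >= n_ter", call. = FALSE)
  structure(list(n_ori = n_ori, n_ter = n_ter,
                 rounds = stats::setNames(integer(0), character(0)),
                 next_round = 1L),
            class = "chromosome_state")
}

#' Number of active replication forks in a state
#'
#' Two forks per active replication bubble.
#'
#' @param state A `"chromosome_state"`.
#' @return Integer fork count (always even).
#' @export
n_forks <- function(state) {
  stopifnot(inherits(state, "chromosome_state"))
  2L * sum(state$rounds)
}

#' @export
print.chromosome_state <- function(x, ...) {
  cat(sprintf("chromosome state: ori = %d, ter = %d, forks = %d\n",
              x$n_ori, x$n_ter, n_forks(x)))
  if (length(x$rounds))
    cat("  open rounds (oldest first): ",
        paste(sprintf("%s[%d bubbles]", names(x$rounds), x$rounds),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fire a synchronous replication initiation
#'
#' Every oriC in the cell fires simultaneously. Each firing origin becomes a
#' new replication bubble carrying two forks, the origin count doubles, and a
#' new round of replication is opened.
#'
#' @param state A `"chromosome_state"`.
#' @return The updated state. Fork count increases by twice the pre-firing
#'   origin count.
#' @examples
#' s <- apply_initiation(chromosome_state())  # 1 chromosome -> 2 forks
#' n_forks(s)
#' @export
apply_initiation <- function(state) {
  stopifnot(inherits(state, "chromosome_state"))
  id <- paste0("r", state$next_round)
  state$rounds <- c(state$rounds, stats::setNames(state$n_ori, id))
  state$n_ori <- 2L * state$n_ori
  state$next_round <- state$next_round + 1L
  state
}

#' Terminate the oldest open round of replication
#'
#' Rounds of replication complete in the order they were initiated (fork
#' speed is uniform within a round, so an earlier-initiated round always
#' reaches the terminus first). All bubbles of the round close; each closing
#' bubble splits its chromosome unit in two, so the terminus count grows by
#' the number of closing bubbles.
#'
#' @param state A `"chromosome_state"` with at least one open round.
#' @param round_id Optional round identifier; if supplied it must name the
#'   oldest open round, otherwise an error signals inconsistent event
#'   ordering.
#' @return The updated state. Fork count decreases by two per closed bubble.
#' @export
apply_termination <- function(state, round_id = NULL) {
  stopifnot(inherits(state, "chromosome_state"))
  if (length(state$rounds) == 0L)
    stop("no open round of replication to terminate", call. = FALSE)
  oldest <- names(state$rounds)[1]
  if (!is.null(round_id) && !identical(as.character(round_id), oldest))
    stop("round '", round_id, "' is not the oldest open round ('", oldest,
         "'); rounds terminate in initiation order", call. = FALSE)
  state$n_ter <- state$n_ter + unname(state$rounds[1])
  state$rounds <- state$rounds[-1]
  state
}

#' Divide the cell, following one daughter
#'
#' Division splits the cell into two equal halves; lineage tracking keeps a
#' single daughter, so every count is halved. The state must be symmetric:
#' origin count, terminus count, and the bubble count of every open round
#' must all be even, otherwise the division was scheduled before the state
#' can support it.
#'
#' @param state A `"chromosome_state"` that can be split into two equal
#'   halves.
#' @return The daughter state with half of each count.
#' @examples
#' s <- chromosome_state(n_ori = 2, n_ter = 2)
#' apply_division(s)  # one complete chromosome per daughter
#' @export
apply_division <- function(state) {
  stopifnot(inherits(state, "chromosome_state"))
  if (state$n_ori %% 2L || state$n_ter %% 2L || any(state$rounds %% 2L))
    stop("state cannot be partitioned into two equal daughters ",
         "(ori = ", state$n_ori, ", ter = ", state$n_ter,
         "); division scheduled before the state supports it",
         call. = FALSE)
  state$n_ori <- state$n_ori %/% 2L
  state$n_ter <- state$n_ter %/% 2L
  state$rounds <- state$rounds %/% 2L
  state
}

# ---------------------------------------------------------------------------
# Deterministic discrete-event engine.

#' Run the deterministic replication cycle to steady state
#'
#' Simulates the chromosome state machine with the same timer triple reused
#' every cycle: initiations fire every `tau_i` minutes, the round initiated
#' at time `t` terminates at `t + tau_C`, and its division occurs at
#' `t + tau_d`. Events simultaneous in time are resolved in the fixed order
#' termination, division, initiation. After a burn-in long enough for all
#' pending divisions to catch up, the event pattern is periodic with period
#' `tau_i`; the trace of one steady-state period is returned.
#'
#' @param tau_i,tau_C,tau_d Timers in minutes (scalars, all positive,
#'   `tau_d > tau_C`). A `"timers"` object may be given as the first
#'   argument instead.
#' @param history_depth Number of cycles to simulate past burn-in; raised
#'   automatically to cover at least `ceiling(tau_d / tau_i) + 6` cycles so
#'   that divisions have caught up.
#' @param full If `TRUE`, return the whole event trace from time zero instead
#'   of one steady-state period.
#' @return A data frame of class `"event_trace"` with columns `event`
#'   (`"initiation"`, `"termination"`, `"division"`), `time_min`, `forks`,
#'   `ori`, `ter` — the state counts just *after* each event. The attribute
#'   `forks_after` is a named vector giving the steady-state fork count just
#'   after each event type; `period_min` holds `tau_i`.
#' @examples
#' tr <- run_deterministic_cycle(100, 50, 70)  # slow growth: 2-fork cycle
#' attr(tr, "forks_after")
#' @export
run_deterministic_cycle <- function(tau_i, tau_C, tau_d,
                                    history_depth = 20L, full = FALSE) {
  if (inherits(tau_i, "timers")) {
    tau_C <- tau_i$tau_C; tau_d <- tau_i$tau_d; tau_i <- tau_i$tau_i
  }
  if (length(tau_i) != 1L || length(tau_C) != 1L || length(tau_d) != 1L)
    stop("run_deterministic_cycle takes scalar timers", call. = FALSE)
  check_timers(tau_i, tau_C, tau_d)

  depth <- max(as.integer(history_depth), ceiling(tau_d / tau_i) + 6L)
  j <- seq_len(depth) - 1L            # round indices 0 .. depth-1
  horizon <- (depth - 1L) * tau_i
  eps <- 1e-9 * max(tau_i, tau_C, tau_d)

  # schedule: priority encodes the tie-break termination < division < initiation
  time <- c(j * tau_i + tau_C, j * tau_i + tau_d, j * tau_i)
  prio <- rep(c(1L, 2L, 3L), each = depth)
  round <- rep(j, 3L)
  keep <- time <= horizon + eps
  time <- time[keep]; prio <- prio[keep]; round <- round[keep]

  # sort by time, breaking near-ties (within eps) by priority
  ord <- order(time, prio, round)
  time <- time[ord]; prio <- prio[ord]; round <- round[ord]
  if (length(time) > 1L) {
    # bubble events whose times differ only by floating-point noise into
    # priority order
    repeat {
      swapped <- FALSE
      for (i in seq_len(length(time) - 1L)) {
        if (abs(time[i + 1L] - time[i]) <= eps && prio[i + 1L] < prio[i]) {
          tmp <- c(i, i + 1L); rev_ <- c(i + 1L, i)
          time[tmp] <- time[rev_]; prio[tmp] <- prio[rev_]
          round[tmp] <- round[rev_]
          swapped <- TRUE
        }
      }
      if (!swapped) break
    }
  }

  n_ev <- length(time)
  ev_label <- c("termination", "division", "initiation")[prio]
  out_forks <- integer(n_ev); out_ori <- integer(n_ev); out_ter <- integer(n_ev)

  # state: counts plus bubbles per open round (oldest first)
  ori <- 1L; ter <- 1L
  open_rounds <- integer(0)   # bubble counts
  open_ids <- integer(0)      # round indices
  for (i in seq_len(n_ev)) {
    p <- prio[i]
    if (p == 3L) {                        # initiation
      open_rounds <- c(open_rounds, ori)
      open_ids <- c(open_ids, round[i])
      ori <- 2L * ori
    } else if (p == 1L) {                 # termination (oldest round)
      if (length(open_rounds) == 0L || open_ids[1] != round[i])
        stop("internal engine error: termination out of order", call. = FALSE)
      ter <- ter + open_rounds[1]
      open_rounds <- open_rounds[-1]; open_ids <- open_ids[-1]
    } else {                              # division
      if (ori %% 2L || ter %% 2L || any(open_rounds %% 2L))
        stop("division scheduled before the state supports it (ori = ",
             ori, ", ter = ", ter, ")", call. = FALSE)
      ori <- ori %/% 2L; ter <- ter %/% 2L
      open_rounds <- open_rounds %/% 2L
    }
    out_forks[i] <- 2L * sum(open_rounds)
    out_ori[i] <- ori; out_ter[i] <- ter
  }

  tr <- data.frame(event = ev_label, time_min = time, forks = out_forks,
                   ori = out_ori, ter = out_ter, stringsAsFactors = FALSE)
  # steady-state window: [ (depth-2) tau_i, (depth-1) tau_i ), with events
  # tied to the right edge (termination/division before the next initiation)
  # included and the next initiation excluded
  t0 <- (depth - 2L) * tau_i; t1 <- horizon
  in_win <- (tr$time_min > t0 + eps |
               (abs(tr$time_min - t0) <= eps & tr$event == "initiation")) &
            (tr$time_min < t1 - eps |
               (abs(tr$time_min - t1) <= eps & tr$event != "initiation"))
  win <- tr[in_win, , drop = FALSE]
  rownames(win) <- NULL
  fa <- vapply(c("initiation", "termination", "division"), function(e) {
    v <- win$forks[win$event == e]
    if (length(v)) v[length(v)] else NA_integer_
  }, integer(1))
  res <- if (full) tr else win
  structure(res, class = c("event_trace", "data.frame"),
            forks_after = fa, period_min = tau_i)
}

# Steady-state fork count just after initiation; fast path used by the
# classifier-equivalence checks.
engine_forks_after_initiation <- function(tau_i, tau_C, tau_d, ...) {
  attr(run_deterministic_cycle(tau_i, tau_C, tau_d, ...),
       "forks_after")[["initiation"]]
}

#' Serialize an event trace to a delimited text table
#'
#' @param trace An `"event_trace"` from [run_deterministic_cycle()].
#' @param path Output path; tab-separated with columns
#'   `event, time_min, forks, ori, ter`.
#' @return `path`, invisibly.
#' @export
write_event_trace <- function(trace, path) {
  stopifnot(inherits(trace, "event_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
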