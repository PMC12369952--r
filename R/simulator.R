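# Seeded workflow simulator.
#
# Generates ground-truth event logs with a known structure -- a sequential
# backbone, probabilistic branch activities, an interleaved parallel block,
# and per-transition delay distributions -- so every other module is
# testable without external data.  The default "clinic-small" spec emulates
# a small clinical process at the scale of a log with a few hundred cases
# and about ten activity types.

#' Define a workflow specification
#'
#' @param backbone Ordered character vector of mandatory activities.
#' @param parallel_block Character vector of activities inserted in a
#'   uniformly random order after position `parallel_after` of the
#'   backbone.  May be empty.
#' @param parallel_after Backbone index after which the parallel block is
#'   inserted.
#' @param branches List of branch descriptors, each
#'   `list(activity =, after =, prob =)`: with probability `prob` the
#'   activity is inserted after backbone activity `after`.
#' @param delay_model `list(family = "exponential", mean =)` or
#'   `list(family = "lognormal", meanlog =, sdlog =)`: the distribution of
#'   the delay preceding every activity after the first.
#' @param context_rules Named list of functions
#'   `function(activities, timestamps) -> value` evaluated per case to
#'   attach context attributes.
#' @param n_cases Number of cases to simulate.
#' @param seed Integer seed; the same spec yields a byte-identical log.
#' @return A `workflow_spec`.
#' @export
workflow_spec <- function(backbone,
                          parallel_block = character(0),
                          parallel_after = length(backbone),
                          branches = list(),
                          delay_model = list(family = "exponential",
                                             mean = 100),
                          context_rules = list(),
                          n_cases = 250L,
                          seed = 1L) {
  if (length(backbone) == 0L) stop("backbone must be non-empty")
  for (br in branches) {
    stopifnot(br$prob >= 0, br$prob <= 1, br$after %in% backbone)
  }
  if (delay_model$family == "exponential" && delay_model$mean <= 0) {
    stop("delay mean must be positive")
  }
  structure(list(backbone = backbone, parallel_block = parallel_block,
                 parallel_after = parallel_after, branches = branches,
                 delay_model = delay_model, context_rules = context_rules,
                 n_cases = as.integer(n_cases), seed = as.integer(seed)),
            class = "workflow_spec")
}

draw_delays <- function(model, n) {
  switch(model$family,
         exponential = stats::rexp(n, rate = 1 / model$mean),
         lognormal = stats::rlnorm(n, meanlog = model$meanlog,
                                   sdlog = model$sdlog),
         stop("unknown delay family: ", model$family))
}

#' Simulate an event log from a workflow specification
#'
#' Per case: the backbone is realized, branch activities are inserted by
#' independent coin flips, the parallel block is shuffled uniformly and
#' spliced in, inter-activity delays are drawn from the delay model, and
#' timestamps accumulate from 0.  Context attributes are computed from the
#' finished trace by the spec's context rules.  Fully reproducible from the
#' spec seed.
#'
#' @param spec A `workflow_spec`.
#' @return An `event_log`.
#' @export
simulate_log <- function(spec) {
  set.seed(spec$seed)
  width <- max(3L, nchar(as.character(spec$n_cases)))
  cases <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    acts <- character(0)
    for (b in seq_along(spec$backbone)) {
      acts <- c(acts, spec$backbone[b])
      if (b == spec$parallel_after && length(spec$parallel_block)) {
        acts <- c(acts, sample(spec$parallel_block))
      }
      for (br in spec$branches) {
        if (br$after == spec$backbone[b] &&
            stats::runif(1) < br$prob) {
          acts <- c(acts, br$activity)
        }
      }
    }
    n <- length(acts)
    ts <- cumsum(c(0, draw_delays(spec$delay_model, n - 1L)))
    contexts <- NULL
    if (length(spec$context_rules)) {
      contexts <- lapply(spec$context_rules, function(f) f(acts, ts))
    }
    cases[[i]] <- process_case(sprintf(paste0("case_%0", width, "d"), i),
                               acts, ts, contexts)
  }
  event_log(cases)
}

#' A degenerate log of identical traces
#'
#' @param n_cases Number of copies.
#' @param trace Character vector of activities.
#' @param delay Constant inter-activity delay.
#' @return An `event_log` whose pairwise-edit-distance diversity is 0.
#' @export
degenerate_log <- function(n_cases, trace, delay = 1) {
  stopifnot(length(trace) >= 1L)
  ts <- (seq_along(trace) - 1L) * delay
  cases <- lapply(seq_len(n_cases), function(i) {
    process_case(sprintf("case_%03d", i), trace, ts)
  })
  event_log(cases)
}

#' The default "clinic-small" fixture specification
#'
#' A 6-activity clinical backbone with a 3-activity parallel work-up block
#' after the assessment step, two optional branches (specialist consult,
#' p = 0.3; observation, p = 0.6), exponential inter-activity delays with
#' mean 100 seconds, and 250 cases: roughly the scale of a small real
#' process log (about ten activity types, lengths 9-11, case durations in
#' the tens of minutes).  Three context rules ship with it, one per
#' learnability regime:
#' \describe{
#'   \item{specialist_seen}{deterministic function of the trace (was the
#'     specialist branch taken?).}
#'   \item{complexity}{noisy function of the trace length ("high" when the
#'     case has many activities, with 15% label noise).}
#'   \item{coin}{an independent fair coin, unpredictable from the trace.}
#' }
#'
#' @param n_cases Number of cases (default 250).
#' @param seed Integer seed.
#' @return A `workflow_spec`.
#' @export
clinic_small_spec <- function(n_cases = 250L, seed = 20260910L) {
  workflow_spec(
    backbone = c("register", "triage", "assess", "treat", "review",
                 "discharge"),
    parallel_block = c("labs", "imaging", "meds"),
    parallel_after = 3L,
    branches = list(
      list(activity = "specialist", after = "treat", prob = 0.3),
      list(activity = "observation", after = "review", prob = 0.6)
    ),
    delay_model = list(family = "exponential", mean = 100),
    context_rules = list(
      specialist_seen = function(acts, ts) {
        if ("specialist" %in% acts) "yes" else "no"
      },
      complexity = function(acts, ts) {
        noisy <- length(acts) + stats::rnorm(1, sd = 1)
        if (noisy > 10) "high" else "low"
      },
      coin = function(acts, ts) {
        if (stats::runif(1) < 0.5) "heads" else "tails"
      }
    ),
    n_cases = n_cases,
    seed = seed
  )
}
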