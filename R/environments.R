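# ---------------------------------------------------------------------------
# Nonstationary binary environments: piecewise-constant Bernoulli schedules
# with seeded sampling. These supply every observation sequence used in the
# simulation study and in the test suite.
# ---------------------------------------------------------------------------

#' Piecewise-constant Bernoulli environment
#'
#' @param segments data.frame (or list coercible to one) with columns
#'   `duration` (positive integer steps) and `p_true` (in [0, 1]).
#' @param cycle repeat the schedule from the start when exhausted?
#' @param seed integer seed controlling the sampled outcome sequence.
#' @return an object of class `bernoulli_environment`.
#' @export
bernoulli_environment <- function(segments, cycle = FALSE, seed = 1L) {
  segments <- as.data.frame(segments)
  if (!all(c("duration", "p_true") %in% names(segments)))
    stop("segments needs columns duration and p_true")
  if (any(segments$duration < 1) || any(segments$duration != round(segments$duration)))
    stop("durations must be positive integers")
  if (any(segments$p_true < 0) || any(segments$p_true > 1))
    stop("p_true must lie in [0, 1]")
  structure(list(segments = segments, cycle = isTRUE(cycle),
                 seed = as.integer(seed)),
            class = "bernoulli_environment")
}

#' Slowly varying environment
#'
#' The true event probability steps gradually upward through 0.2, 0.35 and
#' 0.5, one level per segment, without cycling. Changes are mild enough that
#' prior updating alone can track them to some extent.
#'
#' @param segment_length steps per level (default 200).
#' @param seed integer seed.
#' @return a `bernoulli_environment`.
#' @export
slow_environment <- function(segment_length = 200, seed = 1L) {
  bernoulli_environment(
    data.frame(duration = rep(segment_length, 3), p_true = c(0.2, 0.35, 0.5)),
    cycle = FALSE, seed = seed)
}

#' Abruptly switching environment
#'
#' The true event probability repeatedly switches among 0.8, 0.2, 0.65 and
#' 0.35 (cycling), producing large jumps that a fixed likelihood structure
#' adapts to only slowly.
#'
#' @inheritParams slow_environment
#' @return a `bernoulli_environment`.
#' @export
abrupt_environment <- function(segment_length = 200, seed = 1L) {
  bernoulli_environment(
    data.frame(duration = rep(segment_length, 4),
               p_true = c(0.8, 0.2, 0.65, 0.35)),
    cycle = TRUE, seed = seed)
}

#' True-probability schedule over T steps
#'
#' @param env a `bernoulli_environment`.
#' @param T number of steps.
#' @return numeric vector of length T with p_true at each step.
#' @export
true_probability <- function(env, T) {
  if (T < 1) stop("T must be >= 1")
  per_cycle <- rep(env$segments$p_true, times = env$segments$duration)
  if (length(per_cycle) >= T) return(per_cycle[seq_len(T)])
  if (!env$cycle)
    stop("schedule covers only ", length(per_cycle), " steps and cycling is off")
  rep_len(per_cycle, T)
}

#' Sample an observation sequence from an environment
#'
#' Draws d_t ~ Bernoulli(p_true(t)) independently. Deterministic given the
#' environment seed: the same (env, T) always yields the same sequence, so
#' paired comparisons of inference systems can share one observation stream.
#'
#' @param env a `bernoulli_environment`.
#' @param T positive number of steps.
#' @return list with integer vector `d` (0/1 outcomes) and numeric vector
#'   `p_true`.
#' @export
sample_environment <- function(env, T) {
  p <- true_probability(env, T)
  d <- withr::with_seed(env$seed, stats::rbinom(T, 1L, p))
  list(d = as.integer(d), p_true = p)
}
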