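#' Build trial schedules
#'
#' Schedule builders for the three tasks. The pairwise tasks (implicit and
#' explicit preference scales) present every unordered pair of distinct
#' primes exactly once, so `n` primes yield `n(n-1)/2` trials; the
#' single-prime judgment task (AMP) presents each prime a fixed number of
#' times. Left/right placement within a pair is an independent fair coin
#' per trial and the trial order is randomly permuted; both are fully
#' determined by `seed`.
#'
#' @param primes Stimulus tibble (with a `stimulus_id` column) or character
#'   vector of stimulus IDs.
#' @param seed Integer seed; the schedule is reproducible given the seed and
#'   the global RNG state is left untouched.
#' @return A tibble of trials with 0-based `trial_index`. Pairwise schedules
#'   have columns `trial_index`, `left_prime`, `right_prime`; AMP schedules
#'   have `trial_index`, `prime`.
#' @examples
#' sched <- build_impres_schedule(default_primes(), seed = 1)
#' nrow(sched) # 190 = choose(20, 2)
#' @export
build_impres_schedule <- function(primes, seed) {
  primes <- as_stimulus_table(primes, arg = "primes")
  seed <- check_seed(seed)
  ids <- primes$stimulus_id
  if (length(ids) < 2) {
    abort("At least 2 primes are required for a pairwise schedule.")
  }
  pairs <- t(combn(ids, 2L))
  withr::with_seed(seed, {
    flip <- runif(nrow(pairs)) < 0.5
    ord <- sample.int(nrow(pairs))
  })
  left <- ifelse(flip, pairs[, 2L], pairs[, 1L])
  right <- ifelse(flip, pairs[, 1L], pairs[, 2L])
  tibble::tibble(
    trial_index = seq_len(nrow(pairs)) - 1L,
    left_prime = left[ord],
    right_prime = right[ord]
  )
}

#' @rdname build_impres_schedule
#' @param repetitions Times each prime is shown (default 6, so 20 primes
#'   yield 120 trials).
#' @export
build_amp_schedule <- function(primes, repetitions = 6, seed) {
  primes <- as_stimulus_table(primes, arg = "primes")
  seed <- check_seed(seed)
  if (length(repetitions) != 1 || is.na(repetitions) || repetitions < 1) {
    abort("`repetitions` must be a single integer >= 1.")
  }
  shown <- rep(primes$stimulus_id, times = repetitions)
  ord <- withr::with_seed(seed, sample.int(length(shown)))
  tibble::tibble(
    trial_index = seq_along(shown) - 1L,
    prime = shown[ord]
  )
}

#' @rdname build_impres_schedule
#' @export
build_expres_schedule <- function(primes, seed) {
  build_impres_schedule(primes, seed)
}

#' Task timing metadata
#'
#' Presentation timings for each task, carried as documentation alongside
#' schedules; no computation in the package consumes them. The pairwise
#' implicit task shows both primes simultaneously for 150 ms (twice the
#' 75 ms of the single-prime task, compensating for the double
#' presentation); the explicit task has no response deadline.
#'
#' @param task One of `"impres"`, `"amp"`, `"expres"`.
#' @param seed Optional seed recorded alongside the timings.
#' @return A one-row tibble of durations in milliseconds.
#' @export
schedule_meta <- function(task = c("impres", "amp", "expres"), seed = NA_integer_) {
  task <- match.arg(task)
  meta <- switch(task,
    impres = tibble::tibble(
      task = "impres", fixation_ms = 500, blank1_ms = 0, prime_ms = 150,
      blank2_ms = 150, target_ms = 100, deadline_ms = 1500
    ),
    amp = tibble::tibble(
      task = "amp", fixation_ms = 500, blank1_ms = 500, prime_ms = 75,
      blank2_ms = 125, target_ms = 100, deadline_ms = 1500
    ),
    expres = tibble::tibble(
      task = "expres", fixation_ms = 500, blank1_ms = 0, prime_ms = 150,
      blank2_ms = 150, target_ms = 100, deadline_ms = Inf
    )
  )
  meta$rng_seed <- as.integer(seed)
  meta
}
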