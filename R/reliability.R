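#' Spearman-Brown correction
#'
#' Projects a half-length reliability to full length: `2 r / (1 + r)`.
#' Defined for `r > -1`; it is a monotone increasing map with fixed points
#' at 0 and 1, and `corrected >= r` for `r` in \[0, 1\].
#'
#' @param r Correlation between half scores.
#' @return Corrected reliability.
#' @examples
#' spearman_brown(0.5) # 2/3
#' @export
spearman_brown <- function(r) {
  if (any(!is.finite(r)) || any(r <= -1)) {
    abort("`r` must be finite and > -1.")
  }
  2 * r / (1 + r)
}

#' Repeated random split-half reliability
#'
#' Estimates the reliability of a trial-based score by repeated random
#' split halves: in each run every participant's trials are partitioned at
#' random into two halves (sizes differing by at most one), the score is
#' computed on each half, and the two half-score vectors are correlated
#' (Pearson) across participants. The run correlations are averaged and
#' the average is Spearman-Brown corrected once. Runs whose correlation is
#' undefined (fewer than 3 complete participant pairs, or zero variance in
#' a half-score vector) are dropped and counted, never zero-filled.
#'
#' The split universe is whatever `trials` contains: pass only the trials
#' relevant to the score in question (e.g. only cross-race pairwise trials
#' for a race preference score); see [cross_feature_trials()].
#'
#' @param trials Trial tibble with a `participant_id` column.
#' @param scorer Function mapping a tibble of one participant's trials to a
#'   scalar score (`NA` for unscoreable input); see [proportion_scorer()].
#' @param runs Number of random splits (default 10000).
#' @param seed Integer seed; the estimate is exactly reproducible.
#' @return An object of class `reliability_estimate`: a one-row tibble with
#'   `mean_half_correlation`, `corrected`, `n_runs_used`, `n_runs_dropped`,
#'   `rng_seed`.
#' @export
split_half_reliability <- function(trials, scorer, runs = 10000, seed) {
  trials <- tibble::as_tibble(trials)
  seed <- check_seed(seed)
  stopifnot(runs >= 1)
  by_part <- split(trials, trials$participant_id)
  if (length(by_part) < 3) {
    abort("At least 3 participants are required.")
  }
  sizes <- vapply(by_part, nrow, integer(1))
  if (any(sizes < 2)) {
    abort("Every participant needs at least 2 trials to split.")
  }
  half1_n <- sizes %/% 2L
  p <- length(by_part)
  rs <- withr::with_seed(seed, {
    vapply(seq_len(runs), function(run) {
      s1 <- numeric(p)
      s2 <- numeric(p)
      for (j in seq_len(p)) {
        idx <- sample.int(sizes[j])
        take <- idx <= half1_n[j]
        s1[j] <- scorer(by_part[[j]][take, , drop = FALSE])
        s2[j] <- scorer(by_part[[j]][!take, , drop = FALSE])
      }
      ok <- is.finite(s1) & is.finite(s2)
      if (sum(ok) < 3 || sd(s1[ok]) == 0 || sd(s2[ok]) == 0) {
        return(NA_real_)
      }
      cor(s1[ok], s2[ok])
    }, numeric(1))
  })
  used <- sum(!is.na(rs))
  if (used == 0) {
    abort("degenerate data: every split-half run had an undefined correlation")
  }
  mean_r <- mean(rs, na.rm = TRUE)
  structure(
    tibble::tibble(
      mean_half_correlation = mean_r,
      corrected = spearman_brown(mean_r),
      n_runs_used = used,
      n_runs_dropped = as.integer(runs - used),
      rng_seed = seed
    ),
    class = c("reliability_estimate", "tbl_df", "tbl", "data.frame")
  )
}

#' Scorer factories and trial subsetting for reliability analyses
#'
#' `cross_feature_trials()` keeps the pairwise trials whose two primes
#' differ on `feature` — the split universe for a feature preference
#' score. `proportion_scorer()` returns a scorer closure computing the
#' proportion of responded trials on which the chosen side's prime carried
#' `focal_level` (the pairwise preference score on a trial subset).
#' `amp_proportion_scorer()` does the same for the single-prime task,
#' returning the difference of "more pleasant" proportions, and
#' `rating_scorer()` the mean rating difference.
#'
#' @param trials Pairwise trial tibble.
#' @param stimuli Stimulus table.
#' @param feature Categorical feature name.
#' @param focal_level Focal level of the feature.
#' @return `cross_feature_trials()` a tibble; the factories a
#'   `function(trials) -> scalar`.
#' @export
cross_feature_trials <- function(trials, stimuli, feature) {
  stimuli <- as_stimulus_table(stimuli)
  lookup <- level_lookup(stimuli, feature)
  keep <- lookup[trials$left_prime] != lookup[trials$right_prime]
  tibble::as_tibble(trials)[keep, , drop = FALSE]
}

#' @rdname cross_feature_trials
#' @export
proportion_scorer <- function(stimuli, feature, focal_level) {
  stimuli <- as_stimulus_table(stimuli)
  lookup <- level_lookup(stimuli, feature)
  force(focal_level)
  function(trials) {
    side <- trials$response_side
    resp <- side != "none"
    if (!any(resp)) return(NA_real_)
    chosen <- ifelse(side[resp] == "left",
                     trials$left_prime[resp], trials$right_prime[resp])
    mean(lookup[chosen] == focal_level)
  }
}

#' @rdname cross_feature_trials
#' @param latency_filter,lo_ms,hi_ms Latency filtering applied inside the
#'   scorer (default on for the AMP scorer).
#' @export
amp_proportion_scorer <- function(stimuli, feature, focal_level,
                                  latency_filter = TRUE,
                                  lo_ms = 150, hi_ms = 1500) {
  stimuli <- as_stimulus_table(stimuli)
  lookup <- level_lookup(stimuli, feature)
  function(trials) {
    if (latency_filter) {
      trials <- filter_latency(trials, lo_ms, hi_ms)$kept
    } else {
      trials <- trials[trials$response != "none", , drop = FALSE]
    }
    if (nrow(trials) == 0) return(NA_real_)
    lev <- lookup[trials$prime]
    pos <- lev == focal_level
    if (!any(pos) || all(pos)) return(NA_real_)
    more <- trials$response == "more_pleasant"
    mean(more[pos]) - mean(more[!pos])
  }
}

#' @rdname cross_feature_trials
#' @export
rating_scorer <- function(stimuli, feature, focal_level) {
  stimuli <- as_stimulus_table(stimuli)
  lookup <- level_lookup(stimuli, feature)
  function(trials) {
    lev <- lookup[trials$stimulus_id]
    pos <- lev == focal_level
    if (!any(pos) || all(pos)) return(NA_real_)
    mean(trials$rating[pos]) - mean(trials$rating[!pos])
  }
}
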