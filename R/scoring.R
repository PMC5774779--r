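#' Latency filter
#'
#' Drops trials without a recorded response or with a response latency
#' outside `[lo_ms, hi_ms]` (bounds inclusive; a trial at exactly 150 or
#' 1500 ms is kept). Trials with a recorded response but no measured
#' latency are excluded, since their latency cannot be verified.
#'
#' @param trials Trial tibble with a `latency_ms` column and a
#'   `response_side` or `response` column.
#' @param lo_ms,hi_ms Inclusive bounds in milliseconds (defaults 150, 1500).
#' @return A list with `kept` (the retained tibble) and `excluded_fraction`
#'   (`1 - nrow(kept)/nrow(trials)`; 0 for empty input).
#' @examples
#' sched <- build_amp_schedule(default_primes(), seed = 3)
#' @export
filter_latency <- function(trials, lo_ms = 150, hi_ms = 1500) {
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) {
    return(list(kept = trials, excluded_fraction = 0))
  }
  resp <- responded(trials)
  lat <- trials$latency_ms
  keep <- resp & !is.na(lat) & lat >= lo_ms & lat <= hi_ms
  list(
    kept = trials[keep, , drop = FALSE],
    excluded_fraction = 1 - sum(keep) / nrow(trials)
  )
}

responded <- function(trials) {
  if ("response_side" %in% names(trials)) {
    trials$response_side %in% c("left", "right")
  } else if ("response" %in% names(trials)) {
    trials$response %in% c("less_pleasant", "more_pleasant")
  } else {
    abort("Trials have neither a `response_side` nor a `response` column.")
  }
}

#' AMP difference-of-proportions score
#'
#' For each participant, the proportion of "more pleasant" judgments after
#' primes of the focal level minus the proportion after primes of the other
#' level. The score lies in \[-1, 1\]; its deviation from 0 indexes the
#' strength and direction of the relative preference. Latency filtering
#' (150-1500 ms) is applied before scoring by default, mirroring standard
#' practice for this task. A participant with no valid trial for either
#' level gets a missing (`NA`) score, never an imputed 0.
#'
#' @param trials AMP trial tibble (`participant_id`, `prime`, `response`,
#'   `latency_ms`).
#' @param stimuli Stimulus table mapping every prime to a feature level.
#' @param feature Categorical feature name (e.g. `"race"`).
#' @param positive_level Level whose preference is indexed positively.
#' @param latency_filter Apply [filter_latency()] first (default `TRUE`).
#' @param lo_ms,hi_ms Latency bounds, passed to [filter_latency()].
#' @return A tibble with `participant_id`, `feature`, `focal_level`,
#'   `value`, `n_trials_used`.
#' @export
amp_score <- function(trials, stimuli, feature, positive_level,
                      latency_filter = TRUE, lo_ms = 150, hi_ms = 1500) {
  trials <- tibble::as_tibble(trials)
  stimuli <- as_stimulus_table(stimuli)
  lv <- feature_levels(stimuli, feature)
  if (!positive_level %in% lv) {
    abort(sprintf("`positive_level` must be one of: %s", paste(lv, collapse = ", ")))
  }
  lookup <- level_lookup(stimuli, feature)
  unknown <- setdiff(unique(trials$prime), names(lookup))
  if (length(unknown)) {
    abort(sprintf("Trials reference unknown stimuli: %s", paste(unknown, collapse = ", ")))
  }
  participants <- unique(trials$participant_id)
  if (latency_filter) {
    trials <- filter_latency(trials, lo_ms, hi_ms)$kept
  } else {
    trials <- trials[responded(trials), , drop = FALSE]
  }
  trials$level <- unname(lookup[trials$prime])
  trials$more <- trials$response == "more_pleasant"
  out <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      p_pos = mean(.data$more[.data$level == positive_level]),
      p_neg = mean(.data$more[.data$level != positive_level]),
      n_trials_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      value = .data$p_pos - .data$p_neg,
      feature = feature,
      focal_level = positive_level
    )
  # participants dropped entirely by the filter come back as missing scores
  out |>
    dplyr::select("participant_id", "feature", "focal_level", "value",
                  "n_trials_used") |>
    complete_participants(participants, feature, positive_level)
}

complete_participants <- function(out, participants, feature, focal_level) {
  missing <- setdiff(participants, out$participant_id)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      participant_id = missing, feature = feature, focal_level = focal_level,
      value = NA_real_, n_trials_used = 0L
    ))
  }
  out$value[is.nan(out$value)] <- NA_real_
  dplyr::arrange(out, .data$participant_id)
}

#' Pairwise-choice preference scores
#'
#' For each participant, the proportion of cross-category trials (the two
#' primes differ on `feature`) on which the chosen side's prime carried
#' `focal_level`. 0.5 is indifference; the deviation from 0.5 indexes the
#' strength and direction of the relative preference. Same-category trials
#' and non-responses are excluded; a participant with no usable
#' cross-category trial gets a missing score. `impres_preference_score()`
#' and `expres_preference_score()` share this contract; by default neither
#' applies the latency filter (set `latency_filter = TRUE` to filter the
#' speeded implicit task like the AMP).
#'
#' @inheritParams amp_score
#' @param trials Pairwise trial tibble (`participant_id`, `left_prime`,
#'   `right_prime`, `response_side`, `latency_ms`).
#' @param focal_level Level whose choice proportion is reported.
#' @return A tibble with `participant_id`, `feature`, `focal_level`,
#'   `value`, `n_trials_used`.
#' @export
impres_preference_score <- function(trials, stimuli, feature, focal_level,
                                    latency_filter = FALSE,
                                    lo_ms = 150, hi_ms = 1500) {
  trials <- tibble::as_tibble(trials)
  stimuli <- as_stimulus_table(stimuli)
  lv <- feature_levels(stimuli, feature)
  if (!focal_level %in% lv) {
    abort(sprintf("`focal_level` must be one of: %s", paste(lv, collapse = ", ")))
  }
  lookup <- level_lookup(stimuli, feature)
  unknown <- setdiff(unique(c(trials$left_prime, trials$right_prime)), names(lookup))
  if (length(unknown)) {
    abort(sprintf("Trials reference unknown stimuli: %s", paste(unknown, collapse = ", ")))
  }
  participants <- unique(trials$participant_id)
  if (latency_filter) {
    trials <- filter_latency(trials, lo_ms, hi_ms)$kept
  } else {
    trials <- trials[responded(trials), , drop = FALSE]
  }
  left_lv <- unname(lookup[trials$left_prime])
  right_lv <- unname(lookup[trials$right_prime])
  cross <- left_lv != right_lv
  trials <- trials[cross, , drop = FALSE]
  chosen_lv <- ifelse(trials$response_side == "left",
                      left_lv[cross], right_lv[cross])
  trials$focal_chosen <- chosen_lv == focal_level
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      value = mean(.data$focal_chosen),
      n_trials_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(feature = feature, focal_level = focal_level) |>
    dplyr::select("participant_id", "feature", "focal_level", "value",
                  "n_trials_used") |>
    complete_participants(participants, feature, focal_level)
}

#' @rdname impres_preference_score
#' @export
expres_preference_score <- function(trials, stimuli, feature, focal_level,
                                    latency_filter = FALSE,
                                    lo_ms = 150, hi_ms = 1500) {
  impres_preference_score(trials, stimuli, feature, focal_level,
                          latency_filter, lo_ms, hi_ms)
}

#' Rating difference score
#'
#' Mean pleasantness rating of the focal-level stimuli minus the mean
#' rating of the other level, per participant; on a k-point scale the score
#' lies in \[-(k-1), k-1\].
#'
#' @inheritParams amp_score
#' @param ratings Rating tibble (`participant_id`, `stimulus_id`, `rating`).
#' @param focal_level Level whose mean rating enters positively.
#' @export
rating_difference_score <- function(ratings, stimuli, feature, focal_level) {
  ratings <- tibble::as_tibble(ratings)
  stimuli <- as_stimulus_table(stimuli)
  lv <- feature_levels(stimuli, feature)
  if (!focal_level %in% lv) {
    abort(sprintf("`focal_level` must be one of: %s", paste(lv, collapse = ", ")))
  }
  lookup <- level_lookup(stimuli, feature)
  unknown <- setdiff(unique(ratings$stimulus_id), names(lookup))
  if (length(unknown)) {
    abort(sprintf("Ratings reference unknown stimuli: %s", paste(unknown, collapse = ", ")))
  }
  participants <- unique(ratings$participant_id)
  ratings$level <- unname(lookup[ratings$stimulus_id])
  ratings |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      value = mean(.data$rating[.data$level == focal_level]) -
        mean(.data$rating[.data$level != focal_level]),
      n_trials_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(feature = feature, focal_level = focal_level) |>
    dplyr::select("participant_id", "feature", "focal_level", "value",
                  "n_trials_used") |>
    complete_participants(participants, feature, focal_level)
}

#' Questionnaire sum score
#'
#' Sums item scores per participant after reverse-coding the negatively
#' keyed items: a reversed item scored s contributes `scale_max + 1 - s`.
#' The default layout matches a 10-item, 5-point scale, for which the
#' theoretical midpoint is 30.
#'
#' @param responses Long tibble with `participant_id`, `item` (1-based
#'   index), `score`.
#' @param reverse_items Integer indices of reverse-keyed items.
#' @param scale_max Top of the response scale (default 5).
#' @return A tibble with `participant_id`, `score`, `n_items`.
#' @export
questionnaire_sum_score <- function(responses, reverse_items = integer(),
                                    scale_max = 5) {
  responses <- tibble::as_tibble(responses)
  if (any(responses$score < 1 | responses$score > scale_max)) {
    abort(sprintf("Item scores must lie in [1, %d].", scale_max))
  }
  responses$contrib <- ifelse(responses$item %in% reverse_items,
                              scale_max + 1 - responses$score,
                              responses$score)
  responses |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(score = sum(.data$contrib), n_items = dplyr::n(),
                     .groups = "drop")
}

#' Participant-by-stimulus preference-count matrix
#'
#' Tallies, for every participant, the number of responded trials on which
#' each stimulus's side was chosen. In a complete all-pairs design with
#' `n` stimuli each stimulus appears `K = n - 1` times per participant, so
#' counts lie in `[0, K]` and each row sums to the participant's number of
#' responded trials. All trials count, including same-category pairs: this
#' is the stimulus-level record that downstream unfolding consumes.
#'
#' @param trials Pairwise trial tibble.
#' @param stimuli Optional stimulus table fixing the column universe; any
#'   trial referencing a stimulus outside it is an error. Defaults to the
#'   stimuli present in the trials.
#' @return An object of class `pref_matrix`: a list with `counts`
#'   (integer matrix, participants x stimuli), `appearances` (K, the
#'   maximum number of times any stimulus was shown to a participant) and
#'   `n_responded` (responded trials per participant). Use [tidy()] for a
#'   long tibble.
#' @export
preference_count_matrix <- function(trials, stimuli = NULL) {
  trials <- tibble::as_tibble(trials)
  ids <- if (is.null(stimuli)) {
    sort(unique(c(trials$left_prime, trials$right_prime)))
  } else {
    as_stimulus_table(stimuli)$stimulus_id
  }
  unknown <- setdiff(unique(c(trials$left_prime, trials$right_prime)), ids)
  if (length(unknown)) {
    abort(sprintf("Trials reference unknown stimuli: %s", paste(unknown, collapse = ", ")))
  }
  participants <- sort(unique(trials$participant_id))
  pi <- match(trials$participant_id, participants)
  # appearances per (participant, stimulus), counting unanswered trials too
  app <- matrix(0L, length(participants), length(ids),
                dimnames = list(participants, ids))
  for (col in c("left_prime", "right_prime")) {
    t_ <- table(factor(trials$participant_id, participants),
                factor(trials[[col]], ids))
    app <- app + unclass(t_)
  }
  resp <- responded(trials)
  chosen <- ifelse(trials$response_side == "left",
                   trials$left_prime, trials$right_prime)
  counts <- unclass(table(
    factor(trials$participant_id[resp], participants),
    factor(chosen[resp], ids)
  ))
  storage.mode(counts) <- "integer"
  structure(
    list(
      counts = counts,
      appearances = max(app),
      n_responded = rowSums(counts)
    ),
    class = "pref_matrix"
  )
}

#' @export
print.pref_matrix <- function(x, ...) {
  cat(sprintf(
    "<pref_matrix> %d participants x %d stimuli, K = %d appearances\n",
    nrow(x$counts), ncol(x$counts), x$appearances
  ))
  invisible(x)
}

#' @export
tidy.pref_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    setNames(c("participant_id", "stimulus_id", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}
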