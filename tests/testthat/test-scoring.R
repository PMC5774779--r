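test_that("latency filter is boundary-inclusive and counts exclusions", {
  trials <- tibble::tibble(
    participant_id = "P01", trial_index = 0:4,
    left_prime = "a", right_prime = "b",
    response_side = "left",
    latency_ms = c(100, 150, 800, 1500, 1600)
  )
  out <- filter_latency(trials)
  expect_equal(out$kept$latency_ms, c(150, 800, 1500))
  expect_equal(out$excluded_fraction, 0.4)

  all_in <- dplyr::mutate(trials, latency_ms = 700)
  expect_equal(filter_latency(all_in)$excluded_fraction, 0)
  expect_equal(filter_latency(trials[0, ])$excluded_fraction, 0)

  # non-responses are excluded even with an in-range latency
  nr <- dplyr::mutate(trials, response_side = "none")
  expect_equal(nrow(filter_latency(nr)$kept), 0L)
})

test_that("latency filter matches a brute-force recount on simulated latencies", {
  lat <- withr::with_seed(42, rlnorm(1000, log(500), 0.8))
  trials <- tibble::tibble(
    participant_id = "P01", trial_index = seq_along(lat) - 1L,
    left_prime = "a", right_prime = "b", response_side = "left",
    latency_ms = lat
  )
  kept_oracle <- 0L
  for (l in lat) if (l >= 150 && l <= 1500) kept_oracle <- kept_oracle + 1L
  out <- filter_latency(trials)
  expect_equal(nrow(out$kept), kept_oracle)
  expect_equal(out$excluded_fraction, 1 - kept_oracle / 1000)
})

amp_trials <- function(responses_by_prime) {
  purrr::imap_dfr(responses_by_prime, function(resps, prime) {
    tibble::tibble(prime = prime, response = resps)
  }) |>
    dplyr::mutate(participant_id = "P01",
                  trial_index = dplyr::row_number() - 1L,
                  latency_ms = 700, .before = 1)
}

test_that("AMP score is the difference of more-pleasant proportions", {
  stim <- small_primes()
  # all "more pleasant" -> both proportions 1, score 0
  t0 <- amp_trials(list(WY1 = rep("more_pleasant", 3),
                        BY1 = rep("more_pleasant", 3)))
  expect_equal(amp_score(t0, stim, "race", "white")$value, 0)

  # perfectly polarized -> +1
  t1 <- amp_trials(list(WY1 = rep("more_pleasant", 6),
                        BY1 = rep("less_pleasant", 6)))
  expect_equal(amp_score(t1, stim, "race", "white")$value, 1)

  # 4/6 vs 1/6
  t2 <- amp_trials(list(
    WY1 = rep(c("more_pleasant", "less_pleasant"), c(4, 2)),
    BY1 = rep(c("more_pleasant", "less_pleasant"), c(1, 5))
  ))
  expect_equal(amp_score(t2, stim, "race", "white")$value, 0.5)

  # a level with no valid trials flags the score missing, not zero
  t3 <- amp_trials(list(WY1 = rep("more_pleasant", 6)))
  expect_true(is.na(amp_score(t3, stim, "race", "white")$value))

  # sign flips exactly under level swap
  s_w <- amp_score(t2, stim, "race", "white")$value
  s_b <- amp_score(t2, stim, "race", "black")$value
  expect_equal(s_w, -s_b)
})

test_that("pairwise preference scores count focal-side choices on cross trials", {
  stim <- default_primes()
  sched <- build_impres_schedule(stim, seed = 31)

  # an unwavering white-chooser scores 1.0 on all 100 cross-race trials
  always_white <- respond_with(sched, "P01", choose_level(stim, "race", "white"))
  sc <- impres_preference_score(always_white, stim, "race", "white")
  expect_equal(sc$value, 1.0)
  expect_equal(sc$n_trials_used, 100L)

  # always pressing left scores the left-side white rate of the schedule
  always_left <- respond_with(sched, "P01", function(s) "left")
  lookup <- setNames(stim$race, stim$stimulus_id)
  cross <- lookup[sched$left_prime] != lookup[sched$right_prime]
  white_left_rate <- mean(lookup[sched$left_prime][cross] == "white")
  expect_equal(impres_preference_score(always_left, stim, "race", "white")$value,
               white_left_rate)

  # the explicit-task scorer shares the contract
  expect_equal(
    expres_preference_score(always_white, stim, "race", "white")$value, 1.0)
})

test_that("simulated pairwise scores match an independent per-trial recount", {
  study <- make_study(population_config(n_participants = 4), seed = 13)
  lookup <- setNames(study$stimuli$race, study$stimuli$stimulus_id)
  sc <- impres_preference_score(study$impres, study$stimuli, "race", "white")
  for (p in unique(study$impres$participant_id)) {
    hits <- 0L
    n <- 0L
    for (i in which(study$impres$participant_id == p)) {
      row <- study$impres[i, ]
      if (row$response_side == "none") next
      if (lookup[row$left_prime] == lookup[row$right_prime]) next
      n <- n + 1L
      chosen <- if (row$response_side == "left") row$left_prime else row$right_prime
      if (lookup[chosen] == "white") hits <- hits + 1L
    }
    expect_equal(sc$value[sc$participant_id == p], hits / n)
  }
})

test_that("scores obey relabeling antisymmetry and order invariance", {
  study <- make_study(population_config(n_participants = 5), seed = 17)
  s_w <- impres_preference_score(study$impres, study$stimuli, "race", "white")
  s_b <- impres_preference_score(study$impres, study$stimuli, "race", "black")
  expect_equal(s_w$value, 1 - s_b$value)

  shuffled <- study$impres[withr::with_seed(1, sample.int(nrow(study$impres))), ]
  expect_equal(
    impres_preference_score(shuffled, study$stimuli, "race", "white"), s_w)
})

test_that("rating difference score equals the difference of level means", {
  stim <- small_primes()
  flat <- tidyr::expand_grid(participant_id = "P01",
                             stimulus_id = stim$stimulus_id) |>
    dplyr::mutate(rating = 6L)
  expect_equal(rating_difference_score(flat, stim, "race", "white")$value, 0)

  polar <- dplyr::mutate(flat,
    rating = ifelse(stim$race[match(stimulus_id, stim$stimulus_id)] == "white",
                    9L, 1L))
  expect_equal(rating_difference_score(polar, stim, "race", "white")$value, 8)

  rnd <- dplyr::mutate(flat, rating = withr::with_seed(3, sample(1:9, dplyr::n(), TRUE)))
  lv <- stim$race[match(rnd$stimulus_id, stim$stimulus_id)]
  expect_equal(rating_difference_score(rnd, stim, "race", "white")$value,
               mean(rnd$rating[lv == "white"]) - mean(rnd$rating[lv == "black"]))
})

test_that("questionnaire sum score reverses negatively keyed items", {
  long <- function(scores) tibble::tibble(participant_id = "P01",
                                          item = seq_along(scores),
                                          score = scores)
  expect_equal(questionnaire_sum_score(long(rep(3L, 10)), 6:10)$score, 30L)
  expect_equal(questionnaire_sum_score(long(rep(3L, 10)), c(1, 4, 9))$score, 30L)
  expect_equal(questionnaire_sum_score(long(rep(5L, 10)))$score, 50L)
  expect_equal(
    questionnaire_sum_score(long(c(1:5, 1:5)), 6:10)$score,
    15L + sum(5:1))
  expect_error(questionnaire_sum_score(long(c(rep(3L, 9), 6L))), "1, 5")
})

test_that("preference-count matrix tallies chosen primes", {
  one <- tibble::tibble(participant_id = "P01", trial_index = 0L,
                        left_prime = "WY1", right_prime = "BY1",
                        response_side = "left", latency_ms = 700)
  pm <- preference_count_matrix(one, small_primes())
  expect_equal(sum(pm$counts), 1L)
  expect_equal(pm$counts["P01", "WY1"], 1L)

  study <- make_study(population_config(n_participants = 4), seed = 23)
  pm <- preference_count_matrix(study$impres, study$stimuli)
  expect_equal(pm$appearances, 19L)
  responded <- study$impres$response_side != "none"
  expect_equal(unname(pm$n_responded),
               as.vector(tapply(responded, study$impres$participant_id,
                                sum)[rownames(pm$counts)]))
  expect_true(all(pm$counts <= pm$appearances))

  # brute-force tally oracle
  tally <- matrix(0L, 4, 20,
                  dimnames = dimnames(pm$counts))
  for (i in seq_len(nrow(study$impres))) {
    row <- study$impres[i, ]
    if (row$response_side == "none") next
    chosen <- if (row$response_side == "left") row$left_prime else row$right_prime
    tally[row$participant_id, chosen] <- tally[row$participant_id, chosen] + 1L
  }
  expect_equal(pm$counts, tally)

  bad <- dplyr::mutate(one, left_prime = "XX9")
  expect_error(preference_count_matrix(bad, small_primes()), "unknown stimuli")
})
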