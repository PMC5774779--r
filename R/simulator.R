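#' Population configuration for the attitude simulator
#'
#' Describes the latent attitude population the generative model draws
#' from. Each participant p carries one attitude weight per feature,
#' `beta_f(p) ~ Normal(mean, sd^2)`, plus stimulus-specific idiosyncrasy
#' `gamma(p, s) ~ Normal(0, sigma_gamma^2)`; the latent attitude toward a
#' stimulus is `a(p, s) = sum_f beta_f(p) x_f(s) + gamma(p, s)` with
#' feature coding `x_f` = +1/2 for the positive level and -1/2 otherwise,
#' so `beta_f` is the full between-level attitude gap. A random fraction
#' of participants are outliers whose `beta` weights are inflated by a
#' common multiplier (extreme responders).
#'
#' Defaults mirror the reference study design: 53 participants with
#' attitudes calibrated so that, under the default task parameters, the
#' simulated preference scores stay in the informative mid-range of the
#' proportion scale rather than saturating at 0 or 1 — a slight mean
#' preference for white over black faces (`beta_race ~ N(0.2, 0.5^2)`), a
#' weaker age preference (`beta_age ~ N(0.1, 0.4^2)`), idiosyncrasy SD
#' 0.3, and roughly two extreme responders per sample whose attitude
#' weights are inflated fourfold.
#'
#' @param n_participants Number of participants (default 53).
#' @param features Tibble with `feature`, `positive_level`, `mean`, `sd`.
#' @param sigma_gamma SD of the participant-by-stimulus idiosyncrasy.
#' @param outlier_fraction Fraction of outlier participants.
#' @param outlier_multiplier Multiplier on outliers' `beta` weights.
#' @return A `population_config` list.
#' @export
population_config <- function(n_participants = 53,
                              features = tibble::tibble(
                                feature = c("race", "age"),
                                positive_level = c("white", "young"),
                                mean = c(0.2, 0.1),
                                sd = c(0.5, 0.4)
                              ),
                              sigma_gamma = 0.3,
                              outlier_fraction = 2 / 53,
                              outlier_multiplier = 4) {
  stopifnot(
    n_participants >= 1, all(features$sd >= 0), sigma_gamma >= 0,
    outlier_fraction >= 0, outlier_fraction <= 1, outlier_multiplier >= 0
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      features = tibble::as_tibble(features),
      sigma_gamma = sigma_gamma,
      outlier_fraction = outlier_fraction,
      outlier_multiplier = outlier_multiplier
    ),
    class = "population_config"
  )
}

#' Draw a latent attitude population
#'
#' Samples participant attitude weights and stimulus idiosyncrasies under
#' a [population_config()] and assembles the participant-by-stimulus
#' latent attitude matrix. Fully deterministic given the seed.
#'
#' @param stimuli Stimulus table defining the stimulus set and its
#'   categorical features (must include every feature in the config).
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return An object of class `latent_attitudes`: list with `beta`
#'   (tibble: `participant_id`, `feature`, `beta`, `outlier`), `gamma`
#'   and `attitude` (participant x stimulus matrices), `stimuli`,
#'   `config`, `rng_seed`.
#' @export
draw_population <- function(stimuli, config = population_config(), seed) {
  stimuli <- as_stimulus_table(stimuli)
  stopifnot(inherits(config, "population_config"))
  seed <- check_seed(seed)
  feats <- config$features
  for (f in feats$feature) feature_levels(stimuli, f)
  n <- config$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  s_ids <- stimuli$stimulus_id

  draws <- withr::with_seed(seed, {
    beta <- purrr::pmap(feats, function(feature, positive_level, mean, sd) {
      rnorm(n, mean, sd)
    })
    outlier <- runif(n) < config$outlier_fraction
    gamma <- matrix(rnorm(n * length(s_ids), 0, config$sigma_gamma),
                    n, length(s_ids), dimnames = list(ids, s_ids))
    list(beta = beta, outlier = outlier, gamma = gamma)
  })
  beta_mat <- do.call(cbind, draws$beta)
  colnames(beta_mat) <- feats$feature
  beta_mat[draws$outlier, ] <- beta_mat[draws$outlier, , drop = FALSE] *
    config$outlier_multiplier

  # feature coding: +1/2 at the positive level, -1/2 otherwise
  x <- vapply(seq_len(nrow(feats)), function(i) {
    ifelse(stimuli[[feats$feature[i]]] == feats$positive_level[i], 0.5, -0.5)
  }, numeric(length(s_ids)))
  attitude <- beta_mat %*% t(x) + draws$gamma
  dimnames(attitude) <- list(ids, s_ids)

  structure(
    list(
      beta = tidyr::pivot_longer(
        tibble::as_tibble(beta_mat) |>
          dplyr::mutate(participant_id = ids, outlier = draws$outlier),
        -c("participant_id", "outlier"),
        names_to = "feature", values_to = "beta"
      ) |>
        dplyr::select("participant_id", "feature", "beta", "outlier"),
      gamma = draws$gamma,
      attitude = attitude,
      stimuli = stimuli,
      config = config,
      rng_seed = seed
    ),
    class = "latent_attitudes"
  )
}

#' @export
print.latent_attitudes <- function(x, ...) {
  cat(sprintf(
    "<latent_attitudes> %d participants x %d stimuli (%s)\n",
    nrow(x$attitude), ncol(x$attitude),
    paste(x$config$features$feature, collapse = ", ")
  ))
  invisible(x)
}

#' Task parameter sets for the simulator
#'
#' Behavioral parameters of the generative choice model.
#' `impres_params()`: misattribution strength `lambda` scales the latent
#' attitude difference inside the logistic choice rule of the speeded
#' pairwise task. `amp_params()`: judgment scale `kappa` and response bias
#' `bias` govern the single-prime "more pleasant" judgment.
#' `expres_params()`: explicit discrimination `lambda` (typically larger
#' than the implicit `lambda`, as deliberate judgments discriminate more
#' sharply). All include a lapse rate `lapse` in \[0, 0.5\] (random
#' responding) and a response-latency model: lognormal with fast-guess
#' and slow-tail contamination so the 150-1500 ms latency filter has
#' realistic work to do (about 4-5% exclusions at the defaults).
#' `rating_params()`: a k-point rating is
#' `clip(round(midpoint + scale * a + noise), 1, k)`.
#'
#' @param lambda,kappa,bias,lapse,scale,noise_sd,k Model parameters as
#'   described above.
#' @param latency_meanlog,latency_sdlog,fast_rate,slow_rate Latency model
#'   parameters (log-scale mean/sd; contamination rates).
#' @return A parameter list of class `task_params`.
#' @export
impres_params <- function(lambda = 2, lapse = 0.02,
                          latency_meanlog = log(600), latency_sdlog = 0.3,
                          fast_rate = 0.016, slow_rate = 0.03) {
  stopifnot(lambda >= 0, lapse >= 0, lapse <= 0.5)
  structure(list(task = "impres", lambda = lambda, lapse = lapse,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 fast_rate = fast_rate, slow_rate = slow_rate),
            class = "task_params")
}

#' @rdname impres_params
#' @export
amp_params <- function(kappa = 1.5, bias = 0, lapse = 0.02,
                       latency_meanlog = log(600), latency_sdlog = 0.3,
                       fast_rate = 0.016, slow_rate = 0.03) {
  stopifnot(kappa >= 0, lapse >= 0, lapse <= 0.5)
  structure(list(task = "amp", kappa = kappa, bias = bias, lapse = lapse,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 fast_rate = fast_rate, slow_rate = slow_rate),
            class = "task_params")
}

#' @rdname impres_params
#' @export
expres_params <- function(lambda = 4, lapse = 0.01,
                          latency_meanlog = log(900), latency_sdlog = 0.4,
                          fast_rate = 0, slow_rate = 0) {
  stopifnot(lambda >= 0, lapse >= 0, lapse <= 0.5)
  structure(list(task = "expres", lambda = lambda, lapse = lapse,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 fast_rate = fast_rate, slow_rate = slow_rate),
            class = "task_params")
}

#' @rdname impres_params
#' @export
rating_params <- function(scale = 2, noise_sd = 0.8, k = 9) {
  stopifnot(scale >= 0, noise_sd >= 0, k >= 2)
  structure(list(task = "ratings", scale = scale, noise_sd = noise_sd,
                 k = as.integer(k)),
            class = "task_params")
}

draw_latencies <- function(n, params) {
  u <- runif(n)
  lat <- rlnorm(n, params$latency_meanlog, params$latency_sdlog)
  fast <- u < params$fast_rate
  slow <- u >= params$fast_rate & u < params$fast_rate + params$slow_rate
  lat[fast] <- runif(sum(fast), 50, 140)
  lat[slow] <- runif(sum(slow), 1510, 2600)
  round(lat, 1)
}

attitude_of <- function(attitudes, participant, stimulus) {
  attitudes$attitude[cbind(participant, stimulus)]
}

#' Simulate task responses from latent attitudes
#'
#' Generates trial responses under the misattribution choice model: the
#' preference between two targets is driven by the latent attitudes
#' toward their primes. For the pairwise tasks the left side is chosen
#' with probability
#' `lapse/2 + (1 - lapse) * logistic(lambda * (a_left - a_right))`;
#' for the single-prime task "more pleasant" is emitted with probability
#' `lapse/2 + (1 - lapse) * logistic(kappa * a + bias)`. Ratings are a
#' clipped, rounded linear function of attitude plus Gaussian noise.
#' All simulators are deterministic given their seed.
#'
#' @param schedule Schedule tibble with a `participant_id` column (see
#'   the builders); for `simulate_ratings()` every stimulus is rated
#'   once per participant.
#' @param attitudes A `latent_attitudes` object covering all scheduled
#'   participants and primes.
#' @param params Matching [impres_params()] / [amp_params()] /
#'   [expres_params()] / [rating_params()].
#' @param seed Integer seed.
#' @return A trial tibble in the task's log format.
#' @export
simulate_impres <- function(schedule, attitudes, params = impres_params(),
                            seed) {
  stopifnot(inherits(attitudes, "latent_attitudes"),
            params$task %in% c("impres", "expres"))
  seed <- check_seed(seed)
  schedule <- tibble::as_tibble(schedule)
  missing <- setdiff(unique(c(schedule$left_prime, schedule$right_prime)),
                     colnames(attitudes$attitude))
  if (length(missing)) {
    abort(sprintf("Schedule primes missing from attitudes: %s",
                  paste(missing, collapse = ", ")))
  }
  a_l <- attitude_of(attitudes, schedule$participant_id, schedule$left_prime)
  a_r <- attitude_of(attitudes, schedule$participant_id, schedule$right_prime)
  p_left <- params$lapse / 2 +
    (1 - params$lapse) * plogis(params$lambda * (a_l - a_r))
  withr::with_seed(seed, {
    side <- ifelse(runif(nrow(schedule)) < p_left, "left", "right")
    lat <- draw_latencies(nrow(schedule), params)
  })
  schedule |>
    dplyr::mutate(response_side = side, latency_ms = lat) |>
    dplyr::select("participant_id", "trial_index", "left_prime",
                  "right_prime", "response_side", "latency_ms")
}

#' @rdname simulate_impres
#' @export
simulate_expres <- function(schedule, attitudes, params = expres_params(),
                            seed) {
  simulate_impres(schedule, attitudes, params, seed)
}

#' @rdname simulate_impres
#' @export
simulate_amp <- function(schedule, attitudes, params = amp_params(), seed) {
  stopifnot(inherits(attitudes, "latent_attitudes"), params$task == "amp")
  seed <- check_seed(seed)
  schedule <- tibble::as_tibble(schedule)
  missing <- setdiff(unique(schedule$prime), colnames(attitudes$attitude))
  if (length(missing)) {
    abort(sprintf("Schedule primes missing from attitudes: %s",
                  paste(missing, collapse = ", ")))
  }
  a <- attitude_of(attitudes, schedule$participant_id, schedule$prime)
  p_more <- params$lapse / 2 +
    (1 - params$lapse) * plogis(params$kappa * a + params$bias)
  withr::with_seed(seed, {
    resp <- ifelse(runif(nrow(schedule)) < p_more,
                   "more_pleasant", "less_pleasant")
    lat <- draw_latencies(nrow(schedule), params)
  })
  schedule |>
    dplyr::mutate(response = resp, latency_ms = lat) |>
    dplyr::select("participant_id", "trial_index", "prime", "response",
                  "latency_ms")
}

#' @rdname simulate_impres
#' @export
simulate_ratings <- function(attitudes, params = rating_params(), seed) {
  stopifnot(inherits(attitudes, "latent_attitudes"),
            params$task == "ratings")
  seed <- check_seed(seed)
  a <- attitudes$attitude
  grid <- tidyr::expand_grid(
    participant_id = rownames(a),
    stimulus_id = colnames(a)
  )
  midpoint <- (params$k + 1) / 2
  raw <- midpoint + params$scale * attitude_of(attitudes, grid$participant_id,
                                               grid$stimulus_id)
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, params$noise_sd))
  grid$rating <- as.integer(pmin(params$k, pmax(1, round(raw + noise))))
  grid
}

#' @rdname simulate_impres
#' @param n_items,reverse_items,scale_max Questionnaire layout: number of
#'   items, indices of reverse-keyed items, top of the response scale.
#' @param loading,item_noise_sd Linear loading of item responses on the
#'   participant's first-feature attitude weight, and item noise SD.
#' @export
simulate_questionnaire <- function(attitudes, n_items = 10,
                                   reverse_items = 6:10, scale_max = 5,
                                   loading = 0.8, item_noise_sd = 1, seed) {
  stopifnot(inherits(attitudes, "latent_attitudes"))
  seed <- check_seed(seed)
  first_feature <- attitudes$config$features$feature[1]
  beta <- attitudes$beta |>
    dplyr::filter(.data$feature == first_feature)
  grid <- tidyr::expand_grid(
    participant_id = beta$participant_id,
    item = seq_len(n_items)
  )
  b <- setNames(beta$beta, beta$participant_id)[grid$participant_id]
  midpoint <- (scale_max + 1) / 2
  signed <- ifelse(grid$item %in% reverse_items, -loading, loading)
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, item_noise_sd))
  grid$score <- as.integer(pmin(scale_max, pmax(1, round(
    midpoint + signed * b + noise
  ))))
  structure(grid, reverse_items = as.integer(reverse_items),
            scale_max = as.integer(scale_max))
}

#' Simulate a complete study
#'
#' Generates the full synthetic dataset the analysis pipeline consumes:
#' per-participant schedules (independent random orders and side
#' assignments), responses for all four tasks, a questionnaire stub, and
#' the ground-truth attitude weights. At the defaults this reproduces the
#' reference design: 53 participants, 20 primes (5 per race x age cell),
#' 190 pairwise implicit trials (all pairs), 120 single-prime trials
#' (each prime 6 times), 190 explicit pairwise trials, and one 9-point
#' rating per stimulus. A single seed controls every draw.
#'
#' @param config A [population_config()].
#' @param stimuli Stimulus table (default [default_primes()]).
#' @param impres,amp,expres,ratings Task parameter sets.
#' @param amp_repetitions Prime repetitions in the AMP schedule.
#' @param seed Integer seed.
#' @return An object of class `study`: list of tibbles `stimuli`,
#'   `impres`, `amp`, `expres`, `ratings`, `questionnaire`, `truth`
#'   (per-participant `beta` weights) plus the `latent_attitudes` in
#'   `$attitudes`.
#' @examples
#' study <- make_study(population_config(n_participants = 5), seed = 1)
#' nrow(study$impres) # 5 x 190
#' @export
make_study <- function(config = population_config(),
                       stimuli = default_primes(),
                       impres = impres_params(), amp = amp_params(),
                       expres = expres_params(), ratings = rating_params(),
                       amp_repetitions = 6, seed) {
  seed <- check_seed(seed)
  stimuli <- as_stimulus_table(stimuli)
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, 6L + 3L * config$n_participants))
  attitudes <- draw_population(stimuli, config, seed = seeds[1])
  ids <- rownames(attitudes$attitude)

  per_participant <- function(builder, seed_offset) {
    purrr::imap_dfr(ids, function(id, i) {
      builder(seeds[seed_offset + 3L * (i - 1L)]) |>
        dplyr::mutate(participant_id = id, .before = 1)
    })
  }
  impres_sched <- per_participant(function(s) build_impres_schedule(stimuli, s), 7L)
  amp_sched <- per_participant(function(s) build_amp_schedule(stimuli, amp_repetitions, s), 8L)
  expres_sched <- per_participant(function(s) build_expres_schedule(stimuli, s), 9L)

  structure(
    list(
      stimuli = stimuli,
      impres = simulate_impres(impres_sched, attitudes, impres, seed = seeds[2]),
      amp = simulate_amp(amp_sched, attitudes, amp, seed = seeds[3]),
      expres = simulate_expres(expres_sched, attitudes, expres, seed = seeds[4]),
      ratings = simulate_ratings(attitudes, ratings, seed = seeds[5]),
      questionnaire = simulate_questionnaire(attitudes, seed = seeds[6]),
      truth = attitudes$beta,
      attitudes = attitudes,
      rng_seed = seed
    ),
    class = "study"
  )
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf(
    "<study> %d participants, %d stimuli; %d/%d/%d pairwise/single-prime/pairwise-explicit trials\n",
    nrow(x$attitudes$attitude), nrow(x$stimuli),
    nrow(x$impres), nrow(x$amp), nrow(x$expres)
  ))
  invisible(x)
}

#' Write or read a simulated study as a CSV bundle
#'
#' Writes the trial logs, stimulus table, questionnaire and ground truth
#' of a [make_study()] result into a directory as plain CSV. Two runs of
#' the same seeded study write byte-identical files.
#'
#' @param study A `study` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stimulus_table(study$stimuli, file.path(dir, "stimuli.csv"))
  write_trials(study$impres, file.path(dir, "impres.csv"))
  write_trials(study$amp, file.path(dir, "amp.csv"))
  write_trials(study$expres, file.path(dir, "expres.csv"))
  readr::write_csv(study$ratings, file.path(dir, "ratings.csv"), progress = FALSE)
  readr::write_csv(study$questionnaire, file.path(dir, "questionnaire.csv"),
                   progress = FALSE)
  readr::write_csv(study$truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}
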