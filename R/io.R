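#' Read and write trial logs
#'
#' Trial logs are plain UTF-8 CSV with a header row and fixed columns per
#' task:
#' \itemize{
#'   \item pairwise tasks (`impres`, `expres`): `participant_id`,
#'     `trial_index`, `left_prime`, `right_prime`, `response_side`
#'     (`left`/`right`/`none`), `latency_ms` (nonnegative, may be empty);
#'   \item `amp`: `participant_id`, `trial_index`, `prime`, `response`
#'     (`less_pleasant`/`more_pleasant`/`none`), `latency_ms`;
#'   \item `ratings`: `participant_id`, `stimulus_id`, `rating`.
#' }
#' Reading validates the log and fails with the offending data row number:
#' unknown or missing columns, duplicate (participant, trial_index) pairs,
#' malformed response codes, identical left/right primes, or negative
#' latencies are all rejected. A missing `latency_ms` is a legal record
#' (the response simply has no measured latency); a missing response is
#' coded `none`. Writing then reading reproduces the records exactly.
#'
#' @param path CSV file path.
#' @param task One of `"impres"`, `"amp"`, `"expres"`, `"ratings"`.
#' @return A tibble of trial records.
#' @export
read_trials <- function(path, task = c("impres", "amp", "expres", "ratings")) {
  task <- match.arg(task)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  expected <- trial_columns(task)
  extra <- setdiff(names(tab), expected)
  if (length(extra)) {
    abort(sprintf("%s: unknown column(s): %s", path, paste(extra, collapse = ", ")))
  }
  missing <- setdiff(expected, names(tab))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  tab <- tab[expected]
  validate_trials(tab, task, context = path)
}

#' @rdname read_trials
#' @param trials Tibble of trial records as produced by the schedule
#'   builders / simulator (with `participant_id`).
#' @export
write_trials <- function(trials, path) {
  task <- infer_task(trials)
  trials <- validate_trials(trials, task, context = "trials")
  readr::write_csv(trials, path, na = "", progress = FALSE)
  invisible(path)
}

trial_columns <- function(task) {
  switch(task,
    impres = ,
    expres = c("participant_id", "trial_index", "left_prime", "right_prime",
               "response_side", "latency_ms"),
    amp = c("participant_id", "trial_index", "prime", "response", "latency_ms"),
    ratings = c("participant_id", "stimulus_id", "rating")
  )
}

infer_task <- function(trials) {
  nm <- names(trials)
  if (all(c("left_prime", "right_prime") %in% nm)) return("impres")
  if ("prime" %in% nm) return("amp")
  if ("rating" %in% nm) return("ratings")
  abort("Cannot infer the task type from the trial columns.")
}

row_fail <- function(context, i, msg) {
  abort(sprintf("%s: row %d: %s", context, i, msg))
}

validate_trials <- function(tab, task, context = "trials") {
  tab <- tibble::as_tibble(tab)
  n <- nrow(tab)
  if (task == "ratings") {
    tab$participant_id <- as.character(tab$participant_id)
    tab$stimulus_id <- as.character(tab$stimulus_id)
    tab$rating <- as.integer(tab$rating)
    bad <- which(is.na(tab$rating))
    if (length(bad)) row_fail(context, bad[1], "malformed rating")
    return(tab)
  }
  tab$participant_id <- as.character(tab$participant_id)
  tab$trial_index <- as.integer(tab$trial_index)
  lat <- suppressWarnings(as.numeric(tab$latency_ms))
  bad <- which(!is.na(tab$latency_ms) & as.character(tab$latency_ms) != "" & is.na(lat))
  if (length(bad)) row_fail(context, bad[1], "malformed latency_ms")
  bad <- which(!is.na(lat) & lat < 0)
  if (length(bad)) row_fail(context, bad[1], "negative latency_ms")
  tab$latency_ms <- lat
  dup <- which(duplicated(tab[c("participant_id", "trial_index")]))
  if (length(dup)) {
    row_fail(context, dup[1], "duplicate (participant_id, trial_index)")
  }
  if (task == "amp") {
    tab$prime <- as.character(tab$prime)
    tab$response <- as.character(tab$response)
    tab$response[is.na(tab$response)] <- "none"
    bad <- which(!tab$response %in% c("less_pleasant", "more_pleasant", "none"))
    if (length(bad)) row_fail(context, bad[1], "malformed response code")
  } else {
    tab$left_prime <- as.character(tab$left_prime)
    tab$right_prime <- as.character(tab$right_prime)
    bad <- which(tab$left_prime == tab$right_prime)
    if (length(bad)) row_fail(context, bad[1], "left_prime equals right_prime")
    tab$response_side <- as.character(tab$response_side)
    tab$response_side[is.na(tab$response_side)] <- "none"
    bad <- which(!tab$response_side %in% c("left", "right", "none"))
    if (length(bad)) row_fail(context, bad[1], "malformed response_side code")
  }
  tab
}
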