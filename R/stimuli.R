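#' Default prime stimulus set
#'
#' A 2 x 2 factorial set of 20 face primes: race (black vs. white) crossed
#' with age (young vs. old), five exemplars per cell. IDs follow the
#' convention first-letter race (B/W), second-letter age (Y/O), then the
#' exemplar number, e.g. `"WY3"`.
#'
#' @param n_per_cell Number of exemplars per race x age cell (default 5).
#' @return A tibble with columns `stimulus_id`, `race`, `age`.
#' @examples
#' default_primes()
#' @export
default_primes <- function(n_per_cell = 5) {
  stopifnot(n_per_cell >= 1)
  cells <- tidyr::expand_grid(
    race = c("black", "white"),
    age = c("young", "old"),
    exemplar = seq_len(n_per_cell)
  )
  tibble::tibble(
    stimulus_id = paste0(
      toupper(substr(cells$race, 1, 1)),
      toupper(substr(cells$age, 1, 1)),
      cells$exemplar
    ),
    race = cells$race,
    age = cells$age
  )
}

#' Read or write a stimulus table
#'
#' A stimulus table CSV has a `stimulus_id` column, one column per
#' categorical feature (two levels each) and optionally numeric feature
#' columns. IDs must be unique.
#'
#' @param path File path.
#' @return `read_stimulus_table()` returns a tibble.
#' @export
read_stimulus_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_stimulus_table(tab, arg = path)
}

#' @rdname read_stimulus_table
#' @param stimuli Stimulus tibble to write.
#' @export
write_stimulus_table <- function(stimuli, path) {
  stimuli <- as_stimulus_table(stimuli)
  readr::write_csv(stimuli, path, progress = FALSE)
  invisible(path)
}
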