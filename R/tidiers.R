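#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#' `tidy.unfolding_solution()` returns one row per embedded point
#' (`point_id`, `point_type`, `dim1..dimd`);
#' `glance.unfolding_solution()` a one-row fit summary.
#' `tidy.feature_axis()` returns one row per direction component;
#' `glance.feature_axis()` the fit summary.
#' `tidy.pref_matrix()` returns the long count table.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name prefmap-tidiers
NULL

#' @rdname prefmap-tidiers
#' @export
tidy.unfolding_solution <- function(x, ...) {
  dplyr::bind_rows(
    tibble::as_tibble(x$row_coords, rownames = "point_id") |>
      dplyr::mutate(point_type = "participant", .after = "point_id"),
    tibble::as_tibble(x$col_coords, rownames = "point_id") |>
      dplyr::mutate(point_type = "stimulus", .after = "point_id")
  )
}

#' @rdname prefmap-tidiers
#' @export
glance.unfolding_solution <- function(x, ...) {
  tibble::tibble(
    dim = x$dim,
    stress = x$stress,
    iterations = x$iterations,
    converged = x$converged,
    fitted_var_ratio = x$fitted_var_ratio,
    n_participants = nrow(x$row_coords),
    n_stimuli = nrow(x$col_coords),
    rng_seed = x$rng_seed
  )
}

#' @rdname prefmap-tidiers
#' @export
tidy.feature_axis <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    axis_dim = names(x$direction) %||% paste0("dim", seq_along(x$direction)),
    direction = unname(x$direction)
  )
}

#' @rdname prefmap-tidiers
#' @export
glance.feature_axis <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    positive_level = x$positive_level,
    fit_kind = x$fit_kind,
    intercept = x$intercept,
    goodness = x$goodness
  )
}

#' Export an unfolding solution to CSV with a JSON sidecar
#'
#' Writes the joint configuration as a point table
#' (`point_id`, `point_type`, `dim1..dimd`) and, when `jsonlite` is
#' available, a `.json` sidecar recording stress, iterations, seed and
#' options, so each output file documents how it was produced.
#'
#' @param solution An `unfolding_solution`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  stopifnot(inherits(solution, "unfolding_solution"))
  readr::write_csv(tidy(solution), path, progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- as.list(glance(solution))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Plot an unfolding solution
#'
#' Scatter of the joint configuration: participant ideal points and
#' stimulus locations, optionally overlaid with feature axes drawn
#' through the participant centroid.
#'
#' @param object An `unfolding_solution`.
#' @param axes Optional list of `feature_axis` objects to overlay.
#' @param dims Which two dimensions to draw (default c(1, 2)).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unfolding_solution <- function(object, axes = list(), dims = c(1, 2),
                                        ...) {
  pts <- tidy(object)
  d1 <- paste0("dim", dims[1])
  d2 <- paste0("dim", dims[2])
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data[[d1]], .data[[d2]],
                                         colour = .data$point_type)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$point_type)) +
    ggplot2::geom_text(
      data = dplyr::filter(pts, .data$point_type == "stimulus"),
      ggplot2::aes(label = .data$point_id),
      vjust = -0.7, size = 3, show.legend = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Unfolding map (stress %.3f)", object$stress),
      colour = NULL, shape = NULL
    )
  if (length(axes)) {
    centroid <- colMeans(object$row_coords)
    span <- max(abs(object$col_coords))
    seg <- purrr::map_dfr(axes, function(ax) {
      tibble::tibble(
        feature = ax$feature,
        x = centroid[dims[1]] - span * ax$direction[dims[1]],
        y = centroid[dims[2]] - span * ax$direction[dims[2]],
        xend = centroid[dims[1]] + span * ax$direction[dims[1]],
        yend = centroid[dims[2]] + span * ax$direction[dims[2]]
      )
    })
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$feature),
      inherit.aes = FALSE, colour = "grey30",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    )
  }
  p
}

#' @rdname autoplot.unfolding_solution
#' @param solution An `unfolding_solution`.
#' @export
plot_unfolding <- function(solution, axes = list(), dims = c(1, 2)) {
  autoplot.unfolding_solution(solution, axes = axes, dims = dims)
}
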