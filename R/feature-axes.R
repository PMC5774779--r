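#' Bias-reduced (Firth) logistic regression
#'
#' Maximizes the Jeffreys-prior-penalized binomial log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by iteratively reweighted least
#' squares with the hat-diagonal score adjustment (score contribution
#' `h_i (1/2 - p_i)` added per observation), with step-halving on the
#' penalized likelihood. Unlike plain maximum likelihood, the estimates
#' stay finite under complete separation, which is exactly the regime a
#' well-separated stimulus map produces.
#'
#' @param x Design matrix including the intercept column.
#' @param y Binary response vector (0/1).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence threshold on the coefficient update max-norm
#'   (default 1e-8).
#' @return Coefficient vector (named after the design columns).
#' @export
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (nrow(x) < ncol(x)) {
    abort("Need at least as many observations as coefficients.")
  }
  penalized <- function(beta) {
    eta <- drop(x %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), .Machine$double.eps)
    info <- crossprod(x * sqrt(w))
    # log(1 + exp(eta)) computed overflow-safely
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      0.5 * determinant(info)$modulus
  }
  beta <- numeric(ncol(x))
  ll <- penalized(beta)
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    p <- plogis(drop(x %*% beta))
    w <- pmax(p * (1 - p), .Machine$double.eps)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    # pseudo-inverse tolerates collinear designs (e.g. a constant coordinate)
    info_inv <- MASS::ginv(info)
    # hat diagonals of the weighted design
    h <- rowSums((xw %*% info_inv) * xw)
    score <- drop(crossprod(x, y - p + h * (0.5 - p)))
    grad_norm <- max(abs(score))
    delta <- drop(info_inv %*% score)
    if (max(abs(delta)) < tol) {
      return(setNames(beta, colnames(x)))
    }
    # step-halve until the penalized likelihood does not decrease
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_cand <- penalized(cand)
      if (ll_cand >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll <- penalized(beta)
  }
  abort(sprintf(
    "Firth logistic regression did not converge in %d iterations (last gradient max-norm %.3e).",
    max_iter, grad_norm
  ))
}

#' Overlay a feature axis on an unfolding solution
#'
#' Fits the direction in solution space that best separates (categorical
#' feature) or predicts (continuous feature) a stimulus attribute from the
#' stimulus coordinates. Categorical features use bias-reduced logistic
#' regression ([firth_logistic()]) of the level indicator on the
#' coordinates; the axis is the unit-normalized slope vector, oriented
#' toward `positive_level`, and goodness is the proportion of stimuli on
#' the correct side of the implied boundary. Continuous features use
#' ordinary least squares and report R-squared. The cosine of the angle
#' between two such axes reflects the correlation of the corresponding
#' preference dimensions.
#'
#' @param solution An `unfolding_solution`.
#' @param stimuli Stimulus table covering the solution's stimuli.
#' @param feature Categorical feature name (two levels).
#' @param positive_level Level toward which the axis points.
#' @return An object of class `feature_axis`: list with `feature`,
#'   `positive_level`, `direction` (unit vector), `intercept`,
#'   `fit_kind`, `goodness`.
#' @export
fit_categorical_axis <- function(solution, stimuli, feature, positive_level) {
  stopifnot(inherits(solution, "unfolding_solution"))
  stimuli <- as_stimulus_table(stimuli)
  lv <- feature_levels(stimuli, feature)
  if (!positive_level %in% lv) {
    abort(sprintf("`positive_level` must be one of: %s", paste(lv, collapse = ", ")))
  }
  Y <- solution$col_coords
  lev <- level_lookup(stimuli, feature)[rownames(Y)]
  if (anyNA(lev)) abort("Some solution stimuli are missing from `stimuli`.")
  if (length(unique(lev)) < 2) {
    abort(sprintf("Feature `%s` has a single level among these stimuli.", feature))
  }
  y <- as.numeric(lev == positive_level)
  design <- cbind(intercept = 1, Y)
  beta <- firth_logistic(design, y)
  slope <- beta[-1]
  direction <- slope / sqrt(sum(slope^2))
  fitted_p <- plogis(drop(design %*% beta))
  structure(
    list(
      feature = feature, positive_level = positive_level,
      direction = direction, intercept = unname(beta[1]),
      fit_kind = "bias_reduced_logistic",
      goodness = mean((fitted_p > 0.5) == (y == 1))
    ),
    class = "feature_axis"
  )
}

#' @rdname fit_categorical_axis
#' @param values Continuous stimulus attribute: a named numeric vector
#'   (names = stimulus IDs) or a tibble with `stimulus_id` and `value`.
#' @param label Name recorded for the continuous feature.
#' @export
fit_continuous_axis <- function(solution, values, label = "feature") {
  stopifnot(inherits(solution, "unfolding_solution"))
  Y <- solution$col_coords
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$stimulus_id)
  }
  v <- values[rownames(Y)]
  if (anyNA(v)) abort("Some solution stimuli have no feature value.")
  if (nrow(Y) < solution$dim + 1) {
    abort("Need at least dim + 1 stimuli for a continuous axis.")
  }
  if (sd(v) == 0) abort("Feature values are constant.")
  fit <- lm(v ~ Y)
  slope <- coef(fit)[-1]
  if (all(slope == 0)) abort("Feature values are orthogonal to all coordinates.")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      feature = label, positive_level = NA_character_,
      direction = setNames(slope / sqrt(sum(slope^2)), colnames(Y)),
      intercept = unname(coef(fit)[1]),
      fit_kind = "linear",
      goodness = r2
    ),
    class = "feature_axis"
  )
}

#' @export
print.feature_axis <- function(x, ...) {
  cat(sprintf(
    "<feature_axis> %s%s (%s), goodness %.3f\n  direction: (%s)\n",
    x$feature,
    if (!is.na(x$positive_level)) paste0(" -> ", x$positive_level) else "",
    x$fit_kind, x$goodness,
    paste(sprintf("%.3f", x$direction), collapse = ", ")
  ))
  invisible(x)
}

#' Cosine of the angle between two feature axes
#'
#' The dot product of the unit direction vectors; because the axes are
#' unit-normalized this lies in \[-1, 1\] and reflects the correlation of
#' the two preference dimensions in the map (1 = identical, 0 =
#' orthogonal, independent preferences).
#'
#' @param a,b `feature_axis` objects of equal dimensionality.
#' @export
axis_cosine <- function(a, b) {
  stopifnot(inherits(a, "feature_axis"), inherits(b, "feature_axis"))
  if (length(a$direction) != length(b$direction)) {
    abort("Axes have different dimensionality.")
  }
  min(1, max(-1, sum(a$direction * b$direction)))
}

#' Project points onto a feature axis
#'
#' Orthogonally projects points of an unfolding solution onto an axis
#' direction after centering at the participant centroid:
#' `score = <point - centroid, direction>`. Higher scores lie further
#' toward the axis's positive level. Because only the centered inner
#' product is used, scores are invariant to translations of the whole
#' configuration.
#'
#' @param solution An `unfolding_solution`.
#' @param axis A `feature_axis`.
#' @param which `"participants"` (default) or `"stimuli"`.
#' @return Tibble with `point_id`, `score`.
#' @export
project_points <- function(solution, axis,
                           which = c("participants", "stimuli")) {
  stopifnot(inherits(solution, "unfolding_solution"),
            inherits(axis, "feature_axis"))
  which <- match.arg(which)
  if (length(axis$direction) != solution$dim) {
    abort("Axis dimensionality does not match the solution.")
  }
  centroid <- colMeans(solution$row_coords)
  pts <- if (which == "participants") solution$row_coords else solution$col_coords
  score <- drop(sweep(pts, 2, centroid) %*% axis$direction)
  tibble::tibble(point_id = rownames(pts), score = unname(score))
}

# geometric median by Weiszfeld iteration
geometric_median <- function(pts, tol = 1e-9, max_iter = 500) {
  m <- colMeans(pts)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(pts, 2, m)^2))
    if (all(d < tol)) return(m)
    w <- 1 / pmax(d, tol)
    m_new <- colSums(pts * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Flag extreme points in an unfolding solution
#'
#' Computes every point's distance from the point set's spatial
#' (geometric) median and applies the standard Hampel screen to those
#' distances: a point is flagged when its distance exceeds the median
#' distance by more than `k` (scaled) median absolute deviations.
#' Extreme responders fall far outside the central participant cluster,
#' so this is a robust screen for them.
#'
#' @param solution An `unfolding_solution`.
#' @param which `"participants"` (default) or `"stimuli"`.
#' @param k Multiplier on the MAD (default 3).
#' @return Tibble with `point_id`, `distance`, `flagged`.
#' @export
flag_extreme_points <- function(solution, which = c("participants", "stimuli"),
                                k = 3) {
  stopifnot(inherits(solution, "unfolding_solution"))
  which <- match.arg(which)
  pts <- if (which == "participants") solution$row_coords else solution$col_coords
  if (nrow(pts) < 5) abort("Need at least 5 points to flag outliers.")
  center <- geometric_median(pts)
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  cutoff <- median(d) + k * mad(d)
  tibble::tibble(
    point_id = rownames(pts),
    distance = unname(d),
    flagged = unname(d > cutoff)
  )
}
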