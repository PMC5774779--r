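#' Convert preference counts to dissimilarities
#'
#' Reverse-scores a preference-count matrix into the rectangular
#' dissimilarity matrix that metric unfolding consumes:
#' `delta[p, s] = K - count[p, s]`, where K is the number of times each
#' stimulus was shown to a participant (n - 1 in an all-pairs design). A
#' stimulus chosen every time it appeared gets dissimilarity 0 (the
#' participant's ideal point should sit on top of it); a stimulus never
#' chosen gets K. The linear reversal is the minimal metric transform;
#' supply `K` explicitly to use a different ceiling.
#'
#' @param x A `pref_matrix` from [preference_count_matrix()], or a
#'   nonnegative count matrix.
#' @param K Appearance ceiling; defaults to the `pref_matrix` ceiling or
#'   `max(x)` for a plain matrix. Any count above `K` is an error.
#' @return An object of class `dissimilarity_matrix`: list with `delta`
#'   (participants x stimuli) and `weights` (same shape, all 1).
#' @export
counts_to_dissimilarities <- function(x, K = NULL) {
  counts <- if (inherits(x, "pref_matrix")) x$counts else as.matrix(x)
  if (is.null(K)) {
    K <- if (inherits(x, "pref_matrix")) x$appearances else max(counts)
  }
  if (any(counts < 0)) abort("Counts must be nonnegative.")
  if (any(counts > K)) {
    abort(sprintf("Count exceeds the appearance ceiling K = %d.", K))
  }
  structure(
    list(
      delta = K - counts,
      weights = matrix(1, nrow(counts), ncol(counts),
                       dimnames = dimnames(counts))
    ),
    class = "dissimilarity_matrix"
  )
}

# participant x stimulus Euclidean distance matrix
rect_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

#' Normalized stress of an unfolding configuration
#'
#' Stress-1 for the rectangular (participant x stimulus) case:
#' `sqrt( sum(w * (delta - d)^2) / sum(w * d^2) )` where `d` are the
#' participant-stimulus distances of the configuration. The
#' normalization puts the value on the 0-1 scale (0 = perfect fit) and
#' makes it invariant to rigid motions of the joint configuration.
#'
#' @param row_coords,col_coords Coordinate matrices (participants x d,
#'   stimuli x d).
#' @param delta Rectangular dissimilarity matrix (or
#'   `dissimilarity_matrix` object).
#' @param weights Optional nonnegative weight matrix (default all 1).
#' @return The stress value.
#' @export
stress <- function(row_coords, col_coords, delta, weights = NULL) {
  if (inherits(delta, "dissimilarity_matrix")) {
    weights <- weights %||% delta$weights
    delta <- delta$delta
  }
  row_coords <- as.matrix(row_coords)
  col_coords <- as.matrix(col_coords)
  if (is.null(weights)) weights <- matrix(1, nrow(delta), ncol(delta))
  stopifnot(
    nrow(row_coords) == nrow(delta), nrow(col_coords) == ncol(delta),
    ncol(row_coords) == ncol(col_coords)
  )
  d <- rect_dist(row_coords, col_coords)
  den <- sum(weights * d^2)
  if (den == 0) abort("undefined stress: all fitted distances are zero")
  sqrt(sum(weights * (delta - d)^2) / den)
}

# Classical-scaling start: complete the square (n1+n2) dissimilarity matrix
# with the triangle-inequality-consistent average heuristic
# (within-set d(a, b) = mean over opposite-set points j of (d_aj + d_bj)/2),
# then torgerson-scale it.
classical_start <- function(delta, ndim) {
  n1 <- nrow(delta)
  n2 <- ncol(delta)
  within_rows <- (outer(rowMeans(delta), rowMeans(delta), "+")) / 2
  within_cols <- (outer(colMeans(delta), colMeans(delta), "+")) / 2
  full <- rbind(
    cbind(within_rows, delta),
    cbind(t(delta), within_cols)
  )
  diag(full) <- 0
  Z <- suppressWarnings(cmdscale(full, k = ndim))
  if (ncol(Z) < ndim) {
    Z <- cbind(Z, matrix(0, nrow(Z), ndim - ncol(Z)))
  }
  Z
}

#' Fit a metric multidimensional unfolding model
#'
#' Embeds participants (ideal points) and stimuli jointly in `ndim`
#' dimensions so that participant-stimulus distances approximate the
#' dissimilarities, by minimizing normalized stress-1 (see [stress()])
#' with alternating majorization: each iteration applies the Guttman
#' transform for the rectangular weight structure (within-set weights
#' zero) followed by the stress-optimal rescaling of the joint
#' configuration. Stress is guaranteed non-increasing across iterations
#' (asserted while fitting); iteration stops when the decrease falls
#' below `tol` or `max_iter` is reached.
#'
#' @param delta Rectangular dissimilarity matrix, or the result of
#'   [counts_to_dissimilarities()].
#' @param ndim Number of dimensions (default 2); needs at least
#'   `ndim + 1` stimuli.
#' @param max_iter Iteration cap (default 5000).
#' @param tol Stop when the per-iteration stress decrease drops below
#'   this (default 1e-6).
#' @param init `"classical"` (default) for a classical-scaling start on
#'   the completed square matrix, or `"random"` for a seeded Gaussian
#'   start.
#' @param seed Integer seed (used by the random start and recorded).
#' @param weights Optional nonnegative weight matrix.
#' @param n_starts Number of starts (default 1). With more than one, the
#'   first start uses `init` and the rest use seeded random
#'   configurations; the solution with the lowest final stress is kept.
#'   Majorization is a local method, so small or noisy problems benefit
#'   from restarts the same way other MDS fitters do.
#' @return An object of class `unfolding_solution`: list with
#'   `row_coords`, `col_coords`, `dim`, `stress`, `iterations`,
#'   `converged`, `stress_trace`, `rng_seed`, and `fitted_var_ratio`
#'   (variance of fitted distances over variance of delta; values near 0
#'   flag a degenerate solution).
#' @examples
#' delta <- matrix(c(1, 2, 3, 2, 1, 3), 2, 3, byrow = TRUE)
#' fit <- fit_unfolding(delta, ndim = 2, seed = 1)
#' fit$stress
#' @export
fit_unfolding <- function(delta, ndim = 2, max_iter = 5000, tol = 1e-6,
                          init = c("classical", "random"), seed = 1L,
                          weights = NULL, n_starts = 1) {
  init <- match.arg(init)
  seed <- check_seed(seed)
  if (n_starts > 1) {
    start_seeds <- withr::with_seed(seed,
      sample.int(.Machine$integer.max - 1L, n_starts - 1L))
    fits <- c(
      list(fit_unfolding(delta, ndim, max_iter, tol, init, seed, weights)),
      lapply(start_seeds, function(s) {
        fit_unfolding(delta, ndim, max_iter, tol, "random", s, weights)
      })
    )
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]])
  }
  if (inherits(delta, "dissimilarity_matrix")) {
    weights <- weights %||% delta$weights
    delta <- delta$delta
  }
  delta <- as.matrix(delta)
  n1 <- nrow(delta)
  n2 <- ncol(delta)
  if (ndim < 1) abort("`ndim` must be >= 1.")
  if (n2 < ndim + 1) {
    abort(sprintf("Need at least ndim + 1 = %d stimuli.", ndim + 1))
  }
  if (any(!is.finite(delta)) || any(delta < 0)) {
    abort("`delta` must be finite and nonnegative.")
  }
  if (all(delta == 0)) {
    abort("degenerate configuration: all dissimilarities are zero")
  }
  W <- weights %||% matrix(1, n1, n2)
  if (any(W < 0)) abort("`weights` must be nonnegative.")

  V <- rbind(
    cbind(diag(rowSums(W), n1), -W),
    cbind(-t(W), diag(colSums(W), n2))
  )
  Vinv <- MASS::ginv(V)

  Z <- switch(init,
    classical = classical_start(delta, ndim),
    random = withr::with_seed(seed,
      matrix(rnorm((n1 + n2) * ndim, sd = mean(delta)), n1 + n2, ndim)
    )
  )
  # a collapsed start cannot produce distances to majorize over
  if (all(rect_dist(Z[seq_len(n1), , drop = FALSE],
                    Z[-seq_len(n1), , drop = FALSE]) == 0)) {
    Z <- Z + withr::with_seed(seed, matrix(rnorm(length(Z), sd = mean(delta) / 100),
                                           nrow(Z), ndim))
  }

  sw_d2 <- sum(W * delta^2)
  rows <- seq_len(n1)
  sigma_of <- function(Z) {
    D <- rect_dist(Z[rows, , drop = FALSE], Z[-rows, , drop = FALSE])
    list(D = D, num = sum(W * (delta - D)^2), den = sum(W * D^2))
  }
  cur <- sigma_of(Z)
  sigma <- sqrt(cur$num / cur$den)
  trace <- sigma
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    D <- cur$D
    B <- W * delta / ifelse(D > 0, D, 1)
    B[D <= 0] <- 0
    Bfull <- rbind(
      cbind(diag(rowSums(B), n1), -B),
      cbind(-t(B), diag(colSums(B), n2))
    )
    Z_new <- Vinv %*% (Bfull %*% Z)
    if (any(!is.finite(Z_new))) {
      abort(sprintf("numerical error: non-finite coordinates at iteration %d", iter))
    }
    D_new <- rect_dist(Z_new[rows, , drop = FALSE], Z_new[-rows, , drop = FALSE])
    S <- sum(W * delta * D_new)
    if (S <= 0) {
      abort(sprintf("numerical error: degenerate update at iteration %d", iter))
    }
    Z <- Z_new * (sw_d2 / S)
    cur <- sigma_of(Z)
    sigma_new <- sqrt(cur$num / cur$den)
    if (sigma_new > sigma + 1e-8) {
      abort(sprintf(
        "internal error: stress increased at iteration %d (%.3e -> %.3e)",
        iter, sigma, sigma_new
      ))
    }
    trace <- c(trace, sigma_new)
    done <- (sigma - sigma_new) < tol
    sigma <- sigma_new
    if (done) {
      converged <- TRUE
      break
    }
  }

  X <- Z[rows, , drop = FALSE]
  Y <- Z[-rows, , drop = FALSE]
  rownames(X) <- rownames(delta)
  rownames(Y) <- colnames(delta)
  colnames(X) <- colnames(Y) <- paste0("dim", seq_len(ndim))
  structure(
    list(
      row_coords = X, col_coords = Y, dim = ndim,
      stress = sigma, iterations = iter, converged = converged,
      stress_trace = trace, rng_seed = seed, init = init,
      fitted_var_ratio = var(as.vector(cur$D)) / var(as.vector(delta)),
      delta = delta, weights = W
    ),
    class = "unfolding_solution"
  )
}

#' @export
print.unfolding_solution <- function(x, ...) {
  cat(sprintf(
    "<unfolding_solution> %d participants + %d stimuli in %d-D\n  stress-1 %.4f after %d iterations (%s)\n",
    nrow(x$row_coords), nrow(x$col_coords), x$dim, x$stress, x$iterations,
    if (x$converged) "converged" else "max_iter reached"
  ))
  invisible(x)
}

#' Compare unfolding fits across dimensionalities
#'
#' Fits one unfolding model per requested dimensionality under a shared
#' seed policy and tabulates the stress values, supporting the usual
#' scree-style judgment of whether added dimensions buy a substantial
#' stress reduction.
#'
#' @inheritParams fit_unfolding
#' @param dims Dimensionalities to fit (default 1:3).
#' @param ... Passed to [fit_unfolding()].
#' @return A tibble with `dim`, `stress`, `iterations`, `converged`,
#'   sorted by `dim`.
#' @export
select_dimensionality <- function(delta, dims = 1:3, ...) {
  if (length(dims) == 0) abort("`dims` must be nonempty.")
  purrr::map_dfr(sort(unique(dims)), function(d) {
    fit <- fit_unfolding(delta, ndim = d, ...)
    tibble::tibble(dim = d, stress = fit$stress,
                   iterations = fit$iterations, converged = fit$converged)
  })
}

#' Rotate a solution to the principal axes of the stimulus cloud
#'
#' Computes the principal axes of the centered stimulus coordinates and
#' applies that rotation identically to participants and stimuli, so
#' axis 1 carries the largest stimulus variance (a collinear stimulus
#' cloud maps its line onto axis 1; a fully collapsed cloud triggers a
#' warning and the identity rotation). A rigid rotation leaves
#' every distance, and hence the stress, unchanged (verified internally
#' to 1e-12). Reflections are the only remaining indeterminacy; axis
#' signs are fixed either by `orient` (a named character vector mapping
#' consecutive axes to feature levels whose stimuli should have positive
#' mean coordinate, e.g. `c(race = "white", age = "young")`, with
#' `stimuli` supplied) or, by default, so the largest loading of each
#' axis is positive.
#'
#' @param solution An `unfolding_solution`.
#' @param orient Optional named character vector `feature = level`; the
#'   i-th entry orients axis i.
#' @param stimuli Stimulus table (required with `orient`).
#' @return The rotated `unfolding_solution`.
#' @export
rotate_to_principal_axes <- function(solution, orient = NULL, stimuli = NULL) {
  stopifnot(inherits(solution, "unfolding_solution"))
  Y <- solution$col_coords
  if (nrow(Y) < 2) abort("Need at least 2 stimuli to define principal axes.")
  C <- sweep(Y, 2, colMeans(Y))
  ev <- eigen(crossprod(C) / nrow(Y), symmetric = TRUE)
  # a flat cloud (e.g. collinear stimuli) still has a well-defined leading
  # axis; only a fully collapsed cloud leaves no axis to rotate to
  if (ev$values[1] <= 1e-12 * max(1, sum(abs(C)))) {
    warn("Stimulus cloud is degenerate (zero variance); keeping the identity rotation.")
    R <- diag(solution$dim)
  } else {
    R <- ev$vectors
  }
  X2 <- solution$row_coords %*% R
  Y2 <- Y %*% R
  dimnames(X2) <- dimnames(solution$row_coords)
  dimnames(Y2) <- dimnames(Y)
  # resolve reflections
  for (k in seq_len(solution$dim)) {
    flip <- if (!is.null(orient) && k <= length(orient)) {
      if (is.null(stimuli)) abort("`orient` requires `stimuli`.")
      stimuli <- as_stimulus_table(stimuli)
      lev <- level_lookup(stimuli, names(orient)[k])[rownames(Y2)]
      mean(Y2[lev == orient[[k]], k]) < 0
    } else {
      R[which.max(abs(R[, k])), k] < 0
    }
    if (isTRUE(flip)) {
      X2[, k] <- -X2[, k]
      Y2[, k] <- -Y2[, k]
    }
  }
  new_stress <- stress(X2, Y2, solution$delta, solution$weights)
  if (abs(new_stress - solution$stress) > 1e-12 * max(1, solution$stress)) {
    abort("internal error: rotation changed the stress")
  }
  out <- solution
  out$row_coords <- X2
  out$col_coords <- Y2
  out
}
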