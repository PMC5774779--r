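# Shared fixtures and independent oracles used across test files.

# small 2x2 stimulus set: 2 exemplars per race x age cell (8 stimuli)
small_primes <- function(n_per_cell = 2) default_primes(n_per_cell)

# trial tibble for one participant choosing a fixed rule on a schedule
respond_with <- function(schedule, participant_id, choose_side) {
  schedule$participant_id <- participant_id
  schedule$response_side <- choose_side(schedule)
  schedule$latency_ms <- 700
  schedule[c("participant_id", "trial_index", "left_prime", "right_prime",
             "response_side", "latency_ms")]
}

# rule: always choose the side whose prime has `level` on `feature`
# (falls back to left when both sides match)
choose_level <- function(stimuli, feature, level) {
  lookup <- stats::setNames(as.character(stimuli[[feature]]),
                            stimuli$stimulus_id)
  function(schedule) {
    ifelse(lookup[schedule$left_prime] == level, "left",
           ifelse(lookup[schedule$right_prime] == level, "right", "left"))
  }
}

# hand-constructed unfolding_solution around given coordinates; delta is
# taken as the exact configuration distances so stress is 0
fake_solution <- function(row_coords, col_coords) {
  row_coords <- as.matrix(row_coords)
  col_coords <- as.matrix(col_coords)
  colnames(row_coords) <- colnames(col_coords) <-
    paste0("dim", seq_len(ncol(col_coords)))
  if (is.null(rownames(row_coords)))
    rownames(row_coords) <- sprintf("P%02d", seq_len(nrow(row_coords)))
  if (is.null(rownames(col_coords)))
    rownames(col_coords) <- sprintf("S%02d", seq_len(nrow(col_coords)))
  d2 <- outer(rowSums(row_coords^2), rowSums(col_coords^2), "+") -
    2 * tcrossprod(row_coords, col_coords)
  delta <- sqrt(pmax(d2, 0))
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         dim = ncol(col_coords), stress = 0, iterations = 0L,
         converged = TRUE, stress_trace = 0, rng_seed = 0L,
         init = "fixed", fitted_var_ratio = 1,
         delta = delta, weights = matrix(1, nrow(delta), ncol(delta))),
    class = "unfolding_solution"
  )
}

# random planar rotation matrix
random_rotation <- function(d, seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(rnorm(d * d), d))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

# --- independent oracles ------------------------------------------------

# normalized stress-1 evaluated from a flat parameter vector
sigma1_flat <- function(par, n1, n2, ndim, delta) {
  Z <- matrix(par, n1 + n2, ndim)
  X <- Z[seq_len(n1), , drop = FALSE]
  Y <- Z[-seq_len(n1), , drop = FALSE]
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d <- sqrt(pmax(d2, 1e-12))
  sqrt(sum((delta - d)^2) / sum(d^2))
}

# multi-start general-purpose minimizer of stress-1 (the brute-force oracle
# the majorizer is checked against)
oracle_stress <- function(delta, ndim = 2, restarts = 50, seed = 1) {
  n1 <- nrow(delta)
  n2 <- ncol(delta)
  withr::with_seed(seed, {
    vals <- replicate(restarts, {
      par0 <- rnorm((n1 + n2) * ndim, sd = max(mean(delta), 1))
      opt <- stats::optim(par0, sigma1_flat, n1 = n1, n2 = n2, ndim = ndim,
                          delta = delta, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      opt$value
    })
  })
  min(vals)
}

# Jeffreys-penalized logistic log-likelihood, maximized directly
oracle_firth <- function(x, y) {
  npll <- function(beta) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), .Machine$double.eps)
    info <- crossprod(x * sqrt(w))
    -(sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
        0.5 * determinant(info)$modulus)
  }
  opt <- stats::optim(numeric(ncol(x)), npll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, npll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt$par
}

# mean per-point error after Procrustes alignment (vegan = independent
# implementation)
procrustes_error <- function(target, fitted) {
  pro <- vegan::procrustes(as.matrix(target), as.matrix(fitted))
  mean(sqrt(rowSums((pro$Yrot - pro$X)^2)))
}
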