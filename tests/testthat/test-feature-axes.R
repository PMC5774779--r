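test_that("Firth logistic respects symmetry and handles flat designs", {
  # labels follow the sign of coordinate 1; coordinate 2 is symmetric
  # under reflection, so its coefficient must vanish
  Y <- cbind(rep(c(-1, 1), each = 4), rep(c(-1.5, -0.5, 0.5, 1.5), 2))
  y <- as.numeric(Y[, 1] > 0)
  beta <- firth_logistic(cbind(1, Y), y)
  expect_lt(abs(beta[3]), 1e-6)
  expect_gt(beta[2], 0)

  # identical coordinates carry no information: zero slope
  flat <- cbind(1, rep(2, 8))
  beta_flat <- firth_logistic(flat, rep(c(0, 1), 4))
  expect_lt(abs(beta_flat[2]), 1e-6)
})

test_that("Firth estimates stay finite under complete separation", {
  sep_battery <- list(
    cbind(1, c(-3, -2, -1, 1, 2, 3)),
    cbind(1, c(-2, -1, -0.5, 0.5, 1, 2), c(1, -1, 0, 0, 1, -1)),
    cbind(1, seq(-1, 1, length.out = 10), seq(-1, 1, length.out = 10)^2)
  )
  for (x in sep_battery) {
    y <- as.numeric(x[, 2] > 0)
    beta <- firth_logistic(x, y)
    expect_true(all(is.finite(beta)))
    expect_lt(max(abs(beta)), 50) # penalization keeps estimates bounded
  }
})

test_that("Firth coefficients match direct penalized-likelihood maximization", {
  for (s in 1:4) {
    dat <- withr::with_seed(200 + s, {
      x <- cbind(1, matrix(rnorm(16), 8, 2))
      y <- rbinom(8, 1, plogis(x[, 2]))
      list(x = x, y = y)
    })
    if (length(unique(dat$y)) < 2) next
    beta <- firth_logistic(dat$x, dat$y)
    ref <- oracle_firth(dat$x, dat$y)
    expect_equal(unname(beta), ref, tolerance = 1e-4)
  }
})

test_that("categorical axes point toward the positive level", {
  Y <- cbind(rep(c(-1, 1), each = 3), rep(c(-1, 0, 1), 2))
  rownames(Y) <- paste0("S", 1:6)
  stim <- tibble::tibble(
    stimulus_id = rownames(Y),
    race = ifelse(Y[, 1] > 0, "white", "black")
  )
  sol <- fake_solution(matrix(rnorm(8), 4, 2), Y)
  ax <- fit_categorical_axis(sol, stim, "race", "white")
  expect_equal(unname(ax$direction), c(1, 0), tolerance = 1e-6)
  expect_equal(ax$goodness, 1)

  # relabeling the focal level flips the direction exactly
  ax_b <- fit_categorical_axis(sol, stim, "race", "black")
  expect_equal(ax$direction, -ax_b$direction, tolerance = 1e-6)

  # labels independent of the coordinates separate at chance
  big <- withr::with_seed(7, {
    Yb <- matrix(rnorm(80), 40, 2)
    rownames(Yb) <- paste0("S", 1:40)
    list(Y = Yb, lab = sample(c("white", "black"), 40, TRUE))
  })
  solb <- fake_solution(matrix(rnorm(8), 4, 2), big$Y)
  stimb <- tibble::tibble(stimulus_id = rownames(big$Y), race = big$lab)
  axb <- fit_categorical_axis(solb, stimb, "race", "white")
  expect_lt(axb$goodness, 0.8)

  stim_one <- dplyr::mutate(stim, race = "white")
  expect_error(fit_categorical_axis(sol, stim_one, "race", "white"),
               "two levels")
})

test_that("continuous axes reduce to least squares", {
  Y <- withr::with_seed(11, matrix(rnorm(20), 10, 2))
  rownames(Y) <- paste0("S", 1:10)
  sol <- fake_solution(matrix(rnorm(6), 3, 2), Y)

  ax <- fit_continuous_axis(sol, setNames(Y[, 1], rownames(Y)), label = "attr")
  expect_equal(unname(ax$direction), c(1, 0), tolerance = 1e-10)
  expect_equal(ax$goodness, 1)

  # residualized values are orthogonal to the coordinates: R^2 ~ 0
  v <- withr::with_seed(12, rnorm(10))
  resid_v <- stats::resid(lm(v ~ Y))
  ax0 <- fit_continuous_axis(sol, setNames(resid_v, rownames(Y)))
  expect_lt(ax0$goodness, 1e-10)

  # closed-form normal equations oracle
  v2 <- withr::with_seed(13, rnorm(10))
  X <- cbind(1, Y)
  ref <- drop(solve(crossprod(X), crossprod(X, v2)))[-1]
  ax2 <- fit_continuous_axis(sol, setNames(v2, rownames(Y)))
  expect_equal(unname(ax2$direction), unname(ref / sqrt(sum(ref^2))),
               tolerance = 1e-10)

  expect_error(fit_continuous_axis(sol, setNames(rep(1, 10), rownames(Y))),
               "constant")
})

test_that("axis cosine is the inner product of unit directions", {
  mk <- function(d) structure(list(feature = "f", positive_level = "a",
                                   direction = d / sqrt(sum(d^2)),
                                   intercept = 0, fit_kind = "linear",
                                   goodness = 1), class = "feature_axis")
  expect_equal(axis_cosine(mk(c(1, 0)), mk(c(1, 0))), 1)
  expect_equal(axis_cosine(mk(c(1, 0)), mk(c(0, 1))), 0)
  expect_equal(axis_cosine(mk(c(1, 1)), mk(c(1, 0))), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(axis_cosine(mk(c(1, 1)), mk(c(1, 0))),
               axis_cosine(mk(c(1, 0)), mk(c(1, 1))))
})

test_that("projection scores are centered and translation-invariant", {
  sol <- fake_solution(withr::with_seed(21, matrix(rnorm(12), 6, 2)),
                       withr::with_seed(22, matrix(rnorm(10), 5, 2)))
  ax <- structure(list(feature = "f", positive_level = "a",
                       direction = c(1, 0), intercept = 0,
                       fit_kind = "linear", goodness = 1),
                  class = "feature_axis")
  # a point at the participant centroid scores 0 (symmetric cloud: the
  # fifth point sits exactly at the mean of all five)
  sym <- fake_solution(
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0, 0)),
    sol$col_coords
  )
  expect_equal(project_points(sym, ax)$score[5], 0)

  # translating the whole configuration moves the centroid with it, so
  # every projection score is unchanged
  shifted <- sol
  shifted$row_coords <- sweep(sol$row_coords, 2, c(5, -2), "+")
  shifted$col_coords <- sweep(sol$col_coords, 2, c(5, -2), "+")
  expect_equal(project_points(shifted, ax, "stimuli")$score,
               project_points(sol, ax, "stimuli")$score)
  expect_equal(project_points(shifted, ax)$score,
               project_points(sol, ax)$score)
})

test_that("axis fitting is rotation-equivariant", {
  Y <- withr::with_seed(31, matrix(rnorm(24), 12, 2))
  rownames(Y) <- paste0("S", 1:12)
  stim <- tibble::tibble(stimulus_id = rownames(Y),
                         race = ifelse(Y[, 1] + 0.3 * Y[, 2] > 0,
                                       "white", "black"))
  sol <- fake_solution(matrix(rnorm(8), 4, 2), Y)
  ax <- fit_categorical_axis(sol, stim, "race", "white")

  R <- random_rotation(2, seed = 33)
  sol_r <- fake_solution(sol$row_coords %*% R, Y %*% R)
  rownames(sol_r$col_coords) <- rownames(Y)
  ax_r <- fit_categorical_axis(sol_r, stim, "race", "white")
  expect_equal(sum((ax$direction %*% R) * ax_r$direction), 1,
               tolerance = 1e-8)
})

test_that("extreme points are flagged robustly", {
  tight <- withr::with_seed(41, matrix(rnorm(24, sd = 0.1), 12, 2))
  pts <- rbind(tight, c(5, 5))
  sol <- fake_solution(pts, matrix(rnorm(10), 5, 2))
  flags <- flag_extreme_points(sol)
  expect_equal(which(flags$flagged), 13L)

  same <- fake_solution(matrix(1, 6, 2), matrix(rnorm(10), 5, 2))
  expect_true(!any(flag_extreme_points(same)$flagged))
})

test_that("the screen flags planted far-out points at high power", {
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    pts <- withr::with_seed(1000 + s, {
      cloud <- matrix(rnorm(50), 25, 2)
      theta <- runif(2, 0, 2 * pi)
      r <- runif(2, 6, 10)
      rbind(cloud, cbind(r * cos(theta), r * sin(theta)))
    })
    sol <- fake_solution(pts, matrix(rnorm(10), 5, 2))
    flags <- flag_extreme_points(sol)
    hits <- hits + sum(flags$flagged[26:27])
    total <- total + 2L
  }
  expect_gte(hits / total, 0.9)
})

test_that("map distance from the participant cluster tracks score extremity", {
  # extreme responders drift outward in the unfolding map; the radial
  # position also carries embedding noise, so this is a rank-level
  # association, not a sharp separation
  cors <- vapply(1:6, function(s) {
    study <- make_study(population_config(n_participants = 25), seed = 810 + s)
    pm <- preference_count_matrix(study$impres, study$stimuli)
    fit <- fit_unfolding(counts_to_dissimilarities(pm), ndim = 2, seed = 1,
                         max_iter = 800)
    flags <- flag_extreme_points(fit)
    sc_r <- impres_preference_score(study$impres, study$stimuli, "race", "white")
    sc_a <- impres_preference_score(study$impres, study$stimuli, "age", "young")
    i <- match(flags$point_id, sc_r$participant_id)
    ext <- sqrt((sc_r$value[i] - 0.5)^2 + (sc_a$value[i] - 0.5)^2)
    cor(flags$distance, ext, method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.3)
  expect_true(all(cors > 0))
})
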