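test_that("adjacent distances: direct subtraction and gap handling", {
  tr <- focus_track(10, c(2.0, 7.5))
  expect_equal(adjacent_distances(tr), 5.5)
  expect_equal(adjacent_distances(focus_track(10, 3)), numeric(0))
  gapped <- focus_track(10, c(1, 3, 7), segments = cbind(c(0, 6), c(4, 10)))
  expect_equal(adjacent_distances(gapped), 2)          # 3 -> 7 spans the gap
  expect_equal(adjacent_distances(gapped, within_segments = FALSE), c(2, 4))
})

test_that("relative distances are percentages of axis length", {
  expect_equal(relative_distances(5.5, 10), 55)
  expect_equal(relative_distances(numeric(0), 10), numeric(0))
  expect_equal(relative_distances(10, 10), 100)
  expect_error(relative_distances(1, 0), "positive")
})

test_that("the shape MLE matches a grid-search profile-likelihood oracle", {
  x <- c(0.5, 1.0, 1.5, 2.0)
  # independent oracle: exhaustive log-spaced grid over the profile
  # likelihood (scale concentrated out as mean/shape)
  grid <- exp(seq(log(0.01), log(1000), length.out = 10000))
  ll <- vapply(grid, function(a)
    sum(dgamma(x, shape = a, scale = mean(x) / a, log = TRUE)), numeric(1))
  oracle <- grid[which.max(ll)]
  expect_equal(oracle, 4.263468, tolerance = 1e-6)     # frozen value
  fit <- fit_gamma_shape(x, n_bootstrap = 0)
  expect_equal(fit$shape, oracle, tolerance = 1.5e-3)  # 3 significant digits
  expect_equal(fit$scale, mean(x) / fit$shape)
  expect_gte(fit$loglik, max(ll))
})

test_that("degenerate and insufficient spacing samples are rejected", {
  expect_error(fit_gamma_shape(c(1, 1, 1, 1)), "degenerate")
  expect_error(fit_gamma_shape(2), "at least 2")
  expect_error(fit_gamma_shape(c(-1, 2)), "non-negative")
  expect_warning(f <- fit_gamma_shape(c(0, 0.5, 1, 1.5, 2), n_bootstrap = 0),
                 "zero spacing")
  expect_equal(f$n_zero_dropped, 1L)
  expect_equal(f$n_spacings, 4L)
})

test_that("the fitted shape recovers the generating shape", {
  coh <- simulate_cohort(sim_config(n_nuclei = 120, seed = 51,
                                    obligate_co = FALSE))
  d <- pooled_distances(coh)
  expect_gt(length(d), 600)
  fit <- fit_gamma_shape(d, n_bootstrap = 100, seed = 1)
  expect_lt(abs(fit$shape - 5.03) / 5.03, 0.1)
  expect_true(is.finite(fit$shape_se) && fit$shape_se > 0)
})

test_that("the shape is invariant under rescaling of the sample", {
  set.seed(52)
  d <- rgamma(300, 4, scale = 0.6)
  f_um <- fit_gamma_shape(d, n_bootstrap = 0, units = "um")
  f_pc <- fit_gamma_shape(relative_distances(d, 8.4), n_bootstrap = 0,
                          units = "percent")
  expect_equal(f_um$shape, f_pc$shape, tolerance = 1e-9)
  expect_equal(f_pc$scale, f_um$scale * 100 / 8.4, tolerance = 1e-9)
})

test_that("gamma_fit behaves like a model object", {
  set.seed(53)
  fit <- fit_gamma_shape(rgamma(200, 5, scale = 0.5), n_bootstrap = 20,
                         seed = 9)
  expect_named(coef(fit), c("shape", "scale"))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(attr(logLik(fit), "nobs"), 200)
  sims <- simulate(fit, nsim = 1000, seed = 3)
  expect_length(sims, 1000)
  expect_identical(sims, simulate(fit, nsim = 1000, seed = 3))
  expect_output(print(fit), "shape nu")
  expect_output(print(summary(fit)), "loglik")
})

test_that("CoC is 1 under independent occupancy and 0 under exclusion", {
  # occupancies {1,2}, {1}, {2}, {} over 2 intervals
  tracks <- tracks_from_occupancy(list(c(1, 2), 1, 2, integer(0)), K = 2)
  curve <- coc_curve(tracks, n_intervals = 2)
  expect_equal(curve$points$coc, 1.0)
  expect_equal(curve$interference_distance, 0)  # already at/above threshold
  # occupancies {1}, {1}, {2}, {2}: never together
  curve0 <- coc_curve(tracks_from_occupancy(list(1, 1, 2, 2), K = 2),
                      n_intervals = 2)
  expect_equal(curve0$points$coc, 0.0)
  expect_true(is.na(curve0$interference_distance))  # not reached
})

test_that("coc_curve equals the brute-force pairwise enumeration exactly", {
  fixtures <- list(
    list(occ = list(c(1, 3), 2, c(2, 4), 1, 4, c(1, 4)), K = 4),
    list(occ = list(c(1, 2, 4), c(3, 4), 1, c(1, 4)), K = 4),
    list(occ = list(1, c(2, 5), c(1, 3, 5), 4, c(2, 4), 5), K = 5))
  for (fx in fixtures) {
    tracks <- tracks_from_occupancy(fx$occ, fx$K, L = 10)
    curve <- coc_curve(tracks, n_intervals = fx$K)
    oracle <- oracle_coc(fx$occ, fx$K, mean_interval_um = 10 / fx$K)
    expect_identical(curve$points$n_pairs, oracle$points$n_pairs)
    expect_identical(curve$points$n_skipped, oracle$points$n_skipped)
    expect_equal(curve$points$distance_um, oracle$points$distance_um)
    expect_equal(curve$points$coc, oracle$points$coc)
    expect_equal(curve$interference_distance, oracle$interference_distance)
  }
})

test_that("random occupancies also match the oracle (property check)", {
  set.seed(54)
  for (i in 1:10) {
    K <- sample(3:6, 1)
    n <- sample(4:6, 1)
    occ <- lapply(seq_len(n), function(j)
      sort(sample(seq_len(K), sample(0:3, 1))))
    tracks <- tracks_from_occupancy(occ, K, L = 12)
    curve <- tryCatch(coc_curve(tracks, n_intervals = K),
                      error = function(e) e)
    oracle <- oracle_coc(occ, K, mean_interval_um = 12 / K)
    if (inherits(curve, "error")) {
      expect_equal(nrow(oracle$points), 0L)
    } else {
      expect_equal(curve$points$coc, oracle$points$coc)
      expect_equal(curve$interference_distance,
                   oracle$interference_distance)
    }
  }
})

test_that("boundary foci are assigned to the lower-index interval", {
  # a focus exactly at the midpoint boundary of 2 intervals must land in
  # interval 1: with occupancies then {1,2},{1},{2},{} the curve is exactly
  # the independence fixture
  tracks <- list(focus_track(10, c(5.0, 7)), focus_track(10, 5.0),
                 focus_track(10, 7), focus_track(10))
  curve <- coc_curve(tracks, n_intervals = 2)
  expect_equal(curve$points$coc, 1.0)
})

test_that("auto interval rule follows 5 x mean CO count, floor 2", {
  set.seed(55)
  tracks <- lapply(1:20, function(i) focus_track(10, runif(3) * 10))
  expect_equal(coc_curve(tracks)$n_intervals, 15)
  sparse <- lapply(1:20, function(i)
    focus_track(10, if (i == 1) 5 else numeric(0)))
  expect_error(coc_curve(sparse), "expected > 0")
  expect_error(coc_curve(tracks, n_intervals = 1), ">= 2")
  expect_error(coc_curve(list()), "no tracks")
})

test_that("interference_distance interpolates linearly", {
  mk <- function(d, coc) structure(
    list(points = data.frame(distance_um = d, coc = coc,
                             n_pairs = rep(1L, length(d)),
                             n_skipped = rep(0L, length(d))),
         threshold = 0.5),
    class = "coc_curve")
  expect_equal(interference_distance(mk(c(0.5, 1, 1.5), c(0.2, 0.4, 0.6))),
               1.25)
  expect_equal(interference_distance(mk(c(0.5, 1), c(0.6, 1.1))), 0)
  expect_true(is.na(interference_distance(mk(c(0.5, 1), c(0.2, 0.4)))))
  expect_error(interference_distance(mk(numeric(0), numeric(0))), "empty")
})

test_that("e_distribution tallies proportions that sum to one", {
  ed <- e_distribution(c(0, 1, 1, 2))
  expect_equal(as.numeric(ed$proportions), c(0.25, 0.5, 0.25))
  expect_named(ed$proportions, c("E0", "E1", "E2"))
  expect_equal(sum(ed$proportions), 1, tolerance = 1e-12)
  expect_equal(e_distribution(c(1, 2, 1))$proportions[["E0"]], 0)
  expect_error(e_distribution(integer(0)), "empty")
  set.seed(56)
  for (i in 1:20) {
    ed <- e_distribution(rpois(50, 2))
    expect_lt(abs(sum(ed$proportions) - 1), 1e-12)
  }
})
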