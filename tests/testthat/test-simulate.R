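# single-track statistics use the package RNG directly under a local seed
sim_counts <- function(n, L, shape, mean_spacing, seed = 42, ...) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    length(simulate_track(L, shape, mean_spacing, ...)$focus_positions),
    integer(1))
}

test_that("zero intensity and bad parameters are handled", {
  tr <- simulate_track(10, 5, Inf)
  expect_length(tr$focus_positions, 0L)
  expect_error(simulate_track(-1, 5, 2), "length")
  expect_error(simulate_track(10, 0, 2), "shape")
  expect_error(simulate_track(10, 5, 0), "mean_spacing")
  expect_error(sim_config(shape = -2), "shape")
  expect_error(sim_config(fragmentation = list(retained_fraction = 1.5)),
               "retained_fraction")
})

test_that("stationarity fixes the mean count at length/mean_spacing", {
  n <- 10000
  cnt <- sim_counts(n, L = 10, shape = 1, mean_spacing = 2.5)
  se <- sd(cnt) / sqrt(n)
  expect_lt(abs(mean(cnt) - 4), 3 * se)
  # the same holds away from the Poisson case
  cnt5 <- sim_counts(n, L = 10, shape = 5, mean_spacing = 2.5, seed = 43)
  se5 <- sd(cnt5) / sqrt(n)
  expect_lt(abs(mean(cnt5) - 4), 3 * se5)
  # regular spacing under-disperses the counts relative to Poisson
  expect_lt(var(cnt5), var(cnt))
})

test_that("shape 1 is a homogeneous Poisson process (dispersion check)", {
  cnt <- sim_counts(10000, L = 10, shape = 1, mean_spacing = 2.5, seed = 7)
  expect_gt(var(cnt) / mean(cnt), 0.9)
  expect_lt(var(cnt) / mean(cnt), 1.1)
})

test_that("the equilibrium first-arrival quantile matches its CDF", {
  p <- c(0.01, 0.25, 0.5, 0.9, 0.999)
  q <- cocount:::equilibrium_quantile(p, shape = 5, mean_spacing = 2.35)
  expect_equal(cocount:::equilibrium_cdf(q, 5, 2.35), p, tolerance = 1e-9)
  # for shape 1 the equilibrium law is the exponential itself
  q1 <- cocount:::equilibrium_quantile(p, shape = 1, mean_spacing = 2.5)
  expect_equal(q1, qexp(p, rate = 1 / 2.5), tolerance = 1e-7)
})

test_that("simulate_cohort is deterministic under its seed", {
  cfg <- sim_config(n_nuclei = 5, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(cohort_signature(a), cohort_signature(b))
  c <- simulate_cohort(sim_config(n_nuclei = 5, seed = 12))
  expect_false(identical(cohort_signature(a), cohort_signature(c)))
  expect_length(simulate_cohort(sim_config(n_nuclei = 0))$nuclei, 0L)
})

test_that("cohort mean focus count matches the analytic renewal mean", {
  cfg <- sim_config(n_nuclei = 200, seed = 21, obligate_co = FALSE,
                    length_cv = 0)
  coh <- simulate_cohort(cfg)
  counts <- vapply(coh$nuclei, `[[`, integer(1), "total_focus_count")
  expected <- sum(cfg$chromosome_lengths) / cfg$mean_spacing
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("fragment_track identity, proportional loss and feasibility", {
  tr <- focus_track(10, c(1, 3, 5, 7, 9))
  expect_identical(fragment_track(tr, 1, 1), tr)
  expect_error(fragment_track(tr, 60, 0.5), "infeasible")
  expect_error(fragment_track(focus_track(10, segments = cbind(0, 5)), 2, 0.5),
               "fully synapsed")
  # uniformly placed foci: about half survive a 50% retained fraction
  set.seed(31)
  kept <- replicate(400, {
    t0 <- focus_track(10, runif(20) * 10)
    length(fragment_track(t0, 3, 0.5)$focus_positions) / 20
  })
  expect_lt(abs(mean(kept) - 0.5), 3 * sd(kept) / sqrt(length(kept)))
})

test_that("end bias pulls segments towards chromosome ends", {
  set.seed(32)
  mid_dist <- function(end_bias) {
    replicate(1000, {
      t0 <- focus_track(10)
      fr <- fragment_track(t0, 3, 0.4, end_bias = end_bias)
      mids <- rowMeans(fr$segments)
      mean(pmin(mids, 10 - mids))
    })
  }
  d0 <- mid_dist(0)
  d_big <- mid_dist(25)
  expect_lt(mean(d_big), mean(d0))
})

test_that("fragmentation only ever deletes foci", {
  set.seed(33)
  for (i in 1:50) {
    t0 <- focus_track(8, sort(runif(10) * 8))
    fr <- fragment_track(t0, 4, 0.7, end_bias = 2)
    expect_true(all(fr$focus_positions %in% t0$focus_positions))
  }
  # ... including through the cohort path
  coh <- simulate_cohort(sim_config(n_nuclei = 10, seed = 34,
                                    fragmentation = list()))
  plain <- simulate_cohort(sim_config(n_nuclei = 10, seed = 34))
  expect_lt(sum(vapply(coh$nuclei, `[[`, integer(1), "total_focus_count")),
            sum(vapply(plain$nuclei, `[[`, integer(1), "total_focus_count")))
})

test_that("fragmented cohorts emulate the stated phenotype geometry", {
  coh <- simulate_cohort(sim_config(n_nuclei = 60, seed = 35,
                                    fragmentation = list()))
  nseg <- vapply(coh$nuclei, function(n)
    sum(vapply(n$tracks, function(t) nrow(t$segments), integer(1))),
    integer(1))
  lens <- vapply(coh$nuclei, `[[`, numeric(1), "total_sc_length")
  expect_gt(mean(nseg), 12); expect_lt(mean(nseg), 18)
  expect_gt(mean(lens) / 52.2, 0.5); expect_lt(mean(lens) / 52.2, 0.7)
})

test_that("first_spacing='gamma' is available for sensitivity checks", {
  set.seed(36)
  tr <- simulate_track(10, 5, 2.35, first_spacing = "gamma")
  expect_s3_class(tr, "focus_track")
  # non-stationary start: first arrival has mean mean_spacing, larger than
  # the equilibrium mean for shape > 1
  first_g <- sim_counts(3000, 2.0, 5, 2.35, seed = 37,
                        first_spacing = "gamma")
  first_s <- sim_counts(3000, 2.0, 5, 2.35, seed = 38)
  expect_lt(mean(first_g > 0), mean(first_s > 0))
})
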