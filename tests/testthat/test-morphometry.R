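# cohort with given per-nucleus SC lengths and focus counts
make_cohort <- function(lengths, counts, genotype = "WT") {
  nuclei <- lapply(seq_along(lengths), function(i) {
    L <- lengths[i]; k <- counts[i]
    pos <- if (k > 0) seq(L / (k + 1), L - L / (k + 1), length.out = k)
           else numeric(0)
    nucleus(list(focus_track(L, pos)), nucleus_id = sprintf("n%02d", i),
            genotype = genotype)
  })
  cohort(nuclei, genotype = genotype)
}

test_that("summarize_cohort reports mean and sample SD per nucleus", {
  coh <- make_cohort(c(10, 10, 10), c(20, 22, 24))
  s <- summarize_cohort(coh, "focus_count")
  expect_equal(s$mean, 22)
  expect_equal(s$sd, 2)
  expect_equal(s$n, 3)
  sl <- summarize_cohort(coh, "total_sc_length")
  expect_equal(sl$mean, 10); expect_equal(sl$sd, 0)
  expect_warning(s1 <- summarize_cohort(make_cohort(10, 5), "focus_count"),
                 "single observation")
  expect_equal(s1$sd, 0)
  expect_error(summarize_cohort(cohort(list(), genotype = "x"),
                                "focus_count"),
               "empty cohort")
})

test_that("summaries are permutation-invariant over nuclei", {
  coh <- make_cohort(c(8, 12, 9, 11), c(15, 25, 18, 22))
  perm <- cohort(rev(coh$nuclei))
  for (q in c("focus_count", "total_sc_length", "n_segments",
              "mean_inter_focus_distance")) {
    a <- summarize_cohort(coh, q); b <- summarize_cohort(perm, q)
    expect_equal(c(a$mean, a$sd, a$n), c(b$mean, b$sd, b$n))
  }
})

test_that("crossover density divides counts by SC length", {
  coh <- make_cohort(52.2, 22)
  d <- co_density(coh)
  expect_equal(d$mean, 22 / 52.2, tolerance = 1e-12)
  # doubling lengths at fixed counts halves the density exactly
  coh2 <- make_cohort(c(10, 20), c(4, 4))
  coh4 <- make_cohort(2 * c(10, 20), c(4, 4))
  expect_equal(co_density(coh4)$values, co_density(coh2)$values / 2)
  # a simulated cohort has density about 1/mean_spacing
  sim <- simulate_cohort(sim_config(n_nuclei = 150, seed = 61,
                                    obligate_co = FALSE))
  dd <- co_density(sim)
  expect_lt(abs(dd$mean - 1 / 2.35), 3 * dd$sd / sqrt(dd$n))
  # zero-length nuclei are rejected
  bad <- cohort(list(nucleus(list(
    structure(list(nucleus_id = "z", genotype = "WT", bivalent_rank = 1L,
                   axis_length = 5,
                   segments = matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("start", "end"))),
                   focus_positions = numeric(0)),
              class = "focus_track")), "z", "WT")), genotype = "WT")
  expect_error(co_density(bad), "zero total SC length")
})

test_that("count-on-length regression matches the normal-equations oracle", {
  coh <- make_cohort(c(1, 2, 3), c(2, 3, 5))
  fit <- regress_count_on_length(coh)
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1 / 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 40.5 / 42, tolerance = 1e-12)
  expect_equal(unname(predict(fit, 2)), 1 / 3 + 3, tolerance = 1e-12)
  # exactly collinear points
  fit2 <- regress_count_on_length(make_cohort(c(2, 4, 6, 8), c(1, 2, 3, 4)))
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_count_on_length(make_cohort(c(5, 5, 5), c(1, 2, 3))),
               "degenerate design")
  expect_error(regress_count_on_length(make_cohort(c(1, 2), c(1, 2))),
               ">= 3 nuclei")
})

test_that("regression slope is null when counts ignore length", {
  set.seed(62)
  lens <- runif(500, 40, 65)
  counts <- rpois(500, 22)
  fit <- regress_count_on_length(make_cohort(lens, counts))
  slope_se <- summary(fit$lm)$coefficients[2, 2]
  expect_lt(abs(fit$slope), 3 * slope_se)
})

test_that("adding a constant to counts shifts only the intercept", {
  lens <- c(8, 11, 9, 14, 12)
  counts <- c(3, 5, 4, 7, 5)
  f0 <- regress_count_on_length(make_cohort(lens, counts))
  f3 <- regress_count_on_length(make_cohort(lens, counts + 3))
  expect_equal(f3$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f3$intercept, f0$intercept + 3, tolerance = 1e-12)
})

test_that("two-sample test: null identity, separation, hand formula", {
  idt <- two_sample_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idt$statistic, 0)
  expect_equal(idt$p_value, 1)
  expect_lt(two_sample_test(c(1, 2, 3), c(11, 12, 13))$p_value, 0.001)
  # pooled-variance hand oracle
  ht <- two_sample_test(c(1, 2, 3, 4), c(2, 3, 4, 5), flavor = "student")
  expect_equal(ht$statistic, -sqrt(6 / 5), tolerance = 1e-12)
  expect_equal(ht$dof, 6)
  expect_error(two_sample_test(1, c(1, 2)), "n >= 2")
})

test_that("two-sample test is antisymmetric and supports Welch", {
  a <- c(5.2, 6.1, 4.9, 5.8); b <- c(7.4, 8.1, 6.9)
  ab <- two_sample_test(a, b); ba <- two_sample_test(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  w <- two_sample_test(a, b, flavor = "welch")
  expect_false(isTRUE(all.equal(w$dof, ab$dof)))
  # group summaries feed straight in
  s1 <- summarize_cohort(make_cohort(c(10, 10, 10), c(20, 22, 24)),
                         "focus_count")
  s2 <- summarize_cohort(make_cohort(c(10, 10, 10), c(30, 32, 34)),
                         "focus_count")
  expect_lt(two_sample_test(s1, s2)$p_value, 0.01)
})
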