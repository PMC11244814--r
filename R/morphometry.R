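per_nucleus_quantity <- function(nuc, quantity) {
  switch(quantity,
    focus_count = nuc$total_focus_count,
    total_sc_length = nuc$total_sc_length,
    n_segments = sum(vapply(nuc$tracks, function(t)
      nrow(t$segments), integer(1L))),
    mean_inter_focus_distance = {
      d <- unlist(lapply(nuc$tracks, adjacent_distances), use.names = FALSE)
      if (length(d)) mean(d) else NA_real_
    },
    stop("unknown quantity: ", quantity))
}

#' Per-nucleus summary of a cohort
#'
#' Computes a quantity per nucleus and reports its mean and sample SD
#' (n - 1 denominator), the "mean +/- SD" convention of cytological
#' summaries.  Nuclei for which the quantity is undefined (e.g. mean
#' inter-focus distance with fewer than two foci) are dropped from the
#' summary but counted.
#'
#' @param x a [cohort()].
#' @param quantity one of `"focus_count"`, `"total_sc_length"`,
#'   `"n_segments"`, `"mean_inter_focus_distance"`.
#' @return object of class `"group_summary"`: `genotype`, `quantity`, `n`,
#'   `mean`, `sd`, `values` (per-nucleus vector retained).
#' @export
summarize_cohort <- function(x, quantity = c("focus_count", "total_sc_length",
                                             "n_segments",
                                             "mean_inter_focus_distance")) {
  stopifnot(inherits(x, "cohort"))
  quantity <- match.arg(quantity)
  if (!length(x$nuclei)) stop("insufficient data: empty cohort")
  v <- vapply(x$nuclei, per_nucleus_quantity, numeric(1L), quantity = quantity)
  v <- v[is.finite(v)]
  if (!length(v)) stop("insufficient data: quantity undefined in every nucleus")
  if (length(v) == 1L)
    warning("single observation: SD reported as 0")
  group_summary(x$genotype, quantity, v)
}

group_summary <- function(genotype, quantity, values) {
  structure(list(genotype = genotype, quantity = quantity,
                 n = length(values), mean = mean(values),
                 sd = if (length(values) > 1L) sd(values) else 0,
                 values = as.numeric(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s [%s]: %.*f +/- %.*f (mean +/- SD, n = %d)\n",
              x$quantity, x$genotype, digits, x$mean, digits, x$sd, x$n))
  invisible(x)
}

#' @export
as.data.frame.group_summary <- function(x, ...)
  data.frame(genotype = x$genotype, quantity = x$quantity, n = x$n,
             mean = x$mean, sd = x$sd)

#' Crossover density per micron of SC
#'
#' Per-nucleus total focus count divided by total SC length, summarised as
#' a [summarize_cohort()]-style group summary.  Across diverse situations
#' the crossover density per micron of axis tends to be conserved, which
#' makes this the natural scale-free comparison between genotypes.
#'
#' @param x a [cohort()]; every nucleus must have positive SC length.
#' @return a `"group_summary"` with quantity `"co_density"`.
#' @export
co_density <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (!length(x$nuclei)) stop("insufficient data: empty cohort")
  lens <- vapply(x$nuclei, `[[`, numeric(1L), "total_sc_length")
  if (any(lens <= 0))
    stop("zero total SC length in nucleus ",
         x$nuclei[[which(lens <= 0)[1L]]]$nucleus_id)
  counts <- vapply(x$nuclei, `[[`, integer(1L), "total_focus_count")
  group_summary(x$genotype, "co_density", counts / lens)
}

#' Regression of focus count on SC length
#'
#' Ordinary least squares of per-nucleus focus count on per-nucleus total
#' SC length.  A positive slope with high R-squared reproduces the standard
#' observation that crossover number scales directly with axis/SC length;
#' genotypes can then be compared through their slopes.
#'
#' @param x a [cohort()] with at least 3 nuclei and non-constant lengths.
#' @return object of class `"regression_fit"`: `slope` (foci per micron),
#'   `intercept` (foci), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
regress_count_on_length <- function(x) {
  stopifnot(inherits(x, "cohort"))
  lens <- vapply(x$nuclei, `[[`, numeric(1L), "total_sc_length")
  counts <- vapply(x$nuclei, `[[`, integer(1L), "total_focus_count")
  if (length(lens) < 3L)
    stop("insufficient data: need >= 3 nuclei for a regression")
  if (diff(range(lens)) < 1e-12)
    stop("degenerate design: all SC lengths identical")
  fit <- lm(counts ~ lens)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # collinear fits warn
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2, n = length(lens), lm = fit,
                 genotype = x$genotype),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("foci ~ SC length [%s]: slope %.4f foci/um, intercept %.3f, R^2 = %.4f (n = %d)\n",
              x$genotype, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.regression_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
as.data.frame.regression_fit <- function(x, ...)
  data.frame(genotype = x$genotype, slope = x$slope,
             intercept = x$intercept, r_squared = x$r_squared, n = x$n)

#' @export
predict.regression_fit <- function(object, lengths, ...)
  object$intercept + object$slope * lengths

#' @export
residuals.regression_fit <- function(object, ...) residuals(object$lm)

#' @export
plot.regression_fit <- function(x, ...) {
  m <- x$lm$model
  plot(m$lens, m$counts, xlab = "total SC length (um)",
       ylab = "foci per nucleus", ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Two-sample comparison of per-nucleus quantities
#'
#' Unpaired two-tailed t test between two groups of per-nucleus values:
#' pooled-variance Student's test by default, Welch's unequal-variance
#' test behind the flag.
#'
#' @param group_a,group_b numeric vectors (or `"group_summary"` objects,
#'   whose retained per-nucleus values are used), each of length >= 2.
#' @param flavor `"student"` (pooled variance) or `"welch"`.
#' @return object of class `"two_sample_test"` with `statistic`, `dof`,
#'   `p_value`, `mean_a`, `mean_b`, `flavor`.
#' @export
two_sample_test <- function(group_a, group_b,
                            flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  if (inherits(group_a, "group_summary")) group_a <- group_a$values
  if (inherits(group_b, "group_summary")) group_b <- group_b$values
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("insufficient data: each group needs n >= 2")
  ht <- t.test(group_a, group_b, var.equal = (flavor == "student"),
               alternative = "two.sided")
  structure(list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(group_a),
                 mean_b = mean(group_b), flavor = flavor),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("two-sample t (%s): t = %.4f, df = %.2f, two-sided p = %.4g\n",
              x$flavor, x$statistic, x$dof, x$p_value))
  cat(sprintf("  means: %.4f vs %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' @export
as.data.frame.two_sample_test <- function(x, ...)
  data.frame(statistic = x$statistic, dof = x$dof, p_value = x$p_value,
             mean_a = x$mean_a, mean_b = x$mean_b, flavor = x$flavor)
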