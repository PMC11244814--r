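#' Adjacent inter-focus distances along a track
#'
#' Successive differences of the ordered focus positions, i.e. the distance
#' from the centre of each focus to the centre of the next along the axis.
#' On fragmented tracks, pairs whose two foci lie in different SC segments
#' span a synapsis gap; with `within_segments = TRUE` (the default,
#' matching measurement along SC segments) those pairs are dropped.
#'
#' @param track a [focus_track()].
#' @param within_segments drop spacings that span a gap between segments.
#' @return numeric vector of distances in microns (empty for <= 1 focus).
#' @export
adjacent_distances <- function(track, within_segments = TRUE) {
  stopifnot(inherits(track, "focus_track"))
  pos <- track$focus_positions
  if (length(pos) < 2L) return(numeric(0))
  d <- diff(pos)
  if (within_segments && nrow(track$segments) > 1L) {
    seg <- track$segments
    which_seg <- vapply(pos, function(p)
      which(p >= seg[, "start"] - 1e-9 & p <= seg[, "end"] + 1e-9)[1L],
      integer(1L))
    d <- d[which_seg[-1L] == which_seg[-length(which_seg)]]
  }
  d
}

#' Express distances as percentages of axis length
#'
#' @param distances numeric distances in microns.
#' @param axis_length axis length in microns (> 0).
#' @return `distances * 100 / axis_length`.
#' @export
relative_distances <- function(distances, axis_length) {
  if (!is.numeric(axis_length) || length(axis_length) != 1L ||
      !is.finite(axis_length) || axis_length <= 0)
    stop("axis_length must be a single positive number")
  distances * 100 / axis_length
}

#' Pool adjacent distances over a cohort
#'
#' @param x a cohort, nucleus, track or list of tracks.
#' @param units `"um"` for microns or `"percent"` for percent of each
#'   track's axis length.
#' @param within_segments see [adjacent_distances()].
#' @return pooled numeric vector of spacings.
#' @export
pooled_distances <- function(x, units = c("um", "percent"),
                             within_segments = TRUE) {
  units <- match.arg(units)
  tracks <- cohort_tracks(x)
  unlist(lapply(tracks, function(t) {
    d <- adjacent_distances(t, within_segments = within_segments)
    if (units == "percent") relative_distances(d, t$axis_length) else d
  }), use.names = FALSE)
}

# solve log(a) - digamma(a) = s by safeguarded Newton (bisection fallback);
# the profile-likelihood score equation for the gamma shape
solve_gamma_shape <- function(s, lower = 1e-2, upper = 1e3, tol = 1e-12) {
  g <- function(a) log(a) - digamma(a) - s   # strictly decreasing in a
  if (g(lower) < 0) return(structure(lower, clamped = TRUE))
  if (g(upper) > 0) return(structure(upper, clamped = TRUE))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka/Thom start
  a <- min(max(a, lower), upper)
  lo <- lower; hi <- upper
  for (i in 1:100) {
    ga <- g(a)
    if (ga > 0) lo <- a else hi <- a
    step <- ga / (1 / a - trigamma(a))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= lo || a_new >= hi) a_new <- (lo + hi) / 2
    if (abs(a_new - a) < tol * max(1, a)) { a <- a_new; break }
    a <- a_new
  }
  structure(a, clamped = FALSE)
}

#' Fit the gamma shape parameter to inter-focus spacings
#'
#' Maximum-likelihood fit of a gamma distribution to a sample of
#' inter-crossover distances.  The shape \eqn{\nu} measures crossover
#' interference: \eqn{\nu = 1} is the Poisson (no-interference) case, and
#' larger \eqn{\nu} means more even spacing.  The shape solves the profile
#' score equation \eqn{\log\nu - \psi(\nu) = \log\bar d - \overline{\log d}}
#' by safeguarded Newton iteration on the digamma equation (bisection
#' fallback), and the scale is \eqn{\bar d / \nu} at the optimum.  The
#' shape is clamped to `[1e-2, 1e3]` with a degenerate-sample warning at
#' the bounds.
#'
#' Zero distances (coincident foci), for which the gamma likelihood is
#' undefined when \eqn{\nu > 1}, are dropped with a warning and counted in
#' `n_zero_dropped`.  The uncertainty on the shape is the standard
#' deviation over seeded nonparametric bootstrap resamples; its scale
#' depends on the resampling scheme, so it is reported but should not be
#' compared against published "±" values of unstated origin.
#'
#' @param distances positive spacings, in microns or percent of axis
#'   length (`units` records which; the fitted shape is identical under
#'   any common rescaling of the sample).
#' @param n_bootstrap number of bootstrap resamples for the shape standard
#'   error (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @param units unit flag stored with the fit.
#' @return object of class `"gamma_fit"`: fields `shape`, `scale`,
#'   `n_spacings`, `loglik`, `shape_se`, `units`, `n_zero_dropped`,
#'   `clamped`.  Methods: [print()], [summary()], [coef()], [logLik()],
#'   [simulate()].
#' @examples
#' fit <- fit_gamma_shape(rgamma(500, 5, scale = 0.5), n_bootstrap = 50,
#'                        seed = 1)
#' coef(fit)
#' @export
fit_gamma_shape <- function(distances, n_bootstrap = 1000L, seed = NULL,
                            units = c("um", "percent")) {
  units <- match.arg(units)
  d <- as.numeric(distances)
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  n_zero <- sum(d == 0)
  if (n_zero) {
    warning(sprintf("dropping %d zero spacing(s): gamma likelihood undefined at 0",
                    n_zero))
    d <- d[d > 0]
  }
  if (length(d) < 2L)
    stop("need at least 2 positive distances to fit a gamma shape")
  if (diff(range(d)) < 1e-12 * mean(d))
    stop("all distances are equal: gamma shape likelihood is unbounded (degenerate sample)")

  point <- function(x) {
    s <- log(mean(x)) - mean(log(x))
    solve_gamma_shape(s)
  }
  a <- point(d)
  if (attr(a, "clamped"))
    warning("gamma shape clamped at the [0.01, 1000] bound; degenerate sample?")
  shape <- as.numeric(a)
  scale <- mean(d) / shape
  ll <- sum(dgamma(d, shape = shape, scale = scale, log = TRUE))

  se <- NA_real_
  if (n_bootstrap > 0L) {
    boots <- with_seed(if (is.null(seed)) 1L else seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        x <- sample(d, replace = TRUE)
        if (diff(range(x)) < 1e-12 * mean(x)) return(NA_real_)
        as.numeric(point(x))
      }, numeric(1L))
    })
    se <- sd(boots, na.rm = TRUE)
  }

  structure(list(shape = shape, scale = scale, n_spacings = length(d),
                 loglik = ll, shape_se = se, units = units,
                 n_zero_dropped = n_zero,
                 clamped = isTRUE(attr(a, "clamped"))),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma fit to %d inter-focus spacings (%s)\n",
              x$n_spacings, x$units))
  cat(sprintf("  shape nu = %.3f%s, scale = %.3f, mean spacing = %.3f\n",
              x$shape,
              if (is.na(x$shape_se)) "" else sprintf(" +/- %.3f (bootstrap SE)",
                                                     x$shape_se),
              x$scale, x$shape * x$scale))
  if (x$n_zero_dropped)
    cat(sprintf("  (%d zero spacing(s) dropped)\n", x$n_zero_dropped))
  invisible(x)
}

#' @export
summary.gamma_fit <- function(object, ...) {
  out <- c(shape = object$shape, shape_se = object$shape_se,
           scale = object$scale, mean = object$shape * object$scale,
           n_spacings = object$n_spacings, loglik = object$loglik)
  class(out) <- "summary.gamma_fit"
  out
}

#' @export
print.summary.gamma_fit <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' @export
coef.gamma_fit <- function(object, ...)
  c(shape = object$shape, scale = object$scale)

#' @export
logLik.gamma_fit <- function(object, ...)
  structure(object$loglik, df = 2L, nobs = object$n_spacings,
            class = "logLik")

#' @export
simulate.gamma_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  draw <- function() rgamma(nsim, shape = object$shape, scale = object$scale)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
as.data.frame.gamma_fit <- function(x, ...)
  data.frame(shape = x$shape, scale = x$scale, shape_se = x$shape_se,
             n_spacings = x$n_spacings, loglik = x$loglik, units = x$units,
             n_zero_dropped = x$n_zero_dropped)

#' Coefficient-of-coincidence curve over interval pairs
#'
#' The classic interval-based description of crossover interference.
#' Each bivalent's axis is divided into `n_intervals` equal intervals of
#' its own length (relative-position binning, so bivalents of unequal
#' length share interval identities); each focus is assigned to one
#' interval (boundary ties to the lower index).  For every interval the CO
#' frequency is the fraction of bivalents with at least one CO there, and
#' for every pair of intervals the observed double-CO frequency is
#' compared with the product of the two marginals: CoC = observed /
#' expected.  Pairs are pooled by inter-interval distance (difference of
#' interval midpoints, expressed in microns via the group mean interval
#' length); a pooled class's CoC is sum(observed) / sum(expected).  Pairs
#' with zero expected frequency are skipped and counted.
#'
#' The interference distance is the abscissa where the curve first rises
#' through `threshold` (default CoC = 0.5), by linear interpolation
#' between adjacent points; 0 if already above it at the first point, and
#' "not reached" (`NA`) if the curve never attains it.
#'
#' @param x a cohort, nucleus or list of [focus_track()]s — the bivalent
#'   group to analyse (use `ranks` to select, e.g., the two longest).
#' @param n_intervals `"auto"` (round(5 x mean CO count over the group),
#'   minimum 2 — intervals roughly 5 times finer than the CO spacing) or
#'   an integer >= 2.
#' @param ranks optional bivalent ranks defining the group (see
#'   [cohort_tracks()]).
#' @param threshold CoC level defining the interference distance.
#' @param binning `"relative"` (default, common interval count with
#'   per-bivalent interval size) or `"micron"` (fixed micron-width
#'   intervals shared across bivalents; bivalents too short for an
#'   interval are excluded from its frequencies).
#' @param smooth apply a 3-point moving average to the pooled curve before
#'   locating the interference distance (off by default).
#' @param group optional label stored on the curve.
#' @return object of class `"coc_curve"`: `points` (data frame with
#'   `distance_um`, `coc`, `n_pairs`, `n_skipped`), `n_intervals`,
#'   `interval_length_um`, `n_tracks`, `interference_distance` (`NA` =
#'   not reached), `threshold`, `group`.  Methods: [print()], [plot()],
#'   [as.data.frame()].
#' @export
coc_curve <- function(x, n_intervals = "auto", ranks = NULL, threshold = 0.5,
                      binning = c("relative", "micron"), smooth = FALSE,
                      group = NULL) {
  binning <- match.arg(binning)
  tracks <- cohort_tracks(x, ranks = ranks)
  if (!length(tracks)) stop("insufficient data: no tracks in the group")
  counts <- vapply(tracks, function(t) length(t$focus_positions), integer(1L))
  lens <- vapply(tracks, `[[`, numeric(1L), "axis_length")
  if (identical(n_intervals, "auto")) {
    n_intervals <- max(2L, as.integer(floor(5 * mean(counts) + 0.5)))
  } else {
    n_intervals <- as.integer(n_intervals)
    if (is.na(n_intervals) || n_intervals < 2L)
      stop("n_intervals must be >= 2")
  }
  K <- n_intervals
  mean_int <- mean(lens) / K

  if (binning == "relative") {
    occ <- matrix(FALSE, length(tracks), K)
    for (i in seq_along(tracks)) {
      pos <- tracks[[i]]$focus_positions
      if (!length(pos)) next
      idx <- ceiling(pos / lens[i] * K)
      idx[idx < 1L] <- 1L; idx[idx > K] <- K
      occ[i, unique(idx)] <- TRUE
    }
    eligible <- matrix(TRUE, length(tracks), K)
  } else {
    # fixed micron-width intervals; interval j = [(j-1) w, j w)
    w <- mean_int
    K <- max(2L, ceiling(max(lens) / w))
    occ <- matrix(FALSE, length(tracks), K)
    eligible <- outer(lens, (seq_len(K) - 1) * w, `>`)
    for (i in seq_along(tracks)) {
      pos <- tracks[[i]]$focus_positions
      if (!length(pos)) next
      idx <- ceiling(pos / w)
      idx[idx < 1L] <- 1L; idx[idx > K] <- K
      occ[i, unique(idx)] <- TRUE
    }
  }

  nd <- K - 1L
  obs_sum <- numeric(nd); exp_sum <- numeric(nd)
  n_pairs <- integer(nd); n_skipped <- integer(nd)
  for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
    el <- eligible[, i] & eligible[, j]
    n_el <- sum(el)
    d <- j - i
    if (n_el == 0L) { n_skipped[d] <- n_skipped[d] + 1L; next }
    fi <- sum(occ[el, i]) / n_el
    fj <- sum(occ[el, j]) / n_el
    e <- fi * fj
    if (e == 0) { n_skipped[d] <- n_skipped[d] + 1L; next }
    o <- sum(occ[el, i] & occ[el, j]) / n_el
    obs_sum[d] <- obs_sum[d] + o
    exp_sum[d] <- exp_sum[d] + e
    n_pairs[d] <- n_pairs[d] + 1L
  }
  keep <- n_pairs > 0L
  pts <- data.frame(distance_um = (seq_len(nd) * mean_int)[keep],
                    coc = (obs_sum / exp_sum)[keep],
                    n_pairs = n_pairs[keep], n_skipped = n_skipped[keep])
  if (!nrow(pts)) stop("insufficient data: no interval pair has expected > 0")
  if (smooth && nrow(pts) >= 3L) {
    sm <- pts$coc
    inner <- 2:(nrow(pts) - 1L)
    sm[inner] <- (pts$coc[inner - 1L] + pts$coc[inner] + pts$coc[inner + 1L]) / 3
    pts$coc <- sm
  }
  curve <- structure(list(points = pts, n_intervals = K,
                          interval_length_um = mean_int,
                          n_tracks = length(tracks), binning = binning,
                          threshold = threshold,
                          group = if (is.null(group)) "all" else group,
                          interference_distance = NA_real_),
                     class = "coc_curve")
  curve$interference_distance <- interference_distance(curve, threshold)
  curve
}

#' Interference distance of a CoC curve
#'
#' The inter-interval distance at which the CoC curve first rises through
#' `threshold` (default 0.5), a scalar summary of interference strength:
#' larger distances mean interference reaches further along the axis.
#'
#' @param curve a [coc_curve()].
#' @param threshold CoC level to cross (default 0.5).
#' @return distance in microns; `0` when the very first point is already at
#'   or above the threshold (no detectable interference zone at this
#'   resolution), `NA` when the curve never attains it ("not reached").
#' @export
interference_distance <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "coc_curve"))
  pts <- curve$points
  if (!nrow(pts)) stop("insufficient data: empty CoC curve")
  if (pts$coc[1L] >= threshold) return(0)
  above <- which(pts$coc >= threshold)
  if (!length(above)) return(NA_real_)   # not reached
  k <- above[1L]
  x0 <- pts$distance_um[k - 1L]; x1 <- pts$distance_um[k]
  y0 <- pts$coc[k - 1L]; y1 <- pts$coc[k]
  x0 + (threshold - y0) / (y1 - y0) * (x1 - x0)
}

#' @export
print.coc_curve <- function(x, ...) {
  id <- x$interference_distance
  cat(sprintf("CoC curve, group '%s': %d tracks, %d intervals (%s binning, mean interval %.3f um)\n",
              x$group, x$n_tracks, x$n_intervals, x$binning,
              x$interval_length_um))
  cat(sprintf("  interference distance (CoC = %g): %s\n", x$threshold,
              if (is.na(id)) "not reached" else sprintf("%.3f um", id)))
  cat(sprintf("  %d distance classes, CoC range [%.3f, %.3f]\n",
              nrow(x$points), min(x$points$coc), max(x$points$coc)))
  invisible(x)
}

#' @export
as.data.frame.coc_curve <- function(x, ...) x$points

#' @export
plot.coc_curve <- function(x, ..., add = FALSE, col = "black") {
  pts <- x$points
  if (!add) {
    plot(pts$distance_um, pts$coc, type = "n",
         xlab = "inter-interval distance (um)",
         ylab = "coefficient of coincidence",
         ylim = c(0, max(1.2, max(pts$coc))), ...)
    abline(h = 1, lty = 3, col = "grey50")
    abline(h = x$threshold, lty = 2, col = "grey30")
  }
  lines(pts$distance_um, pts$coc, col = col)
  points(pts$distance_um, pts$coc, pch = 16, cex = 0.6, col = col)
  if (!is.na(x$interference_distance))
    abline(v = x$interference_distance, lty = 2, col = col)
  invisible(x)
}

#' Distribution of focus counts per unit (E-distribution)
#'
#' Proportion of units (bivalents or SC segments) carrying exactly
#' k = 0, 1, 2, ... foci.  E0 = 0 is the signature of the obligatory
#' crossover.
#'
#' @param counts non-empty vector of non-negative integer focus counts, or
#'   a cohort (counts taken per bivalent).
#' @return object of class `"e_distribution"`: `proportions` named
#'   `E0..Ek` (summing to 1), `n_units`.
#' @export
e_distribution <- function(counts) {
  if (inherits(counts, "cohort") || inherits(counts, "nucleus"))
    counts <- vapply(cohort_tracks(counts), function(t)
      length(t$focus_positions), integer(1L))
  if (!length(counts)) stop("insufficient data: empty count list")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  k <- 0:max(counts)
  p <- as.numeric(table(factor(counts, levels = k))) / length(counts)
  structure(list(proportions = setNames(p, paste0("E", k)),
                 n_units = length(counts)),
            class = "e_distribution")
}

#' @export
print.e_distribution <- function(x, ...) {
  cat(sprintf("E-distribution over %d units:\n", x$n_units))
  print(round(x$proportions, 4))
  invisible(x)
}

#' @export
as.data.frame.e_distribution <- function(x, ...)
  data.frame(k = seq_along(x$proportions) - 1L,
             proportion = as.numeric(x$proportions),
             n_units = x$n_units)

#' @export
plot.e_distribution <- function(x, ...) {
  barplot(x$proportions, ylab = "proportion of units",
          xlab = "foci per unit", ...)
  invisible(x)
}
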