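#' Default chromosome axis lengths (microns)
#'
#' Seven descending lengths in an arithmetic-like progression summing to
#' 52.2 um, matching the wild-type total SC length per pachytene nucleus
#' that the generator emulates.
#' @export
default_chromosome_lengths <- function()
  c(10.8, 9.6, 8.4, 7.2, 6.3, 5.4, 4.5)

#' Configuration of the crossover-placement simulator
#'
#' Crossovers are placed along each bivalent as a stationary gamma renewal
#' process: inter-crossover spacings are i.i.d. gamma with shape `shape`
#' (\eqn{\nu}) and mean `mean_spacing`; the first crossover is drawn from
#' the equilibrium (length-biased residual) distribution so the process is
#' translation-stationary and free of chromosome-end edge bias.  `shape = 1`
#' is a homogeneous Poisson process (no interference); larger `shape` gives
#' more even spacing (stronger interference).
#'
#' Defaults describe a wild-type-like nucleus: 7 bivalents totalling
#' 52.2 um, mean spacing 2.35 um (so about 22 crossovers per nucleus) and
#' shape 5.03, with the obligate-crossover rule on.
#'
#' @param n_nuclei number of nuclei to simulate.
#' @param chromosome_lengths 7 positive axis lengths in microns.
#' @param shape gamma shape \eqn{\nu > 0}.
#' @param mean_spacing mean inter-crossover distance in microns (> 0);
#'   `Inf` is the zero-intensity sentinel (no crossovers).
#' @param obligate_co if `TRUE`, each bivalent's draw is rejected and
#'   repeated until it carries at least one crossover, so the spacing law is
#'   exact conditional on a non-zero count.
#' @param fragmentation `NULL` for fully synapsed bivalents, or a list with
#'   `n_segments` (mean SC segments per nucleus), `retained_fraction`
#'   (fraction of total axis length keeping an SC, in (0, 1]), `end_bias`
#'   (>= 0; larger values push segments towards chromosome ends),
#'   optionally `sd_segments` (SD of the per-nucleus segment number,
#'   default 1.9) and `min_segment` (minimum segment length in microns,
#'   default 0.1).  Emulates a fragmented-SC phenotype in which foci
#'   falling outside retained segments are lost.
#' @param noise_sd Gaussian measurement noise SD added to each position,
#'   then clipped to the focus's segment (microns, >= 0).
#' @param length_cv coefficient of variation of a per-nucleus axis-scale
#'   factor (Gaussian, truncated at 0.5): real nuclei differ in total axis
#'   length (e.g. 52.2 +/- 5.1 um, CV about 0.098, the default), and the
#'   count-versus-length regression needs that variation.  0 disables it.
#' @param first_spacing `"stationary"` (equilibrium first arrival, the
#'   default) or `"gamma"` (first spacing drawn from the gamma itself, for
#'   sensitivity checks).
#' @param genotype label attached to the simulated cohort.
#' @param seed integer seed; the same configuration and seed always yield
#'   an identical cohort.
#' @return an object of class `"sim_config"`.
#' @seealso [simulate_cohort()], [simulate_track()], [fragment_track()]
#' @export
sim_config <- function(n_nuclei = 100L,
                       chromosome_lengths = default_chromosome_lengths(),
                       shape = 5.03, mean_spacing = 2.35,
                       obligate_co = TRUE, fragmentation = NULL,
                       noise_sd = 0, length_cv = 5.1 / 52.2,
                       first_spacing = c("stationary", "gamma"),
                       genotype = "sim", seed = 1L) {
  first_spacing <- match.arg(first_spacing)
  if (length_cv < 0) stop("length_cv must be >= 0")
  if (!is.numeric(n_nuclei) || n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (!length(chromosome_lengths) || any(chromosome_lengths <= 0))
    stop("chromosome_lengths must all be positive")
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0")
  if (is.na(mean_spacing) || mean_spacing <= 0)
    stop("mean_spacing must be > 0 (Inf for zero intensity)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(fragmentation)) {
    frag_defaults <- list(n_segments = 15, retained_fraction = 0.6,
                          end_bias = 2, sd_segments = 1.9, min_segment = 0.1)
    fragmentation <- utils::modifyList(frag_defaults, fragmentation)
    if (fragmentation$retained_fraction <= 0 || fragmentation$retained_fraction > 1)
      stop("retained_fraction must be in (0, 1]")
    if (fragmentation$end_bias < 0) stop("end_bias must be >= 0")
  }
  structure(list(n_nuclei = as.integer(n_nuclei),
                 chromosome_lengths = sort(as.numeric(chromosome_lengths),
                                           decreasing = TRUE),
                 shape = shape, mean_spacing = mean_spacing,
                 obligate_co = isTRUE(obligate_co),
                 fragmentation = fragmentation, noise_sd = noise_sd,
                 length_cv = length_cv,
                 first_spacing = first_spacing,
                 genotype = as.character(genotype),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d nuclei x %d bivalents (total %.1f um), nu = %g, mean spacing %g um\n",
              x$n_nuclei, length(x$chromosome_lengths),
              sum(x$chromosome_lengths), x$shape, x$mean_spacing))
  cat(sprintf("  obligate CO: %s; fragmentation: %s; noise sd %g; seed %d\n",
              x$obligate_co,
              if (is.null(x$fragmentation)) "none" else
                sprintf("%g segments, %.0f%% retained, end bias %g",
                        x$fragmentation$n_segments,
                        100 * x$fragmentation$retained_fraction,
                        x$fragmentation$end_bias),
              x$noise_sd, x$seed))
  invisible(x)
}

# Equilibrium (stationary residual) CDF of a gamma renewal process:
# F_e(x) = x S(x) / mu + F_{shape+1}(x), with S the gamma survival.
equilibrium_cdf <- function(x, shape, mean_spacing) {
  theta <- mean_spacing / shape
  x * pgamma(x, shape, scale = theta, lower.tail = FALSE) / mean_spacing +
    pgamma(x, shape + 1, scale = theta)
}

# quantile by bisection; p may be a vector
equilibrium_quantile <- function(p, shape, mean_spacing) {
  lo <- rep(0, length(p))
  hi <- rep(mean_spacing, length(p))
  while (any(equilibrium_cdf(hi, shape, mean_spacing) < p)) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- equilibrium_cdf(mid, shape, mean_spacing) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Simulate crossover foci along one bivalent
#'
#' Draws one realisation of the stationary gamma renewal process on
#' `[0, length]`.  Uses the current RNG state; seed control belongs to
#' [simulate_cohort()].
#'
#' @param length axis length in microns.
#' @param shape gamma shape \eqn{\nu > 0}.
#' @param mean_spacing mean spacing in microns; `Inf` gives an empty track.
#' @param obligate_co reject-and-repeat until at least one focus.
#' @param first_spacing see [sim_config()].
#' @inheritParams focus_track
#' @return a [focus_track()] with one full-length segment.
#' @export
simulate_track <- function(length, shape, mean_spacing, obligate_co = FALSE,
                           first_spacing = "stationary",
                           nucleus_id = "n1", genotype = "sim",
                           bivalent_rank = NA_integer_) {
  if (!is.finite(length) || length <= 0) stop("length must be > 0")
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0")
  if (is.na(mean_spacing) || mean_spacing <= 0) stop("mean_spacing must be > 0")
  if (is.infinite(mean_spacing))
    return(focus_track(length, numeric(0), nucleus_id = nucleus_id,
                       genotype = genotype, bivalent_rank = bivalent_rank))
  theta <- mean_spacing / shape
  for (try in seq_len(100000L)) {
    x <- if (identical(first_spacing, "gamma")) rgamma(1L, shape, scale = theta)
         else equilibrium_quantile(runif(1L), shape, mean_spacing)
    pos <- numeric(0)
    while (x <= length) {
      pos <- c(pos, x)
      x <- x + rgamma(1L, shape, scale = theta)
    }
    if (!obligate_co || length(pos) >= 1L) break
  }
  if (obligate_co && !length(pos))
    stop("obligate_co: no crossover after 100000 rejections; intensity too low")
  focus_track(length, pos, nucleus_id = nucleus_id, genotype = genotype,
              bivalent_rank = bivalent_rank)
}

#' Fragment a fully synapsed track into SC segments
#'
#' Replaces the single full-length segment by `n_segments` disjoint
#' segments totalling `retained_fraction * axis_length`, placed with a
#' probability increased towards both chromosome ends according to
#' `end_bias` (0 = uniform placement).  Foci falling outside the retained
#' segments are deleted — fragmentation never creates foci.  Segment
#' lengths are symmetric-Dirichlet above a floor of `min_segment`; the free
#' (unsynapsed) length is split over the n + 1 gaps by a Dirichlet whose
#' outer-gap concentration is `1 / (1 + end_bias)`.
#'
#' @param track a fully synapsed [focus_track()] (one segment).
#' @param n_segments number of retained segments (>= 1).
#' @param retained_fraction fraction of axis length retained, in (0, 1].
#' @param end_bias non-negative weight pulling segments to the ends.
#' @param min_segment minimum segment length in microns.
#' @return a [focus_track()] with the new segments and surviving foci.
#' @export
fragment_track <- function(track, n_segments, retained_fraction,
                           end_bias = 0, min_segment = 0.1) {
  stopifnot(inherits(track, "focus_track"))
  if (nrow(track$segments) != 1L ||
      abs(segment_total_length(track) - track$axis_length) > 1e-6)
    stop("fragment_track expects a fully synapsed input track")
  if (retained_fraction <= 0 || retained_fraction > 1)
    stop("retained_fraction must be in (0, 1]")
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (end_bias < 0) stop("end_bias must be >= 0")
  L <- track$axis_length
  if (retained_fraction == 1 && n_segments == 1L) return(track)
  R <- retained_fraction * L
  if (R / n_segments < min_segment)
    stop(sprintf("infeasible fragmentation: %d segments of >= %g um cannot fit in %g um retained",
                 n_segments, min_segment, R))
  # segment lengths: floor + Dirichlet(1) remainder
  extra <- R - n_segments * min_segment
  w <- rgamma(n_segments, 1)
  seg_len <- min_segment + extra * w / sum(w)
  # gaps: Dirichlet with down-weighted outer gaps under end bias
  alpha <- rep(1, n_segments + 1L)
  alpha[c(1L, n_segments + 1L)] <- 1 / (1 + end_bias)
  g <- rgamma(n_segments + 1L, alpha)
  gaps <- (L - R) * g / sum(g)
  starts <- cumsum(c(0, seg_len)) + cumsum(gaps)[seq_len(n_segments + 1L)]
  starts <- starts[seq_len(n_segments)]
  segments <- cbind(start = starts, end = starts + seg_len)
  keep <- focus_in_segment(track$focus_positions, segments)
  focus_track(L, track$focus_positions[keep], segments,
              nucleus_id = track$nucleus_id, genotype = track$genotype,
              bivalent_rank = track$bivalent_rank)
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a cohort of nuclei
#'
#' Applies [simulate_track()] to every chromosome of every nucleus, then
#' (optionally) SC fragmentation and Gaussian position noise, determined
#' entirely by `config$seed`.
#'
#' In fragmented mode the per-nucleus segment number is drawn as
#' `round(rnorm(n_segments, sd_segments))` (floored at 1) and allocated to
#' bivalents by a multinomial with probability proportional to axis length;
#' bivalents allocated zero segments lose their SC — and hence all foci —
#' entirely.
#'
#' @param config a [sim_config()].
#' @return a [cohort()]; empty when `n_nuclei = 0`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$chromosome_lengths
  with_seed(config$seed, {
    nuclei <- lapply(seq_len(config$n_nuclei), function(i) {
      id <- sprintf("%s_nuc%04d", config$genotype, i)
      fac <- if (config$length_cv > 0)
        max(0.5, rnorm(1L, 1, config$length_cv)) else 1
      nuc_lens <- lens * fac
      tracks <- lapply(seq_along(nuc_lens), function(k)
        simulate_track(nuc_lens[k], config$shape, config$mean_spacing,
                       obligate_co = config$obligate_co,
                       first_spacing = config$first_spacing,
                       nucleus_id = id, genotype = config$genotype,
                       bivalent_rank = k))
      if (!is.null(config$fragmentation))
        tracks <- fragment_nucleus(tracks, config$fragmentation)
      if (config$noise_sd > 0)
        tracks <- lapply(tracks, jitter_track, sd = config$noise_sd)
      nucleus(tracks, nucleus_id = id, genotype = config$genotype)
    })
    cohort(nuclei, genotype = config$genotype,
           provenance = sprintf("simulate_cohort(seed = %d)", config$seed))
  })
}

fragment_nucleus <- function(tracks, frag) {
  lens <- vapply(tracks, `[[`, numeric(1L), "axis_length")
  n_total <- max(1L, as.integer(round(rnorm(1L, frag$n_segments,
                                            frag$sd_segments))))
  alloc <- as.integer(rmultinom(1L, n_total, prob = lens))
  lapply(seq_along(tracks), function(k) {
    if (alloc[k] == 0L) {
      t <- tracks[[k]]
      t$segments <- t$segments[0L, , drop = FALSE]
      t$focus_positions <- numeric(0)
      return(t)
    }
    k_seg <- alloc[k]
    # cap so the floor always fits in the retained length
    k_max <- max(1L, floor(frag$retained_fraction * lens[k] / frag$min_segment))
    fragment_track(tracks[[k]], min(k_seg, k_max), frag$retained_fraction,
                   end_bias = frag$end_bias, min_segment = frag$min_segment)
  })
}

jitter_track <- function(track, sd) {
  pos <- track$focus_positions
  if (!length(pos)) return(track)
  seg <- track$segments
  idx <- vapply(pos, function(p)
    which(p >= seg[, "start"] - 1e-9 & p <= seg[, "end"] + 1e-9)[1L],
    integer(1L))
  noisy <- pos + rnorm(length(pos), 0, sd)
  noisy <- pmin(pmax(noisy, seg[idx, "start"]), seg[idx, "end"])
  track$focus_positions <- sort(noisy)
  track
}
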