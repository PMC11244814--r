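# Independent oracles and small fixture builders, written directly from the
# definitions and kept free of the package's own computational paths.

# Brute-force CoC: explicit double loop over bivalents and interval pairs.
# occupancy: list of integer vectors (occupied interval indices, 1..K).
# Returns pooled distance classes (in interval units and microns) and the
# interference distance by linear interpolation at `threshold`.
oracle_coc <- function(occupancy, K, mean_interval_um, threshold = 0.5) {
  n <- length(occupancy)
  freq <- sapply(seq_len(K), function(i)
    sum(vapply(occupancy, function(s) i %in% s, logical(1))) / n)
  classes <- list()
  for (i in seq_len(K - 1)) for (j in seq((i + 1), K)) {
    obs <- sum(vapply(occupancy, function(s) (i %in% s) && (j %in% s),
                      logical(1))) / n
    expd <- freq[i] * freq[j]
    d <- j - i
    key <- as.character(d)
    if (is.null(classes[[key]]))
      classes[[key]] <- c(obs = 0, expd = 0, n_pairs = 0, n_skipped = 0)
    if (expd == 0) {
      classes[[key]]["n_skipped"] <- classes[[key]]["n_skipped"] + 1
    } else {
      classes[[key]]["obs"] <- classes[[key]]["obs"] + obs
      classes[[key]]["expd"] <- classes[[key]]["expd"] + expd
      classes[[key]]["n_pairs"] <- classes[[key]]["n_pairs"] + 1
    }
  }
  d <- sort(as.integer(names(classes)))
  tab <- do.call(rbind, lapply(as.character(d), function(k) classes[[k]]))
  keep <- tab[, "n_pairs"] > 0
  out <- data.frame(distance_um = d[keep] * mean_interval_um,
                    coc = (tab[, "obs"] / tab[, "expd"])[keep],
                    n_pairs = as.integer(tab[keep, "n_pairs"]),
                    n_skipped = as.integer(tab[keep, "n_skipped"]))
  id <- if (out$coc[1] >= threshold) 0 else {
    above <- which(out$coc >= threshold)
    if (!length(above)) NA_real_ else {
      k <- above[1]
      out$distance_um[k - 1] +
        (threshold - out$coc[k - 1]) / (out$coc[k] - out$coc[k - 1]) *
        (out$distance_um[k] - out$distance_um[k - 1])
    }
  }
  list(points = out, interference_distance = id)
}

# build equal-length tracks whose foci occupy given intervals (K intervals,
# one focus at each occupied interval's midpoint)
tracks_from_occupancy <- function(occupancy, K, L = 10) {
  lapply(seq_along(occupancy), function(i) {
    mids <- (occupancy[[i]] - 0.5) * L / K
    focus_track(L, mids, nucleus_id = sprintf("n%02d", i), genotype = "fix",
                bivalent_rank = 1L)
  })
}

# a small, varied cohort for round-trip property tests
random_cohort <- function(seed, fragmented = FALSE) {
  cfg <- sim_config(n_nuclei = 4, seed = seed, genotype = "rt",
                    obligate_co = FALSE,
                    fragmentation = if (fragmented)
                      list(n_segments = 10, retained_fraction = 0.6,
                           end_bias = 1) else NULL)
  simulate_cohort(cfg)
}

# flatten a cohort's numeric content for equality comparison
cohort_signature <- function(x) {
  lapply(x$nuclei, function(nuc) lapply(nuc$tracks, function(t)
    list(rank = t$bivalent_rank, L = t$axis_length,
         seg = round(t$segments, 9), pos = round(t$focus_positions, 9))))
}
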