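#' Construct a focus track (one bivalent)
#'
#' A focus track holds the measured geometry of one bivalent: its axis/SC
#' length, the synapsed segments along the axis, and the ordered positions
#' of crossover-correlated foci.  A fully synapsed bivalent has a single
#' segment spanning the whole axis; fragmented-SC phenotypes are represented
#' by several disjoint segments, and foci are only legal inside a segment.
#'
#' Positions are continuous, 0-based microns from the bivalent end chosen as
#' origin.  The origin is arbitrary per track but must be used consistently
#' for all quantities on that track.
#'
#' @param axis_length axis/SC length in microns (> 0).
#' @param focus_positions numeric vector of focus positions in microns;
#'   sorted on construction.
#' @param segments two-column matrix (start, end) of synapsed intervals in
#'   microns, non-overlapping and within `[0, axis_length]`.  Default: one
#'   segment spanning the whole axis.
#' @param nucleus_id,genotype opaque labels.
#' @param bivalent_rank integer 1..7; 1 is the longest axis in its nucleus.
#' @return an object of class `"focus_track"`.
#' @seealso [adjacent_distances()], [simulate_track()]
#' @export
focus_track <- function(axis_length, focus_positions = numeric(0),
                        segments = NULL, nucleus_id = "n1",
                        genotype = "unknown", bivalent_rank = NA_integer_) {
  if (!is.numeric(axis_length) || length(axis_length) != 1L ||
      !is.finite(axis_length) || axis_length <= 0)
    stop("axis_length must be a single positive number")
  if (is.null(segments))
    segments <- matrix(c(0, axis_length), nrow = 1L,
                       dimnames = list(NULL, c("start", "end")))
  segments <- as.matrix(segments)
  if (ncol(segments) != 2L)
    stop("segments must be a two-column (start, end) matrix")
  colnames(segments) <- c("start", "end")
  storage.mode(segments) <- "double"
  if (nrow(segments) > 1L)
    segments <- segments[order(segments[, 1L]), , drop = FALSE]
  track <- structure(
    list(nucleus_id = as.character(nucleus_id),
         genotype = as.character(genotype),
         bivalent_rank = as.integer(bivalent_rank),
         axis_length = as.numeric(axis_length),
         segments = segments,
         focus_positions = sort(as.numeric(focus_positions))),
    class = "focus_track")
  validate_focus_track(track)
  track
}

validate_focus_track <- function(track) {
  seg <- track$segments
  L <- track$axis_length
  if (nrow(seg) > 0L) {
    if (any(seg[, "end"] < seg[, "start"]))
      stop("segment end before start")
    if (any(seg < -1e-9) || any(seg > L + 1e-9))
      stop("segment outside [0, axis_length]")
    if (nrow(seg) > 1L &&
        any(seg[-1L, "start"] < seg[-nrow(seg), "end"] - 1e-9))
      stop("segments overlap")
    if (sum(seg[, "end"] - seg[, "start"]) > L + 1e-6)
      stop("sum of segment lengths exceeds axis_length")
  }
  pos <- track$focus_positions
  if (length(pos)) {
    if (any(!is.finite(pos)))
      stop("non-finite focus position")
    if (any(pos < 0) || any(pos > L))
      stop(sprintf("focus position outside [0, %g]", L))
    if (!all(focus_in_segment(pos, seg)))
      stop("focus position outside every segment")
  }
  invisible(track)
}

# which positions fall inside some (closed) segment
focus_in_segment <- function(pos, segments) {
  if (nrow(segments) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p)
    any(p >= segments[, "start"] - 1e-9 & p <= segments[, "end"] + 1e-9),
    logical(1L))
}

segment_total_length <- function(track)
  if (nrow(track$segments)) sum(track$segments[, "end"] - track$segments[, "start"]) else 0

#' @export
print.focus_track <- function(x, ...) {
  cat(sprintf("<focus_track> %s/%s rank %s: axis %.2f um, %d segment(s), %d focus(i)\n",
              x$genotype, x$nucleus_id,
              ifelse(is.na(x$bivalent_rank), "?", x$bivalent_rank),
              x$axis_length, nrow(x$segments), length(x$focus_positions)))
  invisible(x)
}

#' Construct a nucleus (a set of bivalent tracks)
#'
#' @param tracks list of [focus_track()] objects (at most 7).  Bivalent
#'   ranks are recomputed from descending axis length when absent.
#' @param nucleus_id,genotype opaque labels; tracks are relabelled to match.
#' @return an object of class `"nucleus"` with derived fields
#'   `total_sc_length` (sum of segment lengths) and `total_focus_count`.
#' @export
nucleus <- function(tracks, nucleus_id = "n1", genotype = "unknown") {
  if (!length(tracks)) stop("a nucleus needs at least one track")
  if (length(tracks) > 7L) stop("at most 7 bivalents per nucleus")
  lens <- vapply(tracks, function(t) t$axis_length, numeric(1L))
  ranks <- vapply(tracks, function(t) t$bivalent_rank, integer(1L))
  if (anyNA(ranks) || anyDuplicated(ranks))
    ranks <- as.integer(rank(-lens, ties.method = "first"))
  ord <- order(ranks)
  tracks <- tracks[ord]; ranks <- ranks[ord]
  for (i in seq_along(tracks)) {
    tracks[[i]]$bivalent_rank <- ranks[i]
    tracks[[i]]$nucleus_id <- as.character(nucleus_id)
    tracks[[i]]$genotype <- as.character(genotype)
  }
  structure(
    list(nucleus_id = as.character(nucleus_id),
         genotype = as.character(genotype),
         tracks = tracks,
         total_sc_length = sum(vapply(tracks, segment_total_length, numeric(1L))),
         total_focus_count = sum(vapply(tracks, function(t)
           length(t$focus_positions), integer(1L)))),
    class = "nucleus")
}

#' @export
print.nucleus <- function(x, ...) {
  cat(sprintf("<nucleus> %s/%s: %d bivalents, SC total %.2f um, %d foci\n",
              x$genotype, x$nucleus_id, length(x$tracks),
              x$total_sc_length, x$total_focus_count))
  invisible(x)
}

#' Construct a cohort (all nuclei of one genotype)
#'
#' @param nuclei non-empty list of [nucleus()] objects sharing one genotype.
#' @param genotype genotype label; defaults to the nuclei's common label.
#' @param provenance free-text note on the data source.
#' @return an object of class `"cohort"`.
#' @export
cohort <- function(nuclei, genotype = NULL, provenance = "constructed in R") {
  genos <- unique(vapply(nuclei, function(n) n$genotype, character(1L)))
  if (is.null(genotype)) {
    if (length(nuclei) == 0L) stop("empty cohort needs an explicit genotype")
    if (length(genos) > 1L)
      stop("nuclei carry more than one genotype label: ",
           paste(genos, collapse = ", "))
    genotype <- genos
  } else if (length(genos) && !all(genos == genotype)) {
    stop("nuclei genotype labels disagree with the cohort genotype")
  }
  structure(list(genotype = as.character(genotype), nuclei = nuclei,
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nfoc <- sum(vapply(x$nuclei, function(n) n$total_focus_count, integer(1L)))
  cat(sprintf("<cohort> genotype %s: %d nuclei, %d foci (%s)\n",
              x$genotype, length(x$nuclei), nfoc, x$provenance))
  invisible(x)
}

#' Flatten a cohort to its tracks
#'
#' @param x a `cohort` (or a `nucleus`, or already a list of tracks).
#' @param ranks optional integer vector of bivalent ranks to keep (e.g.
#'   `1:2` for the two longest bivalents, `3:7` for the rest).
#' @return list of `focus_track` objects.
#' @export
cohort_tracks <- function(x, ranks = NULL) {
  tracks <-
    if (inherits(x, "cohort")) unlist(lapply(x$nuclei, `[[`, "tracks"),
                                      recursive = FALSE)
    else if (inherits(x, "nucleus")) x$tracks
    else if (inherits(x, "focus_track")) list(x)
    else x
  if (!all(vapply(tracks, inherits, logical(1L), "focus_track")))
    stop("x must be a cohort, nucleus, focus_track or list of focus_track")
  if (!is.null(ranks))
    tracks <- Filter(function(t) !is.na(t$bivalent_rank) &&
                       t$bivalent_rank %in% ranks, tracks)
  tracks
}
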