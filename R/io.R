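FOCUS_TABLE_COLUMNS <- c("nucleus_id", "genotype", "bivalent_rank",
                         "axis_length_um", "segment_start_um",
                         "segment_end_um", "focus_position_um")

# normalise decimal commas ("2,5" -> 2.5) and parse; NA for empty cells
parse_decimal <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  comma <- !is.na(x) & grepl("^-?[0-9]+,[0-9]+$", x)
  x[comma] <- sub(",", ".", x[comma], fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a focus-position table into a cohort
#'
#' The expected file is delimited text with one row per focus (or one
#' sentinel row with an empty `focus_position_um` cell for a focus-free
#' segment) and header columns `nucleus_id, genotype, bivalent_rank,
#' axis_length_um, segment_start_um, segment_end_um, focus_position_um`.
#' Decimal commas are accepted and normalised on read.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect list with optional entries `sep` (default: sniffed from
#'   the header among `,`, tab and `;`) and `quote`.
#' @return a validated [cohort()] (possibly with zero nuclei); one cohort
#'   per file, so all rows must share one genotype label.
#' @export
read_focus_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- dialect$sep
  if (is.null(sep)) {
    cands <- c(",", "\t", ";")
    hits <- vapply(cands, function(s)
      length(strsplit(header, s, fixed = TRUE)[[1L]]), integer(1L))
    sep <- cands[which.max(hits)]
  }
  raw <- read.table(path, header = TRUE, sep = sep,
                    quote = if (is.null(dialect$quote)) "\"" else dialect$quote,
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(FOCUS_TABLE_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("focus table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L)
    return(cohort(list(), genotype = "empty", provenance = path))

  num <- lapply(raw[c("bivalent_rank", "axis_length_um", "segment_start_um",
                      "segment_end_um", "focus_position_um")], parse_decimal)
  row_id <- seq_len(nrow(raw)) + 1L   # file line numbers (header = 1)

  bad_len <- which(!is.finite(num$axis_length_um) | num$axis_length_um <= 0)
  if (length(bad_len))
    stop("non-positive or missing axis_length_um at file line ",
         row_id[bad_len[1L]])
  neg <- which(num$segment_start_um < 0 | num$segment_end_um < num$segment_start_um)
  if (length(neg))
    stop("negative segment coordinates or negative segment length at file line ",
         row_id[neg[1L]])
  orphan <- which(!is.na(num$focus_position_um) & is.na(num$segment_start_um))
  if (length(orphan))
    stop("focus without a segment at file line ", row_id[orphan[1L]])
  out_seg <- which(!is.na(num$focus_position_um) &
                     (num$focus_position_um < num$segment_start_um |
                        num$focus_position_um > num$segment_end_um))
  if (length(out_seg))
    stop(sprintf("focus_position_um outside its segment at file line %d (position %g not in [%g, %g])",
                 row_id[out_seg[1L]], num$focus_position_um[out_seg[1L]],
                 num$segment_start_um[out_seg[1L]], num$segment_end_um[out_seg[1L]]))

  geno <- unique(raw$genotype)
  if (length(geno) != 1L)
    stop("one cohort per file: found genotypes ", paste(geno, collapse = ", "))

  nuclei <- lapply(split(seq_len(nrow(raw)), raw$nucleus_id), function(ix) {
    # a track is identified by its axis: nucleus x axis_length x rank
    key <- paste(num$axis_length_um[ix], raw$bivalent_rank[ix])
    tracks <- lapply(split(ix, key), function(jx) {
      segs <- unique(cbind(start = num$segment_start_um[jx],
                           end = num$segment_end_um[jx]))
      segs <- segs[!is.na(segs[, "start"]), , drop = FALSE]  # unsynapsed sentinel
      pos <- num$focus_position_um[jx]
      focus_track(axis_length = num$axis_length_um[jx[1L]],
                  focus_positions = pos[!is.na(pos)],
                  segments = segs,
                  nucleus_id = raw$nucleus_id[jx[1L]],
                  genotype = geno,
                  bivalent_rank = as.integer(num$bivalent_rank[jx[1L]]))
    })
    nucleus(unname(tracks), nucleus_id = raw$nucleus_id[ix[1L]],
            genotype = geno)
  })
  # keep stable nucleus order as first seen in the file
  first_seen <- vapply(split(seq_len(nrow(raw)), raw$nucleus_id), min, integer(1L))
  nuclei <- nuclei[order(first_seen)]
  cohort(unname(nuclei), genotype = geno, provenance = path)
}

#' Write a cohort as a focus-position table
#'
#' Inverse of [read_focus_table()]: one row per focus, plus a sentinel row
#' (empty focus cell) for every focus-free segment.  Numbers are printed
#' with 15 significant digits so a read/write round trip is lossless.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_focus_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  rows <- list(paste(FOCUS_TABLE_COLUMNS, collapse = sep))
  fmt <- function(v) sprintf("%.15g", v)
  for (nuc in x$nuclei) for (tr in nuc$tracks) {
    seg <- tr$segments
    if (nrow(seg) == 0L) {
      # fully unsynapsed bivalent: sentinel row with empty segment and focus
      rows <- c(rows, paste(nuc$nucleus_id, x$genotype, tr$bivalent_rank,
                            fmt(tr$axis_length), "", "", "", sep = sep))
      next
    }
    for (s in seq_len(nrow(seg))) {
      inside <- tr$focus_positions[
        tr$focus_positions >= seg[s, "start"] - 1e-9 &
          tr$focus_positions <= seg[s, "end"] + 1e-9]
      cells <- function(p) paste(nuc$nucleus_id, x$genotype, tr$bivalent_rank,
                                 fmt(tr$axis_length), fmt(seg[s, "start"]),
                                 fmt(seg[s, "end"]), p, sep = sep)
      if (length(inside))
        rows <- c(rows, lapply(fmt(inside), cells))
      else
        rows <- c(rows, cells(""))
    }
  }
  writeLines(unlist(rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Serialises any of the package's result objects (gamma fits, CoC curves,
#' E-distributions, group summaries, regression fits, or plain data frames)
#' either as a flat CSV at full precision or as nested JSON.  Re-reading a
#' CSV with [read_results()] reproduces every numeric field to at least 15
#' significant digits.
#'
#' @param results a result object with an [as.data.frame()] method, or any
#'   list for the JSON path.
#' @param path output file; its directory must exist.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("cannot write results: directory does not exist: ", dirname(path))
  if (format == "json") {
    jsonlite::write_json(strip_classes(results), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(path))
  }
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# jsonlite serialises unclassed lists most predictably
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else if (is.matrix(x)) as.data.frame(x) else unclass(x)
}

#' Re-read a CSV written by [write_results()]
#'
#' @param path file path.
#' @return data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", quote = "\"",
                   colClasses = "character", check.names = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    blank <- is.na(df[[j]]) | trimws(df[[j]]) == ""
    if (!any(is.na(v) & !blank)) df[[j]] <- v
  }
  df
}
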