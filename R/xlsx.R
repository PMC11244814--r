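# Minimal xlsx support.  No installed R package reads or writes xlsx in
# this stack, so ingestion parses the OOXML container directly
# (utils::unzip + xml2) and the fixture writer emits a stored
# (uncompressed) zip.  Only the features supplementary workbooks need are
# covered: one table per worksheet, numeric body, string header, shared or
# inline strings.

#' Read figure-panel tables from a supplementary xlsx workbook
#'
#' Published supplementary workbooks typically carry one worksheet per
#' figure panel with a header row and numeric columns.  This reader returns
#' the raw numeric tables untransformed; converting a table into a
#' [cohort()] is the caller's job via an explicit column mapping, because
#' workbook layouts are not standardised (a worksheet may hold raw per-focus
#' positions, per-pair distances, or only per-panel summary values).
#'
#' @param path path to an `.xlsx` file.
#' @param sheet_map optional named character vector or list mapping panel
#'   labels to worksheet names, e.g. `c("Fig 2I" = "Fig 2I")`.  `NULL` reads
#'   every worksheet, keyed by its own name.
#' @return named list of data frames; header row becomes column names,
#'   remaining cells must be numeric (decimal commas tolerated) or empty.
#' @export
read_supplementary_workbook <- function(path, sheet_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  exdir <- tempfile("xlsx")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)

  wb <- xml2::read_xml(file.path(exdir, "xl", "workbook.xml"))
  xml2::xml_ns_strip(wb)
  sheet_nodes <- xml2::xml_find_all(wb, ".//sheet")
  sheet_names <- xml2::xml_attr(sheet_nodes, "name")
  rids <- xml2::xml_attr(sheet_nodes, "id")   # r:id survives ns stripping

  rels <- xml2::read_xml(file.path(exdir, "xl", "_rels", "workbook.xml.rels"))
  xml2::xml_ns_strip(rels)
  rel_nodes <- xml2::xml_find_all(rels, ".//Relationship")
  targets <- setNames(xml2::xml_attr(rel_nodes, "Target"),
                      xml2::xml_attr(rel_nodes, "Id"))

  shared <- character(0)
  ss_path <- file.path(exdir, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::read_xml(ss_path)
    xml2::xml_ns_strip(ss)
    shared <- vapply(xml2::xml_find_all(ss, ".//si"), function(si)
      paste(xml2::xml_text(xml2::xml_find_all(si, ".//t")), collapse = ""),
      character(1L))
  }

  if (is.null(sheet_map)) sheet_map <- setNames(sheet_names, sheet_names)
  sheet_map <- unlist(sheet_map)

  out <- lapply(seq_along(sheet_map), function(k) {
    want <- sheet_map[[k]]
    hit <- match(want, sheet_names)
    if (is.na(hit))
      stop(sprintf("worksheet '%s' not found; available sheets: %s",
                   want, paste(sheet_names, collapse = ", ")))
    target <- targets[[rids[hit]]]
    target <- sub("^/", "", target)
    sheet_file <- if (startsWith(target, "xl/")) file.path(exdir, target)
                  else file.path(exdir, "xl", target)
    parse_worksheet(sheet_file, shared, want)
  })
  names(out) <- names(sheet_map)
  out
}

parse_worksheet <- function(sheet_file, shared, sheet_name) {
  xs <- xml2::read_xml(sheet_file)
  xml2::xml_ns_strip(xs)
  cells <- xml2::xml_find_all(xs, ".//sheetData/row/c")
  if (!length(cells)) return(data.frame())
  ref <- xml2::xml_attr(cells, "r")
  type <- xml2::xml_attr(cells, "t")
  val <- vapply(cells, function(c) {
    v <- xml2::xml_find_first(c, "./v")
    if (!inherits(v, "xml_missing")) return(xml2::xml_text(v))
    t_in <- xml2::xml_find_first(c, "./is")
    if (!inherits(t_in, "xml_missing")) return(xml2::xml_text(t_in))
    NA_character_
  }, character(1L))

  col <- cell_col(ref); row <- cell_row(ref)
  txt <- ifelse(!is.na(type) & type == "s",
                shared[as.integer(val) + 1L], val)

  ncol <- max(col); nrow <- max(row)
  grid <- matrix(NA_character_, nrow, ncol)
  grid[cbind(row, col)] <- txt

  header <- grid[1L, ]
  header[is.na(header) | header == ""] <-
    paste0("V", which(is.na(header) | header == ""))
  body <- grid[-1L, , drop = FALSE]
  df <- as.data.frame(matrix(NA_real_, nrow(body), ncol))
  names(df) <- header
  for (j in seq_len(ncol)) {
    v <- parse_decimal(body[, j])
    bad <- which(is.na(v) & !is.na(body[, j]) & trimws(body[, j]) != "")
    if (length(bad))
      stop(sprintf("non-numeric cell %s%d ('%s') in worksheet '%s'",
                   col_letters(j), bad[1L] + 1L, body[bad[1L], j], sheet_name))
    df[[j]] <- v
  }
  df
}

cell_col <- function(ref) {
  letters_part <- gsub("[0-9]", "", ref)
  vapply(strsplit(letters_part, ""), function(ch)
    sum((match(ch, LETTERS)) * 26^(rev(seq_along(ch)) - 1L)), numeric(1L))
}
cell_row <- function(ref) as.integer(gsub("[A-Z]", "", ref))
col_letters <- function(j) {
  out <- ""
  while (j > 0L) { r <- (j - 1L) %% 26L; out <- paste0(LETTERS[r + 1L], out)
                   j <- (j - 1L) %/% 26L }
  out
}

#' Write a minimal synthetic xlsx workbook (test fixture)
#'
#' Emits just enough of the OOXML spreadsheet format for
#' [read_supplementary_workbook()] (and mainstream readers) to ingest:
#' one worksheet per table, inline strings for the header row, numbers at
#' full precision, stored (uncompressed) zip entries.  Intended for building
#' synthetic stand-ins for supplementary workbooks in tests and examples —
#' not a general spreadsheet writer.
#'
#' @param tables named list of data frames / matrices with numeric bodies.
#' @param path output `.xlsx` path.
#' @export
write_workbook_fixture <- function(tables, path) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  n <- length(tables)
  sheets_xml <- paste0(vapply(seq_len(n), function(i) sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    esc(names(tables)[i]), i, i), character(1L)), collapse = "")
  files <- list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      paste0(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                     seq_len(n)), collapse = ""),
      '</Types>'),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      '<sheets>', sheets_xml, '</sheets></workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      paste0(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                     seq_len(n), seq_len(n)), collapse = ""),
      '</Relationships>'))
  for (i in seq_len(n)) {
    tab <- as.data.frame(tables[[i]])
    rows <- character(nrow(tab) + 1L)
    hdr <- vapply(seq_along(tab), function(j) sprintf(
      '<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
      col_letters(j), esc(names(tab)[j])), character(1L))
    rows[1L] <- sprintf('<row r="1">%s</row>', paste0(hdr, collapse = ""))
    for (r in seq_len(nrow(tab))) {
      cs <- vapply(seq_along(tab), function(j) {
        v <- tab[r, j]
        if (is.na(v)) "" else sprintf('<c r="%s%d"><v>%.15g</v></c>',
                                      col_letters(j), r + 1L, as.numeric(v))
      }, character(1L))
      rows[r + 1L] <- sprintf('<row r="%d">%s</row>', r + 1L,
                              paste0(cs[cs != ""], collapse = ""))
    }
    files[[sprintf("xl/worksheets/sheet%d.xml", i)]] <- paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
      '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')
  }
  zip_store(files, path)
  invisible(path)
}

# ---- stored zip container ------------------------------------------------

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- numeric(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8)
        c <- if (c %% 2) xor32(3988292384, floor(c / 2)) else floor(c / 2)
      t[i + 1] <- c
    }
    tab <<- t
    tab
  }
})

# bitwise xor of two doubles < 2^32, via 16-bit halves
xor32 <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  for (b in as.integer(bytes))
    crc <- xor32(floor(crc / 256), tab[(bitwXor(as.integer(crc %% 256), b)) + 1])
  xor32(crc, 4294967295)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  c(u16(x %% 65536), u16(x %/% 65536))
}

zip_store <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  central <- raw(0)
  pos <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- charToRaw(enc2utf8(files[[i]]))
    crc <- crc32(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0),
                   u16(0), u16(0), u16(0), u32(crc), u32(length(data)),
                   u32(length(data)), u16(length(name)), u16(0))
    writeBin(c(local_hdr, name, data), con)
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20),
                 u16(0), u16(0), u16(0), u16(0), u32(crc),
                 u32(length(data)), u32(length(data)), u16(length(name)),
                 u16(0), u16(0), u16(0), u16(0), u32(0), u32(pos), name)
    offsets[i] <- pos
    pos <- pos + length(local_hdr) + length(name) + length(data)
  }
  writeBin(central, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
             u16(length(files)), u16(length(files)), u32(length(central)),
             u32(pos), u16(0)), con)
  invisible(path)
}
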