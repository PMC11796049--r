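# Readers: parse vendor-dialect instrument files into a uniform
# raw_file_model of ordered headers plus named numeric tables.

#' Raw numeric table parsed from an instrument file
#'
#' @param name Table name as it appears in the file.
#' @param columns Data frame with character columns `label` and `unit`
#'   (unit may be `""`).
#' @param rows Numeric matrix with one column per table column.
#' @return An object of class `raw_table`.
#' @export
raw_table <- function(name, columns, rows) {
  stopifnot(is.character(name), is.data.frame(columns))
  vf_assert(nrow(columns) >= 1, "vf_parse_error", "a table needs at least one column")
  rows <- as.matrix(rows)
  if (length(rows) == 0) rows <- matrix(numeric(0), ncol = nrow(columns))
  vf_assert(ncol(rows) == nrow(columns), "vf_parse_error",
            sprintf("table '%s': %d columns declared but rows have %d cells",
                    name, nrow(columns), ncol(rows)))
  vf_assert(all(is.finite(rows)), "vf_parse_error",
            sprintf("table '%s' contains non-finite cells", name))
  structure(list(name = name, columns = columns, rows = rows),
            class = "raw_table")
}

#' Uniform model of one parsed instrument file
#'
#' Header keys preserve file order and duplicates; [header_value()] returns
#' the first occurrence.
#'
#' @param source_name Original file name.
#' @param header Data frame with character columns `key`, `value`.
#' @param tables List of [raw_table()] objects.
#' @param dialect_id Identifier of the dialect the file was parsed with.
#' @return An object of class `raw_file_model`.
#' @export
raw_file_model <- function(source_name, header, tables, dialect_id) {
  stopifnot(is.data.frame(header), all(c("key", "value") %in% names(header)))
  structure(list(source_name = source_name,
                 header = header[, c("key", "value")],
                 tables = tables,
                 dialect_id = dialect_id),
            class = "raw_file_model")
}

#' Look up a header value (first occurrence)
#'
#' @param raw A [raw_file_model()].
#' @param key Header key.
#' @return The first matching value, or `NA_character_`.
#' @export
header_value <- function(raw, key) {
  i <- match(key, raw$header$key)
  if (is.na(i)) NA_character_ else raw$header$value[i]
}

#' @export
print.raw_file_model <- function(x, ...) {
  cat(sprintf("<raw_file_model> %s [%s]\n", x$source_name, x$dialect_id))
  cat(sprintf("  header: %d entries; tables: %d (%s)\n",
              nrow(x$header), length(x$tables),
              paste(vapply(x$tables, function(t) {
                sprintf("%s %dx%d", t$name, nrow(t$rows), ncol(t$rows))
              }, character(1)), collapse = ", ")))
  invisible(x)
}

parse_gamry_row <- function(line, lineno, ncols, table_name) {
  cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(cells) > 0 && cells[1] == "") cells <- cells[-1]
  if (length(cells) != ncols) {
    vf_error("vf_parse_error",
             sprintf("line %d: table '%s' row has %d cells, expected %d",
                     lineno, table_name, length(cells), ncols),
             line = lineno)
  }
  vals <- parse_numeric_cell(cells)
  if (anyNA(vals)) {
    vf_error("vf_parse_error",
             sprintf("line %d: non-numeric cell in table '%s'", lineno, table_name),
             line = lineno)
  }
  vals
}

#' Read a Gamry-style tagged text (DTA) file
#'
#' Line-oriented dialect: header lines `KEY<TAB>TYPE<TAB>VALUE`; a table
#' starts at `CURVE<TAB>TABLE<TAB><nrows>`, followed by one column-label
#' line, one unit line, and `<nrows>` tab-separated numeric rows.
#'
#' @param path Path to the file.
#' @return A [raw_file_model()] with `dialect_id = "gamry-dta"`.
#' @export
read_gamry_dta <- function(path) {
  vf_assert(file.exists(path), "vf_parse_error", sprintf("file not found: %s", path))
  lines <- read_text_lines(path)
  vf_assert(length(lines) > 0 && any(nzchar(trimws(lines))), "vf_parse_error",
            sprintf("empty file: %s", path))

  hdr_key <- character(0); hdr_val <- character(0)
  tables <- list()
  n_curve <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (!nzchar(trimws(line))) { i <- i + 1L; next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 3 && fields[1] == "CURVE" && fields[2] == "TABLE") {
      nrows <- suppressWarnings(as.integer(fields[3]))
      vf_assert(!is.na(nrows) && nrows >= 0, "vf_parse_error",
                sprintf("line %d: bad CURVE row count '%s'", i, fields[3]))
      vf_assert(i + 2L <= n, "vf_parse_error",
                sprintf("line %d: CURVE table truncated before column labels", i))
      labs <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
      if (length(labs) > 0 && labs[1] == "") labs <- labs[-1]
      units <- strsplit(lines[i + 2L], "\t", fixed = TRUE)[[1]]
      if (length(units) > 0 && units[1] == "") units <- units[-1]
      length(units) <- length(labs)
      units[is.na(units)] <- ""
      vf_assert(length(labs) >= 1, "vf_parse_error",
                sprintf("line %d: CURVE table has no columns", i + 1L))
      vf_assert(i + 2L + nrows <= n, "vf_parse_error",
                sprintf("line %d: CURVE table declares %d rows but file ends early",
                        i, nrows))
      rows <- matrix(numeric(0), ncol = length(labs))
      if (nrows > 0) {
        rows <- t(vapply(seq_len(nrows), function(k) {
          parse_gamry_row(lines[i + 2L + k], i + 2L + k, length(labs),
                          paste0("CURVE", n_curve + 1L))
        }, numeric(length(labs))))
      }
      n_curve <- n_curve + 1L
      tables[[n_curve]] <- raw_table(
        name = paste0("CURVE", n_curve),
        columns = data.frame(label = labs, unit = units, stringsAsFactors = FALSE),
        rows = rows
      )
      i <- i + 3L + nrows
    } else {
      key <- fields[1]
      val <- if (length(fields) >= 3) paste(fields[-(1:2)], collapse = "\t") else ""
      hdr_key <- c(hdr_key, key)
      hdr_val <- c(hdr_val, val)
      i <- i + 1L
    }
  }
  raw_file_model(basename(path),
                 data.frame(key = hdr_key, value = hdr_val, stringsAsFactors = FALSE),
                 tables, "gamry-dta")
}

sniff_delimiter <- function(line) {
  counts <- vapply(c(",", ";", "\t"), function(d) {
    length(strsplit(line, d, fixed = TRUE)[[1]])
  }, integer(1))
  names(counts)[which.max(counts)]
}

#' Read a PalmSens-style CSV export
#'
#' Dialect: leading `key: value` metadata lines, a blank line, then one
#' delimited table whose delimiter is sniffed from `","`, `";"` or tab.
#' Column headers of the form `label/unit` carry the unit; a decimal comma
#' is accepted when the delimiter is `";"`.
#'
#' @param path Path to the file.
#' @return A [raw_file_model()] with `dialect_id = "palmsens-csv"`.
#' @export
read_palmsens_csv <- function(path) {
  vf_assert(file.exists(path), "vf_parse_error", sprintf("file not found: %s", path))
  lines <- read_text_lines(path)
  vf_assert(length(lines) > 0 && any(nzchar(trimws(lines))), "vf_parse_error",
            sprintf("empty file: %s", path))

  hdr_key <- character(0); hdr_val <- character(0)
  i <- 1L
  while (i <= length(lines) && grepl("^[^:]+:", lines[i])) {
    kv <- regmatches(lines[i], regexec("^([^:]+):[ \t]*(.*)$", lines[i]))[[1]]
    hdr_key <- c(hdr_key, trimws(kv[2]))
    hdr_val <- c(hdr_val, kv[3])
    i <- i + 1L
  }
  while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  vf_assert(i <= length(lines), "vf_parse_error",
            sprintf("%s: no data table after header block", path))

  delim <- sniff_delimiter(lines[i])
  decimal_comma <- identical(delim, ";")
  heads <- trimws(strsplit(lines[i], delim, fixed = TRUE)[[1]])
  vf_assert(length(heads) >= 1 && all(nzchar(heads)), "vf_parse_error",
            sprintf("line %d: malformed column header row", i))
  split_lab <- function(h) {
    if (grepl("/", h, fixed = TRUE)) {
      pos <- max(gregexpr("/", h, fixed = TRUE)[[1]])
      c(substr(h, 1, pos - 1), substring(h, pos + 1))
    } else c(h, "")
  }
  lu <- vapply(heads, split_lab, character(2))
  columns <- data.frame(label = lu[1, ], unit = lu[2, ],
                        row.names = NULL, stringsAsFactors = FALSE)

  rows <- list()
  lineno <- i + 1L
  while (lineno <= length(lines) && nzchar(trimws(lines[lineno]))) {
    cells <- strsplit(lines[lineno], delim, fixed = TRUE)[[1]]
    if (length(cells) != length(heads)) {
      vf_error("vf_parse_error",
               sprintf("line %d: row has %d cells, expected %d",
                       lineno, length(cells), length(heads)),
               line = lineno)
    }
    vals <- parse_numeric_cell(cells, decimal_comma = decimal_comma)
    if (anyNA(vals)) {
      vf_error("vf_parse_error",
               sprintf("line %d: non-numeric cell", lineno), line = lineno)
    }
    rows[[length(rows) + 1L]] <- vals
    lineno <- lineno + 1L
  }
  rows <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), ncol = length(heads))
  tab <- raw_table("data", columns, rows)
  raw_file_model(basename(path),
                 data.frame(key = hdr_key, value = hdr_val, stringsAsFactors = FALSE),
                 list(tab), "palmsens-csv")
}

#' Detect which reader dialect a file belongs to
#'
#' Combines the file extension with a first-line sniff.
#'
#' @param path Path to the file.
#' @return The dialect id, `"gamry-dta"` or `"palmsens-csv"`.
#' @export
detect_reader <- function(path) {
  vf_assert(file.exists(path), "vf_unknown_dialect", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lines <- read_text_lines(path)
  first <- if (length(lines)) lines[which(nzchar(trimws(lines)))[1]] else NA_character_
  tried <- c("gamry-dta", "palmsens-csv")
  if (!is.na(first)) {
    if (ext == "dta" && grepl("\t", first, fixed = TRUE)) return("gamry-dta")
    if (ext %in% c("csv", "txt") && grepl("^[^:]+:", first)) return("palmsens-csv")
  }
  vf_error("vf_unknown_dialect",
           sprintf("no dialect matches '%s' (tried: %s)",
                   basename(path), paste(tried, collapse = ", ")),
           tried = tried)
}

#' Dispatch to the matching reader
#'
#' @param path Path to the file.
#' @return A [raw_file_model()].
#' @export
read_instrument_file <- function(path) {
  switch(detect_reader(path),
         "gamry-dta" = read_gamry_dta(path),
         "palmsens-csv" = read_palmsens_csv(path))
}
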