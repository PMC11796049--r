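#' @keywords internal
"_PACKAGE"

# Structured conditions -------------------------------------------------

vf_error <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "voltfair_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

vf_assert <- function(ok, class, message, ...) {
  if (!isTRUE(ok)) vf_error(class, message, ...)
  invisible(TRUE)
}

# Canonical numeric formatting ------------------------------------------

# 6 significant digits, "." decimal separator, C locale exponent form.
# Used for every number the package serializes (JCAMP-DX, fixtures, CSV)
# so that write -> read -> write is byte-stable.
fmt6 <- function(x) {
  out <- sprintf("%.6g", x)
  out[out == "-0"] <- "0"
  out
}

parse_numeric_cell <- function(x, decimal_comma = FALSE) {
  x <- trimws(x)
  if (decimal_comma) x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

# Text reading with encoding fallback -----------------------------------

# Try UTF-8 first, fall back to Latin-1; strip a UTF-8 BOM if present.
read_text_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xef, 0xbb, 0xbf)))) {
    raw <- raw[-(1:3)]
  }
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  }
  if (nchar(txt) == 0) return(character(0))
  strsplit(txt, "\r\n|\r|\n")[[1]]
}

write_text_file <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

csv_quote <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
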