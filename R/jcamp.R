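# JCAMP-DX writer/reader for CV cycles. Version 5.01, XYPOINTS tables
# (CV abscissae are non-monotonic, so equal-increment XYDATA does not
# apply), plain AFFN numbers at 6 significant digits, LF line endings.
# The first block of a document always holds the unmodified original
# cycle data; peak blocks are appended after it.

#' A parsed JCAMP-DX document
#'
#' @param blocks List of blocks; each block is a list with `ldrs`
#'   (data frame of `label`, `value` in file order) and `xy`
#'   (two-column numeric matrix or `NULL`).
#' @return Object of class `jcamp_document`.
#' @export
jcamp_document <- function(blocks) {
  structure(list(blocks = blocks), class = "jcamp_document")
}

#' @export
print.jcamp_document <- function(x, ...) {
  cat(sprintf("<jcamp_document> %d block(s)\n", length(x$blocks)))
  for (b in x$blocks) {
    ttl <- b$ldrs$value[b$ldrs$label == "TITLE"][1]
    np <- if (is.null(b$xy)) 0L else nrow(b$xy)
    cat(sprintf("  %s (%d points)\n", ttl, np))
  }
  invisible(x)
}

ldr_df <- function(labels, values) {
  data.frame(label = labels, value = values, stringsAsFactors = FALSE)
}

ldr_value <- function(block, label) {
  v <- block$ldrs$value[block$ldrs$label == label]
  if (length(v)) v[1] else NA_character_
}

# Scheme metadata is embedded as ##$<UPPERCASE_FIELD_ID>= user LDRs; the
# authoritative copy of the record lives in the bag's JSON.
meta_ldrs <- function(meta) {
  if (is.null(meta)) return(ldr_df(character(0), character(0)))
  set <- Filter(md_present, meta$fields)
  labs <- paste0("$", toupper(names(set)))
  vals <- vapply(set, function(e) {
    v <- e$value
    if (is.numeric(v)) fmt6(v) else as.character(v)
  }, character(1))
  ldr_df(labs, unname(vals))
}

#' Write one CV cycle as JCAMP-DX text
#'
#' @param cycle A `cv_cycle` from [assemble_cycles()].
#' @param meta Optional [metadata_record()] embedded as `##$` user LDRs.
#' @param title Document title.
#' @return JCAMP-DX text (single string, LF line endings).
#' @export
write_cycle_jcamp <- function(cycle, meta = NULL, title = NULL) {
  stopifnot(inherits(cycle, "cv_cycle"))
  pts <- cycle_points(cycle)
  vf_assert(length(pts$E) > 0, "vf_config_error", "empty cycle")
  title <- title %||% sprintf("CV cycle %d", cycle$ordinal)
  head <- ldr_df(
    c("TITLE", "JCAMP-DX", "DATA TYPE", "DATA CLASS", "XUNITS", "YUNITS"),
    c(title, "5.01", "CYCLIC VOLTAMMETRY", "XYPOINTS", "VOLTS", "AMPERES"))
  extra <- ldr_df(c("$CYCLE", "$PARTIAL"),
                  c(as.character(cycle$ordinal),
                    if (cycle$partial) "TRUE" else "FALSE"))
  block <- list(ldrs = rbind(head, meta_ldrs(meta), extra,
                             ldr_df("NPOINTS", as.character(length(pts$E)))),
                xy = cbind(pts$E, pts$I),
                data_label = "XYPOINTS", data_variable_list = "(XY..XY)")
  serialize_jcamp(jcamp_document(list(block)))
}

serialize_block <- function(block) {
  out <- character(0)
  for (i in seq_len(nrow(block$ldrs))) {
    out <- c(out, sprintf("##%s=%s", block$ldrs$label[i], block$ldrs$value[i]))
  }
  if (!is.null(block$xy)) {
    out <- c(out,
             sprintf("##%s=%s", block$data_label, block$data_variable_list),
             paste(fmt6(block$xy[, 1]), fmt6(block$xy[, 2]), sep = ", "))
  }
  c(out, "##END=")
}

#' Serialize a JCAMP document to canonical text
#'
#' Re-serializing an unmodified parsed document reproduces identical
#' bytes.
#'
#' @param doc A [jcamp_document()].
#' @return Single text string, LF line endings, trailing newline.
#' @export
serialize_jcamp <- function(doc) {
  lines <- unlist(lapply(doc$blocks, serialize_block))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse JCAMP-DX text
#'
#' Tolerates unknown LDRs (kept verbatim, in order). Checks that the
#' declared `NPOINTS` matches the actual pair count of every block and
#' that every block is terminated by `##END=`.
#'
#' @param text JCAMP-DX text.
#' @return List with `cycle` (a `cv_cycle` rebuilt from the first block),
#'   `metadata` (named character vector of `##$` user LDR values),
#'   `peaks` (list of peak blocks with `origin` and `xy`), and
#'   `document` (the full [jcamp_document()]).
#' @export
read_jcamp <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  vf_assert(length(lines) > 0 && grepl("^##TITLE=", lines[1]),
            "vf_parse_error", "JCAMP text must start with ##TITLE=")
  blocks <- list()
  cur_ldrs <- NULL
  cur_xy <- NULL
  cur_data_label <- NULL
  cur_varlist <- NULL
  in_block <- FALSE
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^##", ln)) {
      label <- sub("^##([^=]*)=.*$", "\\1", ln)
      value <- sub("^##[^=]*=", "", ln)
      if (label == "TITLE") {
        vf_assert(!in_block, "vf_truncation_error",
                  "new ##TITLE before ##END: truncated block")
        in_block <- TRUE
        cur_ldrs <- ldr_df(character(0), character(0))
        cur_xy <- NULL; cur_data_label <- NULL; cur_varlist <- NULL
      }
      vf_assert(in_block, "vf_parse_error",
                sprintf("LDR outside any block: %s", ln))
      if (label == "END") {
        blocks[[length(blocks) + 1L]] <- list(
          ldrs = cur_ldrs, xy = cur_xy,
          data_label = cur_data_label, data_variable_list = cur_varlist)
        in_block <- FALSE
      } else if (label %in% c("XYPOINTS", "PEAK TABLE")) {
        cur_data_label <- label
        cur_varlist <- value
        cur_xy <- matrix(numeric(0), ncol = 2)
      } else {
        cur_ldrs <- rbind(cur_ldrs, ldr_df(label, value))
      }
    } else {
      vf_assert(in_block && !is.null(cur_xy), "vf_parse_error",
                sprintf("unexpected data line: %s", ln))
      cells <- strsplit(ln, ",", fixed = TRUE)[[1]]
      vf_assert(length(cells) == 2, "vf_parse_error",
                sprintf("malformed XY pair: %s", ln))
      vals <- parse_numeric_cell(cells)
      vf_assert(!anyNA(vals), "vf_parse_error",
                sprintf("non-numeric XY pair: %s", ln))
      cur_xy <- rbind(cur_xy, vals)
    }
  }
  vf_assert(!in_block, "vf_truncation_error", "missing ##END=: truncated file")

  for (b in blocks) {
    np <- ldr_value(b, "NPOINTS")
    if (!is.na(np)) {
      actual <- if (is.null(b$xy)) 0L else nrow(b$xy)
      vf_assert(as.integer(np) == actual, "vf_integrity_error",
                sprintf("NPOINTS=%s declared but %d pairs present", np, actual))
    }
  }

  first <- blocks[[1]]
  xy <- first$xy
  vf_assert(!is.null(xy) && nrow(xy) >= 1, "vf_parse_error",
            "first block carries no data table")
  ordinal <- suppressWarnings(as.integer(ldr_value(first, "$CYCLE")))
  partial <- identical(ldr_value(first, "$PARTIAL"), "TRUE")
  sweep <- structure(list(direction = "anodic",
                          points = list(t = seq_len(nrow(xy)) - 1,
                                        E = unname(xy[, 1]), I = unname(xy[, 2])),
                          index = 1L, range = c(1L, nrow(xy))),
                     class = "cv_sweep")
  cycle <- structure(list(ordinal = if (is.na(ordinal)) 1L else ordinal,
                          sweeps = list(sweep), partial = partial),
                     class = "cv_cycle")

  user <- first$ldrs$label
  is_meta <- startsWith(user, "$")
  metadata <- stats::setNames(first$ldrs$value[is_meta],
                              sub("^\\$", "", user[is_meta]))

  peaks <- lapply(blocks[-1], function(b) {
    if (identical(b$data_label, "PEAK TABLE")) {
      list(origin = ldr_value(b, "$PEAKORIGIN"), xy = b$xy)
    } else NULL
  })
  peaks <- Filter(Negate(is.null), peaks)

  list(cycle = cycle, metadata = metadata, peaks = peaks,
       document = jcamp_document(blocks))
}

#' Append (or replace) a peak table block
#'
#' The original data block is left byte-identical; any existing peak
#' block is replaced (a manual edit supersedes automatic picking). For
#' zero peaks the document is returned unchanged.
#'
#' @param doc A [jcamp_document()].
#' @param peaks List of `cv_peak` objects.
#' @param origin `"auto"` or `"manual"`.
#' @return List with `document` (new [jcamp_document()]) and `suffix`
#'   (`".peak.jdx"` for auto, `".edit.jdx"` for manual, `NULL` for a
#'   no-op).
#' @export
add_peak_block <- function(doc, peaks, origin = c("auto", "manual")) {
  origin <- match.arg(origin)
  stopifnot(inherits(doc, "jcamp_document"))
  if (length(peaks) == 0) return(list(document = doc, suffix = NULL))
  xy <- cbind(vapply(peaks, function(p) p$E_p, numeric(1)),
              vapply(peaks, function(p) p$i_p, numeric(1)))
  kinds <- vapply(peaks, function(p) p$kind, character(1))
  block <- list(
    ldrs = ldr_df(
      c("TITLE", "JCAMP-DX", "DATA TYPE", "$PEAKORIGIN", "$PEAKKINDS", "NPOINTS"),
      c(sprintf("Peak table (%s)", origin), "5.01",
        "CYCLIC VOLTAMMETRY PEAK TABLE", origin,
        paste(kinds, collapse = ","), as.character(nrow(xy)))),
    xy = xy, data_label = "PEAK TABLE", data_variable_list = "(XY..XY)")
  keep <- Filter(function(b) !identical(b$data_label, "PEAK TABLE"), doc$blocks)
  list(document = jcamp_document(c(keep, list(block))),
       suffix = if (origin == "auto") ".peak.jdx" else ".edit.jdx")
}
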