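# Minimal OOXML spreadsheet writer: one worksheet part per data frame,
# inline strings, no shared-string table or styling. Sufficient for the
# metadata/analysis workbook this package exports and readable by any
# spreadsheet application.

col_ref <- function(j) {
  ref <- ""
  while (j > 0) {
    ref <- paste0(LETTERS[(j - 1) %% 26 + 1], ref)
    j <- (j - 1) %/% 26
  }
  ref
}

cell_xml <- function(ref, value) {
  if (length(value) != 1 || is.na(value)) {
    return(sprintf('<c r="%s" t="inlineStr"><is><t></t></is></c>', ref))
  }
  if (is.numeric(value)) {
    sprintf('<c r="%s"><v>%s</v></c>', ref, fmt6(value))
  } else {
    sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
            ref, xml_escape(as.character(value)))
  }
}

sheet_xml <- function(df) {
  rows <- character(nrow(df) + 1L)
  header <- vapply(seq_along(df), function(j) {
    cell_xml(paste0(col_ref(j), 1L), names(df)[j])
  }, character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      cell_xml(paste0(col_ref(j), i + 1L), df[[j]][i])
    }, character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write data frames as a multi-sheet XLSX workbook
#'
#' @param sheets Named list of data frames; names become sheet names.
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsx_sheets <- function(sheets, path) {
  vf_assert(length(sheets) >= 1 && !is.null(names(sheets)),
            "vf_config_error", "sheets must be a named list of data frames")
  stage <- tempfile("xlsx")
  on.exit(unlink(stage, recursive = TRUE))
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)

  n <- length(sheets)
  overrides <- vapply(seq_len(n), function(k) {
    sprintf(paste0('<Override PartName="/xl/worksheets/sheet%d.xml" ',
                   'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'),
            k)
  }, character(1))
  write_text_file(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(overrides, collapse = ""),
    '</Types>'), file.path(stage, "[Content_Types].xml"))

  write_text_file(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(stage, "_rels", ".rels"))

  sheet_entries <- vapply(seq_len(n), function(k) {
    sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
            xml_escape(names(sheets)[k]), k, k)
  }, character(1))
  write_text_file(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', paste(sheet_entries, collapse = ""), '</sheets></workbook>'),
    file.path(stage, "xl", "workbook.xml"))

  rels <- vapply(seq_len(n), function(k) {
    sprintf(paste0('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/',
                   'officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'),
            k, k)
  }, character(1))
  write_text_file(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(rels, collapse = ""), '</Relationships>'),
    file.path(stage, "xl", "_rels", "workbook.xml.rels"))

  for (k in seq_len(n)) {
    write_text_file(sheet_xml(as.data.frame(sheets[[k]])),
                    file.path(stage, "xl", "worksheets", sprintf("sheet%d.xml", k)))
  }

  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path.expand(path), mustWork = FALSE),
           files = list.files(stage, recursive = TRUE, all.files = TRUE),
           root = stage, mode = "mirror")
  invisible(path)
}
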