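# Dataset-level exports: the 2 + x sheet metadata workbook, the
# dataset_description.txt inventory and the combined ZIP archive with its
# per-curve file life cycle (converted -> auto-picked .peak -> manually
# edited .edit, where an edit replaces the peak file).

#' Export the dataset metadata workbook
#'
#' Sheet 1 "Definitions" lists the scheme fields; sheet 2 "Metadata"
#' holds the merged record (one row per scheme field, including missing
#' ones, with a provenance column); one further analysis sheet is added
#' per curve (peak table plus descriptors), so a dataset of x curves
#' yields 2 + x sheets.
#'
#' @param curves List of per-curve lists with elements `peaks` (list of
#'   [cv_peak()]) and `descriptors` ([compute_descriptors()] result).
#' @param metadata Merged [metadata_record()].
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
export_xlsx <- function(curves, metadata, path) {
  vf_assert(length(curves) >= 1, "vf_config_error",
            "a workbook needs at least one curve")
  scheme <- cv_metadata_scheme()
  definitions <- data.frame(
    field = scheme$field, label = scheme$label, unit = scheme$unit,
    stringsAsFactors = FALSE)
  meta_sheet <- data.frame(
    field = scheme$field,
    value = vapply(scheme$field, function(f) {
      e <- metadata$fields[[f]]
      if (md_present(e)) paste(format(e$value), collapse = ";") else ""
    }, character(1)),
    unit = vapply(scheme$field, function(f) metadata$fields[[f]]$unit, character(1)),
    provenance = vapply(scheme$field, function(f) {
      metadata$fields[[f]]$provenance
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  sheets <- c(list(Definitions = definitions, Metadata = meta_sheet),
              stats::setNames(lapply(curves, curve_sheet),
                              sprintf("Curve %d", seq_along(curves))))
  write_xlsx_sheets(sheets, path)
}

curve_sheet <- function(curve) {
  desc <- curve$descriptors
  peak_rows <- lapply(curve$peaks, function(p) {
    data.frame(record = "peak", kind = p$kind, origin = p$origin,
               E_V = p$E_p, I_A = p$i_p, value = NA_real_,
               stringsAsFactors = FALSE)
  })
  desc_rows <- if (!is.null(desc)) {
    list(data.frame(record = c("E1/2 (V)", "dEp (mV)",
                               sprintf("ipa/ipc (%s)", desc$ratio_mode),
                               "i_lambda0 (A)"),
                    kind = "", origin = "",
                    E_V = NA_real_, I_A = NA_real_,
                    value = c(desc$E_half, desc$delta_Ep, desc$ratio,
                              desc$i_lambda0),
                    stringsAsFactors = FALSE))
  } else list()
  do.call(rbind, c(peak_rows, desc_rows))
}

#' Expected archive inventory
#'
#' Pure function of the curve count and per-curve edited flags, per the
#' dataset archive layout: dataset-level (type a) files plus a repeated
#' per-curve (type b) set in which a manual edit replaces the auto-picked
#' peak file.
#'
#' @param name Dataset name.
#' @param n_curves Number of curves.
#' @param edited Logical vector (length `n_curves`): curve was manually
#'   edited.
#' @param picked Logical vector: automatic peak picking produced a peak
#'   file (default all `TRUE`).
#' @param original_ext Extension of the archived original vendor file.
#' @param dialect `"underscore"` (`-curve1_bagit.peak.jdx`) or `"dot"`
#'   (`-curve1.bagit.peak.jdx`) naming.
#' @return Data frame with `path`, `role`, `type` ("a" dataset-level /
#'   "b" per-curve).
#' @export
archive_inventory <- function(name, n_curves, edited = rep(FALSE, n_curves),
                              picked = rep(TRUE, n_curves),
                              original_ext = "DTA",
                              dialect = c("underscore", "dot")) {
  dialect <- match.arg(dialect)
  stopifnot(length(edited) == n_curves, length(picked) == n_curves)
  sep <- if (dialect == "underscore") "_" else "."
  a <- data.frame(
    path = c("dataset_description.txt",
             sprintf("%s.%s", name, original_ext),
             sprintf("%s.bagit.zip", name),
             sprintf("%s.xlsx", name),
             sprintf("%s.combined.png", name),
             sprintf("%s.new_combined.png", name)),
    role = c("dataset description", "original data file", "BagIt bag",
             "metadata workbook", "all-curve preview", "selected-curve preview"),
    type = "a", stringsAsFactors = FALSE)
  b <- do.call(rbind, lapply(seq_len(n_curves), function(k) {
    base <- sprintf("%s-curve%d%sbagit", name, k, sep)
    rows <- data.frame(path = sprintf("%s.jdx", base),
                       role = sprintf("curve %d converted data", k),
                       type = "b", stringsAsFactors = FALSE)
    if (picked[k] && !edited[k]) {
      rows <- rbind(rows, data.frame(
        path = sprintf("%s.peak.jdx", base),
        role = sprintf("curve %d auto-picked peaks", k),
        type = "b", stringsAsFactors = FALSE))
    }
    if (edited[k]) {
      rows <- rbind(rows, data.frame(
        path = sprintf("%s.edit.jdx", base),
        role = sprintf("curve %d manually edited data", k),
        type = "b", stringsAsFactors = FALSE))
    }
    rbind(rows,
          data.frame(path = sprintf("%s.edit.png", base),
                     role = sprintf("curve %d preview", k),
                     type = "b", stringsAsFactors = FALSE),
          data.frame(path = sprintf("%s.edit.csv", base),
                     role = sprintf("curve %d analysis table", k),
                     type = "b", stringsAsFactors = FALSE))
  }))
  rbind(a, b)
}

#' Write dataset_description.txt
#'
#' Three `key: value` header lines (dataset id, creation date, scheme
#' version) followed by one `<path><TAB><role>` line per archived file.
#'
#' @param inventory Data frame from [archive_inventory()].
#' @param name Dataset id.
#' @param path Output path.
#' @param created Creation date string (fix it for reproducible output).
#' @return `path`, invisibly.
#' @export
write_dataset_description <- function(inventory, name, path,
                                      created = format(Sys.Date())) {
  lines <- c(sprintf("dataset_id: %s", name),
             sprintf("created: %s", created),
             sprintf("scheme_version: %s", VF_SCHEME_VERSION),
             paste(inventory$path, inventory$role, sep = "\t"))
  write_text_file(lines, path)
}

#' Build the combined dataset ZIP archive
#'
#' Assembles the dataset-level files (description, original vendor file,
#' BagIt bag, workbook, combined previews) and the per-curve file set
#' into one ZIP. Errors if a mandatory dataset-level component is
#' missing.
#'
#' @param dataset List describing the dataset: `name`, `original_file`,
#'   `bag_zip`, `xlsx`, `combined_png`, `new_combined_png` (paths) and
#'   `curves` — a list of per-curve lists with `jdx`, optional
#'   `peak_jdx`, optional `edit_jdx`, `png`, `csv` (paths) and an
#'   `edited` flag.
#' @param out_zip Output archive path.
#' @param dialect Per-curve naming dialect, see [archive_inventory()].
#' @param created Creation date recorded in the dataset description.
#' @return Object of class `archive_layout`: list with `zip` and `files`
#'   (the inventory data frame).
#' @export
build_archive <- function(dataset, out_zip, dialect = c("underscore", "dot"),
                          created = format(Sys.Date())) {
  dialect <- match.arg(dialect)
  need <- c("name", "original_file", "bag_zip", "xlsx",
            "combined_png", "new_combined_png", "curves")
  for (f in need) {
    vf_assert(!is.null(dataset[[f]]), "vf_config_error",
              sprintf("dataset is missing mandatory component '%s'", f))
  }
  vf_assert(length(dataset$curves) >= 1, "vf_config_error",
            "dataset has no curves")
  for (f in c("original_file", "bag_zip", "xlsx", "combined_png",
              "new_combined_png")) {
    vf_assert(file.exists(dataset[[f]]), "vf_config_error",
              sprintf("dataset component '%s' not found: %s", f, dataset[[f]]))
  }

  name <- dataset$name
  edited <- vapply(dataset$curves, function(c) isTRUE(c$edited), logical(1))
  picked <- vapply(dataset$curves, function(c) !is.null(c$peak_jdx), logical(1))
  inventory <- archive_inventory(
    name, length(dataset$curves), edited = edited,
    picked = picked | edited,
    original_ext = tools::file_ext(dataset$original_file),
    dialect = dialect)

  stage <- tempfile("archive")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE))
  put <- function(src, dest) {
    vf_assert(file.exists(src), "vf_config_error",
              sprintf("archive component not found: %s", src))
    file.copy(src, file.path(stage, dest), overwrite = TRUE)
  }
  write_dataset_description(inventory, name,
                            file.path(stage, "dataset_description.txt"),
                            created = created)
  put(dataset$original_file, sprintf("%s.%s", name,
                                     tools::file_ext(dataset$original_file)))
  put(dataset$bag_zip, sprintf("%s.bagit.zip", name))
  put(dataset$xlsx, sprintf("%s.xlsx", name))
  put(dataset$combined_png, sprintf("%s.combined.png", name))
  put(dataset$new_combined_png, sprintf("%s.new_combined.png", name))
  sep <- if (dialect == "underscore") "_" else "."
  for (k in seq_along(dataset$curves)) {
    cur <- dataset$curves[[k]]
    base <- sprintf("%s-curve%d%sbagit", name, k, sep)
    put(cur$jdx, sprintf("%s.jdx", base))
    if (isTRUE(cur$edited)) {
      put(cur$edit_jdx, sprintf("%s.edit.jdx", base))
    } else if (!is.null(cur$peak_jdx)) {
      put(cur$peak_jdx, sprintf("%s.peak.jdx", base))
    }
    put(cur$png, sprintf("%s.edit.png", base))
    put(cur$csv, sprintf("%s.edit.csv", base))
  }

  if (file.exists(out_zip)) unlink(out_zip)
  zip::zip(normalizePath(path.expand(out_zip), mustWork = FALSE),
           files = list.files(stage, recursive = TRUE),
           root = stage, mode = "mirror")
  structure(list(zip = out_zip, files = inventory), class = "archive_layout")
}

#' @export
print.archive_layout <- function(x, ...) {
  cat(sprintf("<archive_layout> %s: %d files\n", x$zip, nrow(x$files)))
  invisible(x)
}
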