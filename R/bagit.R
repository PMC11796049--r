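# BagIt bag builder/validator. Layout: bagit.txt, data/ payload with one
# JCAMP-DX file per cycle, manifest-sha256.txt + manifest-sha512.txt
# covering every payload file, and metadata/metadata.json holding the sum
# of all extracted metadata of the experiment. metadata/ sits beside
# data/ and is treated as a tag directory: it is not covered by the
# payload manifests (the validator notes this).

BAGIT_DECLARATION <- c("BagIt-Version: 1.0", "Tag-File-Character-Encoding: UTF-8")

file_digest <- function(path, algo) {
  digest::digest(file = path, algo = algo)
}

#' Build a BagIt bag from converted cycle files
#'
#' @param cycle_files Character vector of JCAMP-DX file paths (payload).
#' @param metadata_json Metadata record JSON text (from
#'   [metadata_to_json()]).
#' @param out Output bag directory, or a path ending in `.zip` for a
#'   zipped bag.
#' @return Object of class `bag_manifest`: data frame of payload entries
#'   (`path`, `size`, `sha256`, `sha512`) with the bag location and tag
#'   files as attributes.
#' @export
build_bagit <- function(cycle_files, metadata_json, out) {
  vf_assert(length(cycle_files) >= 1, "vf_config_error", "empty payload")
  vf_assert(all(file.exists(cycle_files)), "vf_config_error",
            "payload file missing")
  zipped <- grepl("\\.zip$", out)
  root <- if (zipped) file.path(tempfile("bag"), "bag") else out
  dir.create(file.path(root, "data"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "metadata"), showWarnings = FALSE)

  write_text_file(BAGIT_DECLARATION, file.path(root, "bagit.txt"))
  write_text_file(metadata_json, file.path(root, "metadata", "metadata.json"))
  rel <- file.path("data", basename(cycle_files))
  file.copy(cycle_files, file.path(root, rel), overwrite = TRUE)

  entries <- data.frame(
    path = rel,
    size = file.size(file.path(root, rel)),
    sha256 = vapply(file.path(root, rel), file_digest, character(1), "sha256"),
    sha512 = vapply(file.path(root, rel), file_digest, character(1), "sha512"),
    row.names = NULL, stringsAsFactors = FALSE)
  write_text_file(paste(entries$sha256, entries$path, sep = "  "),
                  file.path(root, "manifest-sha256.txt"))
  write_text_file(paste(entries$sha512, entries$path, sep = "  "),
                  file.path(root, "manifest-sha512.txt"))

  if (zipped) {
    if (file.exists(out)) unlink(out)
    zip::zip(normalizePath(path.expand(out), mustWork = FALSE),
             files = list.files(root, recursive = TRUE),
             root = root, mode = "mirror")
    unlink(dirname(root), recursive = TRUE)
  }
  structure(entries, class = c("bag_manifest", "data.frame"),
            bag = out,
            tag_files = c("bagit.txt", "manifest-sha256.txt",
                          "manifest-sha512.txt", "metadata/metadata.json"))
}

parse_manifest <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([0-9a-f]+)\\s+(.*)$", lines))
  data.frame(digest = vapply(m, `[`, character(1), 2),
             path = vapply(m, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Validate a BagIt bag
#'
#' Checks the declaration, the presence of both checksum manifests and
#' the payload directory, and recomputes every digest. Report-only: never
#' throws on an invalid bag.
#'
#' @param bag Bag directory or zipped bag.
#' @return List with `valid`, `errors`, `warnings`.
#' @export
validate_bagit <- function(bag) {
  errors <- character(0)
  warnings <- character(0)
  if (!file.exists(bag)) {
    return(list(valid = FALSE, errors = sprintf("bag not found: %s", bag),
                warnings = warnings))
  }
  root <- bag
  if (grepl("\\.zip$", bag)) {
    root <- tempfile("bagval")
    zip::unzip(bag, exdir = root)
    on.exit(unlink(root, recursive = TRUE))
  }

  need <- c("bagit.txt", "manifest-sha256.txt", "manifest-sha512.txt")
  for (f in need) {
    if (!file.exists(file.path(root, f))) {
      errors <- c(errors, sprintf("missing tag file: %s", f))
    }
  }
  if (!dir.exists(file.path(root, "data"))) {
    errors <- c(errors, "missing data/ payload directory")
  }
  if (!file.exists(file.path(root, "metadata", "metadata.json"))) {
    warnings <- c(warnings, "metadata/metadata.json not present")
  }
  if (file.exists(file.path(root, "bagit.txt"))) {
    decl <- read_text_lines(file.path(root, "bagit.txt"))
    if (!any(grepl("^BagIt-Version:", decl))) {
      errors <- c(errors, "bagit.txt lacks BagIt-Version")
    }
  }

  payload <- list.files(file.path(root, "data"), recursive = TRUE)
  payload <- file.path("data", payload)
  for (algo in c("sha256", "sha512")) {
    mf <- file.path(root, sprintf("manifest-%s.txt", algo))
    if (!file.exists(mf)) next
    man <- parse_manifest(mf)
    for (p in setdiff(payload, man$path)) {
      errors <- c(errors, sprintf("payload file %s missing from %s manifest", p, algo))
    }
    for (i in seq_len(nrow(man))) {
      fp <- file.path(root, man$path[i])
      if (!file.exists(fp)) {
        errors <- c(errors, sprintf("%s listed in %s manifest but absent",
                                    man$path[i], algo))
        next
      }
      actual <- file_digest(fp, algo)
      if (!identical(actual, man$digest[i])) {
        errors <- c(errors, sprintf("%s digest mismatch for %s", algo, man$path[i]))
      }
    }
  }
  warnings <- c(warnings,
                "metadata/ is a tag directory and not covered by the payload manifests")
  list(valid = length(errors) == 0, errors = errors, warnings = warnings)
}
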