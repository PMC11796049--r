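# CV metadata scheme: target fields, per-field provenance, validation,
# four-part merging, and lossless JSON serialization.

VF_SCHEME_VERSION <- "1.0"

VF_PROVENANCE <- c("device", "context", "manual", "analysis", "computed", "missing")

#' The target CV metadata scheme
#'
#' Field list modeled on the scope of current reporting guidelines for
#' voltammetry (sample and analyte identity, cell composition, electrode
#' setup, potential program, instrument provenance) and versioned so a
#' community-maintained scheme can replace it.
#'
#' @return Data frame with columns `field`, `label`, `unit`,
#'   `required_minimal`, `required_publication`.
#' @export
cv_metadata_scheme <- function() {
  f <- function(field, label, unit = "", min = FALSE, pub = FALSE) {
    data.frame(field = field, label = label, unit = unit,
               required_minimal = min, required_publication = pub,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    f("sample_id", "Sample identifier"),
    f("analyte_name", "Analyte name"),
    f("analyte_concentration", "Analyte concentration", "mol/L"),
    f("solvent", "Solvent", "", FALSE, TRUE),
    f("supporting_electrolyte", "Supporting electrolyte", "", FALSE, TRUE),
    f("electrolyte_concentration", "Electrolyte concentration", "mol/L"),
    f("working_electrode", "Working electrode", "", FALSE, TRUE),
    f("counter_electrode", "Counter electrode", "", FALSE, TRUE),
    f("reference_electrode", "Reference electrode", "", FALSE, TRUE),
    f("internal_reference_couple", "Internal reference couple", "", FALSE, TRUE),
    f("scan_rate", "Scan rate (nu)", "V/s", TRUE, TRUE),
    f("potential_initial", "Initial potential", "V"),
    f("potential_vertex1", "First vertex potential", "V", TRUE, TRUE),
    f("potential_vertex2", "Second vertex potential", "V", TRUE, TRUE),
    f("potential_final", "Final potential", "V"),
    f("step_potential", "Step potential", "V"),
    f("n_cycles", "Number of cycles"),
    f("temperature", "Temperature", "K"),
    f("atmosphere", "Atmosphere"),
    f("instrument_vendor", "Instrument vendor"),
    f("instrument_model", "Instrument model"),
    f("software_version", "Instrument software version"),
    f("measurement_date", "Measurement date"),
    f("operator", "Operator"),
    f("method_term_label", "Method ontology term"),
    f("method_term_source", "Method ontology source")
  ))
}

#' Create a CV metadata record
#'
#' Every scheme field is present; unset fields carry provenance
#' `"missing"`. The method ontology term defaults to
#' `"cyclic voltammetry (CV)"` from CHMO for all CV records.
#'
#' @param values Named list `field = value` of initial values.
#' @param provenance Provenance tag applied to `values`.
#' @return An object of class `metadata_record`.
#' @export
metadata_record <- function(values = list(), provenance = "manual") {
  provenance <- match.arg(provenance, VF_PROVENANCE)
  scheme <- cv_metadata_scheme()
  fields <- stats::setNames(lapply(seq_len(nrow(scheme)), function(i) {
    list(value = NA, unit = scheme$unit[i], provenance = "missing")
  }), scheme$field)
  rec <- structure(list(fields = fields, extensions = list()),
                   scheme_version = VF_SCHEME_VERSION,
                   class = "metadata_record")
  rec <- md_set(rec, "method_term_label", "cyclic voltammetry (CV)", "context")
  rec <- md_set(rec, "method_term_source", "CHMO", "context")
  for (nm in names(values)) rec <- md_set(rec, nm, values[[nm]], provenance)
  rec
}

#' Set one metadata field
#'
#' @param rec A [metadata_record()].
#' @param field Scheme field id (unknown ids go to the extensions section).
#' @param value Field value.
#' @param provenance One of device, context, manual, analysis, computed.
#' @param unit Optional unit override.
#' @return The updated record.
#' @export
md_set <- function(rec, field, value, provenance, unit = NULL) {
  provenance <- match.arg(provenance, VF_PROVENANCE)
  if (field %in% names(rec$fields)) {
    cur <- rec$fields[[field]]
    rec$fields[[field]] <- list(value = value,
                                unit = unit %||% cur$unit,
                                provenance = provenance)
  } else {
    rec$extensions[[field]] <- list(value = value, unit = unit %||% "",
                                    provenance = provenance)
  }
  rec
}

#' Get one metadata field value
#'
#' @param rec A [metadata_record()].
#' @param field Scheme field id.
#' @return The value, or `NA` if missing.
#' @export
md_get <- function(rec, field) {
  if (field %in% names(rec$fields)) rec$fields[[field]]$value
  else if (field %in% names(rec$extensions)) rec$extensions[[field]]$value
  else NA
}

md_present <- function(entry) {
  !identical(entry$provenance, "missing") &&
    !(length(entry$value) == 1 && is.na(entry$value))
}

#' @export
print.metadata_record <- function(x, ...) {
  set <- Filter(md_present, x$fields)
  cat(sprintf("<metadata_record> scheme %s: %d/%d fields set\n",
              attr(x, "scheme_version"), length(set), length(x$fields)))
  for (nm in names(set)) {
    e <- set[[nm]]
    cat(sprintf("  %-26s %-14s [%s]%s\n", nm, format(e$value), e$provenance,
                if (nzchar(e$unit)) paste0(" ", e$unit) else ""))
  }
  invisible(x)
}

#' Validate a metadata record against the scheme
#'
#' `"minimal"` requires the scan rate and the potential window;
#' `"publication"` additionally requires the electrode setup, the
#' electrolyte, the solvent and the reference couple. The report never
#' throws: conversion must succeed even for sparse device metadata.
#'
#' @param rec A [metadata_record()].
#' @param level `"minimal"` or `"publication"`.
#' @return List with `valid`, `missing` (field ids) and `malformed`
#'   (data frame of field/problem).
#' @export
validate_metadata <- function(rec, level = c("minimal", "publication")) {
  level <- match.arg(level)
  scheme <- cv_metadata_scheme()
  req <- scheme$field[if (level == "minimal") scheme$required_minimal
                      else scheme$required_publication]
  missing <- req[!vapply(rec$fields[req], md_present, logical(1))]

  malformed <- data.frame(field = character(0), problem = character(0),
                          stringsAsFactors = FALSE)
  bad <- function(field, problem) {
    rbind(malformed, data.frame(field = field, problem = problem,
                                stringsAsFactors = FALSE))
  }
  num_or_na <- function(field) {
    v <- md_get(rec, field)
    if (md_present(rec$fields[[field]])) suppressWarnings(as.numeric(v)) else NA_real_
  }
  sr <- num_or_na("scan_rate")
  if (!is.na(sr) && sr <= 0) malformed <- bad("scan_rate", "must be > 0")
  nc <- num_or_na("n_cycles")
  if (!is.na(nc) && nc < 1) malformed <- bad("n_cycles", "must be >= 1")
  tmp <- num_or_na("temperature")
  if (!is.na(tmp) && tmp <= 0) malformed <- bad("temperature", "must be > 0 K")
  for (fld in c("analyte_concentration", "electrolyte_concentration")) {
    v <- num_or_na(fld)
    if (!is.na(v) && v < 0) malformed <- bad(fld, "must be >= 0")
  }
  list(valid = length(missing) == 0 && nrow(malformed) == 0,
       level = level, missing = missing, malformed = malformed)
}

#' Merge the four provenance parts of a CV metadata record
#'
#' Field-wise union with precedence `manual > analysis > context > device`:
#' the human correcting a record always wins. The winning part's
#' provenance is retained; conflicting non-missing values are logged in
#' the `"conflicts"` attribute.
#'
#' @param device,context,manual,analysis [metadata_record()] parts
#'   (any may be `NULL`).
#' @return Merged [metadata_record()].
#' @export
merge_metadata <- function(device = NULL, context = NULL,
                           manual = NULL, analysis = NULL) {
  parts <- list(device = device, context = context,
                analysis = analysis, manual = manual)  # ascending precedence
  parts <- Filter(Negate(is.null), parts)
  out <- metadata_record()
  conflicts <- data.frame(field = character(0), kept = character(0),
                          discarded = character(0), winner = character(0),
                          stringsAsFactors = FALSE)
  all_fields <- names(out$fields)
  ext_fields <- unique(unlist(lapply(parts, function(p) names(p$extensions))))
  for (fld in c(all_fields, ext_fields)) {
    winner <- NULL
    vals <- list()
    for (nm in names(parts)) {
      p <- parts[[nm]]
      e <- if (fld %in% names(p$fields)) p$fields[[fld]] else p$extensions[[fld]]
      if (!is.null(e) && md_present(e)) {
        vals[[nm]] <- e
        winner <- e     # later parts have higher precedence
      }
    }
    if (is.null(winner)) next
    uniq <- unique(vapply(vals, function(e) paste(format(e$value), collapse = ";"),
                          character(1)))
    if (length(uniq) > 1) {
      conflicts <- rbind(conflicts, data.frame(
        field = fld, kept = paste(format(winner$value), collapse = ";"),
        discarded = paste(setdiff(uniq, paste(format(winner$value), collapse = ";")),
                          collapse = " | "),
        winner = winner$provenance, stringsAsFactors = FALSE))
    }
    out <- md_set(out, fld, winner$value, winner$provenance, unit = winner$unit)
  }
  attr(out, "conflicts") <- conflicts
  out
}

#' Serialize a metadata record to JSON
#'
#' Lossless: units, provenance and unknown (extension) fields survive a
#' round trip; keys follow scheme order.
#'
#' @param rec A [metadata_record()].
#' @return JSON text.
#' @export
metadata_to_json <- function(rec) {
  body <- list(
    scheme_version = attr(rec, "scheme_version"),
    fields = lapply(rec$fields, function(e) {
      list(value = if (length(e$value) == 1 && is.na(e$value)) NULL else e$value,
           unit = e$unit, provenance = e$provenance)
    }),
    extensions = lapply(rec$extensions, function(e) {
      list(value = e$value, unit = e$unit, provenance = e$provenance)
    })
  )
  jsonlite::toJSON(body, auto_unbox = TRUE, null = "null", digits = NA,
                   pretty = TRUE)
}

#' Deserialize a metadata record from JSON
#'
#' Unknown field ids are kept in the extensions section.
#'
#' @param text JSON text from [metadata_to_json()].
#' @return A [metadata_record()].
#' @export
json_to_metadata <- function(text) {
  body <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  rec <- metadata_record()
  known <- names(rec$fields)
  # reset context defaults so the parse is faithful to the document
  rec$fields[["method_term_label"]] <- list(value = NA, unit = "", provenance = "missing")
  rec$fields[["method_term_source"]] <- list(value = NA, unit = "", provenance = "missing")
  for (nm in names(body$fields)) {
    e <- body$fields[[nm]]
    if (is.null(e$value)) {
      if (nm %in% known) {
        rec$fields[[nm]] <- list(value = NA, unit = e$unit %||% "",
                                 provenance = e$provenance %||% "missing")
      }
      next
    }
    rec <- md_set(rec, nm, e$value, e$provenance %||% "missing", unit = e$unit)
  }
  for (nm in names(body$extensions)) {
    e <- body$extensions[[nm]]
    rec$extensions[[nm]] <- list(value = e$value, unit = e$unit %||% "",
                                 provenance = e$provenance %||% "missing")
  }
  if (!is.null(body$scheme_version)) {
    attr(rec, "scheme_version") <- body$scheme_version
  }
  rec
}
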