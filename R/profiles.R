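# Declarative conversion profiles: identifier-triggered matching of raw
# instrument files, trace extraction, and metadata mapping onto the CV
# scheme. A profile is defined once per device and then applies to every
# further file carrying the identifiers.

#' Create a conversion profile
#'
#' @param profile_id Unique profile identifier.
#' @param identifiers List of rules, each a list with `scope`
#'   (`"filename"`, `"header"` or `"table-name"`), `pattern` (regular
#'   expression) and `required` (flag, default `TRUE`). Header rules match
#'   against `"key=value"` strings. At least one rule must be required.
#' @param data_map List with `table` (index or name of the source table),
#'   `x_column` (potential, V), `y_column` (current, A), optional
#'   `t_column` (time, s), and optional `x_scale`/`y_scale`/`t_scale`
#'   factors normalizing vendor units to V/A/s.
#' @param metadata_map List of entries with `source` (a header key, or
#'   `"computed:<name>"`), `target` (scheme field id) and optional
#'   `transform` (`list(type = "none")`, `list(type = "scale", factor =)`
#'   or `list(type = "lookup", table = named list)`).
#' @param output_policy Only `"one-file-per-cycle"` is defined.
#' @return Object of class `conversion_profile`.
#' @export
conversion_profile <- function(profile_id, identifiers, data_map,
                               metadata_map = list(),
                               output_policy = "one-file-per-cycle") {
  vf_assert(is.character(profile_id) && nzchar(profile_id), "vf_config_error",
            "profile_id must be a non-empty string")
  identifiers <- lapply(identifiers, function(r) {
    vf_assert(all(c("scope", "pattern") %in% names(r)), "vf_config_error",
              sprintf("profile '%s': identifier rule needs scope and pattern",
                      profile_id))
    vf_assert(r$scope %in% c("filename", "header", "table-name"),
              "vf_config_error",
              sprintf("profile '%s': unknown identifier scope '%s'",
                      profile_id, r$scope))
    r$required <- isTRUE(r$required %||% TRUE)
    r
  })
  vf_assert(any(vapply(identifiers, `[[`, logical(1), "required")),
            "vf_config_error",
            sprintf("profile '%s' needs at least one required identifier",
                    profile_id))
  vf_assert(all(c("x_column", "y_column") %in% names(data_map)),
            "vf_config_error",
            sprintf("profile '%s': data_map needs x_column and y_column",
                    profile_id))
  data_map$table <- data_map$table %||% 1L
  structure(list(profile_id = profile_id, identifiers = identifiers,
                 data_map = data_map, metadata_map = metadata_map,
                 output_policy = output_policy),
            class = "conversion_profile")
}

#' @export
print.conversion_profile <- function(x, ...) {
  cat(sprintf("<conversion_profile> %s: %d identifier rule(s), x=%s y=%s\n",
              x$profile_id, length(x$identifiers),
              x$data_map$x_column, x$data_map$y_column))
  invisible(x)
}

#' Build a profile store
#'
#' @param profiles List of [conversion_profile()] objects with unique ids.
#' @return Object of class `profile_store`.
#' @export
profile_store <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1), "profile_id")
  vf_assert(!anyDuplicated(ids), "vf_config_error",
            sprintf("duplicate profile ids: %s",
                    paste(ids[duplicated(ids)], collapse = ", ")))
  structure(list(profiles = stats::setNames(profiles, ids)),
            class = "profile_store")
}

#' Load a profile store from a directory of JSON documents
#'
#' @param dir Directory containing one `.json` document per profile.
#' @return A [profile_store()].
#' @export
load_profile_store <- function(dir) {
  vf_assert(dir.exists(dir), "vf_config_error",
            sprintf("profile directory not found: %s", dir))
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  vf_assert(length(paths) > 0, "vf_config_error",
            sprintf("no profile documents in %s", dir))
  profile_store(lapply(paths, function(p) {
    doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
    conversion_profile(doc$profile_id, doc$identifiers, doc$data_map,
                       doc$metadata_map %||% list(),
                       doc$output_policy %||% "one-file-per-cycle")
  }))
}

#' Write a profile to a JSON document
#'
#' @param profile A [conversion_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  write_text_file(jsonlite::toJSON(unclass(profile), auto_unbox = TRUE,
                                   pretty = TRUE, digits = NA),
                  path)
}

rule_matches <- function(rule, raw) {
  switch(rule$scope,
         "filename" = grepl(rule$pattern, raw$source_name),
         "header" = any(grepl(rule$pattern,
                              paste0(raw$header$key, "=", raw$header$value))),
         "table-name" = any(grepl(rule$pattern,
                                  vapply(raw$tables, `[[`, character(1), "name"))))
}

#' Match a raw file against a profile store
#'
#' A profile is a candidate when all its required identifier rules match.
#' Tie-break: the candidate with the most satisfied rules (required and
#' optional) wins; remaining ties resolve to the lexicographically
#' smallest profile id, so matching is deterministic.
#'
#' @param raw A [raw_file_model()].
#' @param store A [profile_store()].
#' @return The matching [conversion_profile()].
#' @export
match_profile <- function(raw, store) {
  vf_assert(length(store$profiles) > 0, "vf_config_error", "empty profile store")
  scored <- lapply(store$profiles, function(p) {
    hits <- vapply(p$identifiers, rule_matches, logical(1), raw = raw)
    req <- vapply(p$identifiers, `[[`, logical(1), "required")
    list(candidate = all(hits[req]), satisfied = sum(hits))
  })
  cand <- names(scored)[vapply(scored, `[[`, logical(1), "candidate")]
  if (length(cand) == 0) {
    vf_error("vf_no_profile",
             sprintf("no profile matches '%s'; file parked", raw$source_name),
             source_name = raw$source_name)
  }
  sat <- vapply(scored[cand], `[[`, numeric(1), "satisfied")
  best <- cand[sat == max(sat)]
  store$profiles[[sort(best)[1]]]
}

select_table <- function(raw, selector) {
  if (is.numeric(selector)) {
    vf_assert(selector >= 1 && selector <= length(raw$tables),
              "vf_conversion_error",
              sprintf("table %d not present (file has %d)", selector,
                      length(raw$tables)))
    return(raw$tables[[selector]])
  }
  nms <- vapply(raw$tables, `[[`, character(1), "name")
  i <- match(selector, nms)
  if (is.na(i)) i <- grep(selector, nms)[1]
  vf_assert(!is.na(i), "vf_conversion_error",
            sprintf("no table matching '%s' (tables: %s)", selector,
                    paste(nms, collapse = ", ")))
  raw$tables[[i]]
}

table_column <- function(tab, label) {
  i <- match(label, tab$columns$label)
  if (is.na(i)) {
    vf_error("vf_conversion_error",
             sprintf("column %s not found in table %s", label, tab$name),
             column = label, table = tab$name)
  }
  tab$rows[, i]
}

#' Extract the potential/current/time trace via a profile
#'
#' If the profile names no time column, time is synthesized as cumulative
#' `|dE| / scan_rate` when a scan rate is supplied, and as the bare sample
#' index otherwise.
#'
#' @param raw A [raw_file_model()].
#' @param profile A [conversion_profile()].
#' @param scan_rate Optional scan rate (V/s) for time synthesis.
#' @return A [cv_trace()].
#' @export
extract_trace <- function(raw, profile, scan_rate = NULL) {
  dm <- profile$data_map
  tab <- select_table(raw, dm$table)
  E <- table_column(tab, dm$x_column) * (dm$x_scale %||% 1)
  I <- table_column(tab, dm$y_column) * (dm$y_scale %||% 1)
  if (!is.null(dm$t_column)) {
    t <- table_column(tab, dm$t_column) * (dm$t_scale %||% 1)
    src <- "file"
  } else if (!is.null(scan_rate)) {
    t <- cumsum(c(0, abs(diff(E)))) / scan_rate
    src <- "synthesized"
  } else {
    t <- seq_along(E) - 1
    src <- "index"
  }
  cv_trace(t, E, I, time_source = src)
}

apply_transform <- function(value, transform) {
  if (is.null(transform) || identical(transform$type %||% "none", "none")) {
    return(value)
  }
  switch(transform$type,
         "scale" = {
           v <- suppressWarnings(as.numeric(value))
           if (is.na(v)) NA else v * transform$factor
         },
         "lookup" = transform$table[[as.character(value)]] %||% NA,
         vf_error("vf_config_error",
                  sprintf("unknown transform '%s'", transform$type)))
}

#' Map device metadata onto the CV scheme
#'
#' Header sources are copied (with their transform) under provenance
#' `"device"`. Computed sources (`computed:scan_rate`,
#' `computed:potential_window`, `computed:n_cycles`, ...) are derived from
#' the trace under provenance `"computed"`; they are also filled in by
#' default when the map leaves them open, which covers instruments whose
#' text output carries no mappable headers. Unresolved sources leave the
#' field missing and are recorded as validation warnings — the conversion
#' itself always succeeds.
#'
#' @param raw A [raw_file_model()].
#' @param profile A [conversion_profile()].
#' @param trace The extracted [cv_trace()].
#' @return A [metadata_record()] (device-extracted part) whose
#'   `"warnings"` attribute lists unresolved sources.
#' @export
map_metadata <- function(raw, profile, trace) {
  rec <- metadata_record()
  warnings <- character(0)

  sweeps <- tryCatch(segment_sweeps(trace), voltfair_error = function(e) list())
  cycles <- assemble_cycles(sweeps)
  n_full <- sum(!vapply(cycles, `[[`, logical(1), "partial"))
  nu <- tryCatch(infer_scan_rate(trace, sweeps),
                 voltfair_error = function(e) NA_real_)
  first_dir <- if (length(sweeps)) sweeps[[1]]$direction else "anodic"
  computed <- list(
    scan_rate = nu,
    n_cycles = if (length(cycles)) n_full else NA,
    potential_initial = trace$E[1],
    potential_final = trace$E[length(trace$E)],
    potential_vertex1 = if (first_dir == "anodic") max(trace$E) else min(trace$E),
    potential_vertex2 = if (first_dir == "anodic") min(trace$E) else max(trace$E),
    step_potential = stats::median(abs(diff(trace$E)))
  )

  mapped_targets <- character(0)
  for (entry in profile$metadata_map) {
    src <- entry$source
    target <- entry$target
    if (startsWith(src, "computed:")) {
      name <- sub("^computed:", "", src)
      if (identical(name, "potential_window")) {
        rec <- md_set(rec, "potential_vertex1", computed$potential_vertex1, "computed")
        rec <- md_set(rec, "potential_vertex2", computed$potential_vertex2, "computed")
        mapped_targets <- c(mapped_targets, "potential_vertex1", "potential_vertex2")
        next
      }
      val <- computed[[name]]
      if (is.null(val) || is.na(val)) {
        warnings <- c(warnings, sprintf("computed source '%s' unavailable", name))
        next
      }
      rec <- md_set(rec, target, val, "computed")
    } else {
      val <- header_value(raw, src)
      if (is.na(val)) {
        warnings <- c(warnings,
                      sprintf("header key '%s' not present (target %s)", src, target))
        next
      }
      val <- apply_transform(val, entry$transform)
      if (length(val) == 1 && is.na(val)) {
        warnings <- c(warnings,
                      sprintf("transform failed for header '%s' (target %s)",
                              src, target))
        next
      }
      num <- suppressWarnings(as.numeric(val))
      rec <- md_set(rec, target, if (!is.na(num)) num else val, "device")
    }
    mapped_targets <- c(mapped_targets, target)
  }

  # default-fill computed fields the map left open
  for (name in names(computed)) {
    val <- computed[[name]]
    if (name %in% mapped_targets || is.null(val) || is.na(val)) next
    if (!md_present(rec$fields[[name]])) {
      rec <- md_set(rec, name, val, "computed")
    }
  }
  if (is.na(nu)) warnings <- c(warnings, "scan rate could not be computed")
  attr(rec, "warnings") <- warnings
  rec
}
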