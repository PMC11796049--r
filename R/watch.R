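# Ingestion watcher: decide when an instrument output file is complete
# (its size has been stable for a delay window) and queue it exactly once
# for transfer into the pipeline inbox. Completeness uses size stability
# only — no OS file locks — for portability across instrument PCs.

#' Watcher configuration
#'
#' @param watch_dir Directory to monitor.
#' @param pattern Glob pattern for candidate files.
#' @param delay Stability window in seconds (default 300: the transfer
#'   must not happen before the experiment has finished writing).
#' @param mode `"file"`, `"folder"` or `"zipped-folder"`.
#' @param clock Injectable time source returning seconds (epoch); tests
#'   use a fake clock.
#' @param inbox Optional inbox directory files are copied to on queueing.
#' @return Object of class `watch_config`.
#' @export
watch_config <- function(watch_dir, pattern = "*", delay = 300,
                         mode = c("file", "folder", "zipped-folder"),
                         clock = function() as.numeric(Sys.time()),
                         inbox = NULL) {
  vf_assert(delay > 0, "vf_config_error", "delay must be > 0")
  structure(list(watch_dir = watch_dir, pattern = pattern, delay = delay,
                 mode = match.arg(mode), clock = clock, inbox = inbox),
            class = "watch_config")
}

#' Is a monitored file complete?
#'
#' A file is complete when its size has been stable for at least `delay`
#' seconds: some observation at least `delay` old already shows the
#' latest size, and every later observation shows that same size. A file
#' only just discovered, or one that grew within the window, is not
#' complete.
#'
#' @param observations Data frame with numeric columns `time` (seconds)
#'   and `size` (bytes), in any order.
#' @param delay Stability window in seconds.
#' @param now Current time (seconds).
#' @return `TRUE` or `FALSE`.
#' @export
file_is_complete <- function(observations, delay, now) {
  vf_assert(nrow(observations) >= 1, "vf_config_error", "no observations")
  obs <- observations[order(observations$time), , drop = FALSE]
  latest <- obs$size[nrow(obs)]
  anchor <- obs$time <= now - delay & obs$size == latest
  if (!any(anchor)) return(FALSE)
  t0 <- max(obs$time[anchor])
  all(obs$size[obs$time >= t0] == latest)
}

observed_size <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, recursive = TRUE, full.names = TRUE)
    sum(file.size(files), na.rm = TRUE)
  } else {
    file.size(path)
  }
}

unit_digest <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
    digest::digest(lapply(files, digest::digest, file = TRUE, algo = "sha256"),
                   algo = "sha256")
  } else {
    digest::digest(file = path, algo = "sha256")
  }
}

#' Scan the watch directory and queue completed units
#'
#' Candidate files (or directories, in the folder modes) are evaluated
#' with [file_is_complete()]; complete units are queued once, deduplicated
#' by path plus content digest. In `"zipped-folder"` mode a queued
#' directory is bundled into a single zip in the inbox.
#'
#' @param cfg A [watch_config()].
#' @param state Prior state (from the previous scan) or `NULL`.
#' @return List with `transfers` (data frame `path`, `key`, `delivered`)
#'   and `state` to pass to the next scan.
#' @export
scan_and_queue <- function(cfg, state = NULL) {
  vf_assert(dir.exists(cfg$watch_dir), "vf_config_error",
            sprintf("watch directory unreadable: %s", cfg$watch_dir))
  state <- state %||% list(observations = list(), queued = character(0))
  now <- cfg$clock()

  entries <- list.files(cfg$watch_dir, pattern = utils::glob2rx(cfg$pattern),
                        full.names = TRUE)
  is_dir <- dir.exists(entries)
  entries <- if (cfg$mode == "file") entries[!is_dir] else entries[is_dir]

  transfers <- data.frame(path = character(0), key = character(0),
                          delivered = character(0), stringsAsFactors = FALSE)
  for (path in entries) {
    obs <- state$observations[[path]] %||%
      data.frame(time = numeric(0), size = numeric(0))
    obs <- rbind(obs, data.frame(time = now, size = observed_size(path)))
    state$observations[[path]] <- obs
    if (!file_is_complete(obs, cfg$delay, now)) next
    key <- paste0(path, ":", unit_digest(path))
    if (key %in% state$queued) next
    state$queued <- c(state$queued, key)
    delivered <- NA_character_
    if (!is.null(cfg$inbox)) {
      dir.create(cfg$inbox, showWarnings = FALSE, recursive = TRUE)
      if (cfg$mode == "zipped-folder") {
        delivered <- file.path(cfg$inbox, paste0(basename(path), ".zip"))
        if (file.exists(delivered)) unlink(delivered)
        zip::zip(normalizePath(path.expand(delivered), mustWork = FALSE),
                 files = list.files(path, recursive = TRUE),
                 root = path, mode = "mirror")
      } else if (cfg$mode == "folder") {
        delivered <- file.path(cfg$inbox, basename(path))
        dir.create(delivered, showWarnings = FALSE)
        file.copy(list.files(path, full.names = TRUE), delivered,
                  recursive = TRUE, overwrite = TRUE)
      } else {
        delivered <- file.path(cfg$inbox, basename(path))
        file.copy(path, delivered, overwrite = TRUE)
      }
    }
    transfers <- rbind(transfers,
                       data.frame(path = path, key = key, delivered = delivered,
                                  stringsAsFactors = FALSE))
  }
  list(transfers = transfers, state = state)
}

#' Persist / restore watcher state as JSON
#'
#' @param state State list from [scan_and_queue()].
#' @param path JSON file path.
#' @return `path` (save) or the state list (load).
#' @export
save_watch_state <- function(state, path) {
  obs <- lapply(state$observations, function(df) {
    list(time = df$time, size = df$size)
  })
  write_text_file(jsonlite::toJSON(list(observations = obs,
                                        queued = state$queued),
                                   auto_unbox = FALSE, digits = NA),
                  path)
}

#' @rdname save_watch_state
#' @export
load_watch_state <- function(path) {
  if (!file.exists(path)) return(NULL)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  list(observations = lapply(doc$observations, function(o) {
    data.frame(time = o$time, size = o$size)
  }), queued = as.character(doc$queued))
}
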