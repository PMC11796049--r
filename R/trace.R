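# Trace / sweep / cycle containers and sweep segmentation.

#' Time-potential-current series of one CV measurement
#'
#' @param t Time in seconds, monotone non-decreasing (may be synthesized).
#' @param E Potential in volts.
#' @param I Current in amperes.
#' @param time_source How `t` was obtained: recorded in the file,
#'   synthesized from the potential program, or a bare sample index.
#' @return An object of class `cv_trace`.
#' @export
cv_trace <- function(t, E, I, time_source = c("file", "synthesized", "index")) {
  time_source <- match.arg(time_source)
  n <- length(E)
  vf_assert(n >= 4, "vf_config_error", "a trace needs at least 4 points")
  vf_assert(length(t) == n && length(I) == n, "vf_config_error",
            "t, E, I must have equal length")
  vf_assert(all(is.finite(t)) && all(is.finite(E)) && all(is.finite(I)),
            "vf_config_error", "trace values must be finite")
  vf_assert(!is.unsorted(t), "vf_config_error", "t must be non-decreasing")
  structure(list(t = as.numeric(t), E = as.numeric(E), I = as.numeric(I)),
            time_source = time_source, class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("<cv_trace> %d points, E in [%.4g, %.4g] V, t up to %.4g s (%s)\n",
              length(x$E), min(x$E), max(x$E), max(x$t), attr(x, "time_source")))
  invisible(x)
}

#' Segment a trace into monotone potential sweeps
#'
#' Boundaries are placed where the sign of `diff(E)` changes and the new
#' direction persists for at least `min_run` samples (points); shorter
#' excursions are treated as jitter and absorbed into the current sweep.
#' Zero-difference plateaus inherit the previous direction. Every trace
#' point belongs to exactly one sweep; the vertex sample closes the sweep
#' it ends.
#'
#' @param trace A [cv_trace()].
#' @param min_run Minimum number of samples a new direction must persist.
#' @return List of `cv_sweep` objects (`direction`, `points`, `index`,
#'   `range` of point indices into the trace).
#' @export
segment_sweeps <- function(trace, min_run = 3) {
  stopifnot(inherits(trace, "cv_trace"))
  E <- trace$E
  d <- sign(diff(E))
  if (all(d == 0)) {
    vf_error("vf_no_sweep", "trace potential is constant: no sweeps")
  }
  # plateaus inherit the previous direction; leading plateau takes the
  # first real direction
  first_dir <- d[which(d != 0)[1]]
  cur <- first_dir
  for (k in seq_along(d)) {
    if (d[k] == 0) d[k] <- cur else cur <- d[k]
  }

  # accept a direction change only if its run covers >= min_run points
  # (a run of m equal differences spans m + 1 samples)
  r <- rle(d)
  acc <- r$lengths + 1L >= min_run
  acc[1] <- TRUE
  eff <- numeric(length(r$values))
  cur <- r$values[1]
  for (k in seq_along(r$values)) {
    if (acc[k]) cur <- r$values[k]
    eff[k] <- cur
  }
  # group consecutive runs sharing an effective direction
  grp_of_run <- cumsum(c(1L, as.integer(diff(eff) != 0)))
  groups <- rep(grp_of_run, r$lengths)
  group_dir <- eff[!duplicated(grp_of_run)]
  g <- max(grp_of_run)

  n <- length(E)
  sweeps <- vector("list", g)
  start_pt <- 1L
  for (s in seq_len(g)) {
    last_int <- max(which(groups == s))
    end_pt <- if (s == g) n else last_int + 1L
    idx <- start_pt:end_pt
    sweeps[[s]] <- structure(
      list(direction = if (group_dir[s] > 0) "anodic" else "cathodic",
           points = list(t = trace$t[idx], E = trace$E[idx], I = trace$I[idx]),
           index = s,
           range = c(start_pt, end_pt)),
      class = "cv_sweep")
    start_pt <- end_pt + 1L
  }
  sweeps
}

#' @export
print.cv_sweep <- function(x, ...) {
  cat(sprintf("<cv_sweep> #%d %s, %d points, E %0.4g -> %0.4g V\n",
              x$index, x$direction, length(x$points$E),
              x$points$E[1], x$points$E[length(x$points$E)]))
  invisible(x)
}

#' Pair consecutive sweeps into cycles
#'
#' Consecutive sweep pairs (starting from the first sweep) form cycles;
#' an unpaired trailing sweep forms a partial cycle.
#'
#' @param sweeps List of `cv_sweep` objects from [segment_sweeps()].
#' @return List of `cv_cycle` objects (`ordinal`, `sweeps`, `partial`).
#' @export
assemble_cycles <- function(sweeps) {
  n <- length(sweeps)
  if (n == 0) return(list())
  n_full <- n %/% 2L
  cycles <- vector("list", ceiling(n / 2))
  for (k in seq_len(n_full)) {
    cycles[[k]] <- structure(list(ordinal = k,
                                  sweeps = sweeps[(2L * k - 1L):(2L * k)],
                                  partial = FALSE),
                             class = "cv_cycle")
  }
  if (n %% 2L == 1L) {
    cycles[[n_full + 1L]] <- structure(list(ordinal = n_full + 1L,
                                            sweeps = sweeps[n],
                                            partial = TRUE),
                                       class = "cv_cycle")
  }
  cycles
}

#' @export
print.cv_cycle <- function(x, ...) {
  cat(sprintf("<cv_cycle> #%d, %d sweep(s)%s\n", x$ordinal, length(x$sweeps),
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

#' Flatten a cycle to its point series
#'
#' @param cycle A `cv_cycle`.
#' @return List with `t`, `E`, `I` concatenated over the cycle's sweeps.
#' @export
cycle_points <- function(cycle) {
  list(t = unlist(lapply(cycle$sweeps, function(s) s$points$t)),
       E = unlist(lapply(cycle$sweeps, function(s) s$points$E)),
       I = unlist(lapply(cycle$sweeps, function(s) s$points$I)))
}

#' Infer the scan rate from a trace
#'
#' The scan rate is the median of `|dE/dt|` over consecutive in-sweep
#' sample pairs, reported to 3 significant figures. The median is robust
#' against vertex samples and dropped points.
#'
#' @param trace A [cv_trace()] with real time stamps.
#' @param sweeps Optional precomputed sweeps.
#' @return Scan rate in V/s.
#' @export
infer_scan_rate <- function(trace, sweeps = NULL) {
  stopifnot(inherits(trace, "cv_trace"))
  if (identical(attr(trace, "time_source"), "index")) {
    vf_error("vf_scan_rate_unavailable",
             "trace has no real time stamps; scan rate unavailable")
  }
  if (is.null(sweeps)) sweeps <- segment_sweeps(trace)
  rates <- unlist(lapply(sweeps, function(s) {
    dE <- diff(s$points$E)
    dt <- diff(s$points$t)
    keep <- dt > 0
    abs(dE[keep] / dt[keep])
  }))
  vf_assert(length(rates) > 0, "vf_scan_rate_unavailable",
            "no usable sample pairs to infer a scan rate")
  signif(stats::median(rates), 3)
}
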