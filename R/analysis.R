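# CV computation core: peak picking on sweeps, standardized descriptors
# (E1/2, dEp, ipa/ipc with optional Nicholson switching-current
# correction), per-curve CSV export, inline notation and plotting.

#' A picked CV peak
#'
#' @param E_p Peak potential in volts.
#' @param i_p Peak current in amperes.
#' @param kind `"anodic-max"` or `"cathodic-min"`.
#' @param origin `"auto"` or `"manual"`.
#' @return Object of class `cv_peak`.
#' @export
cv_peak <- function(E_p, i_p, kind = c("anodic-max", "cathodic-min"),
                    origin = c("auto", "manual")) {
  structure(list(E_p = E_p, i_p = i_p, kind = match.arg(kind),
                 origin = match.arg(origin)),
            class = "cv_peak")
}

#' @export
print.cv_peak <- function(x, ...) {
  cat(sprintf("<cv_peak> %s E_p=%s V i_p=%s A (%s)\n",
              x$kind, fmt6(x$E_p), fmt6(x$i_p), x$origin))
  invisible(x)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  # centred window, shrunk symmetrically at the edges
  half <- w %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Topographic prominence of a local maximum at index i: height above the
# higher of the two key saddles toward the nearest higher terrain (or the
# series ends).
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i
  while (j > 1 && y[j - 1] <= y[i]) {
    j <- j - 1
    if (y[j] < left_min) left_min <- y[j]
  }
  right_min <- y[i]
  j <- i
  while (j < n && y[j + 1] <= y[i]) {
    j <- j + 1
    if (y[j] < right_min) right_min <- y[j]
  }
  y[i] - max(left_min, right_min)
}

#' Pick peaks on a single sweep
#'
#' The current is smoothed with a centred moving average; local maxima
#' (anodic sweeps) or minima (cathodic sweeps) whose topographic
#' prominence reaches `min_prominence` of the sweep's current range are
#' kept. Peak coordinates are reported from the unsmoothed data at the
#' located index.
#'
#' @param sweep A `cv_sweep`.
#' @param smooth_window Odd moving-average window (samples).
#' @param min_prominence Minimum prominence as a fraction of the sweep's
#'   smoothed current range.
#' @param origin Origin tag attached to the peaks.
#' @return List of [cv_peak()] objects (possibly empty).
#' @export
pick_peaks <- function(sweep, smooth_window = 5, min_prominence = 0.05,
                       origin = "auto") {
  stopifnot(inherits(sweep, "cv_sweep"))
  vf_assert(smooth_window %% 2 == 1, "vf_config_error",
            "smooth_window must be odd")
  E <- sweep$points$E
  I <- sweep$points$I
  n <- length(I)
  vf_assert(n >= smooth_window, "vf_config_error",
            sprintf("sweep has %d points, shorter than smooth_window=%d",
                    n, smooth_window))
  anodic <- identical(sweep$direction, "anodic")
  y <- moving_average(I, smooth_window)
  if (!anodic) y <- -y
  rng <- max(y) - min(y)
  if (rng <= 1e-9 * max(abs(y), 1e-300)) return(list())  # flat within rounding

  cand <- which(diff(sign(diff(y))) < 0) + 1L  # strict rise before, fall after
  cand <- cand[vapply(cand, function(i) {
    peak_prominence(y, i) >= min_prominence * rng
  }, logical(1))]
  lapply(cand, function(i) {
    cv_peak(E_p = E[i], i_p = I[i],
            kind = if (anodic) "anodic-max" else "cathodic-min",
            origin = origin)
  })
}

#' Standardized descriptors of a redox couple
#'
#' `E1/2 = (E_pa + E_pc)/2`; `dEp = |E_pa - E_pc|` in mV. The peak-current
#' ratio is computed either directly from the zero-current line
#' (`mode = "direct"`, `|i_pa|/|i_pc|`) or with the Nicholson
#' switching-current correction (`mode = "nicholson"`):
#' `ratio = r0 + 0.485 s + 0.086` with `r0 = |i_rev,0|/|i_fwd,0|` (both
#' measured from the zero-current line) and `s = |i_lambda0|/|i_fwd,0|`,
#' where `i_lambda0` is the current at the switching potential, determined
#' graphically by the user. In Nicholson mode the ratio is the corrected
#' reverse-over-forward peak ratio.
#'
#' @param anodic Anodic [cv_peak()].
#' @param cathodic Cathodic [cv_peak()].
#' @param i_lambda0 Switching-potential current (A), user supplied.
#' @param mode `"direct"` (default) or `"nicholson"`.
#' @param forward Which sweep came first in the scan program.
#' @return Object of class `cv_descriptors`.
#' @export
compute_descriptors <- function(anodic, cathodic, i_lambda0 = 0,
                                mode = c("direct", "nicholson"),
                                forward = c("anodic", "cathodic")) {
  mode <- match.arg(mode)
  forward <- match.arg(forward)
  vf_assert(inherits(anodic, "cv_peak") && anodic$kind == "anodic-max",
            "vf_config_error", "anodic peak missing or of wrong kind")
  vf_assert(inherits(cathodic, "cv_peak") && cathodic$kind == "cathodic-min",
            "vf_config_error", "cathodic peak missing or of wrong kind")
  E_half <- (anodic$E_p + cathodic$E_p) / 2
  delta_Ep <- abs(anodic$E_p - cathodic$E_p) * 1000
  if (mode == "direct") {
    vf_assert(abs(cathodic$i_p) > 0, "vf_division_error",
              "cathodic peak current is zero")
    ratio <- abs(anodic$i_p) / abs(cathodic$i_p)
  } else {
    fwd <- if (forward == "anodic") anodic else cathodic
    rev <- if (forward == "anodic") cathodic else anodic
    vf_assert(abs(fwd$i_p) > 0, "vf_division_error",
              "forward peak current is zero")
    r0 <- abs(rev$i_p) / abs(fwd$i_p)
    s <- abs(i_lambda0) / abs(fwd$i_p)
    ratio <- r0 + 0.485 * s + 0.086
  }
  structure(list(E_pa = anodic$E_p, E_pc = cathodic$E_p,
                 i_pa = anodic$i_p, i_pc = cathodic$i_p,
                 i_lambda0 = i_lambda0,
                 E_half = E_half, delta_Ep = delta_Ep,
                 ratio = ratio, ratio_mode = mode, forward = forward),
            class = "cv_descriptors")
}

#' @export
print.cv_descriptors <- function(x, ...) {
  cat(sprintf("<cv_descriptors> E1/2 = %.3f V, dEp = %.1f mV, ipa/ipc (%s) = %.3f\n",
              x$E_half, x$delta_Ep, x$ratio_mode, x$ratio))
  invisible(x)
}

#' Export one curve's peaks and descriptors as CSV
#'
#' One header row, one row per peak, one descriptor summary row;
#' RFC 4180 quoting; units in the header labels.
#'
#' @param desc A [compute_descriptors()] result.
#' @param peaks List of [cv_peak()] objects.
#' @param meta Optional named list of metadata columns repeated per row.
#' @return CSV text.
#' @export
export_curve_csv <- function(desc, peaks, meta = list()) {
  headers <- c("record", "kind", "origin", "E (V)", "I (A)",
               "E1/2 (V)", "dEp (mV)", "ipa/ipc", "ratio_mode",
               "i_lambda0 (A)", names(meta))
  meta_cells <- vapply(meta, as.character, character(1))
  rows <- lapply(peaks, function(p) {
    c("peak", p$kind, p$origin, fmt6(p$E_p), fmt6(p$i_p),
      "", "", "", "", "", meta_cells)
  })
  summary_row <- c("descriptors", "", "", "", "",
                   fmt6(desc$E_half), fmt6(desc$delta_Ep), fmt6(desc$ratio),
                   desc$ratio_mode, fmt6(desc$i_lambda0), meta_cells)
  lines <- vapply(c(list(headers), rows, list(summary_row)),
                  function(r) paste(csv_quote(r), collapse = ","),
                  character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' One-line reporting notation for a CV result
#'
#' `CV (<solvent>, <electrolyte>, <scan rate in mV/s>): E1/2 = <V> V
#' (dEp = <mV> mV, ipa/ipc = <ratio>)`; missing metadata tokens are
#' elided.
#'
#' @param desc A [compute_descriptors()] result.
#' @param meta Optional [metadata_record()].
#' @return Single-line character string.
#' @export
inline_notation <- function(desc, meta = NULL) {
  toks <- character(0)
  if (!is.null(meta)) {
    solv <- md_get(meta, "solvent")
    if (!is.na(solv)) toks <- c(toks, as.character(solv))
    el <- md_get(meta, "supporting_electrolyte")
    if (!is.na(el)) {
      conc <- md_get(meta, "electrolyte_concentration")
      toks <- c(toks, if (!is.na(conc)) sprintf("%s mol/L %s", fmt6(as.numeric(conc)), el)
                else as.character(el))
    }
    nu <- md_get(meta, "scan_rate")
    if (!is.na(nu)) {
      toks <- c(toks, sprintf("%s mV s−1", fmt6(as.numeric(nu) * 1000)))
    }
  }
  head <- if (length(toks)) sprintf("CV (%s)", paste(toks, collapse = ", ")) else "CV"
  clause <- sprintf("ΔEp = %.0f mV", desc$delta_Ep)
  if (is.finite(desc$ratio)) {
    clause <- paste0(clause, sprintf(", ipa/ipc = %.2f", desc$ratio))
  }
  sprintf("%s: E1/2 = %.3f V (%s)", head, desc$E_half, clause)
}

#' Plot cycles as a combined PNG
#'
#' One polyline per selected cycle, potential on the x axis (V), current
#' on the y axis (A). With `selected = NULL` all cycles are plotted (the
#' "combined" picture); with an index set only those cycles are drawn
#' (the "new_combined" picture, which errors on an empty selection).
#'
#' @param cycles List of `cv_cycle` objects.
#' @param path Output PNG path.
#' @param selected Optional integer index set.
#' @param title Plot title.
#' @return `path`, invisibly.
#' @export
render_plot <- function(cycles, path, selected = NULL, title = "Cyclic voltammogram") {
  vf_assert(length(cycles) >= 1, "vf_config_error", "no cycles to plot")
  if (!is.null(selected)) {
    vf_assert(length(selected) >= 1, "vf_config_error",
              "empty cycle selection for plot")
    vf_assert(all(selected %in% seq_along(cycles)), "vf_config_error",
              "cycle selection out of range")
    cycles <- cycles[selected]
  }
  pts <- lapply(cycles, cycle_points)
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  xr <- range(unlist(lapply(pts, `[[`, "E")))
  yr <- range(unlist(lapply(pts, `[[`, "I")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "E / V", ylab = "I / A",
                 main = title)
  cols <- grDevices::hcl.colors(max(2L, length(pts)), "Dark 2")
  for (k in seq_along(pts)) {
    graphics::lines(pts[[k]]$E, pts[[k]]$I, col = cols[k])
  }
  graphics::legend("topleft", bty = "n", col = cols[seq_along(pts)], lty = 1,
                   legend = vapply(cycles, function(cy) {
                     sprintf("cycle %d", cy$ordinal)
                   }, character(1)))
  invisible(path)
}
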