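# Fixture builders used across the suite. Everything is generated in
# code; nothing is read from disk except what the tests themselves write.

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical 6-significant-digit formatting, independent of the package
fmt6 <- function(x) {
  out <- sprintf("%.6g", x)
  out[out == "-0"] <- "0"
  out
}

# ideal triangular potential program: n_cycles cycles, E0 -> Ev -> E0,
# step_mV per sample
triangle_E <- function(n_cycles = 1, lo = 0, hi = 0.2, step = 0.01) {
  up <- seq(lo + step, hi, by = step)
  down <- seq(hi - step, lo, by = -step)
  c(lo, rep(c(up, down), n_cycles))
}

make_trace <- function(E, rate = 0.1, I = NULL, time_source = "file") {
  t <- cumsum(c(0, abs(diff(E)))) / rate
  cv_trace(t, E, I %||% seq_along(E) * 1e-6, time_source = time_source)
}

gamry_fixture_lines <- function(nrows = 5, ncols = 3, n_tables = 1,
                                header = c(TAG = "CV", TITLE = "demo",
                                           SCANRATE = "0.1", PSTAT = "unit-1")) {
  hdr <- sprintf("%s\tLABEL\t%s", names(header), unname(header))
  tab <- function() {
    rows <- vapply(seq_len(nrows), function(i) {
      paste0("\t", paste(sprintf("%g", seq_len(ncols) * i / 10), collapse = "\t"))
    }, character(1))
    c(sprintf("CURVE\tTABLE\t%d", nrows),
      paste0("\t", paste(c("T", "Vf", "Im")[seq_len(ncols)], collapse = "\t")),
      paste0("\t", paste(c("s", "V", "A")[seq_len(ncols)], collapse = "\t")),
      rows)
  }
  c(hdr, unlist(replicate(n_tables, tab(), simplify = FALSE)))
}

write_gamry_fixture <- function(path, ...) {
  writeLines(gamry_fixture_lines(...), path)
  path
}

palmsens_fixture_lines <- function(delim = ",", decimal_comma = FALSE) {
  num <- function(x) {
    s <- sprintf("%g", x)
    if (decimal_comma) gsub(".", ",", s, fixed = TRUE) else s
  }
  rows <- vapply(0:5, function(i) {
    paste(num(i * 0.5), num(0.01 * i), num(1e-6 * i), sep = delim)
  }, character(1))
  c("method: CV", "instrument: PS-3", "scan_rate: 0.125",
    "",
    paste("time/s", "potential/V", "current/A", sep = delim),
    rows)
}

toy_cycle <- function(E = c(0, 0.1, 0.2, 0.3, 0.2, 0.1, 0, -0.1, 0),
                      I = seq_along(E) * 1e-6) {
  tr <- make_trace(E, I = I)
  assemble_cycles(segment_sweeps(tr))[[1]]
}

test_profile <- function(id = "gamry-cv", with_meta = TRUE) {
  conversion_profile(
    id,
    identifiers = list(
      list(scope = "filename", pattern = "\\.[Dd][Tt][Aa]$", required = TRUE),
      list(scope = "header", pattern = "^TAG=CV$", required = FALSE)),
    data_map = list(table = 1, x_column = "Vf", y_column = "Im", t_column = "T"),
    metadata_map = if (with_meta) {
      list(list(source = "SCANRATE", target = "scan_rate",
                transform = list(type = "scale", factor = 1)))
    } else list())
}

# small but physically meaningful simulation (2 cycles, coarse grid)
fast_sim <- function(...) {
  sim_preset("reversible-fast", ...)
}

strongest_peak <- function(peaks) {
  peaks[[which.max(vapply(peaks, function(p) abs(p$i_p), numeric(1)))]]
}

# independent digest oracle via a system tool
system_digest <- function(path, algo = c("sha256", "sha512")) {
  algo <- match.arg(algo)
  tool <- Sys.which(paste0(algo, "sum"))
  if (nzchar(tool)) {
    return(strsplit(system2(tool, shQuote(path), stdout = TRUE), " ")[[1]][1])
  }
  openssl <- Sys.which("openssl")
  if (nzchar(openssl)) {
    out <- system2(openssl, c("dgst", paste0("-", algo), shQuote(path)),
                   stdout = TRUE)
    return(sub(".*= ", "", out))
  }
  stop("no system digest tool available")
}

quiet <- function(expr) suppressMessages(expr)
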