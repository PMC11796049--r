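make_sweep <- function(E, I, direction = "anodic") {
  structure(list(direction = direction,
                 points = list(t = seq_along(E) - 1, E = E, I = I),
                 index = 1L, range = c(1L, length(E))),
            class = "cv_sweep")
}

test_that("a single symmetric bump is found at its centre", {
  E <- seq(0, 1, length.out = 101)
  I <- 1e-6 * exp(-((seq_len(101) - 50)^2) / 50)
  pk <- pick_peaks(make_sweep(E, I))
  expect_length(pk, 1)
  expect_equal(pk[[1]]$E_p, E[50])
  expect_identical(pk[[1]]$kind, "anodic-max")
  # coordinates come from the raw data
  expect_equal(pk[[1]]$i_p, I[50])
})

test_that("peak location matches the raw argmax oracle within one sample", {
  set.seed(11)
  p <- fast_sim(n_cycles = 1)
  tr <- simulate_cv(p)
  sw <- segment_sweeps(tr)[[1]]
  pk <- pick_peaks(sw)
  expect_gte(length(pk), 1)
  main <- pk[[which.max(vapply(pk, function(x) abs(x$i_p), numeric(1)))]]
  oracle_idx <- which.max(sw$points$I)
  found_idx <- which(sw$points$E == main$E_p & sw$points$I == main$i_p)[1]
  expect_lte(abs(found_idx - oracle_idx), 1)
})

test_that("flat sweeps yield no peaks and short sweeps error", {
  expect_identical(pick_peaks(make_sweep(seq(0, 1, length.out = 20),
                                         rep(1e-6, 20))), list())
  expect_error(pick_peaks(make_sweep(c(0, .1, .2), c(0, 1, 0) * 1e-6)),
               class = "vf_config_error")
})

test_that("cathodic sweeps yield cathodic minima only", {
  E <- seq(1, 0, length.out = 101)
  I <- -1e-6 * exp(-((seq_len(101) - 60)^2) / 50)
  pk <- pick_peaks(make_sweep(E, I, direction = "cathodic"))
  expect_length(pk, 1)
  expect_identical(pk[[1]]$kind, "cathodic-min")
  expect_lt(pk[[1]]$i_p, 0)
})

test_that("noise below the prominence threshold is ignored", {
  set.seed(3)
  E <- seq(0, 1, length.out = 201)
  I <- 1e-6 * exp(-((seq_len(201) - 100)^2) / 200) +
    stats::rnorm(201, 0, 5e-9)
  pk <- pick_peaks(make_sweep(E, I), smooth_window = 5, min_prominence = 0.05)
  expect_length(pk, 1)
})

test_that("descriptor arithmetic matches hand calculation", {
  an <- cv_peak(0.28, 1e-6, "anodic-max")
  ca <- cv_peak(0.22, -1e-6, "cathodic-min")
  d <- compute_descriptors(an, ca)
  expect_equal(d$E_half, 0.25)
  expect_equal(d$delta_Ep, 60)
  expect_equal(d$ratio, 1.0)   # symmetric peaks, any i_lambda0
  d2 <- compute_descriptors(an, ca, i_lambda0 = 5e-7)
  expect_equal(d2$ratio, 1.0)
})

test_that("nicholson correction follows the empirical relation", {
  # r0 = 0.5, s = 0.6 -> 0.5 + 0.485*0.6 + 0.086 = 0.877
  an <- cv_peak(0.28, 1e-6, "anodic-max")
  ca <- cv_peak(0.22, -0.5e-6, "cathodic-min")
  d <- compute_descriptors(an, ca, i_lambda0 = 0.6e-6, mode = "nicholson")
  expect_equal(d$ratio, 0.877)
  expect_identical(d$ratio_mode, "nicholson")
})

test_that("descriptor preconditions are enforced", {
  an <- cv_peak(0.28, 1e-6, "anodic-max")
  expect_error(compute_descriptors(an, an), class = "vf_config_error")
  ca0 <- cv_peak(0.22, 0, "cathodic-min")
  expect_error(compute_descriptors(an, ca0), class = "vf_division_error")
})

test_that("curve CSV has header, peak rows, summary row and round-trips", {
  an <- cv_peak(0.28, 1e-6, "anodic-max")
  ca <- cv_peak(0.22, -8e-7, "cathodic-min")
  d <- compute_descriptors(an, ca)
  csv <- export_curve_csv(d, list(an, ca))
  lines <- strsplit(csv, "\n")[[1]]
  expect_length(lines, 4)   # header + 2 peaks + summary
  df <- utils::read.csv(text = csv, check.names = FALSE)
  expect_equal(df$`E (V)`[1], 0.28)
  expect_equal(df$`E1/2 (V)`[3], 0.25)
  expect_equal(df$`dEp (mV)`[3], 60)

  empty <- export_curve_csv(d, list())
  expect_length(strsplit(empty, "\n")[[1]], 2)
})

test_that("inline notation includes metadata tokens and elides missing ones", {
  an <- cv_peak(0.28, 1e-6, "anodic-max")
  ca <- cv_peak(0.22, -1e-6, "cathodic-min")
  d <- compute_descriptors(an, ca)
  meta <- metadata_record(list(solvent = "MeCN",
                               supporting_electrolyte = "TBAPF6",
                               electrolyte_concentration = 0.1,
                               scan_rate = 0.1))
  s <- inline_notation(d, meta)
  expect_match(s, "E1/2 = 0.250 V (ΔEp = 60 mV", fixed = TRUE)
  expect_match(s, "MeCN", fixed = TRUE)
  expect_match(s, "100 mV", fixed = TRUE)
  expect_match(s, "ipa/ipc = 1.00", fixed = TRUE)

  no_solv <- inline_notation(d, metadata_record(list(scan_rate = 0.1)))
  expect_false(grepl("MeCN", no_solv))

  d$ratio <- NA_real_
  expect_false(grepl("ipa/ipc", inline_notation(d, meta)))
})

test_that("plot rendering writes decodable PNGs and honours selection", {
  p <- fast_sim(n_cycles = 3)
  cycles <- assemble_cycles(segment_sweeps(simulate_cv(p)))
  all_png <- withr::local_tempfile(fileext = ".png")
  sel_png <- withr::local_tempfile(fileext = ".png")
  render_plot(cycles, all_png)
  render_plot(cycles, sel_png, selected = 2)
  img1 <- png::readPNG(all_png)
  img2 <- png::readPNG(sel_png)
  expect_gte(length(dim(img1)), 2)
  expect_false(identical(img1, img2))
  expect_error(render_plot(cycles, sel_png, selected = integer(0)),
               class = "vf_config_error")
  expect_error(render_plot(list(), all_png), class = "vf_config_error")
})
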