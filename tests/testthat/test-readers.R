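test_that("gamry reader preserves header order and tables", {
  f <- withr::local_tempfile(fileext = ".DTA")
  write_gamry_fixture(f, nrows = 5, ncols = 3, n_tables = 1)
  raw <- read_gamry_dta(f)
  expect_s3_class(raw, "raw_file_model")
  expect_identical(raw$dialect_id, "gamry-dta")
  expect_equal(nrow(raw$header), 4)
  expect_identical(raw$header$key, c("TAG", "TITLE", "SCANRATE", "PSTAT"))
  expect_length(raw$tables, 1)
  expect_equal(nrow(raw$tables[[1]]$rows), 5)
  expect_identical(raw$tables[[1]]$columns$label, c("T", "Vf", "Im"))
  expect_identical(raw$tables[[1]]$columns$unit, c("s", "V", "A"))
})

test_that("multiple CURVE sections become tables in file order", {
  f <- withr::local_tempfile(fileext = ".DTA")
  write_gamry_fixture(f, n_tables = 2)
  raw <- read_gamry_dta(f)
  expect_length(raw$tables, 2)
  expect_identical(vapply(raw$tables, `[[`, character(1), "name"),
                   c("CURVE1", "CURVE2"))
})

test_that("malformed rows and empty files raise structured parse errors", {
  f <- withr::local_tempfile(fileext = ".DTA")
  lines <- gamry_fixture_lines(nrows = 3)
  lines[8] <- "\t0.1\t0.2"   # first data row: 2 cells under 3 columns
  writeLines(lines, f)
  err <- expect_error(read_gamry_dta(f), class = "vf_parse_error")
  expect_match(conditionMessage(err), "line 8")

  empty <- withr::local_tempfile(fileext = ".DTA")
  file.create(empty)
  expect_error(read_gamry_dta(empty), class = "vf_parse_error")
})

test_that("duplicate header keys are retained; lookup returns the first", {
  f <- withr::local_tempfile(fileext = ".DTA")
  write_gamry_fixture(f, header = c(NOTES = "first", NOTES = "second", TAG = "CV"))
  raw <- read_gamry_dta(f)
  expect_equal(sum(raw$header$key == "NOTES"), 2)
  expect_identical(header_value(raw, "NOTES"), "first")
})

test_that("palmsens reader parses prologue and one table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(palmsens_fixture_lines(), f)
  raw <- read_palmsens_csv(f)
  expect_identical(raw$dialect_id, "palmsens-csv")
  expect_equal(nrow(raw$header), 3)
  expect_length(raw$tables, 1)
  expect_identical(raw$tables[[1]]$columns$label,
                   c("time", "potential", "current"))
  expect_identical(raw$tables[[1]]$columns$unit, c("s", "V", "A"))
  expect_equal(nrow(raw$tables[[1]]$rows), 6)
})

test_that("delimiter variants and decimal commas yield identical models", {
  fc <- withr::local_tempfile(fileext = ".csv")
  fs <- withr::local_tempfile(fileext = ".csv")
  writeLines(palmsens_fixture_lines(delim = ","), fc)
  writeLines(palmsens_fixture_lines(delim = ";", decimal_comma = TRUE), fs)
  a <- read_palmsens_csv(fc)
  b <- read_palmsens_csv(fs)
  a$source_name <- b$source_name <- "x"
  expect_equal(a, b)
  expect_equal(b$tables[[1]]$rows[2, 1], 0.5)  # "0,5" parsed as 0.5
})

test_that("dialect detection uses extension plus first-line sniff", {
  g <- withr::local_tempfile(fileext = ".DTA")
  write_gamry_fixture(g)
  expect_identical(detect_reader(g), "gamry-dta")

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(palmsens_fixture_lines(), p)
  expect_identical(detect_reader(p), "palmsens-csv")

  u <- withr::local_tempfile(fileext = ".txt")
  file.create(u)
  err <- expect_error(detect_reader(u), class = "vf_unknown_dialect")
  expect_match(conditionMessage(err), "gamry-dta")
})

test_that("reading a BOM or Latin-1 file does not fail", {
  f <- withr::local_tempfile(fileext = ".DTA")
  con <- file(f, "wb")
  writeBin(as.raw(c(0xef, 0xbb, 0xbf)), con)
  writeLines(gamry_fixture_lines(), con)
  close(con)
  expect_identical(read_gamry_dta(f)$header$key[1], "TAG")

  l <- withr::local_tempfile(fileext = ".DTA")
  con <- file(l, "wb")
  writeBin(c(charToRaw("TITLE\tLABEL\tprobe "), as.raw(0xe4), charToRaw("\n")),
           con)
  writeLines(gamry_fixture_lines(), con)
  close(con)
  expect_identical(read_gamry_dta(l)$header$value[1], "probe ä")
})

test_that("fixture writer round-trips through the readers exactly", {
  E_prog <- triangle_E(2)
  tr <- make_trace(E_prog, rate = 0.1, I = sin(seq_along(E_prog)) * 1e-5)
  for (dialect in c("gamry-dta", "palmsens-csv")) {
    f <- withr::local_tempfile(fileext = if (dialect == "gamry-dta") ".DTA" else ".csv")
    write_fixture(tr, list(TAG = "CV"), dialect, f)
    raw <- read_instrument_file(f)
    expect_identical(raw$dialect_id, dialect)
    tab <- raw$tables[[1]]
    expect_equal(tab$rows[, 2], as.numeric(fmt6(tr$E)))
    expect_equal(tab$rows[, 3], as.numeric(fmt6(tr$I)))
    # re-writing the parsed content reproduces the file byte for byte
    tr2 <- cv_trace(tab$rows[, 1], tab$rows[, 2], tab$rows[, 3])
    f2 <- withr::local_tempfile()
    write_fixture(tr2, list(TAG = "CV"), dialect, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})
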