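local_gamry_raw <- function(...) {
  f <- withr::local_tempfile(fileext = ".DTA", .local_envir = parent.frame())
  write_gamry_fixture(f, ...)
  read_gamry_dta(f)
}

test_that("profiles require identifiers and data mapping", {
  expect_error(conversion_profile("p", list(), list(x_column = "E", y_column = "I")),
               class = "vf_config_error")
  expect_error(conversion_profile("p",
                                  list(list(scope = "filename", pattern = "x")),
                                  list(x_column = "E")),
               class = "vf_config_error")
  expect_error(profile_store(list(test_profile("a"), test_profile("a"))),
               class = "vf_config_error")
})

test_that("profile JSON documents round-trip through the store", {
  dir <- withr::local_tempdir()
  write_profile_json(test_profile("gamry-cv"), file.path(dir, "gamry.json"))
  store <- load_profile_store(dir)
  expect_length(store$profiles, 1)
  expect_identical(store$profiles[[1]]$profile_id, "gamry-cv")
  expect_identical(store$profiles[[1]]$data_map$x_column, "Vf")
})

test_that("matching picks the profile whose required identifiers fit", {
  raw <- local_gamry_raw()
  store <- profile_store(list(test_profile("gamry-cv")))
  expect_identical(match_profile(raw, store)$profile_id, "gamry-cv")

  other <- conversion_profile(
    "palmsens-cv",
    list(list(scope = "filename", pattern = "\\.csv$", required = TRUE)),
    list(table = 1, x_column = "potential", y_column = "current"))
  expect_error(match_profile(raw, profile_store(list(other))),
               class = "vf_no_profile")
})

test_that("the more specific candidate wins; remaining ties break by id", {
  raw <- local_gamry_raw()
  generic <- conversion_profile(
    "z-generic-dta",
    list(list(scope = "filename", pattern = "\\.[Dd][Tt][Aa]$", required = TRUE)),
    list(table = 1, x_column = "Vf", y_column = "Im"))
  specific <- test_profile("gamry-cv")   # also matches header TAG=CV
  got <- match_profile(raw, profile_store(list(generic, specific)))
  expect_identical(got$profile_id, "gamry-cv")

  twin <- conversion_profile(
    "a-generic-dta",
    list(list(scope = "filename", pattern = "\\.[Dd][Tt][Aa]$", required = TRUE)),
    list(table = 1, x_column = "Vf", y_column = "Im"))
  tie <- match_profile(raw, profile_store(list(generic, twin)))
  expect_identical(tie$profile_id, "a-generic-dta")
})

test_that("trace extraction maps columns and synthesizes time", {
  raw <- local_gamry_raw(nrows = 8)
  tr <- extract_trace(raw, test_profile())
  expect_s3_class(tr, "cv_trace")
  expect_length(tr$E, 8)
  expect_identical(attr(tr, "time_source"), "file")
  expect_identical(tr$E, raw$tables[[1]]$rows[, 2])

  no_t <- test_profile()
  no_t$data_map$t_column <- NULL
  tr2 <- extract_trace(raw, no_t, scan_rate = 0.1)
  expect_identical(attr(tr2, "time_source"), "synthesized")
  expect_equal(diff(tr2$t), abs(diff(tr2$E)) / 0.1)

  tr3 <- extract_trace(raw, no_t)
  expect_identical(attr(tr3, "time_source"), "index")
})

test_that("missing mapped columns raise a conversion error naming them", {
  raw <- local_gamry_raw()
  bad <- test_profile()
  bad$data_map$y_column <- "Missing"
  err <- expect_error(extract_trace(raw, bad), class = "vf_conversion_error")
  expect_match(conditionMessage(err), "column Missing not found")
})

test_that("a selector can address the second of two tables", {
  raw <- local_gamry_raw(n_tables = 2)
  p <- test_profile()
  p$data_map$table <- 2
  tr <- extract_trace(raw, p)
  expect_identical(tr$E, raw$tables[[2]]$rows[, 2])
  p$data_map$table <- "CURVE2"
  expect_identical(extract_trace(raw, p)$E, raw$tables[[2]]$rows[, 2])
})

test_that("header metadata maps with device provenance and transforms", {
  raw <- local_gamry_raw()
  tr <- extract_trace(raw, test_profile())
  rec <- map_metadata(raw, test_profile(), tr)
  expect_identical(md_get(rec, "scan_rate"), 0.1)
  expect_identical(rec$fields$scan_rate$provenance, "device")

  scaled <- test_profile()
  scaled$metadata_map <- list(list(source = "SCANRATE", target = "scan_rate",
                                   transform = list(type = "scale", factor = 1000)))
  rec2 <- map_metadata(raw, scaled, tr)
  expect_identical(md_get(rec2, "scan_rate"), 100)
})

test_that("computed metadata fills in when headers are absent", {
  # an instrument file with no mappable headers: metadata comes from the data
  tr <- make_trace(triangle_E(3, lo = -0.1, hi = 0.4, step = 0.002), rate = 0.05)
  raw <- raw_file_model("anon.DTA",
                        data.frame(key = character(0), value = character(0)),
                        list(), "gamry-dta")
  rec <- map_metadata(raw, test_profile(with_meta = FALSE), tr)
  expect_identical(rec$fields$scan_rate$provenance, "computed")
  expect_equal(md_get(rec, "scan_rate"), 0.05)
  expect_equal(md_get(rec, "n_cycles"), 3)
  expect_equal(md_get(rec, "potential_vertex1"), 0.4)
  expect_equal(md_get(rec, "potential_vertex2"), -0.1)
})

test_that("unresolvable sources produce warnings, never failures", {
  raw <- local_gamry_raw(header = c(TAG = "CV"))
  p <- test_profile()   # maps SCANRATE, which is absent
  tr <- extract_trace(raw, p)
  rec <- map_metadata(raw, p, tr)
  expect_true(any(grepl("SCANRATE", attr(rec, "warnings"))))
  # scan rate falls back to the computed value
  expect_identical(rec$fields$scan_rate$provenance, "computed")
})

test_that("simulator parameters are recovered exactly on noiseless output", {
  p <- fast_sim(n_cycles = 2)
  tr <- simulate_cv(p)
  raw <- raw_file_model("sim.DTA",
                        data.frame(key = character(0), value = character(0)),
                        list(), "gamry-dta")
  rec <- map_metadata(raw, test_profile(with_meta = FALSE), tr)
  expect_equal(md_get(rec, "scan_rate"), p$scan_rate)
  expect_equal(md_get(rec, "n_cycles"), p$n_cycles)
  expect_equal(md_get(rec, "potential_vertex1"), p$E_vertex1)
  expect_equal(md_get(rec, "potential_vertex2"), p$E_vertex2)
})
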