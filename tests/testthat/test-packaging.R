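fake_curve <- function(k = 1) {
  an <- cv_peak(0.03, 2e-5, "anodic-max")
  ca <- cv_peak(-0.03, -1.8e-5, "cathodic-min")
  list(peaks = list(an, ca), descriptors = compute_descriptors(an, ca))
}

read_workbook_sheets <- function(path) {
  dir <- tempfile("wb")
  zip::unzip(path, exdir = dir)
  wb <- xml2::read_xml(file.path(dir, "xl", "workbook.xml"))
  sheets <- xml2::xml_find_all(wb, ".//*[local-name()='sheet']")
  out <- xml2::xml_attr(sheets, "name")
  unlink(dir, recursive = TRUE)
  out
}

test_that("workbook sheet count is 2 + x and sheets are well-formed XML", {
  meta <- metadata_record(list(scan_rate = 0.1))
  for (x in c(1, 4)) {
    f <- withr::local_tempfile(fileext = ".xlsx")
    export_xlsx(lapply(seq_len(x), fake_curve), meta, f)
    sheets <- read_workbook_sheets(f)
    expect_length(sheets, 2 + x)
    expect_identical(sheets[1:2], c("Definitions", "Metadata"))
  }
  expect_error(export_xlsx(list(), meta, tempfile()), class = "vf_config_error")
})

test_that("the metadata sheet lists every scheme field including missing", {
  f <- withr::local_tempfile(fileext = ".xlsx")
  export_xlsx(list(fake_curve()), metadata_record(list(scan_rate = 0.1)), f)
  dir <- withr::local_tempdir()
  zip::unzip(f, exdir = dir)
  sheet2 <- xml2::read_xml(file.path(dir, "xl", "worksheets", "sheet2.xml"))
  rows <- xml2::xml_find_all(sheet2, ".//*[local-name()='row']")
  expect_length(rows, nrow(cv_metadata_scheme()) + 1)  # header + all fields
  txt <- paste(xml2::xml_text(sheet2), collapse = "")
  expect_match(txt, "scan_rate")
  expect_match(txt, "missing")   # unset fields carry their provenance
})

test_that("archive inventory is a pure function of curve count and flags", {
  # table-driven over every edited-flag combination for n <= 3
  for (n in 1:3) {
    flag_sets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    for (r in seq_len(nrow(flag_sets))) {
      edited <- as.logical(flag_sets[r, ])
      inv <- archive_inventory("demo", n, edited = edited)
      expect_equal(sum(inv$type == "a"), 6)
      # per curve: jdx + png + csv always; exactly one of peak/edit unless
      # picking produced nothing
      for (k in seq_len(n)) {
        curve_files <- inv$path[grepl(sprintf("-curve%d_", k), inv$path)]
        expect_length(curve_files, 4)
        expect_identical(sum(grepl("\\.peak\\.jdx$", curve_files)),
                         as.integer(!edited[k]))
        expect_identical(sum(grepl("\\.edit\\.jdx$", curve_files)),
                         as.integer(edited[k]))
      }
      # repeated calls are identical (pure function)
      expect_identical(inv, archive_inventory("demo", n, edited = edited))
    }
  }
})

test_that("unpicked curves omit the peak file; the dot dialect renames", {
  inv <- archive_inventory("d", 1, picked = FALSE)
  expect_false(any(grepl("peak", inv$path)))
  dot <- archive_inventory("d", 1, dialect = "dot")
  expect_true("d-curve1.bagit.peak.jdx" %in% dot$path)
})

test_that("dataset description has a 3-line header plus one line per file", {
  inv <- archive_inventory("demo", 2)
  f <- withr::local_tempfile()
  write_dataset_description(inv, "demo", f, created = "2026-01-01")
  lines <- readLines(f)
  expect_length(lines, 3 + nrow(inv))
  expect_identical(lines[1], "dataset_id: demo")
  expect_match(lines[4], "\t")
})

test_that("build_archive assembles exactly the inventory and errors when incomplete", {
  dir <- withr::local_tempdir()
  mk <- function(name, content = "x") {
    p <- file.path(dir, name)
    writeLines(content, p)
    p
  }
  png_path <- file.path(dir, "p.png")
  grDevices::png(png_path, width = 300, height = 300)
  plot(1)
  grDevices::dev.off()
  bag <- file.path(dir, "demo.bagit.zip")
  jdx <- mk("c1.jdx", write_cycle_jcamp(toy_cycle()))
  build_bagit(jdx, metadata_to_json(metadata_record()), bag)
  xlsx <- file.path(dir, "demo.xlsx")
  export_xlsx(list(fake_curve()), metadata_record(), xlsx)

  dataset <- list(
    name = "demo", original_file = mk("demo.DTA"), bag_zip = bag, xlsx = xlsx,
    combined_png = png_path, new_combined_png = png_path,
    curves = list(list(jdx = jdx, peak_jdx = mk("c1.peak.jdx"),
                       edited = FALSE, png = png_path, csv = mk("c1.csv"))))
  out <- file.path(dir, "demo.zip")
  layout <- build_archive(dataset, out, created = "2026-01-01")
  expect_true(file.exists(out))
  expect_setequal(zip::zip_list(out)$filename, layout$files$path)
  expect_true("demo-curve1_bagit.peak.jdx" %in% layout$files$path)
  expect_false(any(grepl("edit\\.jdx", layout$files$path)))

  # manual edit replaces the peak file
  dataset$curves[[1]]$edited <- TRUE
  dataset$curves[[1]]$edit_jdx <- mk("c1.edit.jdx")
  layout2 <- build_archive(dataset, out, created = "2026-01-01")
  expect_true("demo-curve1_bagit.edit.jdx" %in% layout2$files$path)
  expect_false(any(grepl("peak\\.jdx", layout2$files$path)))
  expect_setequal(zip::zip_list(out)$filename, layout2$files$path)

  dataset$xlsx <- NULL
  expect_error(build_archive(dataset, out), class = "vf_config_error")
})
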