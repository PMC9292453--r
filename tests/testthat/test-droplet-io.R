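test_that("well CSV round-trips through write and read", {
  w <- make_wells(c(0, 5, 120), c(18000, 20000, 21000))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wells(w, path)
  back <- read_wells(path)
  expect_equal(back$k_positive, w$k_positive)
  expect_equal(back$n_accepted, w$n_accepted)
  expect_equal(back$well_id, w$well_id)
  expect_equal(back$target, w$target)
})

test_that("readers enforce the droplet-well invariants and name offenders", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,target,n_accepted,k_positive",
               "A01,p190,20000,5"), path)
  w <- read_wells(path)
  expect_equal(w$k_positive, 5L)
  expect_equal(w$sample_id, "A01")  # defaulted

  writeLines(c("well_id,target,n_accepted,k_positive",
               "B02,p190,20,30"), path)
  expect_error(read_wells(path), "B02")
  expect_warning(w2 <- read_wells(path, permissive = TRUE), "B02")
  expect_equal(nrow(w2), 0)  # rejected rows are dropped, never kept silently

  writeLines(c("well_id,n_accepted,k_positive", "A01,20000,5"), path)
  expect_error(read_wells(path), "target")
})

test_that("plate layout merges metadata onto bare count files", {
  lay_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "run_id: run7",
    "wells:",
    "  A01: {sample_id: S1, target: p190, role: sample, replicate_group: g1}",
    "  A02: {sample_id: blank, target: p190, role: NTC, replicate_group: ntc}"
  ), lay_path)
  layout <- read_plate_layout(lay_path)
  expect_equal(layout$run_id, "run7")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,n_accepted,k_positive",
               "A01,20000,12", "A02,19000,0"), csv)
  w <- read_wells(csv, layout = layout)
  expect_equal(w$role, c("sample", "NTC"))
  expect_equal(w$sample_id, c("S1", "blank"))

  writeLines(c("well_id,n_accepted,k_positive", "Z99,20000,1"), csv)
  expect_error(read_wells(csv, layout = layout), "Z99")

  # same layout as JSON
  js_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    run_id = "run7",
    wells = list(A01 = list(sample_id = "S1", target = "p190",
                            role = "sample", replicate_group = "g1"))
  ), js_path, auto_unbox = TRUE)
  expect_equal(read_plate_layout(js_path)$wells$sample_id, "S1")
})

test_that("results tables round-trip to declared precision", {
  wells <- rbind(
    make_wells(c(4, 2), c(20000, 21000), sample_id = "S1"),
    make_wells(c(3000, 3100), c(20000, 20500), sample_id = "S1",
               target = "control_ABL1", well_id = c("C1", "C2")),
    make_wells(c(0, 0), c(20000, 20000), sample_id = "S2",
               well_id = c("T3", "T4")),
    make_wells(c(2900, 3000), c(20000, 20000), sample_id = "S2",
               target = "control_ABL1", well_id = c("C3", "C4"))
  )
  res <- quantify_wells(wells)
  expect_equal(res$mrd_class, c("POS", "NEG"))
  expect_equal(res$ratio[res$sample_id == "S2"], 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(back$ratio, signif(res$ratio, 6), tolerance = 1e-6)
  expect_equal(back$mrd_class, res$mrd_class)
  expect_equal(names(back), names(res))

  expect_error(write_results(res[0, ], path), "non-empty")
})

test_that("packaged follow-up cross-tab fixture totals 88 samples", {
  ct <- reference_crosstab()
  expect_equal(ct$n_total, 88L)
  expect_equal(unname(diag(ct$counts)), c(10L, 13L, 13L))
  expect_equal(unname(colSums(ct$counts)), c(10L, 54L, 24L))

  # fixture files round-trip through the plain-CSV readers
  dir <- withr::local_tempdir()
  out <- write_reference_fixtures(dir)
  expect_true(all(file.exists(out)))
  expect_equal(utils::read.csv(file.path(dir, "followup_crosstab.csv")),
               utils::read.csv(ddmrd_fixture("followup_crosstab.csv")))
})
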