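# Config-driven runs, report round-trips, figure output.

test_that("a configured run writes a report that round-trips with the same label", {
  out1 <- file.path(tempdir(), "mutdyn-run1")
  res <- runAnalysis(list(model = "case_1_1_1", fixture = "SC",
                          analyses = c("equilibria", "classify"),
                          grid_n = 11, outdir = out1), quiet = TRUE)
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "equilibria.csv")))
  rep <- readReport(file.path(out1, "report.json"))
  expect_identical(rep$outcome_label, "SC")
  expect_identical(rep$model, "case_1_1_1")
  # reruns of the same config are byte-identical
  b1 <- readBin(file.path(out1, "report.json"), "raw",
                file.size(file.path(out1, "report.json")))
  out2 <- file.path(tempdir(), "mutdyn-run2")
  runAnalysis(list(model = "case_1_1_1", fixture = "SC",
                   analyses = c("equilibria", "classify"),
                   grid_n = 11, outdir = out2), quiet = TRUE)
  b2 <- readBin(file.path(out2, "report.json"), "raw",
                file.size(file.path(out2, "report.json")))
  expect_identical(b1, b2)
})

test_that("config validation rejects bad parameters and unknown keys before computing", {
  expect_error(runAnalysis(list(model = "case_1_2",
                                params = list(b12 = -1),
                                outdir = tempdir()), quiet = TRUE),
               "b12")
  expect_error(runAnalysis(list(model = "case_1_1_1", bogus = 1,
                                outdir = tempdir()), quiet = TRUE),
               "unknown config keys: bogus")
  expect_error(runAnalysis(list(fixture = "SC", outdir = tempdir()),
                           quiet = TRUE),
               "requires a 'model'")
  expect_error(runAnalysis(list(model = "case_1_1_1",
                                analyses = "sweep",
                                outdir = tempdir()), quiet = TRUE),
               "sweep")
})

test_that("phase portraits are written as nonempty vector figures", {
  f <- tempfile(fileext = ".svg")
  renderPortrait("case_1_2", canonicalParams("case_1_2", "SC"),
                 box = c(0, 5), file = f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
  expect_error(renderPortrait("case_1_2", box = c(2, 2), file = f),
               "zero or negative area")
})

test_that("sweep tables serialize to CSV with one row per parameter value", {
  sw <- sweepParameter("case_1_1_1", list(r1 = 1, r2 = 1),
                       c("b12", "b21"), values = c(0.5, 2), grid_n = 11)
  f <- tempfile(fileext = ".csv")
  writeSweepCSV(sw, f)
  tab <- utils::read.csv(f)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("value", "label") %in% names(tab)))
})

test_that("strict mode turns a low-confidence classification into an error", {
  # a facultative pair analyzed over a tiny horizon leaves cells undecided
  expect_error(
    runAnalysis(list(model = "case_1_1_1", fixture = "SC",
                     analyses = "classify", grid_n = 11, t_max = 0.5,
                     strict = TRUE, outdir = tempdir()), quiet = TRUE),
    "low-confidence")
})
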