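test_that("feature tables round-trip through CSV", {
  ft <- tyrosol_features()
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  back <- read_feature_table(p)
  expect_equal(nrow(back), 2L)
  expect_equal(back$rt, ft$rt)
  expect_equal(back$mz, ft$mz)
  expect_equal(back$A, ft$A)
  expect_identical(sample_cols(back), "A")
})

test_that("retention times in seconds are normalized to minutes", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt,mz,S1", "580.2,322.0083,1e6"), p)
  ft <- read_feature_table(p, rt_unit = "sec")
  expect_equal(ft$rt, 580.2 / 60)
})

test_that("schema errors name the problem", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,S1", "322.0,1e6"), p)
  expect_error(read_feature_table(p), "retention-time")
  writeLines(c("rt,mz,S1", "1.0,322.0,5e5", "2.0,323.0,abc"), p)
  expect_error(read_feature_table(p), "row 3")
  writeLines("", p)
  expect_error(read_feature_table(p))
})

test_that("alignment-export dialect columns are recognized", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Alignment ID,Average Rt(min),Average Mz,S1,S2",
               "1,9.67,322.0083,1e6,2e6",
               "2,9.67,324.0063,0.97e6,1.9e6"), p)
  ft <- read_feature_table(p, dialect = "alignment_export")
  expect_equal(nrow(ft), 2L)
  expect_identical(sample_cols(ft), c("S1", "S2"))
  expect_equal(ft$mz[1], 322.0083)
})

test_that("MSP libraries round-trip and arrive sorted", {
  sp <- list(
    ms2_spectrum(322.0083, c(183.9393, 107.0488), c(100, 40),
                 rt = 9.67, title = "tyrosol"),
    ms2_spectrum(200.1, c(90, 60, 120), c(5, 10, 2), title = "x"))
  p <- withr::local_tempfile(fileext = ".msp")
  write_msp(sp, p)
  back <- read_spectra(p)
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mz, 322.0083, tolerance = 1e-6)
  expect_equal(back[[1]]$rt, 9.67, tolerance = 1e-4)
  # peaks sorted ascending regardless of input order
  expect_false(is.unsorted(back[[2]]$peaks[, "mz"]))
})

test_that("unparseable spectral records are skipped with a warning", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: good", "PrecursorMZ: 100.5", "Num Peaks: 1",
               "50.0 10", "",
               "Name: broken", "PrecursorMZ: 200.5", "Num Peaks: 1", ""), p)
  expect_warning(back <- read_spectra(p), "skipped")
  expect_length(back, 1L)
})

test_that("MGF blocks parse with retention time in seconds", {
  p <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=322.0083",
               "RTINSECONDS=580.2", "183.9393 100", "107.0488 40",
               "END IONS"), p)
  back <- read_spectra(p)
  expect_length(back, 1L)
  expect_equal(back[[1]]$rt, 580.2 / 60, tolerance = 1e-6)
  expect_equal(nrow(back[[1]]$peaks), 2L)
})

test_that("MS2 linking picks the closest precursor, one spectrum per feature", {
  feats <- data.frame(feature_id = c("a", "b"), rt = c(5, 5),
                      mz = c(322.0083, 322.0100), stringsAsFactors = FALSE)
  sp <- list(ms2_spectrum(322.0080, 100, 1, rt = 5))
  link <- link_ms2(feats, sp)
  expect_identical(link, c(1L, NA_integer_))  # closer m/z wins
  # out-of-tolerance precursor never links
  expect_true(all(is.na(link_ms2(feats, list(ms2_spectrum(322.10, 100, 1, rt = 5))))))
  # permutation of spectra does not change the assignment
  sp2 <- list(ms2_spectrum(330, 100, 1, rt = 5), sp[[1]])
  expect_identical(link_ms2(feats, sp2)[1], 2L)
})

test_that("compound databases fill sites and formulas from structures", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,smiles",
               "tyrosol,C8H10O2,OCCc1ccc(O)cc1",
               "mystery,C5H12O,",
               "tyrosol,C8H10O2,OCCc1ccc(O)cc1"), p)
  db <- read_compound_db(p)
  expect_equal(nrow(db), 3L)                  # duplicates kept
  expect_equal(db$n_sites[1], 2L)             # from SMILES
  expect_equal(db$n_sites[2], 1L)             # config default
  # records without any mass information are dropped with a warning
  writeLines(c("name,formula,smiles", "ghost,,"), p)
  expect_warning(db2 <- read_compound_db(p), "dropped")
  expect_equal(nrow(db2), 0L)
  # formula derived from SMILES when absent
  writeLines(c("name,formula,smiles", "ethanol,,CCO"), p)
  db3 <- read_compound_db(p)
  expect_identical(db3$formula, "C2H6O")
})
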