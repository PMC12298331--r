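test_that("site counting follows the acylation chemistry", {
  sc <- count_sites(c("OCCc1ccc(O)cc1", "OCC(=O)O", "c1ccccc1", "NCCO"))
  expect_equal(sc$n_sites, c(2L, 1L, 0L, 2L))
  expect_equal(sc$n_aliphatic_oh[1], 1L)
  expect_equal(sc$n_phenolic_oh[1], 1L)
  expect_equal(sc$n_aliphatic_oh[2], 1L)  # carboxyl OH excluded
  expect_equal(sc$n_primary_amine[4], 1L)
  # amide NH is not derivatizable
  expect_equal(count_sites("CC(=O)NC")$n_sites, 0L)
  expect_error(count_sites("C("), "invalid SMILES")
})

test_that("candidate m/z enumeration follows the tag arithmetic", {
  rec <- data.frame(name = "tyrosol", formula = "C8H10O2",
                    smiles = "OCCc1ccc(O)cc1", n_sites = 2L,
                    ref_rt = 9.67, source = "db", standard = FALSE,
                    stringsAsFactors = FALSE)
  cm <- candidate_mzs(rec, max_tags = 2)
  expect_equal(nrow(cm), 2L)
  expect_equal(round(cm$mz[cm$n_tags == 1], 4), 322.0073)
  expect_equal(round(cm$mz[cm$n_tags == 2], 4), 504.9393)
  rec$n_sites <- 0L
  expect_equal(nrow(candidate_mzs(rec)), 0L)
})

tyrosol_db <- function(ref_rt = 9.67, standard = FALSE) {
  db <- data.frame(name = "tyrosol", formula = "C8H10O2",
                   smiles = "OCCc1ccc(O)cc1", n_sites = 2L,
                   ref_rt = ref_rt, source = "db", standard = standard,
                   stringsAsFactors = FALSE)
  class(db) <- c("compound_db", "data.frame")
  db
}

tyrosol_ms2 <- function() {
  ms2_spectrum(322.0083,
               c(183.9390, 201.9482, 155.9440, 107.0488, 103.0535),
               c(100, 60, 20, 40, 30), rt = 9.67, title = "tyrosol")
}

test_that("the tyrosol pair walks the confidence ladder with its evidence", {
  pair <- find_pairs(tyrosol_features())
  sp <- tyrosol_ms2()
  # full evidence incl. authentic standard: level 1
  a1 <- annotate_pair(pair, tyrosol_db(standard = TRUE),
                      ref_spectra = list(tyrosol = sp), pair_spectrum = sp)
  expect_equal(a1$level[1], 1L)
  expect_true(a1$standard_confirmed[1])
  # database rt + MS1 + MS2, no standard: level 2
  a2 <- annotate_pair(pair, tyrosol_db(),
                      ref_spectra = list(tyrosol = sp), pair_spectrum = sp)
  expect_equal(a2$level[1], 2L)
  # rt + MS1 only: level 3
  a3 <- annotate_pair(pair, tyrosol_db())
  expect_equal(a3$level[1], 3L)
  # MS1 only: level 4
  a4 <- annotate_pair(pair, tyrosol_db(ref_rt = NA_real_))
  expect_equal(a4$level[1], 4L)
  # nothing in the database: level 5 formula fallback contains the truth
  empty_db <- tyrosol_db()[0, , drop = FALSE]
  a5 <- annotate_pair(pair, empty_db,
                      formula_bounds = list(C = 20, H = 30, N = 3, O = 6))
  expect_true(nrow(a5) >= 1L)
  expect_true(all(a5$level == 5L))
  expect_true("C14H12BrNO3" %in% a5$formula)
})

test_that("evidence levels are monotone in available evidence", {
  # observed levels for nested evidence sets must be non-increasing in
  # evidence: standard+all <= rt+ms2 <= rt <= none
  pair <- find_pairs(tyrosol_features())
  sp <- tyrosol_ms2()
  lv <- c(
    annotate_pair(pair, tyrosol_db(standard = TRUE),
                  ref_spectra = list(tyrosol = sp), pair_spectrum = sp)$level[1],
    annotate_pair(pair, tyrosol_db(),
                  ref_spectra = list(tyrosol = sp), pair_spectrum = sp)$level[1],
    annotate_pair(pair, tyrosol_db())$level[1],
    annotate_pair(pair, tyrosol_db(ref_rt = NA_real_))$level[1])
  expect_identical(lv, c(1L, 2L, 3L, 4L))
})

test_that("out-of-tolerance candidates are excluded entirely", {
  pair <- find_pairs(tyrosol_features())
  pair$mz_light <- pair$mz_light * (1 + 11e-6)  # push past 10 ppm
  pair$mz_heavy <- pair$mz_heavy * (1 + 11e-6)
  ann <- annotate_pair(pair, tyrosol_db(),
                       formula_bounds = list(C = 10, H = 10, N = 0, O = 2))
  expect_false("tyrosol" %in% ann$name)
  # an rt deviation beyond 0.5 min blocks the rt evidence (level 4, not 3)
  a <- annotate_pair(pair <- find_pairs(tyrosol_features()),
                     tyrosol_db(ref_rt = 10.5))
  expect_equal(a$level[1], 4L)
})

test_that("claimed evidence always satisfies the level thresholds", {
  qs <- quick_sim(n_compounds = 12, n_decoys = 30, seed = 17,
                  ratio_noise_sigma = 0, mz_noise_ppm = 0)
  pr <- find_pairs(qs$run$features)
  ann <- annotate_all(pr, qs$db)
  thr <- match_thresholds()
  for (i in seq_len(nrow(ann))) {
    if (ann$level[i] <= 4) expect_lt(abs(ann$ms1_ppm_obs[i]), thr$ms1_ppm)
    if (ann$level[i] <= 3) expect_lt(ann$rt_dev_obs[i], thr$rt_dev)
    if (ann$level[i] <= 2) expect_gt(ann$ms2_score_obs[i], thr$ms2_score)
  }
})

test_that("cohort annotation recovers identities and ranks alternatives", {
  qs <- quick_sim(n_compounds = 25, n_decoys = 60, seed = 23,
                  ratio_noise_sigma = 0, mz_noise_ppm = 0)
  pr <- find_pairs(qs$run$features)
  ann <- suppressMessages(annotate_all(pr, qs$db))
  best <- ann[ann$best, , drop = FALSE]
  expect_equal(nrow(best), nrow(pr))
  expect_true(all(best$level == 3L))  # rt known, no MS2 refs
  expect_gte(mean(best$name %in% qs$run$truth$name), 0.95)
  # withholding rt drops everything to level 4
  db4 <- qs$db; db4$ref_rt <- NA_real_
  ann4 <- suppressMessages(annotate_all(pr, db4))
  expect_true(all(ann4$level[ann4$best] == 4L))
  # duplicate database entries rank by (level, |ppm|)
  dupdb <- rbind(qs$db, qs$db)
  dupdb$source[seq_len(nrow(qs$db))] <- "other"
  ann_dup <- suppressMessages(annotate_all(pr[1, , drop = FALSE], dupdb))
  expect_gte(nrow(ann_dup), 2L)
  expect_true(!is.unsorted(ann_dup$level))
})
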