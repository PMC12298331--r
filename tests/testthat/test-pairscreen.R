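test_that("the observed tyrosol doublet is reported as one pair", {
  pr <- find_pairs(tyrosol_features())
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$ratio, 0.97, tolerance = 1e-6)
  expect_equal(pr$n_tags, 1L)
  expect_equal(pr$mz_light, 322.0083)
})

test_that("the ratio window and co-elution requirement reject impostors", {
  expect_equal(nrow(find_pairs(tyrosol_features(ratio = 0.50))), 0L)
  expect_equal(nrow(find_pairs(tyrosol_features(ratio = 1.25))), 0L)
  expect_equal(nrow(find_pairs(tyrosol_features(rt_heavy = 9.90))), 0L)
  # boundary: ratio exactly at the window edge is accepted
  expect_equal(nrow(find_pairs(tyrosol_features(ratio = 0.8))), 1L)
})

test_that("a 2-bromine doublet is not reported as a single-tag pair", {
  # M / M+2 of a two-bromine ion: intensity ratio 2q/p = 1.9456, outside
  # the 0.8-1.2 single-tag window
  ft <- tyrosol_features(ratio = expected_ratio(2, 1))
  expect_equal(nrow(find_pairs(ft)), 0L)
  # the multi-tag search (n_tags = 2 spacing + binomial ratio window)
  # does find the M / M+4 doublet of a double-tagged derivative
  ft2 <- data.frame(feature_id = c("L", "H"), rt = c(5, 5),
                    mz = c(500, br_shift(500, 2)),
                    A = c(1e6, expected_ratio(2, 2) * 1e6))
  attr(ft2, "sample_cols") <- "A"
  class(ft2) <- c("feature_table", "data.frame")
  pr2 <- find_pairs(ft2, pair_config(n_tags_max = 2))
  expect_equal(nrow(pr2), 1L)
  expect_equal(pr2$n_tags, 2L)
})

test_that("noise-free planted pairs are recovered perfectly", {
  qs <- quick_sim(n_compounds = 20, n_decoys = 100,
                  ratio_noise_sigma = 0, mz_noise_ppm = 0, seed = 42)
  pr <- find_pairs(qs$run$features)
  sc <- scorecard(pr, qs$run$truth)
  expect_identical(sc$recall, 1)
  expect_identical(sc$precision, 1)
})

test_that("pair finding is invariant under feature permutation", {
  qs <- quick_sim(seed = 13)
  ft <- qs$run$features
  set.seed(1)
  perm <- ft[sample(nrow(ft)), , drop = FALSE]
  attr(perm, "sample_cols") <- sample_cols(ft)
  class(perm) <- class(ft)
  a <- find_pairs(ft); b <- find_pairs(perm)
  key <- function(x) x[order(x$rt, x$mz_light),
                       c("rt", "mz_light", "mz_heavy", "ratio")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("widening tolerances never loses pairs", {
  qs <- quick_sim(n_compounds = 15, n_decoys = 80, seed = 31,
                  ratio_noise_sigma = 0.1, mz_noise_ppm = 8)
  n_narrow <- nrow(find_pairs(qs$run$features, pair_config(tol_ppm = 5)))
  n_wide <- nrow(find_pairs(qs$run$features, pair_config(tol_ppm = 20)))
  expect_gte(n_wide, n_narrow)
  n_tight <- nrow(find_pairs(qs$run$features,
                             pair_config(ratio_low = 0.9, ratio_high = 1.05)))
  n_loose <- nrow(find_pairs(qs$run$features,
                             pair_config(ratio_low = 0.7, ratio_high = 1.4)))
  expect_gte(n_loose, n_tight)
})

test_that("deduplication merges coinciding pairs transitively", {
  base <- find_pairs(tyrosol_features())
  # chain A ~ B ~ C: A-B and B-C within tolerance, A-C not
  mk <- function(shift_ppm, inten) {
    p <- base
    p$mz_light <- p$mz_light * (1 + shift_ppm / 1e6)
    p$intensity_light <- inten
    p
  }
  chain <- rbind(mk(0, 5), mk(8, 9), mk(16, 7))
  class(chain) <- c("br_pairs", "data.frame")
  merged <- dedupe_pairs(chain, mz_tol_ppm = 10, rt_tol = 0.05)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$intensity_light, 9)  # most intense representative
  # disjoint pairs survive untouched
  far <- rbind(mk(0, 5), mk(500, 9))
  class(far) <- c("br_pairs", "data.frame")
  expect_equal(nrow(dedupe_pairs(far)), 2L)
})

test_that("blank filtering applies a >= fold rule", {
  pr <- find_pairs(tyrosol_features())  # intensity_light = 1e6
  blank_at <- function(b) {
    bf <- data.frame(feature_id = "B", rt = 9.67, mz = 322.0083, blank = b)
    attr(bf, "sample_cols") <- "blank"
    class(bf) <- c("feature_table", "data.frame")
    bf
  }
  expect_equal(nrow(blank_filter(pr, blank_at(0))), 1L)        # blank-free kept
  expect_equal(nrow(blank_filter(pr, blank_at(1e6 / 1.2))), 0L) # fold 1.2 removed
  expect_equal(nrow(blank_filter(pr, blank_at(1e6 / 3))), 1L)  # fold exactly 3 kept
})

test_that("screening tolerates realistic ratio and mass noise", {
  cfg <- sim_config(n_compounds = 50, n_decoys = 500,
                    ratio_noise_sigma = 0.05, mz_noise_ppm = 5, seed = 7)
  run <- simulate_features(simulate_compounds(cfg), cfg)
  sc <- scorecard(dedupe_pairs(find_pairs(run$features)), run$truth)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})
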