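test_that("formula parsing round-trips and rejects garbage", {
  expect_equal(unclass(parse_formula("C8H10O2"))[c("C", "H", "O")],
               c(C = 8L, H = 10L, O = 2L))
  expect_equal(unclass(parse_formula("C6H2BrNO"))[c("C", "H", "Br", "N", "O")],
               c(C = 6L, H = 2L, Br = 1L, N = 1L, O = 1L))
  # canonical Hill round-trip
  for (f in c("C8H10O2", "C14H12BrNO3", "C6H5BrN2O"))
    expect_identical(format_formula(parse_formula(f)), f)
  expect_identical(format_formula(parse_formula("OC2H6")), "C2H6O")
  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C8H10O2!"), "malformed")
})

test_that("monoisotopic masses match reference values", {
  expect_equal(monoisotopic_mass(parse_formula("C8H10O2")), 138.0681,
               tolerance = 1e-4)
  # reagent diagnostic ions, electron-corrected
  expect_equal(round(monoisotopic_mass("C6H3BrNO", charge = 1), 4), 183.9393)
  tc <- tag_constants()
  expect_equal(round(tc$frag_acylium_mz, 4), 183.9393)
  expect_equal(round(tc$frag_hydroxyl_mz, 4), 201.9498)
  expect_equal(round(tc$frag_amino_mz, 4), 200.9658)
})

test_that("monoisotopic mass is additive over random formula pairs", {
  set.seed(11)
  for (i in 1:50) {
    a <- random_formula(); b <- random_formula()
    expect_equal(monoisotopic_mass(add_formulas(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
})

test_that("derivatization arithmetic adds C6H2BrNO per site", {
  expect_identical(format_formula(derivatize_formula("C8H10O2", 1)),
                   "C14H12BrNO3")
  expect_identical(format_formula(derivatize_formula("C3H8O3", 3)),
                   "C21H14Br3N3O6")
  # derivatized tyrosol [M+H]+ within 10 ppm of the observed 322.0083
  mh <- monoisotopic_mass(derivatize_formula("C8H10O2", 1)) +
    adduct("[M+H]+")$mass_shift
  expect_equal(round(mh, 4), 322.0073)
  expect_lt(abs(ppm_error(322.0083, mh)), 10)
  expect_error(derivatize_formula("C8H10O2", 0), "positive")
})

test_that("bromine isotope shift reproduces the observed pair spacing", {
  tc <- tag_constants()
  expect_equal(round(tc$br_delta, 3), 1.998)
  expect_equal(round(br_shift(322.0083, 1), 4), 324.0063)
  expect_identical(br_shift(500, 0), 500)
  expect_equal(round(br_shift(200, 2), 4), 203.9959)
  # two single shifts equal one double shift, exactly
  expect_identical(br_shift(br_shift(150, 1), 1), br_shift(150, 2))
})

test_that("isotopologue ratios follow the bromine binomial", {
  expect_equal(round(expected_ratio(1, 1), 4), 0.9728)
  expect_identical(expected_ratio(3, 0), 1)
  expect_equal(round(expected_ratio(2, 1), 4), 1.9456)
  expect_error(expected_ratio(1, 2), "exceed")
  # binomial normalization: sum_k ratio(n,k) * p^n = 1
  p <- 0.5069
  for (n in 1:4) {
    s <- sum(vapply(0:n, function(k) expected_ratio(n, k), numeric(1)))
    expect_equal(s * p^n, 1, tolerance = 1e-12)
  }
})

test_that("ppm error is plain relative arithmetic", {
  expect_equal(ppm_error(322.0083, 322.0073), 3.105, tolerance = 1e-3)
  expect_identical(ppm_error(250, 250), 0)
  expect_equal(ppm_error(100.0011, 100.0001), 10, tolerance = 1e-3)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("formula generation finds the derivatized tyrosol composition", {
  g <- generate_formulas(321.0001, 10, n_br = 1,
                         bounds = list(C = 20, H = 30, N = 3, O = 6))
  expect_true("C14H12BrNO3" %in% g$formula)
  g2 <- generate_formulas(16.0313, 5, n_br = 0,
                          bounds = list(C = 2, H = 6, N = 1, O = 1))
  expect_true("CH4" %in% g2$formula)
  expect_identical(nrow(generate_formulas(1.0, 1, n_br = 1,
                                          bounds = list(C = 5, H = 10))), 0L)
})

test_that("formula generation agrees with a brute-force enumeration", {
  # independent oracle: exhaustive quadruple loop incl. hydrogen
  brute <- function(target, tol_ppm, n_br, bC, bH, bN, bO) {
    am <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
            O = 15.9949146196, Br = 78.9183376)
    hits <- character(0)
    for (nC in 0:bC) for (nH in 0:bH) for (nN in 0:bN) for (nO in 0:bO) {
      m <- nC * am["C"] + nH * am["H"] + nN * am["N"] + nO * am["O"] +
        n_br * am["Br"]
      if (m <= 0 || abs(m - target) > target * tol_ppm / 1e6) next
      r <- 1 + nC - (nH + n_br) / 2 + nN / 2
      if (r < 0 || abs(r - round(r)) > 1e-9) next
      cnt <- c(C = nC, H = nH, N = nN, O = nO, Br = n_br)
      hits <- c(hits, format_formula(as_element_counts(cnt[cnt > 0])))
    }
    sort(unique(hits))
  }
  set.seed(5)
  for (i in 1:20) {
    target <- runif(1, 60, 260)
    nbr <- sample(0:1, 1)
    got <- generate_formulas(target, 20, n_br = nbr,
                             bounds = list(C = 12, H = 24, N = 2, O = 4))
    expect_identical(sort(got$formula),
                     brute(target, 20, nbr, 12, 24, 2, 4),
                     info = sprintf("mass %.4f nbr %d", target, nbr))
  }
})

test_that("constants export as JSON", {
  js <- constants_json()
  obj <- jsonlite::fromJSON(js)
  expect_equal(round(obj$tag$br_delta, 3), 1.998)
  expect_equal(round(obj$tag$frag_acylium_mz, 4), 183.9393)
})
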