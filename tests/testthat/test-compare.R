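test_that("presence intersections count shared and unique compounds", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 1, 1), C = c(0, 0, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  groups <- c("g1", "g1", "g2", "g2")
  out <- presence_intersections(m, groups)
  expect_equal(out$shared_all, 1L)                       # B in both
  expect_equal(unname(out$per_group), c(2L, 2L))
  expect_equal(sum(out$intersections$count), 3L)         # all compounds
  # identical groups: everything shared
  m2 <- rbind(A = c(1, 1), B = c(2, 2))
  out2 <- presence_intersections(m2, c("x", "y"))
  expect_equal(out2$shared_all, 2L)
  expect_error(presence_intersections(m, rep("g1", 4)), "2 groups")
})

test_that("intersections match a planted overlap construction", {
  qs <- quick_sim(n_compounds = 30, n_decoys = 0, seed = 12,
                  n_groups = 2, replicates_per_group = 3)
  run <- qs$run
  li <- match(run$truth$light_feature_id, run$features$feature_id)
  mat <- as.matrix(as.data.frame(run$features)[li, sample_cols(run$features)])
  rownames(mat) <- run$truth$name
  # zero out 5 compounds in group 2 only
  g2 <- names(run$groups)[run$groups == "G2"]
  mat[1:5, g2] <- 0
  out <- presence_intersections(mat, run$groups[colnames(mat)])
  expect_equal(out$shared_all, 25L)
  expect_equal(unname(out$per_group["G1"]), 30L)
  expect_equal(unname(out$per_group["G2"]), 25L)
})

test_that("Welch p values agree with the closed form", {
  set.seed(3)
  welch_p <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(y) - mean(x)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  m <- matrix(rlnorm(40 * 12, 10, 0.5), nrow = 40,
              dimnames = list(paste0("c", 1:40), NULL))
  groups <- rep(c("a", "b"), each = 6)
  res <- pairwise_diff(m, groups, "a", "b")
  pseudo <- min(m) / 2
  lm2 <- log2(m + pseudo)
  for (i in c(1, 7, 40))
    expect_equal(res$p[i], welch_p(lm2[i, 1:6], lm2[i, 7:12]),
                 tolerance = 1e-10)
  # BH q values are monotone in p rank
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= res$p))
})

test_that("identical groups yield no significant compounds", {
  m <- matrix(rep(rlnorm(30, 10, 0.3), 8), nrow = 30)
  groups <- rep(c("a", "b"), each = 4)
  res <- pairwise_diff(m, groups, "a", "b")
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("null simulation holds the nominal type-I rate", {
  cfg <- sim_config(n_compounds = 200, n_decoys = 0, n_groups = 2,
                    replicates_per_group = 6, seed = 19)
  run <- simulate_features(simulate_compounds(cfg), cfg)
  li <- match(run$truth$light_feature_id, run$features$feature_id)
  mat <- as.matrix(as.data.frame(run$features)[li, sample_cols(run$features)])
  rownames(mat) <- run$truth$name
  res <- pairwise_diff(mat, run$groups[colnames(mat)], "G1", "G2")
  k <- sum(res$p < 0.05)
  expect_gte(k, qbinom(0.005, 200, 0.05))
  expect_lte(k, qbinom(0.995, 200, 0.05))
})

test_that("planted two-fold effects are recovered after BH correction", {
  cfg <- sim_config(n_compounds = 200, n_decoys = 0, n_groups = 2,
                    replicates_per_group = 6, n_effect = 20,
                    effect_fold = 2, seed = 29)
  run <- simulate_features(simulate_compounds(cfg), cfg)
  li <- match(run$truth$light_feature_id, run$features$feature_id)
  mat <- as.matrix(as.data.frame(run$features)[li, sample_cols(run$features)])
  rownames(mat) <- run$truth$name
  res <- pairwise_diff(mat, run$groups[colnames(mat)], "G1", "G2")
  hits <- res$compound[res$q < 0.05]
  expect_gte(sum(run$effect_compounds %in% hits), 15L)
})

test_that("VIP scores satisfy the normalization identity", {
  set.seed(31)
  for (i in 1:5) {
    p <- sample(10:40, 1); n <- sample(8:16, 1)
    m <- matrix(rnorm(p * n), nrow = p)
    rownames(m) <- paste0("c", 1:p)
    groups <- rep(c("a", "b"), length.out = n)
    vip <- plsda_vip(m, groups)
    expect_equal(mean(vip^2), 1, tolerance = 1e-9)
  }
})

test_that("a single informative compound carries the top VIP", {
  set.seed(37)
  m <- matrix(rnorm(25 * 12), nrow = 25,
              dimnames = list(paste0("c", 1:25), NULL))
  groups <- rep(c("a", "b"), each = 6)
  m[9, groups == "b"] <- m[9, groups == "b"] + 5
  vip <- plsda_vip(m, groups)
  expect_identical(names(which.max(vip)), "c9")
  expect_gt(vip["c9"], 1.4)
})

test_that("VIP agrees with the mixOmics reference implementation", {
  set.seed(41)
  m <- matrix(rnorm(20 * 12), nrow = 20,
              dimnames = list(paste0("c", 1:20), paste0("s", 1:12)))
  groups <- rep(c("a", "b"), each = 6)
  m[3, groups == "b"] <- m[3, groups == "b"] + 3
  mine <- plsda_vip(m, groups, n_components = 2)
  ref <- mixOmics::vip(mixOmics::plsda(t(m), factor(groups),
                                       ncomp = 2, scale = TRUE))[, 2]
  expect_equal(unname(mine[names(ref)]), unname(ref), tolerance = 1e-8)
})

test_that("label permutation reshuffles the VIP ranking", {
  set.seed(43)
  m <- matrix(rnorm(30 * 12), nrow = 30,
              dimnames = list(paste0("c", 1:30), NULL))
  groups <- rep(c("a", "b"), each = 6)
  m[5, groups == "b"] <- m[5, groups == "b"] + 4
  v1 <- plsda_vip(m, groups)
  v2 <- plsda_vip(m, sample(groups))
  expect_false(identical(order(v1), order(v2)))
})
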