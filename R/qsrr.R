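#' Molecular descriptors for retention modeling
#'
#' Computes a fixed-order vector of molecular descriptors from SMILES:
#' OpenBabel physicochemical properties (logP, molar refractivity, TPSA,
#' H-bond donor/acceptor counts, molecular weight), constitutional terms
#' derived from the molecular formula (atom counts, monoisotopic mass,
#' RDBE, H/C and O/C ratios), and SMARTS-based functional-group and
#' topology counts (hydroxyls, amines, carbonyls, ethers, aromatic and ring
#' atoms, rotatable bonds, sp3/sp2 carbons). The descriptor set and order
#' are fixed per package version; a fitted model stores its own manifest.
#'
#' @param smiles character vector of SMILES (optionally named)
#' @return numeric matrix, one row per molecule, with descriptor columns;
#'   attribute \code{"engine"} records the descriptor engine
#' @examples
#' d <- compute_descriptors("CCO")
#' dim(d)
#' @export
compute_descriptors <- function(smiles) {
  sdf <- .smiles_to_sdf(smiles)
  pr <- ChemmineR::propOB(sdf)
  smarts <- c(
    n_aliphatic_oh    = "[CX4][OX2H]",
    n_phenolic_oh     = "[c][OX2H]",
    n_primary_amine   = "[NX3H2;!$(NC=O)]",
    n_secondary_amine = "[NX3H1;!$(NC=O)]",
    n_carboxyl        = "[CX3](=O)[OX2H1]",
    n_ester           = "[CX3](=O)[OX2H0]",
    n_carbonyl        = "[CX3]=[OX1]",
    n_ether           = "[OD2]([#6])[#6]",
    n_amide           = "[NX3][CX3]=[OX1]",
    n_aromatic_atoms  = "a",
    n_aromatic_n      = "n",
    n_ring_atoms      = "[R]",
    n_rotatable_bonds = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
    n_sp3_carbon      = "[CX4]",
    n_sp2_carbon      = "[CX3]",
    n_methyl          = "[CH3]",
    n_methylene       = "[CH2]"
  )
  sm <- vapply(smarts, function(p) .smarts_count(sdf, p),
               integer(length(smiles)))
  sm <- matrix(sm, nrow = length(smiles), dimnames = list(NULL, names(smarts)))
  fm <- lapply(as.character(pr$formula), parse_formula)
  cnt <- function(el) vapply(fm, function(f)
    if (el %in% names(f)) as.numeric(f[[el]]) else 0, numeric(1))
  nC <- cnt("C"); nH <- cnt("H"); nN <- cnt("N"); nO <- cnt("O")
  mono <- vapply(fm, monoisotopic_mass, numeric(1))
  out <- cbind(
    logp = pr$logP, mr = pr$MR, tpsa = pr$TPSA,
    hba = pr$HBA1, hbd = pr$HBD, mw = pr$MW,
    n_c = nC, n_h = nH, n_n = nN, n_o = nO,
    n_heavy = nC + nN + nO,
    mono_mass = mono,
    rdbe = vapply(fm, rdbe, numeric(1)),
    h_to_c = nH / pmax(nC, 1), o_to_c = nO / pmax(nC, 1),
    sm,
    frac_sp3 = sm[, "n_sp3_carbon"] / pmax(nC, 1),
    frac_aromatic = sm[, "n_aromatic_atoms"] / pmax(nC + nN + nO, 1)
  )
  rownames(out) <- if (!is.null(names(smiles))) names(smiles) else NULL
  structure(out, engine = .DESCRIPTOR_ENGINE)
}

.DESCRIPTOR_ENGINE <- "ChemmineR/OpenBabel + SMARTS counts v1"

#' Drop near-duplicate descriptors by pairwise correlation
#'
#' Greedy keep-first decorrelation: descriptors are scanned in column
#' order and one is dropped when its absolute Pearson correlation with an
#' already-kept descriptor exceeds \code{cutoff}. Removes the
#' interchangeable near-copies (e.g. multiple size measures) that would
#' otherwise dilute forest importance across a redundant cluster.
#'
#' @param X numeric descriptor matrix
#' @param cutoff absolute correlation above which the later column is
#'   dropped (default 0.95)
#' @return character vector of retained descriptor names
#' @export
decorrelate_descriptors <- function(X, cutoff = 0.95) {
  X <- as.matrix(X)
  vars <- apply(X, 2, stats::var)
  cols <- colnames(X)[is.finite(vars) & vars > 1e-12]
  kept <- character(0)
  for (cl in cols) {
    if (length(kept) == 0L) { kept <- cl; next }
    r <- suppressWarnings(stats::cor(X[, cl], X[, kept, drop = FALSE]))
    if (all(!is.finite(r)) || max(abs(r), na.rm = TRUE) <= cutoff)
      kept <- c(kept, cl)
  }
  kept
}

#' Select descriptors by recursive forest-importance elimination
#'
#' Removes (near-)constant columns, drops near-duplicate descriptors
#' (\code{\link{decorrelate_descriptors}}), then recursively eliminates the
#' least-important 20 percent by random-forest permutation importance until
#' \code{k} remain. Deterministic given \code{seed}.
#'
#' @param X numeric descriptor matrix (rows = molecules)
#' @param y numeric response (retention time, minutes)
#' @param k target number of descriptors (default 11)
#' @param seed RNG seed
#' @param ntree trees per elimination round
#' @param cor_cutoff redundancy cutoff passed to
#'   \code{\link{decorrelate_descriptors}}; \code{NULL} disables the filter
#' @return character vector of \code{k} selected descriptor names
#' @export
select_features <- function(X, y, k = 11L, seed = 1L, ntree = 300L,
                            cor_cutoff = 0.95) {
  stopifnot(is.matrix(X) || is.data.frame(X), nrow(X) == length(y))
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("need at least 10 samples for selection", call. = FALSE)
  vars <- apply(X, 2, stats::var)
  keep <- names(vars)[is.finite(vars) & vars > 1e-12]
  if (!is.null(cor_cutoff)) {
    dec <- decorrelate_descriptors(X[, keep, drop = FALSE], cor_cutoff)
    if (length(dec) >= k) keep <- dec
  }
  if (k > length(keep))
    stop("k = ", k, " exceeds the ", length(keep),
         " descriptors surviving the variance filter", call. = FALSE)
  round <- 0L
  while (length(keep) > k) {
    round <- round + 1L
    set.seed(seed + round)
    rf <- randomForest::randomForest(X[, keep, drop = FALSE], y,
                                     ntree = ntree, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    n_drop <- max(1L, min(length(keep) - k, floor(length(keep) * 0.2)))
    keep <- names(sort(imp, decreasing = TRUE))[seq_len(length(keep) - n_drop)]
  }
  keep
}

#' Fit a quantitative structure-retention relationship model
#'
#' Fits a random-forest QSRR model predicting derivative retention time
#' (minutes) from molecular descriptors of the parent structures. The
#' pipeline is: descriptor computation, median imputation of non-finite
#' values, variance filtering, recursive importance-based selection down to
#' \code{k} descriptors, forest fit, and seeded \code{cv_folds}-fold
#' cross-validation. Descriptors are computed from the parent SMILES by
#' default; set \code{derivatized = TRUE} to use the mono-derivatized
#' structure instead.
#'
#' @param smiles character vector of training SMILES
#' @param rt numeric derivative retention times, minutes
#' @param k number of descriptors retained by selection (default 11)
#' @param ntree forest size (default 500)
#' @param cv_folds internal cross-validation folds (default 5)
#' @param seed RNG seed controlling selection, forest and fold assignment
#' @param derivatized compute descriptors on the BrNC mono-derivative
#'   structure rather than the parent
#' @param descriptors optional precomputed descriptor matrix (rows aligned
#'   with \code{smiles}); bypasses structure handling
#' @param cor_cutoff redundancy cutoff for
#'   \code{\link{decorrelate_descriptors}}; \code{NULL} disables it
#' @return object of class \code{"qsrr"}: list with the fitted forest,
#'   selected descriptor names, imputation medians, descriptor manifest,
#'   training summary (\code{cv_r2}), seed and training rt range
#' @seealso \code{\link{simulate_qsrr_standards}} for a seeded standards
#'   panel with known retention dependencies, and
#'   \code{\link{evaluate_qsrr}} for held-out evaluation.
#' @export
qsrr <- function(smiles, rt, k = 11L, ntree = 500L, cv_folds = 5L,
                 seed = 1L, derivatized = FALSE, descriptors = NULL,
                 cor_cutoff = 0.95) {
  if (length(rt) != length(smiles))
    stop("smiles and rt lengths differ", call. = FALSE)
  if (length(rt) < 20L)
    stop("need at least 20 training records", call. = FALSE)
  if (stats::var(rt) <= 0 || !is.finite(stats::var(rt)))
    stop("degenerate retention times: no variance", call. = FALSE)
  if (is.null(descriptors)) {
    struct <- if (derivatized) .derivatized_smiles(smiles) else smiles
    X <- compute_descriptors(struct)
  } else {
    X <- as.matrix(descriptors)
    stopifnot(nrow(X) == length(smiles))
  }
  med <- apply(X, 2, function(col) stats::median(col[is.finite(col)]))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- med[j]
  }
  sel <- select_features(X, rt, k = k, seed = seed, cor_cutoff = cor_cutoff)
  Xs <- X[, sel, drop = FALSE]
  set.seed(seed)
  forest <- randomForest::randomForest(Xs, rt, ntree = ntree)
  # seeded k-fold CV on the selected descriptors
  set.seed(seed + 1000L)
  fold <- sample(rep_len(seq_len(cv_folds), length(rt)))
  pred_cv <- numeric(length(rt))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    set.seed(seed + 2000L + f)
    m <- randomForest::randomForest(Xs[tr, , drop = FALSE], rt[tr], ntree = ntree)
    pred_cv[!tr] <- stats::predict(m, Xs[!tr, , drop = FALSE])
  }
  cv_r2 <- 1 - sum((rt - pred_cv)^2) / sum((rt - mean(rt))^2)
  structure(list(
    forest = forest, selected = sel, impute_medians = med,
    manifest = list(engine = .DESCRIPTOR_ENGINE,
                    n_descriptors = ncol(X), descriptor_names = colnames(X),
                    k = k, ntree = ntree, cv_folds = cv_folds,
                    derivatized = derivatized),
    cv_r2 = cv_r2, seed = seed,
    rt_range = range(rt), n_train = length(rt)
  ), class = "qsrr")
}

.derivatized_smiles <- function(smiles) {
  # mono-derivative: esterify/amidate one site with the 5-bromonicotinoyl
  # group; used only when descriptors of the derivative are requested
  vapply(smiles, function(s)
    paste0("O=C(c1cncc(Br)c1)O", s), character(1), USE.NAMES = FALSE)
}

#' @export
print.qsrr <- function(x, ...) {
  cat("QSRR random-forest retention model\n")
  cat(sprintf("  training molecules : %d\n", x$n_train))
  cat(sprintf("  descriptors        : %d selected of %d computed\n",
              length(x$selected), x$manifest$n_descriptors))
  cat(sprintf("  %d-fold CV R^2      : %.3f\n", x$manifest$cv_folds, x$cv_r2))
  cat(sprintf("  rt range (min)     : %.2f - %.2f\n",
              x$rt_range[1], x$rt_range[2]))
  invisible(x)
}

#' @export
summary.qsrr <- function(object, ...) {
  imp <- object$forest$importance[, 1]
  out <- list(selected = object$selected,
              importance = sort(imp, decreasing = TRUE),
              cv_r2 = object$cv_r2, n_train = object$n_train,
              manifest = object$manifest)
  class(out) <- "summary.qsrr"
  out
}

#' @export
print.summary.qsrr <- function(x, ...) {
  cat("QSRR model summary\n")
  cat(sprintf("  CV R^2 = %.3f over %d molecules\n", x$cv_r2, x$n_train))
  cat("  selected descriptors (by importance):\n")
  for (nm in names(x$importance))
    cat(sprintf("    %-20s %10.3f\n", nm, x$importance[[nm]]))
  invisible(x)
}

#' Predict derivative retention times
#'
#' @param object fitted \code{\link{qsrr}} model
#' @param newdata character vector of SMILES, or a descriptor matrix with
#'   the model's descriptor columns
#' @param clip clip predictions to the training retention-time range
#' @param ... unused
#' @return numeric vector of predicted retention times, minutes
#' @export
predict.qsrr <- function(object, newdata, clip = TRUE, ...) {
  if (is.character(newdata)) {
    struct <- if (object$manifest$derivatized)
      .derivatized_smiles(newdata) else newdata
    X <- compute_descriptors(struct)
  } else {
    X <- as.matrix(newdata)
  }
  missing_cols <- setdiff(object$selected, colnames(X))
  if (length(missing_cols))
    stop("newdata lacks descriptor(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  Xs <- X[, object$selected, drop = FALSE]
  for (j in seq_len(ncol(Xs))) {
    bad <- !is.finite(Xs[, j])
    if (any(bad)) Xs[bad, j] <- object$impute_medians[[object$selected[j]]]
  }
  p <- as.numeric(stats::predict(object$forest, Xs))
  if (clip) p <- pmin(pmax(p, object$rt_range[1]), object$rt_range[2])
  p
}

#' Evaluate a QSRR model on a held-out test set
#'
#' @param model fitted \code{\link{qsrr}} model
#' @param smiles test SMILES (disjoint from training)
#' @param rt observed derivative retention times, minutes
#' @param descriptors optional precomputed descriptor matrix
#' @return list with \code{test_r2} and \code{aae_seconds} (mean absolute
#'   prediction error reported in seconds)
#' @export
evaluate_qsrr <- function(model, smiles, rt, descriptors = NULL) {
  if (length(rt) == 0L) stop("empty test set", call. = FALSE)
  pred <- if (is.null(descriptors)) predict(model, smiles)
  else predict(model, descriptors)
  ss_tot <- sum((rt - mean(rt))^2)
  test_r2 <- if (ss_tot > 0) 1 - sum((rt - pred)^2) / ss_tot else NA_real_
  list(test_r2 = test_r2, aae_seconds = mean(abs(pred - rt)) * 60)
}

#' Save / load a QSRR model
#'
#' The model is written as a single archive holding the serialized forest
#' together with its descriptor manifest; reloading reproduces predictions
#' exactly.
#'
#' @param model fitted \code{\link{qsrr}} model
#' @param path archive path (conventionally \code{.qsrr})
#' @return \code{path} invisibly (save); the model (load)
#' @export
save_qsrr <- function(model, path) {
  stopifnot(inherits(model, "qsrr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_qsrr
#' @export
load_qsrr <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "qsrr")) stop("not a qsrr model archive", call. = FALSE)
  model
}
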