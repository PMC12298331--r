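#' Simulation configuration
#'
#' Parameters of the forward model that the pair screen assumes: planted
#' mono-brominated derivative pairs with the theoretical 81Br/79Br
#' intensity ratio (0.9728) under multiplicative log-normal noise, m/z
#' jitter in ppm mirroring instrument mass accuracy, unlabeled decoy
#' features, and multiplicative group effects on planted compounds.
#'
#' @param n_compounds planted derivatized compounds
#' @param n_decoys unlabeled singleton decoy features
#' @param rt_range chromatographic window, minutes (default 1-25, a 28-min
#'   gradient's elution region)
#' @param intensity_lognormal_sigma log-scale sd of base intensities across
#'   replicates
#' @param ratio_noise_sigma log-scale sd on the heavy/light ratio
#' @param mz_noise_ppm sd of m/z jitter, ppm
#' @param n_groups,replicates_per_group sample design
#' @param n_effect number of compounds carrying a group effect
#' @param effect_fold multiplicative effect size for affected compounds
#' @param seed RNG seed (mandatory)
#' @return list of class \code{"sim_config"}
#' @export
sim_config <- function(n_compounds = 50L, n_decoys = 500L,
                       rt_range = c(1, 25),
                       intensity_lognormal_sigma = 0.2,
                       ratio_noise_sigma = 0.05,
                       mz_noise_ppm = 5,
                       n_groups = 1L, replicates_per_group = 1L,
                       n_effect = 0L, effect_fold = 2,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  stopifnot(n_compounds >= 0, n_decoys >= 0, length(rt_range) == 2L,
            rt_range[1] < rt_range[2], n_groups >= 1, replicates_per_group >= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_decoys = as.integer(n_decoys), rt_range = rt_range,
                 intensity_lognormal_sigma = intensity_lognormal_sigma,
                 ratio_noise_sigma = ratio_noise_sigma,
                 mz_noise_ppm = mz_noise_ppm,
                 n_groups = as.integer(n_groups),
                 replicates_per_group = as.integer(replicates_per_group),
                 n_effect = as.integer(n_effect), effect_fold = effect_fold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# SMILES grammar: scaffold templates x chain length, every product carrying
# at least one derivatizable OH or NH site. Deterministic enumeration.
.smiles_grammar <- function(max_chain = 9L) {
  chain <- function(n) strrep("C", n)
  tpl <- list(
    alcohol        = function(n) paste0(chain(n), "O"),
    diol           = function(n) paste0("OC", chain(n), "O"),
    amine          = function(n) paste0(chain(n), "N"),
    amino_alcohol  = function(n) paste0("NC", chain(n), "O"),
    alkyl_phenol   = function(n) paste0(chain(n), "c1ccc(O)cc1"),
    benzyl_alcohol = function(n) paste0("OC", chain(n), "c1ccccc1"),
    hydroxy_acid   = function(n) paste0(chain(n), "C(O)C(=O)O"),
    phenethylamine = function(n) paste0("NC", chain(n), "c1ccccc1"),
    methoxy_phenol = function(n) paste0("CO", chain(n), "c1ccc(O)cc1"),
    amino_acid_like= function(n) paste0("NC(", chain(n), ")C(=O)O")
  )
  out <- character(0)
  for (nm in names(tpl)) for (n in seq_len(max_chain))
    out[sprintf("%s_%02d", nm, n)] <- tpl[[nm]](n)
  out
}

#' Simulate derivatizable compounds with ground truth
#'
#' Draws \code{n_compounds} distinct structures from a deterministic
#' scaffold-by-chain-length SMILES grammar (alcohols, diols, amines, amino
#' alcohols, phenols, benzyl alcohols, hydroxy acids, phenethylamines, ...),
#' each with at least one derivatizable site, assigns uniform retention
#' times over \code{rt_range}, and computes the true light/heavy derivative
#' m/z from the elemental composition.
#'
#' @param cfg \code{\link{sim_config}}
#' @return list with \code{db} (a \code{compound_db} including measured
#'   \code{ref_rt}) and \code{truth} (data.frame: name, formula, smiles,
#'   n_tags, rt, mz_light, mz_heavy, base intensity, group means)
#' @export
simulate_compounds <- function(cfg) {
  set.seed(cfg$seed)
  # chain lengths grow with demand; the default study stays in the
  # small-molecule (<= C9) regime typical of derivatizable metabolites
  pool <- .smiles_grammar(max_chain = max(9L, ceiling(cfg$n_compounds / 10)))
  if (cfg$n_compounds > length(pool))
    stop("grammar supplies at most ", length(pool), " distinct compounds",
         call. = FALSE)
  if (cfg$n_compounds == 0L)
    return(list(db = NULL, truth = data.frame()))
  pick <- sort(sample(length(pool), cfg$n_compounds))
  smiles <- pool[pick]
  formula <- smiles_to_formula(smiles)
  sites <- count_sites(smiles)
  proton <- adduct("[M+H]+")$mass_shift
  mz_light <- vapply(formula, function(f)
    monoisotopic_mass(derivatize_formula(f, 1L)) + proton, numeric(1),
    USE.NAMES = FALSE)
  truth <- data.frame(
    name = names(smiles), smiles = as.character(smiles), formula = formula,
    n_sites = sites$n_sites, n_tags = 1L,
    rt = stats::runif(cfg$n_compounds, cfg$rt_range[1], cfg$rt_range[2]),
    mz_light = mz_light, mz_heavy = br_shift(mz_light, 1L),
    base_intensity = 10^stats::runif(cfg$n_compounds, 5, 7),
    stringsAsFactors = FALSE)
  db <- data.frame(name = truth$name, formula = truth$formula,
                   smiles = truth$smiles, n_sites = truth$n_sites,
                   ref_rt = truth$rt, source = "sim", standard = FALSE,
                   stringsAsFactors = FALSE)
  class(db) <- c("compound_db", "data.frame")
  list(db = db, truth = truth)
}

#' Simulate an aligned feature table from planted truth
#'
#' Each planted compound yields a light and a heavy feature: per-sample
#' light intensities are log-normal around the compound's base intensity
#' (with multiplicative group effects for effect compounds), and heavy
#' intensities equal light x 0.9728 x exp(N(0, ratio_noise_sigma)). All
#' m/z are jittered by N(0, mz_noise_ppm) ppm. Decoys are singleton
#' features whose m/z is re-drawn if it could form an accidental 1.998-Da
#' pair (within twice the screening tolerance) with any co-eluting feature,
#' so the planted ground truth is unambiguous. A blank table with zero
#' intensity for planted compounds is also produced.
#'
#' @param sim result of \code{\link{simulate_compounds}}
#' @param cfg the same \code{\link{sim_config}}
#' @return list with \code{features} (feature table), \code{blank}
#'   (single-column blank table), \code{groups} (sample -> group map),
#'   \code{truth} (augmented with per-group mean intensities and feature
#'   ids), and \code{effect_compounds}
#' @export
simulate_features <- function(sim, cfg) {
  truth <- sim$truth
  set.seed(cfg$seed + 1L)
  n <- nrow(truth)
  n_samp <- cfg$n_groups * cfg$replicates_per_group
  samp_names <- paste0("S", rep(seq_len(cfg$n_groups), each = cfg$replicates_per_group),
                       "_R", rep(seq_len(cfg$replicates_per_group), cfg$n_groups))
  group_of <- rep(paste0("G", seq_len(cfg$n_groups)), each = cfg$replicates_per_group)
  effect_idx <- if (cfg$n_effect > 0L && n > 0L)
    sort(sample(n, min(cfg$n_effect, n))) else integer(0)
  # group mean multipliers: effect compounds get effect_fold in even groups
  gmult <- matrix(1, nrow = max(n, 1L), ncol = cfg$n_groups)
  if (length(effect_idx) && cfg$n_groups >= 2L)
    gmult[effect_idx, seq(2L, cfg$n_groups, by = 2L)] <- cfg$effect_fold

  # mass error is dominated by calibration, which is common-mode for the
  # co-eluting isotopologues of one compound: the pair shares one jitter
  # draw, plus a small independent centroiding residual. Isotope spacings
  # are therefore measured much more precisely than absolute m/z.
  rows <- list()
  if (n > 0L) {
    for (i in seq_len(n)) {
      light <- truth$base_intensity[i] *
        gmult[i, match(group_of, unique(group_of))] *
        exp(stats::rnorm(n_samp, 0, cfg$intensity_lognormal_sigma))
      heavy <- light * expected_ratio(1, 1) *
        exp(stats::rnorm(n_samp, 0, cfg$ratio_noise_sigma))
      shared <- stats::rnorm(1, 0, cfg$mz_noise_ppm / 1e6)
      resid <- stats::rnorm(2, 0, cfg$mz_noise_ppm / 5e6)
      rows[[length(rows) + 1L]] <- c(truth$rt[i],
        truth$mz_light[i] * (1 + shared + resid[1]), light)
      rows[[length(rows) + 1L]] <- c(truth$rt[i],
        truth$mz_heavy[i] * (1 + shared + resid[2]), heavy)
    }
  }
  planted <- do.call(rbind, rows)
  # decoys: rejection-sample m/z so no accidental pair arises
  tc <- tag_constants()
  guard <- function(mz_new, rt_new, mz_all, rt_all) {
    if (length(mz_all) == 0L) return(TRUE)
    co <- abs(rt_all - rt_new) <= 2 * 0.05
    if (!any(co)) return(TRUE)
    d <- abs(abs(mz_all[co] - mz_new) - tc$br_delta)
    all(d > 2 * mz_new * 10 / 1e6)
  }
  mz_dec <- numeric(0); rt_dec <- numeric(0)
  mz_seen <- if (is.null(planted)) numeric(0) else planted[, 2]
  rt_seen <- if (is.null(planted)) numeric(0) else planted[, 1]
  while (length(mz_dec) < cfg$n_decoys) {
    mzc <- stats::runif(1, 120, 900)
    rtc <- stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
    if (guard(mzc, rtc, c(mz_seen, mz_dec), c(rt_seen, rt_dec))) {
      mz_dec <- c(mz_dec, mzc); rt_dec <- c(rt_dec, rtc)
    }
  }
  dec_int <- matrix(10^stats::runif(cfg$n_decoys * n_samp, 4.5, 6.5),
                    ncol = n_samp)
  feat <- data.frame(
    feature_id = sprintf("F%04d", seq_len(2L * n + cfg$n_decoys)),
    rt = c(if (n > 0L) planted[, 1], rt_dec),
    mz = c(if (n > 0L) planted[, 2], mz_dec),
    stringsAsFactors = FALSE)
  inten <- rbind(if (n > 0L) planted[, -(1:2), drop = FALSE], dec_int)
  colnames(inten) <- samp_names
  feat <- cbind(feat, inten)
  attr(feat, "sample_cols") <- samp_names
  class(feat) <- c("feature_table", "data.frame")
  truth$light_feature_id <- if (n > 0L) feat$feature_id[seq(1L, 2L * n, by = 2L)] else character(0)
  truth$heavy_feature_id <- if (n > 0L) feat$feature_id[seq(2L, 2L * n, by = 2L)] else character(0)
  blank <- data.frame(feature_id = feat$feature_id, rt = feat$rt, mz = feat$mz,
                      blank = c(rep(0, 2L * n),
                                dec_int[, 1] * stats::runif(cfg$n_decoys, 0.5, 1.5)),
                      stringsAsFactors = FALSE)
  attr(blank, "sample_cols") <- "blank"
  class(blank) <- c("feature_table", "data.frame")
  list(features = feat, blank = blank,
       groups = stats::setNames(group_of, samp_names),
       truth = truth, effect_compounds = truth$name[effect_idx])
}

#' Simulate a derivative MS2 spectrum
#'
#' Produces a centroid spectrum containing the acylium tag fragment
#' (183.9393) plus the class diagnostic (201.9498 for hydroxyl, 200.9658
#' for amino derivatives) and 3-8 random structure fragments below the
#' precursor.
#'
#' @param precursor_mz precursor m/z of the light derivative ion
#' @param class \code{"hydroxyl"} or \code{"amino"}
#' @param rt retention time to stamp on the spectrum, minutes
#' @param title spectrum title
#' @param include_diagnostics set \code{FALSE} to suppress reagent
#'   fragments (negative-control spectra)
#' @param seed optional seed for the random structure peaks
#' @return an \code{\link{ms2_spectrum}}
#' @export
simulate_ms2 <- function(precursor_mz, class = c("hydroxyl", "amino"),
                         rt = NA_real_, title = NA_character_,
                         include_diagnostics = TRUE, seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  tc <- tag_constants()
  n_extra <- sample(3:8, 1)
  mz <- stats::runif(n_extra, 50, max(60, precursor_mz - 5))
  int <- stats::runif(n_extra, 5, 60)
  if (include_diagnostics) {
    mz <- c(mz, tc$frag_acylium_mz,
            if (class == "hydroxyl") tc$frag_hydroxyl_mz else tc$frag_amino_mz)
    int <- c(int, 100, 80)
  }
  ms2_spectrum(precursor_mz, mz, int, rt = rt, title = title)
}

#' Simulate a QSRR standards panel with known retention dependencies
#'
#' Draws distinct molecules from the SMILES grammar, computes their
#' descriptors, and generates retention times as a linear function of three
#' named descriptors (autoscaled) plus Gaussian noise. Mirrors the
#' 62-train / 20-test design used for retention modeling, and provides the
#' ground truth needed for parameter-recovery checks: the informative
#' descriptors and the noise level are known by construction.
#'
#' @param n_train,n_test panel sizes (defaults 62 and 20)
#' @param informative names of the three informative descriptors. The
#'   default triple (lipophilicity, saturated-carbon fraction, sp3-carbon
#'   count) spans distinct, identifiable axes of the panel's chemistry;
#'   on a homologous-series panel size and lipophilicity measures are
#'   near-collinear, so planting the effect on one member of such a
#'   cluster would make recovery ill-posed
#' @param coefs their coefficients on the autoscaled scale, minutes
#' @param intercept mean retention time, minutes
#' @param noise_sd retention noise, minutes (default 0.1)
#' @param seed RNG seed
#' @return list with \code{train} and \code{test} (each: \code{smiles},
#'   \code{rt}, \code{descriptors}) and \code{informative}
#' @export
simulate_qsrr_standards <- function(n_train = 62L, n_test = 20L,
                                    informative = c("logp", "frac_sp3",
                                                    "n_sp3_carbon"),
                                    coefs = c(3, -2, 2.5), intercept = 12,
                                    noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  pool <- .smiles_grammar()
  n <- n_train + n_test
  if (n > length(pool))
    stop("grammar supplies at most ", length(pool), " molecules", call. = FALSE)
  smiles <- pool[sample(length(pool), n)]
  X <- compute_descriptors(smiles)
  stopifnot(all(informative %in% colnames(X)))
  Z <- base::scale(X[, informative, drop = FALSE])
  rt <- intercept + as.numeric(Z %*% coefs) + stats::rnorm(n, 0, noise_sd)
  rt <- pmax(rt, 0.5)
  idx_tr <- seq_len(n_train)
  list(
    train = list(smiles = smiles[idx_tr], rt = rt[idx_tr],
                 descriptors = X[idx_tr, , drop = FALSE]),
    test = list(smiles = smiles[-idx_tr], rt = rt[-idx_tr],
                descriptors = X[-idx_tr, , drop = FALSE]),
    informative = informative)
}

#' Score detected pairs against planted truth
#'
#' Matches detected pairs to planted compounds by the light feature id
#' (exact, when the truth table carries feature ids) or by light m/z and
#' retention time, and reports recall and precision. When annotations are
#' supplied, a per-level confusion summary of the recovered identities is
#' added.
#'
#' @param pairs detected \code{br_pairs}
#' @param truth \code{truth} table from \code{\link{simulate_features}}
#' @param annotations optional annotation table (best rows are used)
#' @param tol_ppm m/z matching tolerance (id-free fallback)
#' @param rt_tol retention-time matching tolerance, minutes (fallback)
#' @return list with \code{recall}, \code{precision}, \code{n_detected},
#'   \code{n_planted}, \code{undetected} (names) and, when annotations are
#'   given, \code{identity_recall} and \code{levels} (table)
#' @export
scorecard <- function(pairs, truth, annotations = NULL,
                      tol_ppm = 10, rt_tol = 0.1) {
  n_planted <- nrow(truth)
  matched <- logical(n_planted)
  pair_is_tp <- logical(nrow(pairs))
  by_id <- "light_feature_id" %in% names(truth) && "light_id" %in% names(pairs)
  for (i in seq_len(nrow(pairs))) {
    hit <- if (by_id) which(truth$light_feature_id == pairs$light_id[i])
    else which(abs(pairs$mz_light[i] - truth$mz_light) / truth$mz_light * 1e6
               <= tol_ppm & abs(pairs$rt[i] - truth$rt) <= rt_tol)
    if (length(hit)) { matched[hit] <- TRUE; pair_is_tp[i] <- TRUE }
  }
  recall <- if (n_planted > 0L) mean(matched) else NA_real_
  precision <- if (nrow(pairs) > 0L) mean(pair_is_tp) else 0
  out <- list(recall = recall, precision = precision,
              n_detected = nrow(pairs), n_planted = n_planted,
              undetected = truth$name[!matched])
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    best <- annotations[annotations$best, , drop = FALSE]
    # identity recovered when the top candidate names a planted compound
    out$identity_recall <- sum(best$name %in% truth$name) / max(nrow(best), 1L)
    out$levels <- table(factor(best$level, levels = 1:5))
  }
  out
}

#' Simulate a complete study to disk
#'
#' Writes \code{features.csv}, \code{blank.csv}, \code{spectra.msp},
#' \code{db.csv}, \code{groups.csv} and \code{truth.json} under
#' \code{outdir}. With a fixed seed the files are byte-identical across
#' runs.
#'
#' @param cfg \code{\link{sim_config}}
#' @param outdir output directory (created if needed)
#' @return invisible list of written paths
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_compounds(cfg)
  run <- simulate_features(sim, cfg)
  # one MS2 spectrum per planted compound, class from its site chemistry
  sc <- count_sites(run$truth$smiles)
  cls <- ifelse(sc$n_primary_amine + sc$n_secondary_amine > 0, "amino", "hydroxyl")
  spectra <- lapply(seq_len(nrow(run$truth)), function(i)
    simulate_ms2(run$truth$mz_light[i], cls[i], rt = run$truth$rt[i],
                 title = run$truth$name[i], seed = cfg$seed + 10L + i))
  paths <- list(
    features = file.path(outdir, "features.csv"),
    blank = file.path(outdir, "blank.csv"),
    spectra = file.path(outdir, "spectra.msp"),
    db = file.path(outdir, "db.csv"),
    groups = file.path(outdir, "groups.csv"),
    truth = file.path(outdir, "truth.json"))
  write_feature_table(run$features, paths$features)
  write_feature_table(run$blank, paths$blank)
  write_msp(spectra, paths$spectra)
  utils::write.csv(as.data.frame(sim$db), paths$db, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(run$groups), group = run$groups,
                              row.names = NULL), paths$groups, row.names = FALSE)
  jsonlite::write_json(run$truth, paths$truth, digits = NA, auto_unbox = FALSE)
  invisible(paths)
}
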