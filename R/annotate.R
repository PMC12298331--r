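#' Annotation match thresholds
#'
#' Evidence thresholds of the five-level annotation scheme: MS1 mass error
#' below 10 ppm, retention-time deviation below 0.5 min, MS2 similarity
#' score above 0.5.
#'
#' @param ms1_ppm MS1 mass tolerance, ppm
#' @param rt_dev retention-time tolerance, minutes
#' @param ms2_score minimum MS2 similarity score
#' @return list of class \code{"match_thresholds"}
#' @export
match_thresholds <- function(ms1_ppm = 10, rt_dev = 0.5, ms2_score = 0.5) {
  stopifnot(ms1_ppm > 0, rt_dev > 0, ms2_score > 0)
  structure(list(ms1_ppm = ms1_ppm, rt_dev = rt_dev, ms2_score = ms2_score),
            class = "match_thresholds")
}

#' Theoretical light-isotopologue m/z of database candidates
#'
#' For one database record, enumerates the theoretical m/z of the light
#' (all-79Br) derivative ion over tag counts 1..min(max_tags, n_sites) and
#' the given adducts.
#'
#' @param record one-row slice of a \code{compound_db} (needs
#'   \code{formula} and \code{n_sites})
#' @param adducts list of \code{\link{adduct}} definitions
#' @param max_tags cap on the number of tags considered
#' @return data.frame with \code{n_tags}, \code{adduct}, \code{mz} (empty
#'   when the record has no derivatizable site)
#' @export
candidate_mzs <- function(record, adducts = list(adduct("[M+H]+")),
                          max_tags = 1L) {
  n_sites <- record$n_sites
  if (is.na(n_sites) || n_sites < 1L)
    return(data.frame(n_tags = integer(0), adduct = character(0),
                      mz = numeric(0)))
  parent <- parse_formula(record$formula)
  out <- list()
  for (nt in seq_len(min(max_tags, n_sites))) {
    m <- monoisotopic_mass(derivatize_formula(parent, nt))
    for (ad in adducts)
      out[[length(out) + 1L]] <- data.frame(
        n_tags = nt, adduct = ad$name,
        mz = (m + ad$mass_shift) / abs(ad$charge),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.empty_annotations <- function() {
  data.frame(pair_id = character(0), name = character(0),
             formula = character(0), n_tags = integer(0),
             adduct = character(0), level = integer(0),
             ms1_ppm_obs = numeric(0), rt_dev_obs = numeric(0),
             ms2_score_obs = numeric(0), standard_confirmed = logical(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Annotate one screened pair against a compound database
#'
#' MS1 matching uses the light (79Br, monoisotopic) m/z of the pair against
#' the theoretical derivative m/z of each database candidate. Retention
#' evidence compares the pair's retention time with the record's reference
#' retention time (measured, or QSRR-predicted from its SMILES when a model
#' is supplied). MS2 evidence scores the pair's spectrum against the
#' record's reference spectrum. Confidence levels: 1 = confirmed by an
#' authentic-standard entry (rt + MS1 + MS2 within thresholds and the
#' record is flagged as a standard); 2 = rt + MS1 + MS2 database match;
#' 3 = rt + MS1; 4 = MS1 only; 5 = molecular formula only (generated from
#' the accurate mass with the pair's bromine count when no database record
#' matches). Candidates are ranked by (level, |ppm|, rt deviation,
#' -MS2 score).
#'
#' @param pair one-row slice of a \code{br_pairs} table
#' @param db \code{compound_db}
#' @param model optional \code{\link{qsrr}} model supplying predicted
#'   reference retention times for records lacking a measured one
#' @param ref_spectra optional named list of reference MS2 spectra keyed by
#'   compound name
#' @param pair_spectrum optional \code{\link{ms2_spectrum}} measured for the
#'   pair's light feature
#' @param thr \code{\link{match_thresholds}}
#' @param sim_cfg \code{\link{similarity_config}} for MS2 scoring
#' @param formula_bounds element bounds for the level-5 formula fallback
#' @return data.frame of candidate annotations, best level first (zero rows
#'   when nothing matches and no formula can be generated)
#' @export
annotate_pair <- function(pair, db, model = NULL, ref_spectra = NULL,
                          pair_spectrum = NULL, thr = match_thresholds(),
                          sim_cfg = similarity_config(),
                          formula_bounds = list(C = 40, H = 80, N = 5, O = 12, S = 0)) {
  out <- list()
  proton <- adduct("[M+H]+")$mass_shift
  for (r in seq_len(nrow(db))) {
    rec <- db[r, , drop = FALSE]
    cand <- candidate_mzs(rec, max_tags = max(1L, pair$n_tags))
    cand <- cand[cand$n_tags == pair$n_tags, , drop = FALSE]
    if (nrow(cand) == 0L) next
    for (ci in seq_len(nrow(cand))) {
      ppm <- ppm_error(pair$mz_light, cand$mz[ci])
      if (abs(ppm) >= thr$ms1_ppm) next
      # retention evidence: measured reference rt, else QSRR prediction
      ref_rt <- rec$ref_rt
      if ((is.null(ref_rt) || is.na(ref_rt)) && !is.null(model) &&
          !is.na(rec$smiles) && nzchar(rec$smiles))
        ref_rt <- predict(model, rec$smiles)
      rt_dev <- if (is.null(ref_rt) || is.na(ref_rt)) NA_real_
      else abs(pair$rt - ref_rt)
      rt_ok <- !is.na(rt_dev) && rt_dev < thr$rt_dev
      # MS2 evidence
      score <- NA_real_
      if (!is.null(pair_spectrum) && !is.null(ref_spectra) &&
          rec$name %in% names(ref_spectra))
        score <- similarity(pair_spectrum, ref_spectra[[rec$name]], sim_cfg)
      ms2_ok <- !is.na(score) && score > thr$ms2_score
      level <- if (rt_ok && ms2_ok && isTRUE(rec$standard)) 1L
      else if (rt_ok && ms2_ok) 2L
      else if (rt_ok) 3L
      else 4L
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pair$pair_id, name = rec$name, formula = rec$formula,
        n_tags = pair$n_tags, adduct = cand$adduct[ci], level = level,
        ms1_ppm_obs = ppm, rt_dev_obs = rt_dev, ms2_score_obs = score,
        standard_confirmed = level == 1L, source = rec$source,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    # level 5: formula-only fallback from the accurate mass; the pair's
    # bromine count equals its tag count
    neutral <- pair$mz_light - proton
    fg <- generate_formulas(neutral, tol_ppm = thr$ms1_ppm,
                            n_br = pair$n_tags, bounds = formula_bounds)
    if (nrow(fg) == 0L) return(.empty_annotations())
    res <- data.frame(
      pair_id = pair$pair_id, name = NA_character_, formula = fg$formula,
      n_tags = pair$n_tags, adduct = "[M+H]+", level = 5L,
      ms1_ppm_obs = fg$ppm, rt_dev_obs = NA_real_,
      ms2_score_obs = NA_real_, standard_confirmed = FALSE,
      source = "formula", stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  o <- order(res$level, abs(res$ms1_ppm_obs),
             ifelse(is.na(res$rt_dev_obs), Inf, res$rt_dev_obs),
             -ifelse(is.na(res$ms2_score_obs), -Inf, res$ms2_score_obs))
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate all screened pairs
#'
#' Runs \code{\link{annotate_pair}} over a pair table, linking each pair's
#' MS2 spectrum when spectra are provided, and returns the best candidate
#' per pair together with ranked alternatives. A per-level summary is
#' emitted as a message.
#'
#' @param pairs \code{br_pairs} table
#' @param db \code{compound_db}
#' @param model optional \code{\link{qsrr}} model
#' @param ref_spectra optional named list of reference MS2 spectra
#' @param spectra optional list of measured MS2 spectra to link to pairs
#' @param thr \code{\link{match_thresholds}}
#' @param sim_cfg \code{\link{similarity_config}}
#' @param alternatives keep ranked non-best candidates in the result
#' @param formula_bounds bounds for the level-5 fallback
#' @return data.frame of annotations; column \code{best} flags the top
#'   candidate of each pair
#' @export
annotate_all <- function(pairs, db, model = NULL, ref_spectra = NULL,
                         spectra = NULL, thr = match_thresholds(),
                         sim_cfg = similarity_config(),
                         alternatives = TRUE,
                         formula_bounds = list(C = 40, H = 80, N = 5, O = 12, S = 0)) {
  if (nrow(pairs) == 0L) return(cbind(.empty_annotations(), best = logical(0)))
  link <- if (!is.null(spectra)) {
    feat <- data.frame(feature_id = pairs$pair_id, rt = pairs$rt,
                       mz = pairs$mz_light, stringsAsFactors = FALSE)
    link_ms2(feat, spectra)
  } else rep(NA_integer_, nrow(pairs))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    sp <- if (!is.na(link[i])) spectra[[link[i]]] else NULL
    ann <- annotate_pair(pairs[i, , drop = FALSE], db, model = model,
                         ref_spectra = ref_spectra, pair_spectrum = sp,
                         thr = thr, sim_cfg = sim_cfg,
                         formula_bounds = formula_bounds)
    if (nrow(ann) == 0L) next
    ann$best <- seq_len(nrow(ann)) == 1L
    out[[length(out) + 1L]] <- if (alternatives) ann else ann[1, , drop = FALSE]
  }
  if (length(out) == 0L) {
    message("no pair could be annotated")
    return(cbind(.empty_annotations(), best = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  lv <- table(factor(res$level[res$best], levels = 1:5))
  message("annotation levels (best per pair): ",
          paste(sprintf("L%d=%d", 1:5, as.integer(lv)), collapse = " "))
  res
}

#' Write annotations to CSV
#' @param annotations annotation table from \code{\link{annotate_all}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
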