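#' Classify a derivative from diagnostic MS2 fragments
#'
#' The BrNC tag produces reagent-derived product ions independent of the
#' analyte: the acylium cation at m/z 183.9393 (all derivatives), a fragment
#' at 201.9498 specific to hydroxyl derivatives, and one at 200.9658
#' characteristic of amino derivatives. A peak within \code{tol_ppm} of a
#' diagnostic m/z counts as seen. The MS2 tolerance defaults wider (20 ppm)
#' than the MS1 screen because product-ion calibration is looser.
#'
#' @param spec an \code{\link{ms2_spectrum}}
#' @param tol_ppm matching tolerance, ppm
#' @param require_tag when \code{TRUE}, the hydroxyl/amino class additionally
#'   requires the acylium tag fragment; by default standalone class
#'   fragments suffice
#' @return list with logical flags \code{tag_seen}, \code{hydroxyl_seen},
#'   \code{amino_seen} and \code{class} in
#'   \code{c("hydroxyl", "amino", "both", "tag_only", "none")}
#' @examples
#' sp <- ms2_spectrum(322.0083, c(183.9390, 201.9482, 107.0488),
#'                    c(100, 80, 40))
#' diagnostic_class(sp)$class  # "hydroxyl"
#' @export
diagnostic_class <- function(spec, tol_ppm = 20, require_tag = FALSE) {
  tc <- tag_constants()
  seen <- function(target) {
    if (nrow(spec$peaks) == 0L) return(FALSE)
    any(abs(spec$peaks[, "mz"] - target) <= target * tol_ppm / 1e6)
  }
  tag <- seen(tc$frag_acylium_mz)
  hyd <- seen(tc$frag_hydroxyl_mz)
  ami <- seen(tc$frag_amino_mz)
  if (require_tag) { hyd <- hyd && tag; ami <- ami && tag }
  cls <- if (hyd && ami) "both"
  else if (hyd) "hydroxyl"
  else if (ami) "amino"
  else if (tag) "tag_only"
  else "none"
  list(tag_seen = tag, hydroxyl_seen = hyd, amino_seen = ami, class = cls)
}

#' Spectral similarity configuration
#'
#' @param align_tol peak-alignment tolerance; interpreted in ppm when
#'   \code{tol_is_ppm} is \code{TRUE}, otherwise Da
#' @param tol_is_ppm logical
#' @param intensity_power exponent applied to intensities before the cosine
#'   (0.5 = square-root weighting, the dominant convention)
#' @param mz_power exponent on m/z weighting (0 disables)
#' @param exclude_precursor drop peaks near the precursor before scoring
#' @param precursor_tol_da half-width of the precursor exclusion window, Da
#' @return list of class \code{"similarity_config"}
#' @export
similarity_config <- function(align_tol = 20, tol_is_ppm = TRUE,
                              intensity_power = 0.5, mz_power = 0,
                              exclude_precursor = TRUE,
                              precursor_tol_da = 0.5) {
  stopifnot(align_tol > 0)
  structure(list(align_tol = align_tol, tol_is_ppm = tol_is_ppm,
                 intensity_power = intensity_power, mz_power = mz_power,
                 exclude_precursor = exclude_precursor,
                 precursor_tol_da = precursor_tol_da),
            class = "similarity_config")
}

#' Cosine similarity between two MS2 spectra
#'
#' Peaks are greedily matched one-to-one within the alignment tolerance in
#' order of decreasing intensity product; the score is the cosine between
#' the weighted intensity vectors (weight = intensity^p * mz^q). The score
#' is symmetric, lies in [0, 1], and is invariant to global intensity
#' scaling of either spectrum. Empty spectra score 0 with a warning.
#'
#' @param a,b \code{\link{ms2_spectrum}} objects
#' @param cfg \code{\link{similarity_config}}
#' @return similarity score in [0, 1]
#' @examples
#' a <- ms2_spectrum(300, c(100, 200), c(1, 1))
#' b <- ms2_spectrum(300, 100, 1)
#' similarity(a, b, similarity_config(intensity_power = 1))  # 0.7071
#' @export
similarity <- function(a, b, cfg = similarity_config()) {
  pa <- a$peaks; pb <- b$peaks
  if (cfg$exclude_precursor) {
    if (is.finite(a$precursor_mz))
      pa <- pa[abs(pa[, "mz"] - a$precursor_mz) > cfg$precursor_tol_da, , drop = FALSE]
    if (is.finite(b$precursor_mz))
      pb <- pb[abs(pb[, "mz"] - b$precursor_mz) > cfg$precursor_tol_da, , drop = FALSE]
  }
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    warning("empty spectrum in similarity(); returning 0", call. = FALSE)
    return(0)
  }
  wa <- pa[, "intensity"]^cfg$intensity_power
  wb <- pb[, "intensity"]^cfg$intensity_power
  if (cfg$mz_power != 0) {
    wa <- wa * pa[, "mz"]^cfg$mz_power
    wb <- wb * pb[, "mz"]^cfg$mz_power
  }
  # candidate matches within tolerance
  tol_of <- function(mz) if (cfg$tol_is_ppm) mz * cfg$align_tol / 1e6 else cfg$align_tol
  cand <- list()
  for (i in seq_len(nrow(pa))) {
    d <- abs(pb[, "mz"] - pa[i, "mz"])
    ok <- which(d <= tol_of(pa[i, "mz"]))
    for (j in ok) cand[[length(cand) + 1L]] <- c(i, j, wa[i] * wb[j])
  }
  if (length(cand) == 0L) return(0)
  cm <- do.call(rbind, cand)
  cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  num <- 0
  for (r in seq_len(nrow(cm))) {
    i <- cm[r, 1]; j <- cm[r, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      num <- num + cm[r, 3]
    }
  }
  score <- num / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  min(max(score, 0), 1)
}

#' Diagnostic classification for a table of screened pairs
#'
#' Links MS2 spectra to the light members of screened pairs and classifies
#' each pair's derivative type from the diagnostic fragments.
#'
#' @param pairs \code{br_pairs}
#' @param spectra list of \code{\link{ms2_spectrum}}
#' @param tol_ppm MS2 diagnostic tolerance (ppm)
#' @param link_ppm,link_rt precursor linking tolerances (see
#'   \code{\link{link_ms2}})
#' @return \code{pairs} with added columns \code{ms2_idx} (index into
#'   \code{spectra} or NA), \code{tag_seen}, \code{hydroxyl_seen},
#'   \code{amino_seen}, \code{ms2_class}
#' @export
classify_pairs <- function(pairs, spectra, tol_ppm = 20,
                           link_ppm = 10, link_rt = 0.2) {
  feat <- data.frame(feature_id = pairs$pair_id, rt = pairs$rt,
                     mz = pairs$mz_light, stringsAsFactors = FALSE)
  idx <- link_ms2(feat, spectra, tol_ppm = link_ppm, rt_window = link_rt)
  res <- as.data.frame(pairs)
  res$ms2_idx <- idx
  res$tag_seen <- res$hydroxyl_seen <- res$amino_seen <- NA
  res$ms2_class <- NA_character_
  for (i in which(!is.na(idx))) {
    fl <- diagnostic_class(spectra[[idx[i]]], tol_ppm = tol_ppm)
    res$tag_seen[i] <- fl$tag_seen
    res$hydroxyl_seen[i] <- fl$hydroxyl_seen
    res$amino_seen[i] <- fl$amino_seen
    res$ms2_class[i] <- fl$class
  }
  class(res) <- c("br_pairs", "data.frame")
  res
}
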