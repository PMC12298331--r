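#' Pair-screening configuration
#'
#' Parameters of the bromine isotopologue pair screen. The mass spacing
#' defaults to the 81Br-79Br difference (1.998 Da) with a 10 ppm tolerance
#' applied to the heavy member's m/z, the intensity-ratio window to
#' 0.8-1.2 (the theoretical mono-bromine ratio 0.9728 sits inside it), and
#' co-elution to +/- 0.05 min, since aligned tables quantize retention time.
#'
#' @param delta_target expected light->heavy mass spacing per tag, Da
#' @param tol_ppm mass tolerance in ppm of the heavy m/z
#' @param ratio_low,ratio_high accepted I(heavy)/I(light) window for one tag
#' @param rt_tol co-elution tolerance, minutes
#' @param n_tags_max maximum tag count searched; for n > 1 the spacing is
#'   n x delta and the ratio window is centered on the binomial
#'   \code{expected_ratio(n, n)} scaled by \code{ratio_rel_tol}
#' @param ratio_rel_tol relative half-width of the ratio window for n > 1
#' @return list of class \code{"pair_config"}
#' @export
pair_config <- function(delta_target = NULL, tol_ppm = 10,
                        ratio_low = 0.8, ratio_high = 1.2,
                        rt_tol = 0.05, n_tags_max = 1L,
                        ratio_rel_tol = 0.25) {
  if (is.null(delta_target)) delta_target <- tag_constants()$br_delta
  stopifnot(tol_ppm > 0, ratio_low > 0, ratio_low < ratio_high,
            rt_tol >= 0, n_tags_max >= 1)
  structure(list(delta_target = delta_target, tol_ppm = tol_ppm,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 rt_tol = rt_tol, n_tags_max = as.integer(n_tags_max),
                 ratio_rel_tol = ratio_rel_tol),
            class = "pair_config")
}

.pair_intensity <- function(features, reference_sample = NULL) {
  sc <- sample_cols(features)
  if (!is.null(reference_sample)) {
    if (!reference_sample %in% sc)
      stop("reference sample '", reference_sample, "' not in table", call. = FALSE)
    return(features[[reference_sample]])
  }
  if (length(sc) == 1L) return(features[[sc]])
  rowSums(as.data.frame(features)[, sc, drop = FALSE])
}

#' Find bromine isotopologue pairs in a feature table
#'
#' Scans all co-eluting feature pairs for the 79Br/81Br signature: a mass
#' spacing of n_tags x 1.998 Da (within \code{tol_ppm} of the heavy m/z) and
#' a heavy/light intensity ratio inside the configured window. Intensity is
#' the per-sample sum unless a reference sample is named. Every qualifying
#' (light, heavy) combination is reported exactly once; for multi-tag search
#' the smallest qualifying n_tags is assigned per pair.
#'
#' @param features feature table from \code{\link{read_feature_table}} or
#'   the simulator
#' @param cfg \code{\link{pair_config}}
#' @param reference_sample optional intensity column to use instead of the
#'   per-sample sum
#' @return data.frame of class \code{"br_pairs"}: \code{pair_id},
#'   \code{light_id}, \code{heavy_id}, \code{rt}, \code{mz_light},
#'   \code{mz_heavy}, \code{delta_obs}, \code{ratio}, \code{n_tags},
#'   \code{intensity_light}, \code{intensity_heavy}, sorted by (rt, mz)
#' @export
find_pairs <- function(features, cfg = pair_config(), reference_sample = NULL) {
  stopifnot(inherits(cfg, "pair_config"))
  n <- nrow(features)
  if (n == 0L) stop("empty feature table", call. = FALSE)
  inten <- .pair_intensity(features, reference_sample)
  o <- order(features$mz, features$rt)
  mz <- features$mz[o]; rt <- features$rt[o]; ii <- inten[o]
  ids <- features$feature_id[o]
  out <- list()
  for (nt in seq_len(cfg$n_tags_max)) {
    delta <- nt * cfg$delta_target
    if (nt == 1L) {
      rlo <- cfg$ratio_low; rhi <- cfg$ratio_high
    } else {
      # all-81Br isotopologue of an nt-bromine ion relative to monoisotopic
      r0 <- expected_ratio(nt, nt)
      rlo <- r0 * (1 - cfg$ratio_rel_tol); rhi <- r0 * (1 + cfg$ratio_rel_tol)
    }
    for (i in seq_len(n)) {
      target <- mz[i] + delta
      tol <- target * cfg$tol_ppm / 1e6
      j_lo <- findInterval(target - tol, mz) + 1L
      j_hi <- findInterval(target + tol, mz)
      if (j_hi < j_lo) next
      for (j in seq.int(j_lo, j_hi)) {
        if (j == i) next
        if (abs(rt[j] - rt[i]) > cfg$rt_tol) next
        if (ii[i] <= 0) next
        ratio <- ii[j] / ii[i]
        if (ratio < rlo || ratio > rhi) next
        out[[length(out) + 1L]] <- data.frame(
          light_id = ids[i], heavy_id = ids[j], rt = rt[i],
          mz_light = mz[i], mz_heavy = mz[j], delta_obs = mz[j] - mz[i],
          ratio = ratio, n_tags = nt,
          intensity_light = ii[i], intensity_heavy = ii[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(pair_id = character(0), light_id = character(0),
                      heavy_id = character(0), rt = numeric(0),
                      mz_light = numeric(0), mz_heavy = numeric(0),
                      delta_obs = numeric(0), ratio = numeric(0),
                      n_tags = integer(0), intensity_light = numeric(0),
                      intensity_heavy = numeric(0))
    class(res) <- c("br_pairs", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  # a pair found at several tag counts keeps the smallest n_tags
  key <- paste(res$light_id, res$heavy_id)
  res <- res[order(res$n_tags), , drop = FALSE]
  res <- res[!duplicated(key[order(res$n_tags)]), , drop = FALSE]
  res <- res[order(res$rt, res$mz_light), , drop = FALSE]
  res <- cbind(pair_id = sprintf("P%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("br_pairs", "data.frame")
  res
}

#' Deduplicate screened pairs
#'
#' Pairs whose light members coincide within the m/z and retention-time
#' tolerances are merged transitively (single-linkage), keeping the most
#' intense representative of each cluster. The output is re-sorted by
#' (rt, mz) and re-numbered.
#'
#' @param pairs \code{br_pairs} from \code{\link{find_pairs}}
#' @param mz_tol_ppm m/z tolerance for collapsing (ppm)
#' @param rt_tol retention-time tolerance (minutes)
#' @return deduplicated \code{br_pairs}
#' @export
dedupe_pairs <- function(pairs, mz_tol_ppm = 10, rt_tol = 0.05) {
  n <- nrow(pairs)
  if (n <= 1L) return(pairs)
  # union-find over coinciding light members
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (abs(pairs$rt[i] - pairs$rt[j]) > rt_tol) next
    if (abs(pairs$mz_light[i] - pairs$mz_light[j]) >
        pairs$mz_light[i] * mz_tol_ppm / 1e6) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), root), function(idx)
    idx[which.max(pairs$intensity_light[idx])], integer(1))
  res <- pairs[sort(keep), , drop = FALSE]
  res <- res[order(res$rt, res$mz_light), , drop = FALSE]
  res$pair_id <- sprintf("P%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Remove pairs present in procedural blanks
#'
#' Drops pairs whose light feature is not at least \code{min_fold} times
#' more intense in samples than in the blank. A blank intensity of zero
#' always keeps the pair; a fold change exactly equal to \code{min_fold}
#' keeps it (>= comparison).
#'
#' @param pairs \code{br_pairs}
#' @param blank_features feature table of the blank run(s)
#' @param min_fold minimum sample/blank intensity fold (default 3)
#' @param mz_tol_ppm,rt_tol matching tolerances between sample and blank
#'   features
#' @return filtered \code{br_pairs}
#' @export
blank_filter <- function(pairs, blank_features, min_fold = 3,
                         mz_tol_ppm = 10, rt_tol = 0.05) {
  if (nrow(pairs) == 0L) return(pairs)
  bint <- .pair_intensity(blank_features)
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    hit <- abs(blank_features$mz - pairs$mz_light[i]) <=
      pairs$mz_light[i] * mz_tol_ppm / 1e6 &
      abs(blank_features$rt - pairs$rt[i]) <= rt_tol
    b <- if (any(hit)) max(bint[hit]) else 0
    if (b <= 0) TRUE else (pairs$intensity_light[i] / b) >= min_fold
  }, logical(1))
  res <- pairs[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write screened pairs to CSV
#' @param pairs \code{br_pairs}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
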