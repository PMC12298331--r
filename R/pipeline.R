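#' Run configuration for the full workflow
#'
#' Validates paths and assembles the per-stage parameter objects. All
#' settings can come from a YAML file via \code{\link{read_run_config}}.
#'
#' @param features path to the sample feature table (CSV)
#' @param db path to the compound database (CSV)
#' @param outdir output directory
#' @param spectra optional MS2 file (MSP/MGF/mzML)
#' @param blank optional blank feature table
#' @param model optional saved QSRR model archive
#' @param standards optional standards-library CSV
#' @param groups optional sample->group CSV (columns sample, group) for the
#'   comparison stage
#' @param pair \code{\link{pair_config}}
#' @param thresholds \code{\link{match_thresholds}}
#' @param sim_cfg \code{\link{similarity_config}}
#' @param compare_alpha,compare_min_lfc differential-analysis thresholds
#' @param seed RNG seed echoed into the manifest
#' @return list of class \code{"run_config"}
#' @export
run_config <- function(features, db, outdir,
                       spectra = NULL, blank = NULL, model = NULL,
                       standards = NULL, groups = NULL,
                       pair = pair_config(), thresholds = match_thresholds(),
                       sim_cfg = similarity_config(),
                       compare_alpha = 0.05, compare_min_lfc = 1,
                       seed = 1L) {
  for (p in c(features, db, spectra, blank, model, standards, groups))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p, call. = FALSE)
  structure(list(features = features, db = db, outdir = outdir,
                 spectra = spectra, blank = blank, model = model,
                 standards = standards, groups = groups,
                 pair = pair, thresholds = thresholds, sim_cfg = sim_cfg,
                 compare_alpha = compare_alpha,
                 compare_min_lfc = compare_min_lfc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; nested
#' mappings \code{pair}, \code{thresholds} and \code{similarity} override
#' individual fields of the corresponding defaults.
#'
#' @param path YAML file
#' @return \code{run_config}
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- do.call(pair_config, y$pair %||% list())
  thr <- do.call(match_thresholds, y$thresholds %||% list())
  sc <- do.call(similarity_config, y$similarity %||% list())
  run_config(features = y$features, db = y$db, outdir = y$outdir %||% ".",
             spectra = y$spectra, blank = y$blank, model = y$model,
             standards = y$standards, groups = y$groups,
             pair = p, thresholds = thr, sim_cfg = sc,
             compare_alpha = y$compare_alpha %||% 0.05,
             compare_min_lfc = y$compare_min_lfc %||% 1,
             seed = y$seed %||% 1L)
}

.stage <- function(manifest, name, in_rows, out_rows, outputs = character(0)) {
  message(sprintf("[%s] %s rows in -> %s rows out", name,
                  format(in_rows), format(out_rows)))
  manifest$stages[[name]] <- list(
    stage = name, rows_in = in_rows, rows_out = out_rows,
    outputs = as.list(outputs))
  manifest
}

#' Run the complete screening-to-comparison workflow
#'
#' Stages, in order: read inputs; bromine pair screen (+ deduplication and
#' optional blank filtering); MS2 diagnostic classification (when spectra
#' are provided); five-level annotation; group comparison (when group
#' labels are provided). Each stage logs its input/output row counts; a
#' manifest JSON with md5 hashes of every written file and a parameter echo
#' is written last. Rerunning with identical inputs and seed reproduces the
#' manifest hashes.
#'
#' @param config \code{\link{run_config}}
#' @return the manifest, invisibly (list; also written to
#'   \code{manifest.json} in the output directory)
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed, stages = list(),
                   parameters = list(
                     pair = unclass(config$pair),
                     thresholds = unclass(config$thresholds),
                     similarity = unclass(config$sim_cfg)))
  outputs <- character(0)
  fail <- function(stage, e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  features <- tryCatch(read_feature_table(config$features),
                       error = function(e) fail("read", e))
  db <- tryCatch(read_compound_db(config$db), error = function(e) fail("read", e))
  manifest <- .stage(manifest, "read", NA_integer_, nrow(features))

  pairs <- tryCatch({
    p <- find_pairs(features, config$pair)
    p <- dedupe_pairs(p, mz_tol_ppm = config$pair$tol_ppm,
                      rt_tol = config$pair$rt_tol)
    if (!is.null(config$blank))
      p <- blank_filter(p, read_feature_table(config$blank))
    p
  }, error = function(e) fail("pairs", e))
  pairs_path <- file.path(config$outdir, "pairs.csv")
  write_pairs(pairs, pairs_path); outputs <- c(outputs, pairs_path)
  manifest <- .stage(manifest, "pairs", nrow(features), nrow(pairs), pairs_path)

  spectra <- NULL
  if (!is.null(config$spectra)) {
    spectra <- tryCatch(read_spectra(config$spectra),
                        error = function(e) fail("ms2", e))
    pairs <- classify_pairs(pairs, spectra)
    flags_path <- file.path(config$outdir, "ms2_flags.csv")
    utils::write.csv(as.data.frame(pairs), flags_path, row.names = FALSE)
    outputs <- c(outputs, flags_path)
    manifest <- .stage(manifest, "ms2", length(spectra), nrow(pairs), flags_path)
  }

  model <- if (!is.null(config$model)) load_qsrr(config$model) else NULL
  ref_spectra <- NULL
  if (!is.null(spectra)) {
    titles <- vapply(spectra, function(s) s$title, character(1))
    ref_spectra <- stats::setNames(spectra, titles)[!is.na(titles)]
  }
  if (!is.null(config$standards)) {
    st <- read_standards(config$standards)
    hit <- match(db$name, st$table$name)
    db$standard <- !is.na(hit)
    upd <- !is.na(hit) & is.na(db$ref_rt)
    db$ref_rt[upd] <- st$table$ref_rt[hit[upd]]
  }
  ann <- tryCatch(
    annotate_all(pairs, db, model = model, ref_spectra = ref_spectra,
                 spectra = spectra, thr = config$thresholds,
                 sim_cfg = config$sim_cfg),
    error = function(e) fail("annotate", e))
  ann_path <- file.path(config$outdir, "annotations.csv")
  write_annotations(ann, ann_path); outputs <- c(outputs, ann_path)
  manifest <- .stage(manifest, "annotate", nrow(pairs), nrow(ann), ann_path)

  if (!is.null(config$groups)) {
    gr <- utils::read.csv(config$groups, stringsAsFactors = FALSE)
    sc <- intersect(sample_cols(features), gr$sample)
    glab <- gr$group[match(sc, gr$sample)]
    best <- ann[ann$best & ann$level <= 4, , drop = FALSE]
    keep_pairs <- pairs[pairs$pair_id %in% best$pair_id, , drop = FALSE]
    lid <- match(keep_pairs$light_id, features$feature_id)
    mat <- as.matrix(as.data.frame(features)[lid, sc, drop = FALSE])
    rownames(mat) <- best$name[match(keep_pairs$pair_id, best$pair_id)]
    cmp <- tryCatch({
      inter <- presence_intersections(mat, glab)
      diffs <- list()
      glev <- unique(glab)
      for (i in seq_along(glev)) for (j in seq_along(glev)) if (j > i) {
        d <- pairwise_diff(mat, glab, glev[i], glev[j],
                           alpha = config$compare_alpha,
                           min_lfc = config$compare_min_lfc)
        d$comparison <- paste0(glev[j], "_vs_", glev[i])
        diffs[[length(diffs) + 1L]] <- d
      }
      vip <- plsda_vip(mat, glab)
      list(inter = inter, diff = do.call(rbind, diffs), vip = vip)
    }, error = function(e) fail("compare", e))
    ip <- file.path(config$outdir, "intersections.csv")
    dp <- file.path(config$outdir, "diff.csv")
    vp <- file.path(config$outdir, "vip.csv")
    utils::write.csv(cmp$inter$intersections, ip, row.names = FALSE)
    utils::write.csv(cmp$diff, dp, row.names = FALSE)
    utils::write.csv(data.frame(compound = names(cmp$vip), vip = cmp$vip,
                                row.names = NULL), vp, row.names = FALSE)
    outputs <- c(outputs, ip, dp, vp)
    manifest <- .stage(manifest, "compare", nrow(mat), nrow(cmp$diff),
                       c(ip, dp, vp))
  }

  manifest$file_hashes <- as.list(tools::md5sum(outputs))
  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
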