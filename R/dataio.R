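#' Read an aligned LC-MS feature table
#'
#' Reads a centroided, aligned feature table (one row per feature) from CSV
#' or TSV. Two dialects are supported: \code{"generic"} expects columns
#' \code{rt}, \code{mz} and one or more intensity columns; and
#' \code{"alignment_export"} accepts the export of common alignment software
#' (columns such as \code{"Average Rt(min)"} / \code{"Average Mz"} followed
#' by per-sample area columns). Retention times are normalized to minutes
#' internally.
#'
#' @param path CSV/TSV file path
#' @param dialect \code{"generic"} or \code{"alignment_export"}
#' @param rt_unit unit of the retention-time column, \code{"min"} or
#'   \code{"sec"}; seconds are divided by 60 on read
#' @param sep field separator; guessed from the file extension by default
#' @return data.frame of class \code{"feature_table"} with columns
#'   \code{feature_id}, \code{rt} (minutes), \code{mz}, then one numeric
#'   intensity column per sample; attribute \code{"sample_cols"} names the
#'   intensity columns. Row order follows the file.
#' @export
read_feature_table <- function(path, dialect = c("generic", "alignment_export"),
                               rt_unit = c("min", "sec"), sep = NULL) {
  dialect <- match.arg(dialect)
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("cannot parse feature table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("feature table '", path, "' has no usable rows/columns", call. = FALSE)

  find_col <- function(cands) {
    hit <- which(tolower(names(df)) %in% tolower(cands))
    if (length(hit)) hit[1] else NA_integer_
  }
  if (dialect == "generic") {
    rt_col <- find_col(c("rt", "retention_time", "rt_min"))
    mz_col <- find_col(c("mz", "m/z", "mass"))
    id_col <- find_col(c("feature_id", "id"))
    meta <- c(rt_col, mz_col, id_col)
  } else {
    rt_col <- find_col(c("Average Rt(min)", "Average Rt", "RT [min]", "row retention time"))
    mz_col <- find_col(c("Average Mz", "Average m/z", "m/z", "row m/z"))
    id_col <- find_col(c("Alignment ID", "row ID"))
    meta <- c(rt_col, mz_col, id_col,
              find_col(c("Metabolite name", "Adduct type", "Fill %", "MS/MS assigned")))
  }
  if (is.na(rt_col)) stop("feature table is missing a retention-time column", call. = FALSE)
  if (is.na(mz_col)) stop("feature table is missing an m/z column", call. = FALSE)

  # a non-meta column counts as intensity when most of its cells look
  # numeric; stray non-numeric cells are then reported with a row number
  int_cols <- setdiff(seq_along(df), meta[!is.na(meta)])
  int_cols <- int_cols[vapply(df[int_cols], function(x) {
    if (is.numeric(x)) return(TRUE)
    x <- as.character(x[!is.na(x) & nzchar(x)])
    length(x) == 0L || mean(grepl("^[0-9eE+.\\-]+$", x)) >= 0.5
  }, logical(1))]
  if (length(int_cols) == 0L)
    stop("feature table has no intensity columns", call. = FALSE)

  num <- function(x, what, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(as.character(x)))
    if (length(bad))
      stop("non-numeric ", what, " in column '", col, "', row ", bad[1] + 1L,
           " (1-based incl. header)", call. = FALSE)
    v
  }
  rt <- num(df[[rt_col]], "retention time", names(df)[rt_col])
  if (rt_unit == "sec") rt <- rt / 60
  mz <- num(df[[mz_col]], "m/z", names(df)[mz_col])
  ids <- if (!is.na(id_col)) as.character(df[[id_col]]) else
    sprintf("F%04d", seq_len(nrow(df)))

  out <- data.frame(feature_id = ids, rt = rt, mz = mz,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in int_cols) {
    v <- num(df[[j]], "intensity", names(df)[j])
    v[is.na(v)] <- 0
    out[[names(df)[j]]] <- v
  }
  if (any(out$rt < 0) || any(out$mz <= 0))
    stop("feature table contains negative rt or non-positive m/z", call. = FALSE)
  structure(out, sample_cols = names(df)[int_cols], class = c("feature_table", "data.frame"))
}

#' Write a feature table to CSV
#'
#' Inverse of \code{\link{read_feature_table}} (generic dialect): columns
#' \code{feature_id}, \code{rt}, \code{mz}, then the sample intensity
#' columns.
#'
#' @param x feature table
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample (intensity) columns of a feature table
#' @param x feature table
#' @return character vector of intensity column names
#' @export
sample_cols <- function(x) {
  sc <- attr(x, "sample_cols")
  if (is.null(sc)) setdiff(names(x), c("feature_id", "rt", "mz")) else sc
}

#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor m/z
#' @param mz,intensity peak centroids; zero/negative intensities are dropped
#'   and peaks are stored sorted by m/z
#' @param rt optional retention time (minutes) of the acquisition
#' @param title optional identifier
#' @return object of class \code{"ms2_spectrum"}
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity, rt = NA_real_, title = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  keep <- is.finite(mz) & is.finite(intensity) & intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  o <- order(mz)
  structure(list(precursor_mz = as.numeric(precursor_mz),
                 peaks = cbind(mz = mz[o], intensity = intensity[o]),
                 rt = as.numeric(rt), title = as.character(title)),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f, %d peaks", x$precursor_mz, nrow(x$peaks)))
  if (is.finite(x$rt)) cat(sprintf(", rt %.2f min", x$rt))
  cat("\n")
  invisible(x)
}

#' Read MS2 spectra from MSP, MGF or mzML
#'
#' MSP and MGF text libraries are parsed directly; mzML files are read
#' through the \pkg{mzR} package when it is installed. Unparseable records
#' are skipped with a warning carrying the skip count. Peak lists are
#' returned sorted by m/z.
#'
#' @param path spectrum file; format inferred from the extension
#' @return list of \code{\link{ms2_spectrum}} objects
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msp = read_msp(path),
         mgf = read_mgf(path),
         mzml = read_mzml(path),
         stop("unsupported spectrum format: .", ext, call. = FALSE))
}

read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # records separated by blank lines; header "Key: value" pairs then peaks
  rec_starts <- grep("^\\s*name\\s*:", lines, ignore.case = TRUE)
  if (length(rec_starts) == 0L) return(list())
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  out <- list(); skipped <- 0L
  for (i in seq_along(rec_starts)) {
    block <- lines[rec_starts[i]:rec_ends[i]]
    sp <- tryCatch(parse_msp_block(block), error = function(e) NULL)
    if (is.null(sp)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- sp
  }
  if (skipped > 0L)
    warning(skipped, " MSP record(s) skipped as unparseable", call. = FALSE)
  out
}

parse_msp_block <- function(block) {
  kv_idx <- grep("^[A-Za-z][A-Za-z0-9_/ ]*:", block)
  kv <- block[kv_idx]
  keys <- tolower(trimws(sub(":.*$", "", kv)))
  vals <- trimws(sub("^[^:]*:", "", kv))
  get <- function(k) { i <- which(keys == k); if (length(i)) vals[i[1]] else NA_character_ }
  prec <- suppressWarnings(as.numeric(get("precursormz")))
  rt <- suppressWarnings(as.numeric(get("retentiontime")))
  title <- get("name")
  peak_lines <- block[setdiff(seq_along(block), kv_idx)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  if (length(peak_lines) == 0L) stop("no peaks")
  pm <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[\t ;]+"), function(p) {
    as.numeric(p[1:2])
  }))
  if (anyNA(pm)) stop("bad peak line")
  ms2_spectrum(prec, pm[, 1], pm[, 2], rt = rt, title = title)
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  out <- list(); skipped <- 0L
  for (i in seq_along(starts)) {
    end <- ends[ends > starts[i]][1]
    if (is.na(end)) { skipped <- skipped + 1L; next }
    block <- lines[(starts[i] + 1L):(end - 1L)]
    sp <- tryCatch({
      kv_idx <- grep("=", block, fixed = TRUE)
      kv <- block[kv_idx]
      keys <- toupper(sub("=.*$", "", kv))
      vals <- sub("^[^=]*=", "", kv)
      get <- function(k) { j <- which(keys == k); if (length(j)) vals[j[1]] else NA_character_ }
      prec <- suppressWarnings(as.numeric(strsplit(get("PEPMASS"), "[ \t]")[[1]][1]))
      rt_s <- suppressWarnings(as.numeric(get("RTINSECONDS")))
      peak_lines <- trimws(block[setdiff(seq_along(block), kv_idx)])
      peak_lines <- peak_lines[nzchar(peak_lines)]
      pm <- do.call(rbind, lapply(strsplit(peak_lines, "[\t ]+"),
                                  function(p) as.numeric(p[1:2])))
      if (is.null(pm) || anyNA(pm)) stop("bad peaks")
      ms2_spectrum(prec, pm[, 1], pm[, 2], rt = rt_s / 60, title = get("TITLE"))
    }, error = function(e) NULL)
    if (is.null(sp)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- sp
  }
  if (length(starts) > length(ends))
    skipped <- skipped + (length(starts) - length(ends))
  if (skipped > 0L)
    warning(skipped, " MGF record(s) skipped as unparseable", call. = FALSE)
  out
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  ms2 <- which(hdr$msLevel == 2L)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(h, i)
    ms2_spectrum(hdr$precursorMZ[i], pk[, 1], pk[, 2],
                 rt = hdr$retentionTime[i] / 60,
                 title = as.character(hdr$acquisitionNum[i]))
  })
}

#' Write spectra to an MSP library file
#'
#' @param spectra list of \code{\link{ms2_spectrum}} objects
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (sp in spectra) {
    nm <- if (is.na(sp$title)) "unknown" else sp$title
    writeLines(sprintf("Name: %s", nm), con)
    writeLines(sprintf("PrecursorMZ: %.6f", sp$precursor_mz), con)
    if (is.finite(sp$rt)) writeLines(sprintf("RetentionTime: %.4f", sp$rt), con)
    writeLines(sprintf("Num Peaks: %d", nrow(sp$peaks)), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.4f", sp$peaks[, 1], sp$peaks[, 2]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Link MS2 spectra to features by precursor m/z and retention time
#'
#' Each feature is assigned the spectrum whose precursor m/z lies within
#' \code{tol_ppm} and (when both carry a retention time) within
#' \code{rt_window} minutes, choosing the closest precursor m/z; each
#' spectrum is assigned to at most one feature. The assignment is greedy in
#' order of increasing m/z distance, so it is deterministic under
#' permutation of either input.
#'
#' @param features feature table
#' @param spectra list of \code{\link{ms2_spectrum}}
#' @param tol_ppm precursor tolerance (default 10 ppm)
#' @param rt_window co-elution window in minutes (default 0.2); ignored for
#'   spectra without a retention time
#' @return integer vector over features: index into \code{spectra} or
#'   \code{NA} when unlinked
#' @export
link_ms2 <- function(features, spectra, tol_ppm = 10, rt_window = 0.2) {
  n <- nrow(features)
  if (n == 0L || length(spectra) == 0L) return(rep(NA_integer_, n))
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  srt <- vapply(spectra, function(s) s$rt, numeric(1))
  cand <- list()
  for (i in seq_len(n)) {
    dmz <- abs(prec - features$mz[i])
    ok <- dmz <= features$mz[i] * tol_ppm / 1e6
    ok <- ok & (!is.finite(srt) | abs(srt - features$rt[i]) <= rt_window)
    for (j in which(ok))
      cand[[length(cand) + 1L]] <- c(i, j, dmz[j])
  }
  link <- rep(NA_integer_, n)
  if (length(cand) == 0L) return(link)
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
  used_sp <- logical(length(spectra))
  for (r in seq_len(nrow(cm))) {
    i <- cm[r, 1]; j <- cm[r, 2]
    if (is.na(link[i]) && !used_sp[j]) { link[i] <- as.integer(j); used_sp[j] <- TRUE }
  }
  link
}

#' Read a compound database
#'
#' Reads a CSV/TSV compound database with columns \code{name} and at least
#' one of \code{formula} or \code{smiles}; optional columns \code{n_sites},
#' \code{ref_rt} (minutes, measured or QSRR-predicted derivative retention
#' time), \code{source}, \code{standard} (logical: authentic standard
#' available). When \code{n_sites} is absent it is computed from the SMILES
#' by \code{\link{count_sites}}; records with neither formula nor SMILES are
#' dropped with a warning. Formulas absent but SMILES present are filled
#' from the structure.
#'
#' @param path CSV/TSV path
#' @param default_sites site count for formula-only records (default 1)
#' @return data.frame of class \code{"compound_db"} with columns
#'   \code{name}, \code{formula}, \code{smiles}, \code{n_sites},
#'   \code{ref_rt}, \code{source}, \code{standard}
#' @export
read_compound_db <- function(path, default_sites = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  names(df) <- tolower(names(df))
  if (!"name" %in% names(df)) stop("compound database needs a 'name' column", call. = FALSE)
  get <- function(col, default) if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  out <- data.frame(
    name = as.character(df$name),
    formula = as.character(get("formula", NA_character_)),
    smiles = as.character(get("smiles", NA_character_)),
    n_sites = suppressWarnings(as.integer(get("n_sites", NA_integer_))),
    ref_rt = suppressWarnings(as.numeric(get("ref_rt", NA_real_))),
    source = as.character(get("source", "db")),
    standard = as.logical(get("standard", FALSE)),
    stringsAsFactors = FALSE)
  out$standard[is.na(out$standard)] <- FALSE
  usable <- !(is.na(out$formula) | !nzchar(out$formula)) |
    !(is.na(out$smiles) | !nzchar(out$smiles))
  if (any(!usable)) {
    warning(sum(!usable), " record(s) without formula or SMILES dropped", call. = FALSE)
    out <- out[usable, , drop = FALSE]
  }
  need_formula <- (is.na(out$formula) | !nzchar(out$formula)) & nzchar(out$smiles)
  if (any(need_formula))
    out$formula[need_formula] <- smiles_to_formula(out$smiles[need_formula])
  need_sites <- is.na(out$n_sites)
  has_smiles <- !is.na(out$smiles) & nzchar(out$smiles)
  if (any(need_sites & has_smiles)) {
    sc <- count_sites(out$smiles[need_sites & has_smiles])
    out$n_sites[need_sites & has_smiles] <- sc$n_sites
  }
  out$n_sites[is.na(out$n_sites)] <- as.integer(default_sites)
  rownames(out) <- NULL
  class(out) <- c("compound_db", "data.frame")
  out
}

#' Read a standards library
#'
#' A standards library records, per authentic standard, the measured
#' derivative retention time and (optionally, via an MSP file) the measured
#' derivative MS2 spectrum. Used to confirm level-1 annotations.
#'
#' @param path CSV with columns \code{name}, \code{ref_rt}; optional
#'   \code{msp} column naming spectra in \code{msp_path} by title
#' @param msp_path optional MSP library of measured derivative spectra
#' @return list with elements \code{table} (data.frame) and \code{spectra}
#'   (named list of spectra, possibly empty)
#' @export
read_standards <- function(path, msp_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("name", "ref_rt") %in% names(df)))
    stop("standards library needs 'name' and 'ref_rt' columns", call. = FALSE)
  spectra <- list()
  if (!is.null(msp_path)) {
    sl <- read_spectra(msp_path)
    names(sl) <- vapply(sl, function(s) s$title, character(1))
    spectra <- sl
  }
  list(table = df, spectra = spectra)
}
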