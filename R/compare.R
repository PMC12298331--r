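#' Presence/absence intersections across sample groups
#'
#' A compound counts as present in a group when its intensity exceeds
#' \code{detect_threshold} in at least one (\code{rule = "any"}) or more
#' than half (\code{rule = "majority"}) of the group's samples. Returns the
#' per-group presence counts plus the full upset-style intersection table
#' over presence patterns.
#'
#' @param matrix numeric compounds-by-samples intensity matrix with row and
#'   column names
#' @param groups character/factor vector of group labels, one per column
#' @param detect_threshold intensity above which a compound is detected
#' @param rule \code{"any"} or \code{"majority"}
#' @return list with \code{per_group} (named presence counts),
#'   \code{shared_all} (count present in every group), and
#'   \code{intersections} (data.frame: one row per observed presence
#'   pattern with its member groups and compound count)
#' @export
presence_intersections <- function(matrix, groups, detect_threshold = 0,
                                   rule = c("any", "majority")) {
  rule <- match.arg(rule)
  groups <- as.character(groups)
  stopifnot(ncol(matrix) == length(groups))
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need at least 2 groups", call. = FALSE)
  pres <- sapply(glev, function(g) {
    sub <- matrix[, groups == g, drop = FALSE]
    det <- sub > detect_threshold
    if (rule == "any") rowSums(det) >= 1L else rowSums(det) > ncol(sub) / 2
  })
  colnames(pres) <- glev
  pattern <- apply(pres, 1, function(p) paste(glev[p], collapse = "&"))
  tab <- table(pattern)
  inter <- data.frame(pattern = names(tab),
                      n_groups = vapply(strsplit(names(tab), "&", fixed = TRUE),
                                        function(x) sum(nzchar(x)), integer(1)),
                      count = as.integer(tab), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$n_groups, -inter$count), , drop = FALSE]
  rownames(inter) <- NULL
  list(per_group = colSums(pres),
       shared_all = sum(rowSums(pres) == length(glev)),
       intersections = inter)
}

#' Pairwise differential abundance between two groups
#'
#' Per compound: Welch's unequal-variance t-test on log2-transformed
#' intensities (half-minimum pseudo-count for zeros), Benjamini-Hochberg
#' correction across compounds, and a significance call requiring both
#' q < \code{alpha} and |log2 fold change| >= \code{min_lfc}. Compounds with
#' zero variance in both groups and equal means get p = 1.
#'
#' @param matrix compounds-by-samples intensity matrix
#' @param groups group label per column
#' @param g1,g2 the two group labels to compare (fold change is g2 vs g1)
#' @param alpha BH-adjusted significance threshold (default 0.05)
#' @param min_lfc minimum absolute log2 fold change (default 1)
#' @return data.frame: \code{compound}, \code{log2fc}, \code{p}, \code{q},
#'   \code{significant}
#' @export
pairwise_diff <- function(matrix, groups, g1, g2, alpha = 0.05, min_lfc = 1) {
  groups <- as.character(groups)
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need at least 2 replicates per group", call. = FALSE)
  m <- as.matrix(matrix)
  pos <- m[m > 0]
  pseudo <- if (length(pos)) min(pos) / 2 else 1
  lm2 <- log2(m + pseudo)
  res <- t(apply(lm2, 1, function(row) {
    x <- row[i1]; y <- row[i2]
    lfc <- mean(y) - mean(x)
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else tryCatch(stats::t.test(y, x)$p.value, error = function(e) 1)
    c(lfc, p)
  }))
  out <- data.frame(compound = rownames(m) %||% as.character(seq_len(nrow(m))),
                    log2fc = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha & abs(out$log2fc) >= min_lfc
  rownames(out) <- NULL
  out
}

#' PLS-DA variable importance in projection
#'
#' Fits a PLS-DA model by the NIPALS algorithm on autoscaled (unit-variance)
#' data against dummy-coded group membership and returns the VIP score per
#' compound: VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a), where
#' SSY_a is the Y-variance explained by component a and w_a the unit weight
#' vector. By construction the mean of squared VIP scores equals 1.
#'
#' @param matrix compounds-by-samples intensity matrix
#' @param groups group label per column
#' @param n_components number of PLS components (default 2)
#' @param scale autoscale variables to unit variance (default TRUE)
#' @return named numeric vector of VIP scores, one per compound
#' @export
plsda_vip <- function(matrix, groups, n_components = 2L, scale = TRUE) {
  X <- t(as.matrix(matrix))              # samples x compounds
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  Y <- stats::model.matrix(~ groups - 1)
  X <- base::scale(X, center = TRUE, scale = scale)
  sdev0 <- attr(X, "scaled:scale")
  if (!is.null(sdev0)) X[, sdev0 == 0] <- 0
  X[!is.finite(X)] <- 0
  Y <- base::scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(X)
  if (n_components > min(nrow(X) - 1L, p))
    stop("n_components exceeds the data rank", call. = FALSE)
  W <- matrix(0, p, n_components)
  SSY <- numeric(n_components)
  Xa <- X; Ya <- Y
  for (a in seq_len(n_components)) {
    # NIPALS for one component with multivariate Y
    u <- Ya[, which.max(apply(Ya, 2, stats::var)), drop = TRUE]
    for (it in seq_len(500L)) {
      w <- crossprod(Xa, u); w <- w / sqrt(sum(w^2))
      t_ <- Xa %*% w
      q <- crossprod(Ya, t_) / sum(t_^2)
      u_new <- Ya %*% q / sum(q^2)
      if (sum((u_new - u)^2) / max(sum(u^2), 1e-12) < 1e-12) { u <- u_new; break }
      u <- u_new
    }
    t_ <- Xa %*% w
    p_load <- crossprod(Xa, t_) / sum(t_^2)
    q <- crossprod(Ya, t_) / sum(t_^2)
    SSY[a] <- sum(t_^2) * sum(q^2)
    W[, a] <- w
    Xa <- Xa - t_ %*% t(p_load)
    Ya <- Ya - t_ %*% t(q)
  }
  vip <- sqrt(p * as.numeric(W^2 %*% SSY) / sum(SSY))
  names(vip) <- colnames(X)
  vip
}
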