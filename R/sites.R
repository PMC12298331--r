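#' @importFrom ChemmineR smiles2sdf
NULL

# Parse SMILES to an SDFset via OpenBabel; errors name the offending record.
.smiles_to_sdf <- function(smiles) {
  if (any(is.na(smiles) | !nzchar(smiles)))
    stop("empty or missing SMILES", call. = FALSE)
  nm <- names(smiles)
  if (is.null(nm)) nm <- paste0("mol", seq_along(smiles))
  names(smiles) <- nm
  sdf <- suppressWarnings(tryCatch(ChemmineR::smiles2sdf(smiles),
                                   error = function(e)
                                     stop("invalid SMILES: ",
                                          conditionMessage(e), call. = FALSE)))
  ok <- ChemmineR::validSDF(sdf)
  if (length(ok) != length(smiles) || any(!ok))
    stop("invalid SMILES: '",
         smiles[if (length(ok) == length(smiles)) which(!ok)[1] else 1L],
         "'", call. = FALSE)
  sdf
}

.smarts_count <- function(sdf, smarts) {
  as.integer(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE))
}

#' Count derivatizable hydroxyl/amino sites in a structure
#'
#' Counts the functional groups that 5-bromonicotinoyl chloride acylates:
#' aliphatic hydroxyls (OH on sp3 carbon), phenolic hydroxyls, and primary
#' and secondary aliphatic amines. Carboxylic-acid OH and amide NH are
#' excluded; they are not derivatized under the mild labeling conditions.
#'
#' @param smiles character vector of SMILES
#' @return data.frame with one row per structure: \code{smiles},
#'   \code{n_aliphatic_oh}, \code{n_phenolic_oh}, \code{n_primary_amine},
#'   \code{n_secondary_amine}, \code{n_sites} (the sum)
#' @examples
#' count_sites("OCCc1ccc(O)cc1")  # tyrosol: 1 aliphatic + 1 phenolic OH
#' @export
count_sites <- function(smiles) {
  sdf <- .smiles_to_sdf(smiles)
  pats <- c(
    n_aliphatic_oh    = "[CX4][OX2H]",
    n_phenolic_oh     = "[c][OX2H]",
    n_primary_amine   = "[NX3H2;!$(NC=O)]",
    n_secondary_amine = "[NX3H1;!$(NC=O)]"
  )
  counts <- vapply(pats, function(p) .smarts_count(sdf, p),
                   integer(length(smiles)))
  counts <- matrix(counts, nrow = length(smiles),
                   dimnames = list(NULL, names(pats)))
  out <- data.frame(smiles = as.character(smiles), counts,
                    stringsAsFactors = FALSE)
  out$n_sites <- rowSums(counts)
  out
}

#' Molecular formula from SMILES
#'
#' @param smiles character vector of SMILES
#' @return character vector of Hill formulas
#' @export
smiles_to_formula <- function(smiles) {
  sdf <- .smiles_to_sdf(smiles)
  as.character(ChemmineR::propOB(sdf)$formula)
}
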