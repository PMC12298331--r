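#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as \code{"C8H10O2"} into a named integer
#' vector of element counts. Only elements in the internal constants table
#' are accepted; repeated element symbols are summed.
#'
#' @param text formula string (Hill or any element-count order)
#' @return named integer vector of element counts (class
#'   \code{"element_counts"}), in Hill order
#' @examples
#' parse_formula("C8H10O2")
#' parse_formula("C6H2BrNO")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  txt <- gsub("[[:space:]]", "", text)
  tokens <- regmatches(txt, gregexpr("([A-Z][a-z]?)([0-9]*)", txt))[[1]]
  if (length(tokens) == 0L || paste(tokens, collapse = "") != txt)
    stop("malformed formula: '", text, "'", call. = FALSE)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ATOMIC_MASS))
      stop("unknown element '", sym, "' in formula '", text, "'", call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  as_element_counts(counts)
}

#' Construct element counts from a named vector
#'
#' Validates and canonicalizes (Hill order: C, H, then alphabetical) a named
#' count vector. Zero counts are dropped.
#'
#' @param x named numeric/integer vector of non-negative element counts
#' @return named integer vector with class \code{"element_counts"}
#' @export
as_element_counts <- function(x) {
  if (inherits(x, "element_counts")) return(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("element counts must be named", call. = FALSE)
  if (any(!names(x) %in% names(.ATOMIC_MASS)))
    stop("unknown element(s): ",
         paste(setdiff(names(x), names(.ATOMIC_MASS)), collapse = ", "),
         call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers", call. = FALSE)
  x <- x[x > 0]
  counts <- tapply(as.integer(x), names(x), sum)
  syms <- names(counts)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  out <- as.integer(counts[hill])
  names(out) <- hill
  structure(out, class = "element_counts")
}

#' Format element counts as a Hill-notation string
#'
#' @param counts an \code{element_counts} vector (or coercible)
#' @return single formula string, e.g. \code{"C14H12BrNO3"}
#' @export
format_formula <- function(counts) {
  counts <- as_element_counts(counts)
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Sum of two element-count vectors
#' @param a,b element counts
#' @return combined element counts
#' @export
add_formulas <- function(a, b) {
  a <- as_element_counts(a); b <- as_element_counts(b)
  as_element_counts(c(unclass(a), unclass(b)))
}

#' Monoisotopic mass or m/z
#'
#' Sums monoisotopic atomic masses (most abundant isotope per element;
#' bromine enters as 79Br). For charged species the electron mass is
#' subtracted (cations) or added (anions) per charge when
#' \code{electron_correct} is \code{TRUE}, and the result is divided by
#' \code{|charge|} to give m/z. The electron correction matters at the fourth
#' decimal place for the diagnostic fragments.
#'
#' @param counts element counts (or formula string)
#' @param charge integer charge; 0 returns the neutral monoisotopic mass
#' @param electron_correct apply the electron-mass correction for ions
#' @return mass in Da (charge 0) or m/z
#' @examples
#' monoisotopic_mass(parse_formula("C8H10O2"))            # 138.0681
#' monoisotopic_mass("C6H3BrNO", charge = 1)              # 183.9393 (acylium)
#' @export
monoisotopic_mass <- function(counts, charge = 0L, electron_correct = TRUE) {
  if (is.character(counts)) counts <- parse_formula(counts)
  counts <- as_element_counts(counts)
  m <- sum(.ATOMIC_MASS[names(counts)] * counts)
  if (charge == 0L) return(m)
  if (electron_correct) m <- m - charge * .MASS_ELECTRON
  m / abs(charge)
}

#' Elemental composition of a BrNC derivative
#'
#' Adds the net tag composition C6H2BrNO once per derivatized site
#' (acylation replaces one labile hydrogen per OH/NH site).
#'
#' @param parent element counts (or formula string) of the underivatized
#'   compound
#' @param n_tags number of derivatized sites (>= 1)
#' @return element counts of the derivative
#' @examples
#' format_formula(derivatize_formula("C8H10O2", 1))  # "C14H12BrNO3"
#' @export
derivatize_formula <- function(parent, n_tags = 1L) {
  if (is.character(parent)) parent <- parse_formula(parent)
  if (length(n_tags) != 1L || is.na(n_tags) || n_tags < 1L || n_tags != round(n_tags))
    stop("n_tags must be a positive integer", call. = FALSE)
  tag <- tag_constants()$tag_addition
  as_element_counts(c(unclass(as_element_counts(parent)), tag * as.integer(n_tags)))
}

#' Shift an m/z by bromine isotope substitution
#'
#' Returns the m/z of the isotopologue in which \code{n_swapped} 79Br atoms
#' are replaced by 81Br (singly charged ions assumed).
#'
#' @param mz observed or theoretical m/z of the light species
#' @param n_swapped number of 79Br -> 81Br substitutions (0 allowed: identity)
#' @return shifted m/z
#' @examples
#' br_shift(322.0083, 1)  # 324.0063
#' @export
br_shift <- function(mz, n_swapped = 1L) {
  if (any(n_swapped < 0) || any(n_swapped != round(n_swapped)))
    stop("n_swapped must be a non-negative integer", call. = FALSE)
  mz + n_swapped * (.MASS_BR81 - .MASS_BR79)
}

#' Theoretical bromine isotopologue intensity ratio
#'
#' For an ion carrying \code{n_br} bromine atoms, returns the intensity of
#' the isotopologue with \code{k} 81Br substitutions relative to the all-79Br
#' monoisotopic peak, from the binomial expansion of the natural 79Br/81Br
#' abundances: C(n,k) q^k p^(n-k) / p^n with p = a(79Br), q = a(81Br).
#' For n = k = 1 this is the ~0.97 ratio of the pair signature.
#'
#' @param n_br number of bromine atoms (>= 1)
#' @param k number of 81Br substitutions, 0 <= k <= n_br
#' @return intensity ratio I(M + 2k) / I(M)
#' @examples
#' expected_ratio(1, 1)  # 0.9728
#' expected_ratio(2, 1)  # 1.9456
#' @export
expected_ratio <- function(n_br, k = 1L) {
  if (n_br < 1L || n_br != round(n_br)) stop("n_br must be a positive integer", call. = FALSE)
  if (k < 0L || k != round(k)) stop("k must be a non-negative integer", call. = FALSE)
  if (k > n_br) stop("k must not exceed n_br", call. = FALSE)
  choose(n_br, k) * (.ABUND_BR81 / .ABUND_BR79)^k
}

#' Relative mass error in parts per million
#'
#' @param observed observed m/z
#' @param theoretical theoretical m/z (> 0)
#' @return signed ppm error, 1e6 (observed - theoretical) / theoretical
#' @examples
#' ppm_error(322.0083, 322.0073)  # ~ +3.1 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}

#' Ring and double-bond equivalents
#'
#' RDBE = 1 + C + Si - (H + halogens + Na + K)/2 + (N + P)/2 under standard
#' valences; used as a plausibility filter in formula generation.
#'
#' @param counts element counts (or formula string)
#' @return RDBE value (can be half-integral for radicals/ions)
#' @export
rdbe <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  counts <- as_element_counts(counts)
  g <- function(syms) sum(counts[intersect(syms, names(counts))])
  1 + g(c("C", "Si")) - g(c("H", "F", "Cl", "Br", "I", "Na", "K")) / 2 + g(c("N", "P")) / 2
}

#' Generate candidate molecular formulas for an accurate mass
#'
#' Exhaustively enumerates CHNO(S) compositions carrying exactly
#' \code{n_br} bromine atoms whose neutral monoisotopic mass lies within
#' \code{tol_ppm} of \code{neutral_mass}. Candidates with negative or
#' non-integral RDBE are discarded (even-electron neutral molecules); the
#' result is sorted by absolute ppm error. This is the level-5 fallback of
#' the annotation scheme, where only a molecular formula can be assigned.
#'
#' @param neutral_mass target neutral monoisotopic mass, Da
#' @param tol_ppm mass tolerance in ppm
#' @param n_br exact number of bromine atoms (tag count for derivatives)
#' @param bounds named list of upper bounds per element, e.g.
#'   \code{list(C = 30, H = 60, N = 5, O = 10, S = 0)}; lower bounds are 0
#' @return data.frame with columns \code{formula}, \code{mass}, \code{ppm},
#'   \code{rdbe}, sorted by \code{abs(ppm)}; zero rows when nothing matches
#' @examples
#' generate_formulas(321.0001, 10, n_br = 1,
#'                   bounds = list(C = 20, H = 30, N = 3, O = 6))
#' @export
generate_formulas <- function(neutral_mass, tol_ppm = 10,
                              n_br = 0L,
                              bounds = list(C = 40, H = 80, N = 5, O = 12, S = 2)) {
  stopifnot(neutral_mass > 0, tol_ppm > 0, n_br >= 0)
  bC <- bounds$C %||% 0L; bN <- bounds$N %||% 0L
  bO <- bounds$O %||% 0L; bS <- bounds$S %||% 0L; bH <- bounds$H %||% 0L
  tol_da <- neutral_mass * tol_ppm / 1e6
  mH <- .ATOMIC_MASS[["H"]]
  base_br <- n_br * .ATOMIC_MASS[["Br"]]
  out <- list()
  for (nC in 0:bC) {
    mC <- nC * 12
    if (base_br + mC > neutral_mass + tol_da) break
    for (nN in 0:bN) {
      for (nO in 0:bO) {
        for (nS in 0:bS) {
          m0 <- base_br + mC + nN * .ATOMIC_MASS[["N"]] +
            nO * .ATOMIC_MASS[["O"]] + nS * .ATOMIC_MASS[["S"]]
          if (m0 > neutral_mass + tol_da) break
          # solve the hydrogen count from the residual mass; the tolerance
          # window spans < 1 H so at most a couple of integer candidates
          h_mid <- (neutral_mass - m0) / mH
          for (nH in unique(pmax(0L, c(floor(h_mid), ceiling(h_mid))))) {
            if (nH > bH) next
            mass <- m0 + nH * mH
            if (abs(mass - neutral_mass) > tol_da) next
            cnt <- c(C = nC, H = nH, N = nN, O = nO, S = nS, Br = n_br)
            cnt <- cnt[cnt > 0]
            if (length(cnt) == 0L) next
            ec <- as_element_counts(cnt)
            r <- rdbe(ec)
            if (r < 0 || abs(r - round(r)) > 1e-9) next
            out[[length(out) + 1L]] <- data.frame(
              formula = format_formula(ec), mass = mass,
              ppm = ppm_error(neutral_mass, mass), rdbe = r,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$formula), , drop = FALSE]
  res <- res[order(abs(res$ppm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
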