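#' @title Atomic constants used throughout the package
#' @description Monoisotopic masses (Da) of the most abundant isotope of each
#'   supported element, pinned to IUPAC 2021 values so that computed m/z are
#'   bit-stable across platforms. Bromine additionally carries its two-isotope
#'   envelope (79Br/81Br), the basis of the pair-screening signature.
#' @keywords internal
#' @name constants
NULL

# Monoisotopic mass of the most abundant isotope, Da (IUPAC 2021 / AME2020)
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183376,   # 79Br, the light (monoisotopic) bromine
  I  = 126.904473,
  Na = 22.98976928,
  K  = 38.96370668,
  Si = 27.97692653
)

# Standard valences for ring-double-bond-equivalent filtering
.VALENCE <- c(C = 4, H = 1, N = 3, O = 2, S = 2, P = 3,
              F = 1, Cl = 1, Br = 1, I = 1, Na = 1, K = 1, Si = 4)

.MASS_ELECTRON <- 0.000548579909   # Da
.MASS_PROTON   <- .ATOMIC_MASS[["H"]] - .MASS_ELECTRON

# Bromine isotopes: mass and natural abundance
.MASS_BR79 <- 78.9183376
.MASS_BR81 <- 80.9162906
.ABUND_BR79 <- 0.5069
.ABUND_BR81 <- 0.4931

#' BrNC tag constants
#'
#' Constants describing the 5-bromonicotinoyl (BrNC) derivatization tag: the
#' net elemental addition per labeled hydroxyl/amino site, the three
#' diagnostic MS2 fragment m/z values produced by the reagent moiety, and the
#' bromine isotope signature (mass spacing and abundance ratio) that the pair
#' screen exploits.
#'
#' Acylation by 5-bromonicotinoyl chloride replaces one labile hydrogen on an
#' OH or NH group, so the net composition added per site is C6H2BrNO. The
#' diagnostic fragments are: the acylium cation C6H3BrNO+ (ester/amide bond
#' cleavage, seen for all derivatives), protonated 5-bromonicotinic acid
#' [C6H4BrNO2+H]+ (specific to hydroxyl derivatives), and protonated
#' 5-bromonicotinamide [C6H5BrN2O+H]+ (characteristic of amino derivatives).
#'
#' @return A list with elements:
#'   \item{tag_addition}{named integer vector, net elemental addition per
#'     derivatized site (C6H2BrNO)}
#'   \item{frag_acylium_mz}{m/z of the C6H3BrNO+ acylium diagnostic}
#'   \item{frag_hydroxyl_mz}{m/z of the hydroxyl-derivative diagnostic}
#'   \item{frag_amino_mz}{m/z of the amino-derivative diagnostic}
#'   \item{br_delta}{mass difference m(81Br) - m(79Br), Da}
#'   \item{br_ratio}{natural abundance ratio a(81Br)/a(79Br)}
#' @examples
#' tc <- tag_constants()
#' round(tc$frag_acylium_mz, 4)  # 183.9393
#' round(tc$br_delta, 3)         # 1.998
#' @export
tag_constants <- function() {
  list(
    tag_addition    = c(C = 6L, H = 2L, Br = 1L, N = 1L, O = 1L),
    frag_acylium_mz = monoisotopic_mass(parse_formula("C6H3BrNO"), charge = 1L),
    frag_hydroxyl_mz = monoisotopic_mass(parse_formula("C6H4BrNO2"), charge = 0L) + .MASS_PROTON,
    frag_amino_mz    = monoisotopic_mass(parse_formula("C6H5BrN2O"), charge = 0L) + .MASS_PROTON,
    br_delta = .MASS_BR81 - .MASS_BR79,
    br_ratio = .ABUND_BR81 / .ABUND_BR79
  )
}

#' Ionization adducts
#'
#' Builds an adduct definition (name, mass shift in Da, charge). The default
#' workflow uses protonation only, matching positive-ion electrospray
#' acquisition of BrNC derivatives; the pyridine nitrogen of the tag is the
#' favored protonation site.
#'
#' @param name adduct name; currently \code{"[M+H]+"} or \code{"[M+Na]+"}
#' @return list with \code{name}, \code{mass_shift} (Da) and \code{charge}
#' @examples
#' adduct("[M+H]+")$mass_shift  # proton mass
#' @export
adduct <- function(name = "[M+H]+") {
  shifts <- list(
    "[M+H]+"  = .MASS_PROTON,
    "[M+Na]+" = .ATOMIC_MASS[["Na"]] - .MASS_ELECTRON
  )
  if (!name %in% names(shifts))
    stop("unknown adduct: ", name, call. = FALSE)
  list(name = name, mass_shift = shifts[[name]], charge = 1L)
}

#' Export package constants as JSON
#'
#' Serializes the atomic-mass table, bromine isotope data and tag constants
#' to a JSON string (or file) for documentation and provenance.
#'
#' @param path optional file path; if \code{NULL} the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
constants_json <- function(path = NULL) {
  tc <- tag_constants()
  obj <- list(
    atomic_mass = as.list(.ATOMIC_MASS),
    electron_mass = .MASS_ELECTRON,
    proton_mass = .MASS_PROTON,
    br79 = list(mass = .MASS_BR79, abundance = .ABUND_BR79),
    br81 = list(mass = .MASS_BR81, abundance = .ABUND_BR81),
    tag = list(
      tag_addition = as.list(tc$tag_addition),
      frag_acylium_mz = tc$frag_acylium_mz,
      frag_hydroxyl_mz = tc$frag_hydroxyl_mz,
      frag_amino_mz = tc$frag_amino_mz,
      br_delta = tc$br_delta,
      br_ratio = tc$br_ratio
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
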