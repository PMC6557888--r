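# Physical constants shared by the digestion, mass and spectrum modules.
# All masses are monoisotopic and in Daltons.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 standard amino-acid
#' residues, i.e. the mass each residue contributes to a peptide chain
#' (free amino-acid mass minus water). One mass convention is used across
#' the whole package: peptide and protein masses are residue sums plus one
#' water.
#'
#' @format Named numeric vector of length 20; names are one-letter residue
#'   codes.
#' @export
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname RESIDUE_MASS
#' @export
MASS_WATER <- 18.0105646863

#' @rdname RESIDUE_MASS
#' @export
MASS_PROTON <- 1.00727646688

# Mass shift of the fixed carbamidomethyl modification on cysteine.
#' @rdname RESIDUE_MASS
#' @export
MASS_CARBAMIDOMETHYL <- 57.02146

# Spacing of the C13-C12 isotope envelope used for isotope-error windows.
#' @rdname RESIDUE_MASS
#' @export
MASS_ISOTOPE <- 1.00335

#' Per-residue pKa table for isoelectric-point calculation
#'
#' Dissociation constants of the ionizable groups used by [compute_pI()]:
#' the peptide N- and C-termini and the side chains of K, R, H (basic) and
#' D, E, C, Y (acidic). Values are the EMBOSS set, a commonly tabulated
#' standard; any internally consistent set positions spots on the same
#' relative IEF scale.
#'
#' @format Named numeric vector (pH units).
#' @export
PKA_TABLE <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1
)

# Residues with positively / negatively ionizable side chains.
.PKA_POSITIVE <- c("K", "R", "H")
.PKA_NEGATIVE <- c("D", "E", "C", "Y")

STANDARD_RESIDUES <- names(RESIDUE_MASS)

# Reserved accession prefixes in the search database.
DECOY_PREFIX <- "REV_"
CONTAMINANT_PREFIX <- "CONT_"
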