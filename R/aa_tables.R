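#' Canonical amino-acid alphabet and physicochemical tables
#'
#' Constants used across the package: the 20-letter canonical alphabet,
#' Kyte-Doolittle hydropathy, maximal accessible surface areas for RSA
#' normalization (Rost & Sander 1994), monoisotopic-free average residue
#' masses, pKa values for charge/pI calculations (EMBOSS set), and the
#' Arg/N-end-rule residue classification.
#'
#' @name aa_tables
#' @keywords internal
NULL

# 20 canonical residues, alphabetical by one-letter code
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Kyte & Doolittle (1982) hydropathy scale; range [-4.5, 4.5]
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Maximal accessible surface area (A^2) per residue type, Rost & Sander (1994),
# used to normalize DSSP-style absolute ASA to relative solvent accessibility.
SANDER_MAX_ASA <- c(
  A = 106, C = 135, D = 163, E = 194, F = 197,
  G =  84, H = 184, I = 169, K = 205, L = 164,
  M = 188, N = 157, P = 136, Q = 198, R = 248,
  S = 130, T = 142, V = 142, W = 227, Y = 222
)

# Average residue (monomer minus water) masses in Da
AA_RESIDUE_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.0153

# EMBOSS pKa values for ionizable groups
PKA_SIDECHAIN <- c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
PKA_NTERM <- 8.6
PKA_CTERM <- 3.6
AA_BASIC <- c("H", "K", "R")
AA_ACIDIC <- c("C", "D", "E", "Y")

AA_AROMATIC <- c("F", "W", "Y")

# Arg/N-end-rule classification of the N-terminal residue.
# type-1 primary: basic; type-2 primary: bulky hydrophobic;
# secondary: arginylation substrates; tertiary: deamidation/oxidation substrates.
N_END_RULE_TABLE <- c(
  R = "type1_primary", K = "type1_primary", H = "type1_primary",
  F = "type2_primary", W = "type2_primary", Y = "type2_primary",
  L = "type2_primary", I = "type2_primary",
  D = "secondary", E = "secondary",
  N = "tertiary", Q = "tertiary", C = "tertiary"
)

N_END_CLASSES <- c("type1_primary", "type2_primary", "secondary", "tertiary", "stabilizing")

#' Classify an N-terminal residue under the Arg/N-end rule
#'
#' Maps a residue one-letter code to its Arg/N-degron pathway class:
#' type-1 primary destabilizing (R, K, H), type-2 primary destabilizing
#' (F, W, Y, L, I), secondary (D, E), tertiary (N, Q, C) or stabilizing
#' (everything else). The table can be overridden, e.g. to explore
#' organism-specific variants of the rule.
#'
#' @param residue Character vector of one-letter residue codes.
#' @param table Named character vector mapping residues to classes; residues
#'   absent from the table are classified `"stabilizing"`.
#' @return Character vector of classes, same length as `residue`.
#' @examples
#' n_end_rule_class(c("K", "F", "G"))
#' @export
n_end_rule_class <- function(residue, table = N_END_RULE_TABLE) {
  residue <- toupper(residue)
  bad <- !residue %in% AA_CANONICAL
  if (any(bad)) {
    stop("non-canonical residue(s): ", paste(unique(residue[bad]), collapse = ", "))
  }
  cls <- unname(table[residue])
  cls[is.na(cls)] <- "stabilizing"
  cls
}

#' Grand average of hydropathy (Gravy) of a peptide
#'
#' Mean Kyte-Doolittle hydropathy over all residues of `x`.
#'
#' @param x Character vector of peptide sequences (canonical residues).
#' @return Numeric vector in `[-4.5, 4.5]`.
#' @examples
#' gravy(c("AAAA", "GGGG"))
#' @export
gravy <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(NA_real_)
    aa <- strsplit(toupper(s), "")[[1]]
    h <- KD_HYDROPATHY[aa]
    if (anyNA(h)) stop("non-canonical residue in peptide: ", s)
    mean(h)
  }, numeric(1), USE.NAMES = FALSE)
}
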