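# Physical constants and residue-level lookup tables.
#
# Monoisotopic residue masses are computed from CODATA/AME monoisotopic
# atomic masses (H 1.00782503207, C 12, N 14.0030740048, O 15.9949146196,
# S 31.97207069) and embedded here at 8 decimals; 'J' denotes a
# Leu/Ile-ambiguous residue and carries the shared Leu/Ile mass.

#' Physical constants used in peptide mass arithmetic
#'
#' Monoisotopic masses in Dalton: the proton (`proton`, used for the
#' \[M+H\]+ convention), the hydrogen atom (`hydrogen`, gained per cysteine
#' on disulfide reduction) and water (`water`, gained on hydrolysis of a
#' backbone bond, e.g. ring opening of a cyclic peptide).
#'
#' @format Named numeric vector with elements `proton`, `hydrogen`, `water`.
#' @export
MASS_CONSTANTS <- c(
  proton   = 1.007276,
  hydrogen = 1.007825,
  water    = 18.010565
)

#' Monoisotopic residue masses (Da)
#'
#' Masses of the 20 standard amino-acid residues plus `J`, the
#' Leu/Ile-ambiguous letter used by de novo sequencing (isobaric, so
#' `J`, `L` and `I` share one mass).
#'
#' @format Named numeric vector over the 21-letter residue alphabet.
#' @export
RESIDUE_MONO <- c(
  G = 57.02146372,
  A = 71.03711378,
  S = 87.03202840,
  P = 97.05276385,
  V = 99.06841391,
  T = 101.04767847,
  C = 103.00918447,
  L = 113.08406398,
  I = 113.08406398,
  J = 113.08406398,
  N = 114.04292744,
  D = 115.02694302,
  Q = 128.05857751,
  K = 128.09496301,
  E = 129.04259309,
  M = 131.04048460,
  H = 137.05891186,
  F = 147.06841391,
  R = 156.10111102,
  Y = 163.06332853,
  W = 186.07931295
)

#' Average residue masses (Da)
#'
#' Standard average (chemical) residue masses, provided for linear-mode
#' MALDI comparisons; the pipeline's own arithmetic is monoisotopic.
#'
#' @format Named numeric vector over the 21-letter residue alphabet.
#' @export
RESIDUE_AVG <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, J = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155,
  M = 131.1926, H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760,
  W = 186.2132
)

#' Eisenberg consensus hydrophobicity scale
#'
#' Per-residue hydrophobicity values of the Eisenberg consensus scale
#' (Eisenberg et al. 1984), used for cyclotide surface-hydrophobicity
#' profiling. Higher is more hydrophobic.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
EISENBERG_SCALE <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
)

#' Formal residue charges at pH 7.0-7.4
#'
#' Integer charge model used for cyclotide net-charge prediction:
#' Lys/Arg +1, Asp/Glu -1, His 0 in this pH band (His pKa ~6 is mostly
#' deprotonated), all other residues 0. Linear peptides additionally carry
#' +1 (free N-terminus) and -1 (free C-terminus); cyclic peptides have no
#' termini.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
CHARGE_PH7 <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Internal: validate a residue string over the 21-letter alphabet.
# Returns the split character vector; stops naming the first bad position.
split_residues <- function(sequence, allow_j = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  alphabet <- names(RESIDUE_MONO)
  if (!allow_j) alphabet <- setdiff(alphabet, "J")
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  chars
}
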