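# Independent oracles used across the suite.

# Per-atom mass oracle: residue elemental compositions x monoisotopic atom
# masses, summed naively. Independent of the package's residue table.
ATOM_MONO <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207069)
RESIDUE_ATOMS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  J = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracle_atom_mass <- function(sequence, cyclic = FALSE, n_disulfides = 0,
                             mod_delta = 0) {
  atoms <- c(H = 0, C = 0, N = 0, O = 0, S = 0)
  for (a in strsplit(sequence, "")[[1]]) {
    comp <- RESIDUE_ATOMS[[a]]
    atoms[names(comp)] <- atoms[names(comp)] + comp
  }
  if (!cyclic) atoms["H"] <- atoms["H"] + 2; if (!cyclic) atoms["O"] <- atoms["O"] + 1
  atoms["H"] <- atoms["H"] - 2 * n_disulfides
  sum(atoms * ATOM_MONO[names(atoms)]) + mod_delta
}

# Random peptide over the 20 standard letters.
random_sequence <- function(n, alphabet = setdiff(names(RESIDUE_ATOMS), "J")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

SPAT1 <- "GIPCGESCVYIPCFTSVIGCSCSNKVCYKN"
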