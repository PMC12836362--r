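# Exact mass arithmetic for linear and head-to-tail cyclic peptides with
# disulfides and chemical derivatization.

#' Modification specification
#'
#' Describes a chemical modification by its per-site monoisotopic mass delta
#' and the residues it targets.
#'
#' @param name Modification name.
#' @param delta Per-site monoisotopic mass delta (Da).
#' @param targets Character vector of target residue letters (may be empty
#'   for sequence-independent deltas).
#' @param fixed Logical; `TRUE` for fixed (always applied) modifications.
#'
#' @return An object of class `mod_spec`.
#' @examples
#' mod_carbamidomethyl()
#' @export
mod_spec <- function(name, delta, targets = character(), fixed = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta), length(delta) == 1L)
  structure(list(name = name, delta = delta,
                 targets = toupper(targets), fixed = isTRUE(fixed)),
            class = "mod_spec")
}

#' @rdname mod_spec
#' @export
mod_carbamidomethyl <- function() {
  mod_spec("carbamidomethyl", 57.021464, targets = "C")
}

#' @rdname mod_spec
#' @details `mod_reduction()` is the +1.007825 Da gained per cysteine freed
#'   from a disulfide bond; it is normally accounted for implicitly by
#'   setting `n_disulfides = 0` on the reduced species, but is exposed for
#'   explicit bookkeeping.
#' @export
mod_reduction <- function() {
  mod_spec("reduction", unname(MASS_CONSTANTS["hydrogen"]), targets = "C")
}

#' Construct a peptide species
#'
#' A peptide species is a residue string with a backbone topology
#' (head-to-tail `"cyclic"` or `"linear"`), a number of disulfide bonds, and
#' a list of modifications with per-modification site counts. Residue masses
#' are stored for the free (reduced) thiol state; each disulfide removes two
#' hydrogens, so derivatization shifts such as the cyclotide +348 Da
#' signature emerge compositionally.
#'
#' @param sequence Residue string over the 21-letter alphabet (including
#'   `J` for Leu/Ile-ambiguous positions).
#' @param topology `"linear"` or `"cyclic"`.
#' @param n_disulfides Number of disulfide bonds (each consumes two Cys).
#' @param modifications List of `(spec, count)` pairs, e.g.
#'   `list(list(spec = mod_carbamidomethyl(), count = 2))`. A bare
#'   `mod_spec` entry is taken with count 1.
#'
#' @return An object of class `peptide_species`.
#' @examples
#' peptide_species("GIPCGESCVYIPCFTSVIGCSCSNKVCYKN", "cyclic", n_disulfides = 3)
#' @export
peptide_species <- function(sequence, topology = c("linear", "cyclic"),
                            n_disulfides = 0L, modifications = list()) {
  topology <- match.arg(topology)
  chars <- split_residues(sequence)
  n_cys <- sum(chars == "C")
  if (!is.numeric(n_disulfides) || length(n_disulfides) != 1L ||
      n_disulfides < 0 || n_disulfides != round(n_disulfides)) {
    stop("n_disulfides must be a non-negative integer", call. = FALSE)
  }
  if (2 * n_disulfides > n_cys) {
    stop(sprintf("%d disulfides need %d Cys but sequence has %d",
                 n_disulfides, 2 * n_disulfides, n_cys), call. = FALSE)
  }
  mods <- lapply(modifications, function(m) {
    if (inherits(m, "mod_spec")) m <- list(spec = m, count = 1L)
    stopifnot(inherits(m$spec, "mod_spec"),
              is.numeric(m$count), m$count >= 0)
    m
  })
  structure(list(sequence = paste(chars, collapse = ""),
                 topology = topology,
                 n_disulfides = as.integer(n_disulfides),
                 modifications = mods),
            class = "peptide_species")
}

#' @export
print.peptide_species <- function(x, ...) {
  mods <- if (length(x$modifications) == 0L) "none" else
    paste(vapply(x$modifications,
                 function(m) sprintf("%dx %s", m$count, m$spec$name),
                 character(1)), collapse = ", ")
  cat(sprintf("<peptide_species> %s %s (%d aa, %d S-S, mods: %s)\n",
              x$topology, x$sequence, nchar(x$sequence), x$n_disulfides, mods))
  invisible(x)
}

#' Monoisotopic neutral mass of a peptide species
#'
#' Linear species: sum of residue masses plus one water (the termini) plus
#' modification deltas minus two hydrogens per disulfide. Cyclic species:
#' the same without the water term (a head-to-tail cyclic backbone has no
#' termini).
#'
#' @param species A [peptide_species()].
#' @param average Use average instead of monoisotopic residue masses.
#' @return Neutral mass in Da.
#' @examples
#' monoisotopic_mass(peptide_species("G"))  # 75.032 Da
#' @export
monoisotopic_mass <- function(species, average = FALSE) {
  stopifnot(inherits(species, "peptide_species"))
  table <- if (average) RESIDUE_AVG else RESIDUE_MONO
  chars <- strsplit(species$sequence, "", fixed = TRUE)[[1]]
  m <- sum(table[chars])
  if (species$topology == "linear") m <- m + MASS_CONSTANTS[["water"]]
  for (mod in species$modifications) m <- m + mod$spec$delta * mod$count
  m - 2 * MASS_CONSTANTS[["hydrogen"]] * species$n_disulfides
}

#' Singly protonated m/z of a peptide species
#'
#' \[M+H\]+ convention: neutral monoisotopic mass plus one proton
#' (1.007276 Da).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Da for the singly protonated ion.
#' @export
mh_plus <- function(species) {
  monoisotopic_mass(species) + MASS_CONSTANTS[["proton"]]
}

#' Mass shift of reduction plus complete carbamidomethylation
#'
#' The diagnostic cyclotide derivatization shift: reducing `n_disulfides`
#' bonds frees cysteines (+1.007825 Da each) and alkylating all `n_cys`
#' cysteines with iodoacetamide adds +57.021464 Da per site. For the
#' canonical six-Cys, three-disulfide cyclotide scaffold the nominal shift
#' is +348 Da.
#'
#' @param n_cys Number of cysteines alkylated.
#' @param n_disulfides Number of disulfide bonds reduced.
#' @param nominal If `TRUE`, return the nominal (integer) shift of
#'   58 Da per cysteine; otherwise the exact monoisotopic shift.
#' @return Mass shift in Da.
#' @examples
#' derivatization_shift(6, 3, nominal = TRUE)   # 348
#' derivatization_shift(6, 3)                   # 348.176
#' @export
derivatization_shift <- function(n_cys, n_disulfides = n_cys %/% 2,
                                 nominal = FALSE) {
  if (n_cys < 0 || n_disulfides < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (2 * n_disulfides > n_cys) {
    stop("2 * n_disulfides cannot exceed n_cys", call. = FALSE)
  }
  if (nominal) return(58 * n_cys)
  n_cys * mod_carbamidomethyl()$delta +
    2 * n_disulfides * MASS_CONSTANTS[["hydrogen"]]
}

#' Mass shift of cyclic backbone ring opening
#'
#' A single hydrolytic cleavage of a head-to-tail cyclic backbone (e.g. by
#' EndoGluC at the conserved Glu) adds one water: +18 Da nominal,
#' +18.010565 Da exact. Together with the nominal six-Cys derivatization
#' shift this gives the +366 Da cumulative cyclotide signature.
#'
#' @param nominal If `TRUE` return 18, else the exact water mass.
#' @return Mass shift in Da.
#' @export
ring_opening_shift <- function(nominal = FALSE) {
  if (nominal) 18 else MASS_CONSTANTS[["water"]]
}
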