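# Sequence-level cyclotide characterization: inter-cysteine loop
# annotation, bracelet/Moebius subfamily call, formal net charge, and
# Eisenberg hydrophobicity profiling.

#' Annotate the six inter-cysteine loops of a cyclotide ring
#'
#' Partitions the non-Cys residues of a six-cysteine ring into loops 1-6,
#' the backbone segments between consecutive conserved cysteines. Loop
#' numbering is anchored on the cyclotide convention that loop 1 carries
#' the conserved glutamic acid: loop 1 is the inter-Cys segment containing
#' Glu (the first such segment in ring order if several do). When no Glu
#' exists the smallest loop is taken as loop 4 (the single-residue loop of
#' the canonical scaffold) with a warning.
#'
#' @param ring A `cyclic_sequence` or ring string with exactly 6 Cys.
#' @return A list of class `loop_annotation`: `loops` (named character
#'   vector `loop1`..`loop6`), `cys_positions` (positions of Cys 1-6 on the
#'   returned `ring` rotation, where Cys 1 precedes loop 1), `ring`, and
#'   `anchor` (`"glu"` or `"smallest-loop-4"`).
#' @examples
#' annotate_loops("GIPCGESCVYIPCFTSVIGCSCSNKVCYKN")$loops
#' @export
annotate_loops <- function(ring) {
  seq_in <- if (inherits(ring, "cyclic_sequence")) ring$ring else ring
  chars <- split_residues(seq_in)
  n <- length(chars)
  cys <- which(chars == "C")
  if (length(cys) != 6L) {
    stop(sprintf("loop annotation requires exactly 6 Cys, found %d",
                 length(cys)), call. = FALSE)
  }
  # segments between consecutive Cys (ring order, wrapping)
  segs <- lapply(seq_len(6L), function(i) {
    from <- cys[i]
    to <- if (i == 6L) cys[1L] + n else cys[i + 1L]
    if (to - from <= 1L) "" else
      paste(chars[((seq(from + 1L, to - 1L) - 1L) %% n) + 1L], collapse = "")
  })
  has_glu <- vapply(segs, function(s) grepl("E", s, fixed = TRUE), logical(1))
  if (any(has_glu)) {
    anchor_seg <- which(has_glu)[1L]
    anchor <- "glu"
  } else {
    anchor_seg <- ((which.min(nchar(unlist(segs))) - 1L + 6L - 3L) %% 6L) + 1L
    anchor <- "smallest-loop-4"
    warning("no Glu on ring; anchoring loop numbering on smallest loop = loop 4",
            call. = FALSE)
  }
  idx <- ((anchor_seg - 1L + 0:5L) %% 6L) + 1L
  loops <- unlist(segs)[idx]
  names(loops) <- paste0("loop", 1:6)
  # rotate ring so Cys1 (the Cys preceding loop 1) is position 1
  rot <- rotate_ring(paste(chars, collapse = ""), cys[anchor_seg])
  structure(list(loops = loops,
                 cys_positions = cumsum(c(1L, nchar(loops[1:5]) + 1L)),
                 ring = rot, anchor = anchor),
            class = "loop_annotation")
}

#' Classify a cyclotide as bracelet or Moebius
#'
#' Sequence-level heuristic for the subfamily split: Moebius cyclotides
#' carry a cis-proline in loop 5 that twists the backbone; bracelets lack
#' it. Conformation is not computed — the call is Pro-in-loop-5 only.
#'
#' @param loops A [annotate_loops()] result (or a ring acceptable to it).
#' @return `"moebius"` if loop 5 contains Pro, else `"bracelet"`.
#' @export
classify_subfamily <- function(loops) {
  if (!inherits(loops, "loop_annotation")) loops <- annotate_loops(loops)
  if (grepl("P", loops$loops[["loop5"]], fixed = TRUE)) "moebius" else "bracelet"
}

#' Formal net charge at pH 7.0-7.4
#'
#' Residue-counting charge model: Lys/Arg +1, Asp/Glu -1, His 0 in this pH
#' band. Linear peptides add +1 for the free N-terminus and -1 for the free
#' C-terminus (net 0); cyclic peptides have no termini. A
#' Henderson-Hasselbalch fractional-charge mode is available via
#' `ph` (non-integer output).
#'
#' @param sequence Residue string (no `J`; resolve first).
#' @param topology `"cyclic"` or `"linear"`.
#' @param ph If non-`NULL`, compute fractional charges from standard side
#'   chain pKas instead of the integer model.
#' @return Net charge (integer under the default model).
#' @examples
#' net_charge("GIPCGESCVYIPCFTSVIGCSCSNKVCYKN", "cyclic")  # +1
#' @export
net_charge <- function(sequence, topology = c("cyclic", "linear"), ph = NULL) {
  topology <- match.arg(topology)
  chars <- split_residues(sequence, allow_j = FALSE)
  if (is.null(ph)) {
    q <- sum(CHARGE_PH7[chars])
    if (topology == "linear") q <- q + 1 - 1  # N-term +1, C-term -1
    return(as.integer(q))
  }
  pka <- c(K = 10.5, R = 12.5, H = 6.0, D = 3.9, E = 4.1, C = 8.3, Y = 10.1)
  frac_pos <- function(pk) 1 / (1 + 10^(ph - pk))
  frac_neg <- function(pk) -1 / (1 + 10^(pk - ph))
  q <- sum(vapply(chars, function(a) {
    switch(a,
           K = frac_pos(pka[["K"]]), R = frac_pos(pka[["R"]]),
           H = frac_pos(pka[["H"]]),
           D = frac_neg(pka[["D"]]), E = frac_neg(pka[["E"]]),
           C = frac_neg(pka[["C"]]), Y = frac_neg(pka[["Y"]]),
           0)
  }, numeric(1)))
  if (topology == "linear") q <- q + frac_pos(9.0) + frac_neg(2.3)
  q
}

#' Net charge from a residue composition
#'
#' Convenience for charge comparisons from a charged-residue inventory
#' (e.g. 2 Lys + 1 Arg + 1 Glu), as used when comparing cyclotides whose
#' full sequences are not at hand.
#'
#' @param counts Named counts over residue letters.
#' @return Integer net charge under the pH 7.0-7.4 model (no termini).
#' @examples
#' net_charge_from_composition(c(K = 2, R = 1, E = 1))  # +2
#' @export
net_charge_from_composition <- function(counts) {
  stopifnot(!is.null(names(counts)))
  as.integer(sum(CHARGE_PH7[names(counts)] * as.numeric(counts)))
}

#' Eisenberg hydrophobicity profile
#'
#' Per-position hydrophobicity under the Eisenberg consensus scale, the
#' overall mean, and a sliding-window average (cyclic wrap-around for
#' rings).
#'
#' @param sequence Residue string (no `J`).
#' @param scale Named residue scale (default [EISENBERG_SCALE]).
#' @param window Odd window width for the smoothed profile (default 3).
#' @param topology `"cyclic"` wraps the window around the ring; `"linear"`
#'   truncates it at the termini.
#' @return A list of class `hydrophobicity_profile`: `values`, `mean`,
#'   `windowed`.
#' @export
hydrophobicity_profile <- function(sequence, scale = EISENBERG_SCALE,
                                   window = 3L,
                                   topology = c("cyclic", "linear")) {
  topology <- match.arg(topology)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  chars <- split_residues(sequence, allow_j = FALSE)
  vals <- unname(scale[chars])
  n <- length(vals)
  half <- (window - 1L) %/% 2L
  win <- vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    if (topology == "cyclic") {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    mean(vals[idx])
  }, numeric(1))
  structure(list(values = vals, mean = mean(vals), windowed = win),
            class = "hydrophobicity_profile")
}
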