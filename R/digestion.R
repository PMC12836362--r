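# In-silico proteolysis of linear and head-to-tail cyclic peptides.
#
# Cleavage is modeled as "cut after residue X unless the next residue is
# blocked" (e.g. trypsin: after K/R, not before P). For cyclic parents the
# successor of the last ring position is the first, and fragments are read
# off the doubled ring string.

#' Built-in cleavage rules
#'
#' `cleavage_rule()` builds an arbitrary rule; `enzyme_rule()` returns one
#' of the built-ins used in cyclotide sequencing workflows:
#' * `endoGluC` — cut after Glu (E) only (ammonium-bicarbonate conditions;
#'   Asp cleavage off).
#' * `trypsin` — cut after Lys/Arg (K/R), blocked before Pro.
#' * `chymotrypsin` — high-specificity set Phe/Tyr/Trp (F/Y/W), blocked
#'   before Pro; `low_specificity = TRUE` adds Leu/Met.
#'
#' @param name Enzyme name.
#' @param cut_after Residues after which the backbone is cut.
#' @param blocked_before Residues that block cleavage when they follow the
#'   cut site.
#' @return A list of class `cleavage_rule`.
#' @export
cleavage_rule <- function(name, cut_after, blocked_before = character()) {
  cut_after <- toupper(cut_after)
  if (length(cut_after) == 0L) stop("cut_after must be non-empty", call. = FALSE)
  structure(list(name = name, cut_after = cut_after,
                 blocked_before = toupper(blocked_before)),
            class = "cleavage_rule")
}

#' @rdname cleavage_rule
#' @param enzyme One of `"endoGluC"`, `"trypsin"`, `"chymotrypsin"`.
#' @param low_specificity Chymotrypsin only: include L and M in the
#'   cut-after set.
#' @export
enzyme_rule <- function(enzyme = c("endoGluC", "trypsin", "chymotrypsin"),
                        low_specificity = FALSE) {
  enzyme <- match.arg(enzyme)
  switch(enzyme,
    endoGluC = cleavage_rule("endoGluC", "E"),
    trypsin = cleavage_rule("trypsin", c("K", "R"), "P"),
    chymotrypsin = cleavage_rule(
      "chymotrypsin",
      if (low_specificity) c("F", "Y", "W", "L", "M") else c("F", "Y", "W"),
      "P")
  )
}

# Internal: positions (1-based) after which the rule cuts. For cyclic
# sequences position n can be a site (successor wraps to 1); for linear
# sequences only internal bonds 1..n-1 are considered.
cut_sites <- function(chars, rule, cyclic) {
  n <- length(chars)
  idx <- if (cyclic) seq_len(n) else seq_len(max(n - 1L, 0L))
  succ <- function(i) chars[if (i == n) 1L else i + 1L]
  idx[vapply(idx, function(i) {
    chars[i] %in% rule$cut_after && !(succ(i) %in% rule$blocked_before)
  }, logical(1))]
}

#' Digest a peptide species in silico
#'
#' Computes the proteolytic fragments of a linear or head-to-tail cyclic
#' parent under a cleavage rule, including missed-cleavage variants up to
#' `max_missed`. A linear parent with k internal sites yields k+1
#' zero-missed fragments; a cyclic parent with k sites yields k zero-missed
#' linear fragments (for k = 1 this is the full-length ring opening). A
#' cyclic parent with no cut site cannot be opened: the result is empty
#' with `attr(, "status") == "no ring opening"`.
#'
#' Fragments are linear, have no disulfides (digestion is performed on the
#' reduced/alkylated material), and re-acquire the parent's residue-targeted
#' fixed modifications at full occupancy of their own target residues.
#' Start offsets for cyclic parents are reported on the canonical (lexicographically
#' smallest) rotation of the ring so that results are identical across
#' input rotations.
#'
#' @param species A [peptide_species()].
#' @param rule A [cleavage_rule()].
#' @param max_missed Maximum number of missed cleavages (default 1, the
#'   value needed to reproduce observed chymotryptic cyclotide fragments).
#' @return Data frame of class `digest_result` with columns `sequence`,
#'   `start`, `length`, `missed`, `enzyme`, `mh` (\[M+H\]+ of the modified
#'   linear fragment); attribute `status` is `"ok"` or `"no ring opening"`.
#' @examples
#' spat1 <- peptide_species("GIPCGESCVYIPCFTSVIGCSCSNKVCYKN", "cyclic", 3)
#' digest(spat1, enzyme_rule("endoGluC"))
#' @export
digest <- function(species, rule, max_missed = 1L) {
  stopifnot(inherits(species, "peptide_species"),
            inherits(rule, "cleavage_rule"))
  if (max_missed < 0) stop("max_missed must be >= 0", call. = FALSE)
  chars <- strsplit(species$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cyclic <- species$topology == "cyclic"

  empty <- function(status) {
    out <- data.frame(sequence = character(), start = integer(),
                      length = integer(), missed = integer(),
                      enzyme = character(), mh = numeric())
    structure(out, class = c("digest_result", "data.frame"),
              status = status, parent = species$sequence)
  }

  # canonicalize cyclic parents so offsets are rotation-independent
  if (cyclic) {
    rot <- canonical_rotation(species$sequence)
    chars <- strsplit(rot, "", fixed = TRUE)[[1]]
  }
  sites <- cut_sites(chars, rule, cyclic)
  k <- length(sites)

  frags <- list()
  add <- function(start, len, missed) {
    idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
    frags[[length(frags) + 1L]] <<- list(
      sequence = paste(chars[idx], collapse = ""),
      start = start, length = len, missed = missed)
  }

  if (cyclic) {
    if (k == 0L) return(empty("no ring opening"))
    # arcs between consecutive sites on the ring, in ring order
    starts <- (sites %% n) + 1L
    ends <- c(sites[-1L], sites[1L] + n)  # exclusive ring coordinates
    lens <- ends - sites
    for (j in seq_len(k)) {
      max_span <- min(max_missed, k - 1L)
      for (m in 0:max_span) {
        span <- sum(lens[((j - 1L + 0:m) %% k) + 1L])
        add(starts[j], span, m)
      }
    }
  } else {
    bounds <- c(0L, sites, n)
    nseg <- length(bounds) - 1L
    for (j in seq_len(nseg)) {
      for (m in 0:min(max_missed, nseg - j)) {
        add(bounds[j] + 1L, bounds[j + 1L + m] - bounds[j], m)
      }
    }
  }

  seqs <- vapply(frags, `[[`, character(1), "sequence")
  mods <- lapply(species$modifications, function(mod) mod$spec)
  mh <- vapply(seq_along(frags), function(i) {
    fr_mods <- list()
    fr_chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (spec in mods) {
      if (length(spec$targets) > 0L) {
        cnt <- sum(fr_chars %in% spec$targets)
        if (cnt > 0L) fr_mods[[length(fr_mods) + 1L]] <-
            list(spec = spec, count = cnt)
      }
    }
    mh_plus(peptide_species(seqs[i], "linear", 0L, fr_mods))
  }, numeric(1))

  out <- data.frame(
    sequence = seqs,
    start = vapply(frags, `[[`, integer(1), "start"),
    length = vapply(frags, `[[`, integer(1), "length"),
    missed = vapply(frags, `[[`, integer(1), "missed"),
    enzyme = rule$name,
    mh = mh)
  ord <- order(out$start, out$missed)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("digest_result", "data.frame"),
            status = "ok", parent = species$sequence)
}
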