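# Assembly of a head-to-tail cyclic primary sequence from multi-enzyme
# fragment evidence, and Leu/Ile resolution against acid-hydrolysis
# amino-acid composition.

#' Canonical rotation of a cyclic sequence
#'
#' The lexicographically smallest rotation: a deterministic,
#' convention-free representative of the ring. Display in an arbitrary
#' rotation with [rotate_ring()].
#'
#' @param sequence Ring residue string.
#' @return The canonical rotation string.
#' @export
canonical_rotation <- function(sequence) {
  chars <- split_residues(sequence)
  n <- length(chars)
  rots <- vapply(seq_len(n), function(i) {
    paste(chars[((seq_len(n) + i - 2L) %% n) + 1L], collapse = "")
  }, character(1))
  min(rots)
}

#' @rdname canonical_rotation
#' @param start 1-based position to start the displayed rotation at, or a
#'   prefix string to rotate to (e.g. the conventional loop-6/loop-1
#'   display start).
#' @export
rotate_ring <- function(sequence, start) {
  chars <- split_residues(sequence)
  n <- length(chars)
  if (is.character(start)) {
    hit <- ring_find(sequence, start)
    if (is.na(hit)) stop("prefix not found on ring", call. = FALSE)
    start <- hit
  }
  stopifnot(start >= 1, start <= n)
  paste(chars[((seq_len(n) + start - 2L) %% n) + 1L], collapse = "")
}

# Internal: J-tolerant equality of residue letters (J == L == I).
ji_equal <- function(a, b) {
  a == b | (a %in% c("J", "L", "I") & b %in% c("J", "L", "I"))
}

# Internal: first 1-based ring position where `needle` occurs on the ring
# `sequence` (J-tolerant, wrapping allowed); NA if absent.
ring_find <- function(sequence, needle) {
  ring <- split_residues(sequence)
  frag <- split_residues(needle)
  n <- length(ring); m <- length(frag)
  if (m > n) return(NA_integer_)
  doubled <- c(ring, ring)
  for (i in seq_len(n)) {
    if (all(ji_equal(doubled[i:(i + m - 1L)], frag))) return(i)
  }
  NA_integer_
}

#' Fragment evidence for cyclic assembly
#'
#' @param sequence Residue string over the 21-letter alphabet (may contain
#'   `J` at Leu/Ile-ambiguous positions).
#' @param enzyme Enzyme name the fragment came from.
#' @param form `"linearized"` for a full-length ring-opened sequence
#'   (single-site digest of the cyclic parent), `"cyclic"` for an internal
#'   fragment of the (possibly still cyclic) parent.
#' @return A list of class `fragment_evidence`.
#' @export
fragment_evidence <- function(sequence, enzyme = NA_character_,
                              form = c("cyclic", "linearized")) {
  form <- match.arg(form)
  chars <- split_residues(sequence)
  structure(list(sequence = paste(chars, collapse = ""),
                 enzyme = enzyme, form = form),
            class = "fragment_evidence")
}

#' Assemble a cyclic sequence from multi-enzyme fragment evidence
#'
#' The ring is the head-to-tail cyclization of a full-length ring-opened
#' evidence (`form = "linearized"`, e.g. the single-Glu EndoGluC product).
#' Every other evidence must occur as a contiguous substring of the ring
#' (checked on the doubled ring string, with `J` matching `L`/`I` in both
#' directions); an evidence that does not is an inconsistency error naming
#' the fragment. Multiple linearized evidences must describe the same ring
#' up to rotation and J-resolution, else an ambiguity error. The junction
#' coverage flag records whether some other fragment spans the ring-closure
#' bond of the linearized evidence (last-to-first residue), i.e. whether
#' the cyclization itself is evidenced and not just assumed.
#'
#' @param evidences List of [fragment_evidence()] objects.
#' @return A list of class `cyclic_sequence`: `ring` (canonical rotation),
#'   `length`, `cys_positions` (on the canonical rotation),
#'   `junction_covered`, and `provenance` (per-evidence ring placement).
#' @export
assemble_cyclic <- function(evidences) {
  if (inherits(evidences, "fragment_evidence")) evidences <- list(evidences)
  stopifnot(length(evidences) > 0L,
            all(vapply(evidences, inherits, logical(1), "fragment_evidence")))
  full <- Filter(function(e) e$form == "linearized", evidences)
  if (length(full) == 0L) {
    stop(paste("assembly requires at least one full-length ring-opened",
               "(linearized) evidence"), call. = FALSE)
  }
  ring <- full[[1]]$sequence
  for (e in full[-1]) {
    if (nchar(e$sequence) != nchar(ring) || is.na(ring_find(ring, e$sequence))) {
      stop(sprintf("incompatible full-length evidences: '%s' vs '%s'",
                   full[[1]]$sequence, e$sequence), call. = FALSE)
    }
  }
  # merge J-resolution across linearized evidences onto one ring string
  ring_chars <- split_residues(ring)
  for (e in full[-1]) {
    off <- ring_find(ring, e$sequence)
    idx <- ((seq_len(nchar(ring)) + off - 2L) %% nchar(ring)) + 1L
    ec <- split_residues(e$sequence)
    resolve <- ring_chars[idx] == "J" & ec %in% c("L", "I")
    ring_chars[idx[resolve]] <- ec[resolve]
  }
  ring <- paste(ring_chars, collapse = "")
  n <- nchar(ring)

  junction_pos <- nchar(full[[1]]$sequence)  # bond n -> 1 of the linearization
  junction_covered <- FALSE
  prov <- lapply(evidences, function(e) {
    off <- ring_find(ring, e$sequence)
    if (is.na(off)) {
      stop(sprintf("evidence '%s' (%s) is inconsistent with the assembled ring '%s'",
                   e$sequence, e$enzyme, ring), call. = FALSE)
    }
    list(sequence = e$sequence, enzyme = e$enzyme, form = e$form,
         start = off, length = nchar(e$sequence))
  })
  # junction: the linearized evidence starts at ring position 1 by
  # construction; its closure bond is between positions n and 1. A
  # fragment spans it iff its ring interval wraps past position n,
  # covering both residues n and 1.
  for (p in prov) {
    if (p$form == "linearized") next
    if (p$start + p$length - 1L > n) junction_covered <- TRUE
  }
  canon <- canonical_rotation(ring)
  shift <- ring_find(canon, substr(ring, 1, n))  # map offsets to canonical
  prov <- lapply(prov, function(p) {
    p$start <- ((p$start - 1L + shift - 1L) %% n) + 1L
    p
  })
  cys <- which(strsplit(canon, "", fixed = TRUE)[[1]] == "C")
  structure(list(ring = canon, length = n, cys_positions = cys,
                 junction_covered = junction_covered, provenance = prov),
            class = "cyclic_sequence")
}

#' @export
print.cyclic_sequence <- function(x, ...) {
  cat(sprintf("<cyclic_sequence> cyclo-%s (%d aa, %d Cys, junction %s)\n",
              x$ring, x$length, length(x$cys_positions),
              if (isTRUE(x$junction_covered)) "covered" else "not covered"))
  invisible(x)
}

#' Acid-hydrolysis amino-acid composition of a sequence
#'
#' Emulates the information content of 6 M HCl hydrolysis followed by
#' amino-acid quantification: Asn deamidates to Asp (pooled as `Asx`), Gln
#' to Glu (pooled as `Glx`), and Cys/Trp are destroyed (unobservable); all
#' other residues, including the Leu/Ile pair the method does resolve, are
#' counted directly.
#'
#' @param sequence Residue string; `J` is rejected — the caller must
#'   enumerate concrete Leu/Ile assignments (see [resolve_isobaric()]).
#' @return Named integer vector of observable counts (keys `Asx`, `Glx`
#'   and single-letter residues; `C`/`W` never appear).
#' @examples
#' hydrolysis_transform("NQ")  # Asx 1, Glx 1
#' @export
hydrolysis_transform <- function(sequence) {
  chars <- split_residues(sequence)
  if (any(chars == "J")) {
    stop("sequence contains unresolved 'J'; enumerate Leu/Ile assignments first",
         call. = FALSE)
  }
  chars <- chars[!(chars %in% c("C", "W"))]
  key <- ifelse(chars %in% c("N", "D"), "Asx",
                ifelse(chars %in% c("Q", "E"), "Glx", chars))
  tab <- table(key)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Internal: L1 distance between two composition vectors over their key union.
composition_l1 <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  sum(abs(as.numeric(av) - as.numeric(bv)))
}

#' Resolve Leu/Ile ambiguity against observed hydrolysate composition
#'
#' Enumerates every Leu/Ile assignment over the `J` positions of a ring
#' (at most 2^k, refused above `max_j`), scores each by the L1 distance
#' between its [hydrolysis_transform()] and the observed composition, and
#' returns the minimizer. Assignments tying at the optimum leave the
#' affected positions unresolved (reported, and kept as `J`).
#'
#' @param ring A `cyclic_sequence` (from [assemble_cyclic()]) or a ring
#'   string possibly containing `J`.
#' @param observed Observed composition: named counts using the
#'   [hydrolysis_transform()] key convention.
#' @param max_j Enumeration cap on the number of `J` positions (default 16).
#' @return A list of class `isobaric_resolution`: `ring` (canonical, with
#'   resolved letters; ties stay `J`), `distance` (optimal L1 distance),
#'   `n_optima`, `unresolved` (positions still ambiguous), and
#'   `assignments` (the scored enumeration).
#' @export
resolve_isobaric <- function(ring, observed, max_j = 16L) {
  seq_in <- if (inherits(ring, "cyclic_sequence")) ring$ring else
    canonical_rotation(ring)
  chars <- split_residues(seq_in)
  jpos <- which(chars == "J")
  k <- length(jpos)
  if (k > max_j) {
    stop(sprintf("%d ambiguous positions exceed the enumeration cap (%d)",
                 k, max_j), call. = FALSE)
  }
  grid <- if (k == 0L) matrix(character(0), nrow = 1L) else
    as.matrix(expand.grid(rep(list(c("I", "L")), k),
                          stringsAsFactors = FALSE))
  scored <- lapply(seq_len(nrow(grid)), function(i) {
    cand <- chars
    if (k > 0L) cand[jpos] <- grid[i, ]
    s <- paste(cand, collapse = "")
    list(sequence = s,
         distance = composition_l1(hydrolysis_transform(s), observed))
  })
  dist <- vapply(scored, `[[`, numeric(1), "distance")
  best <- which(dist == min(dist))
  # positions on which all optima agree are resolved; others stay J
  out_chars <- split_residues(scored[[best[1]]]$sequence)
  unresolved <- integer(0)
  if (length(best) > 1L && k > 0L) {
    for (j in seq_len(k)) {
      vals <- unique(grid[best, j])
      if (length(vals) > 1L) {
        out_chars[jpos[j]] <- "J"
        unresolved <- c(unresolved, jpos[j])
      }
    }
  }
  structure(list(
    ring = canonical_rotation(paste(out_chars, collapse = "")),
    distance = min(dist),
    n_optima = length(best),
    unresolved = unresolved,
    assignments = data.frame(
      sequence = vapply(scored, `[[`, character(1), "sequence"),
      distance = dist)),
    class = "isobaric_resolution")
}
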