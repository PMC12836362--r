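# Identity filtering, p-distances, neighbor-joining with bootstrap
# supports, and Newick I/O for cyclotide homolog panels. Tree construction
# is delegated to ape (Saitou-Nei NJ); distances, identity semantics and
# bootstrap resampling are defined here.

#' Construct an aligned sequence set
#'
#' @param sequences Named character vector of equal-length gapped sequences
#'   (gap `-`).
#' @return A list of class `aligned_set` with `ids` and a character matrix
#'   `mat` (rows = sequences).
#' @export
aligned_set <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("sequences must carry unique non-empty names", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat), class = "aligned_set")
}

#' Percent identity of two (aligned) sequences
#'
#' identities / compared positions x 100. Columns gapped in both sequences
#' are always excluded; columns gapped in exactly one are excluded under
#' the default `gap_mode = "exclude"` or counted as mismatches under
#' `"mismatch"`.
#'
#' @param a,b Equal-length gapped sequences.
#' @param gap_mode `"exclude"` or `"mismatch"` for one-sided gap columns.
#' @return Identity percentage in \[0, 100\].
#' @export
percent_identity <- function(a, b, gap_mode = c("exclude", "mismatch")) {
  gap_mode <- match.arg(gap_mode)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  both_gap <- ca == "-" & cb == "-"
  one_gap <- xor(ca == "-", cb == "-")
  if (gap_mode == "exclude") {
    keep <- !both_gap & !one_gap
    if (!any(keep)) stop("no comparable (ungapped) columns", call. = FALSE)
    100 * sum(ca[keep] == cb[keep]) / sum(keep)
  } else {
    keep <- !both_gap
    if (!any(keep)) stop("no comparable columns", call. = FALSE)
    100 * sum(ca[keep] == cb[keep] & !one_gap[keep]) / sum(keep)
  }
}

#' Filter alignment rows by identity to a query
#'
#' Homolog-panel selection: keep sequences whose percent identity to the
#' query lies within \[lo, hi\] (the kind of ">= 75% identity, <= 86%
#' similarity" window used to pick BLAST hits for cyclotide phylogenies).
#'
#' @param alignment An [aligned_set()].
#' @param query Id of the query row (always retained).
#' @param lo,hi Identity bounds in percent.
#' @inheritParams percent_identity
#' @return An `aligned_set` restricted to the retained rows.
#' @export
identity_filter <- function(alignment, query, lo = 75, hi = 100,
                            gap_mode = "exclude") {
  stopifnot(inherits(alignment, "aligned_set"), query %in% alignment$ids)
  qs <- paste(alignment$mat[query, ], collapse = "")
  keep <- vapply(alignment$ids, function(id) {
    if (id == query) return(TRUE)
    p <- percent_identity(paste(alignment$mat[id, ], collapse = ""), qs,
                          gap_mode = gap_mode)
    p >= lo & p <= hi
  }, logical(1))
  seqs <- apply(alignment$mat[keep, , drop = FALSE], 1, paste, collapse = "")
  aligned_set(seqs)
}

#' Pairwise p-distance matrix of an alignment
#'
#' d = 1 - identity/compared under pairwise deletion of gap columns (the
#' same column semantics as [percent_identity()] with `gap_mode =
#' "exclude"`).
#'
#' @param alignment An [aligned_set()] with >= 3 sequences.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "aligned_set"))
  n <- length(alignment$ids)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- tryCatch(
        percent_identity(paste(alignment$mat[i, ], collapse = ""),
                         paste(alignment$mat[j, ], collapse = "")),
        error = function(e) stop(sprintf(
          "pair (%s, %s): %s", alignment$ids[i], alignment$ids[j],
          conditionMessage(e)), call. = FALSE))
      d[i, j] <- d[j, i] <- 1 - p / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`); negative branch lengths are
#' clamped to zero and recorded in the `n_clamped` attribute.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (ids as
#'   dimnames), e.g. from [p_distance_matrix()].
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tr <- ape::nj(d)
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Bootstrap supports on the full-data NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds a p-distance NJ
#' tree per replicate, and maps onto each internal edge of the full-data
#' tree the fraction of replicates containing the same bipartition
#' (supports in \[0, 1\], the "bootstrap consensus value" display
#' convention; this is not a majority-rule consensus topology).
#'
#' @param alignment An [aligned_set()] with >= 1 column.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the resampling is fully reproducible.
#' @return The full-data NJ tree with `node.label` set to supports in
#'   \[0, 1\] (root label empty) and attribute `supports`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "aligned_set"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  ncol_aln <- ncol(alignment$mat)
  if (ncol_aln < 1L) stop("alignment has no columns", call. = FALSE)
  full <- nj_tree(p_distance_matrix(alignment))
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    sub <- alignment
    sub$mat <- alignment$mat[, cols, drop = FALSE]
    reps[[r]] <- nj_tree(p_distance_matrix(sub))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- counts / n_replicates
  full$node.label <- c("", format(supports[-1L], trim = TRUE))
  # node 1 is the (arbitrary) root of the unrooted representation
  attr(full, "supports") <- supports
  full
}

#' Write / read a support-labeled Newick tree
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; supports travel
#' as internal node labels in \[0, 1\].
#'
#' @param tree An `ape::phylo` object.
#' @param path File path.
#' @return `read_newick` returns an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    ok <- is.na(sup) | (sup >= 0 & sup <= 1)
    if (!all(ok)) stop("node supports must lie in [0, 1]", call. = FALSE)
  }
  tr
}
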