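# Identity filtering, p-distances, NJ recovery, bootstrap supports, Newick.

# Synthetic alignment with two cleanly separated clades: high divergence
# between clades, none within (pairs within a clade are identical), so the
# single informative bipartition is the clade split.
two_clade_alignment <- function(ncol = 60, seed = 4) {
  set.seed(seed)
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  base1 <- paste(sample(alpha, ncol, replace = TRUE), collapse = "")
  base2 <- paste(sample(alpha, ncol, replace = TRUE), collapse = "")
  aligned_set(c(a1 = base1, a2 = base1, b1 = base2, b2 = base2))
}

# Six-taxon panel with mild within-clade divergence, for filtering and
# distance tests.
six_taxon_alignment <- function(ncol = 60, seed = 4) {
  set.seed(seed)
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  base1 <- sample(alpha, ncol, replace = TRUE)
  base2 <- sample(alpha, ncol, replace = TRUE)
  mut <- function(x, k) {
    i <- sample(seq_along(x), k)
    x[i] <- sample(alpha, k, replace = TRUE)
    x
  }
  aligned_set(c(a1 = paste(base1, collapse = ""),
                a2 = paste(mut(base1, 2), collapse = ""),
                a3 = paste(mut(base1, 2), collapse = ""),
                b1 = paste(base2, collapse = ""),
                b2 = paste(mut(base2, 2), collapse = ""),
                b3 = paste(mut(base2, 2), collapse = "")))
}

topo_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))

test_that("percent identity follows the stated column semantics", {
  expect_equal(percent_identity("AAAA", "AAAA"), 100)
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
  expect_equal(percent_identity("AA-A", "AA-T"), 100 * 2 / 3)  # both-gap dropped
  expect_equal(percent_identity("AAGA", "AA-A"), 100)          # one-gap excluded
  expect_equal(percent_identity("AAGA", "AA-A", gap_mode = "mismatch"), 75)
  expect_error(percent_identity("----", "----"), "comparable")
  expect_error(percent_identity("AA", "AAA"), "equal length")
})

test_that("identity filtering retains exactly the in-band pairs", {
  aln <- six_taxon_alignment()
  q <- "a1"
  ids <- setdiff(aln$ids, q)
  pid <- vapply(ids, function(id) {
    percent_identity(paste(aln$mat[id, ], collapse = ""),
                     paste(aln$mat[q, ], collapse = ""))
  }, numeric(1))
  kept <- identity_filter(aln, q, lo = 75, hi = 100)
  expect_setequal(setdiff(kept$ids, q), ids[pid >= 75])
  # an upper similarity bound excludes near-duplicates
  kept2 <- identity_filter(aln, q, lo = 50, hi = 90)
  expect_setequal(setdiff(kept2$ids, q), ids[pid >= 50 & pid <= 90])
})

test_that("p-distance matrix equals a per-pair recount oracle", {
  aln <- six_taxon_alignment(seed = 8)
  d <- p_distance_matrix(aln)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) for (j in (i + 1):6) {
    a <- aln$mat[i, ]; b <- aln$mat[j, ]
    keep <- a != "-" & b != "-"
    expect_equal(d[i, j], 1 - sum(a[keep] == b[keep]) / sum(keep))
  }
  expect_equal(p_distance_matrix(aligned_set(
    c(x = "AAAA", y = "TTTT", z = "AATT")))["x", "y"], 1)
})

test_that("NJ recovers a known additive quartet exactly", {
  # tree ((A:1,B:2):3,(C:4,D:5)): frozen additive distances
  d <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 9,
                9, 10, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(topo_dist(tr, ape::read.tree(text = "((A:1,B:2):3,C:4,D:5);")),
               0)
  leaf_edge <- function(t, tip)
    t$edge.length[t$edge[, 2] == which(t$tip.label == tip)]
  expect_equal(leaf_edge(tr, "A"), 1)
  expect_equal(leaf_edge(tr, "B"), 2)
  expect_equal(leaf_edge(tr, "C"), 4)
  expect_equal(leaf_edge(tr, "D"), 5)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ is consistent on random additive trees, 50/50", {
  ok <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(true)
    d <- d[true$tip.label, true$tip.label]
    if (topo_dist(nj_tree(d), true) == 0) ok <- ok + 1L
  }
  expect_identical(ok, 50L)
})

test_that("permuting taxon order never changes the unrooted topology", {
  aln <- six_taxon_alignment(seed = 12)
  d <- p_distance_matrix(aln)
  tr <- nj_tree(d)
  for (i in 1:5) {
    set.seed(i)
    p <- sample(rownames(d))
    expect_equal(topo_dist(tr, nj_tree(d[p, p])), 0)
  }
})

test_that("clean clades get full bootstrap support and seeds reproduce", {
  aln <- two_clade_alignment()
  tr <- bootstrap_support(aln, n_replicates = 200, seed = 11)
  sup <- attr(tr, "supports")
  expect_true(all(sup[-1] >= 0.95))  # the clade split is fully supported
  expect_true(all(sup >= 0 & sup <= 1))
  tr2 <- bootstrap_support(aln, n_replicates = 200, seed = 11)
  expect_identical(attr(tr2, "supports"), sup)
  one <- attr(bootstrap_support(aln, n_replicates = 1, seed = 3), "supports")
  expect_true(all(one %in% c(0, 1)))
  expect_error(bootstrap_support(aln, n_replicates = 0), ">= 1")
})

test_that("supports are invariant to leaf relabeling", {
  aln <- two_clade_alignment(seed = 21)
  sup <- sort(attr(bootstrap_support(aln, 100, seed = 5), "supports"))
  perm <- aln
  ord <- c("b2", "a1", "b1", "a2")
  perm$mat <- perm$mat[ord, ]
  perm$ids <- ord
  sup_p <- sort(attr(bootstrap_support(perm, 100, seed = 5), "supports"))
  expect_equal(sup, sup_p)
})

test_that("support-labeled Newick round-trips byte-identically", {
  aln <- six_taxon_alignment()
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 2)
  p1 <- tempfile(fileext = ".nwk"); p2 <- tempfile(fileext = ".nwk")
  write_newick(tr, p1)
  back <- read_newick(p1)
  write_newick(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  sup <- suppressWarnings(as.numeric(back$node.label))
  expect_true(all(is.na(sup) | (sup >= 0 & sup <= 1)))
})
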