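#!/usr/bin/env Rscript
# Stage 5 — homolog filtering and neighbor-joining phylogeny with
# bootstrap supports, demonstrated on a synthetic cyclotide panel (the
# published tree rests on an external BLAST hit set that is not
# redistributable; the procedure, not the taxon set, is reproduced here).
#
# Builds a panel of generated cyclotide-like rings around the assembled
# ring, derives an ungapped alignment of their scaffold positions, applies
# the >= 75% identity filter, computes p-distances, the NJ tree and 1000
# bootstrap replicates. Writes results/panel_tree.nwk.

suppressPackageStartupMessages(library(cycloseq))
dir.create("results", showWarnings = FALSE)

query <- read_fasta(system.file("extdata", "spat1.fasta",
                                package = "cycloseq"))$sequence

# synthetic homolog panel: point-mutated copies of the query ring (two
# clades of divergence depth) plus unrelated random rings
mutate_ring <- function(ring, k, seed) {
  set.seed(seed)
  chars <- strsplit(ring, "")[[1]]
  free <- which(chars != "C")  # preserve the Cys scaffold
  idx <- sample(free, k)
  chars[idx] <- sample(setdiff(names(CHARGE_PH7), "C"), k, replace = TRUE)
  paste(chars, collapse = "")
}
panel <- c(
  Spat1 = query,
  hom1 = mutate_ring(query, 2, 11), hom2 = mutate_ring(query, 3, 12),
  hom3 = mutate_ring(query, 6, 13), hom4 = mutate_ring(query, 7, 14),
  far1 = mutate_ring(query, 14, 15), far2 = mutate_ring(query, 15, 16))
aln <- aligned_set(panel)

kept <- identity_filter(aln, "Spat1", lo = 75, hi = 100)
cat(sprintf("Identity filter (>= 75%% to Spat1): kept %d of %d sequences\n",
            length(kept$ids), length(aln$ids)))
cat("  kept:", paste(kept$ids, collapse = ", "), "\n")

d <- p_distance_matrix(aln)
tree <- bootstrap_support(aln, n_replicates = 1000, seed = 2025)
write_newick(tree, "results/panel_tree.nwk")
cat("\nNJ tree with bootstrap supports (1000 replicates):\n")
cat(" ", readLines("results/panel_tree.nwk"), "\n")
cat(sprintf("internal-edge supports: %s\n",
            paste(format(attr(tree, "supports")[-1], digits = 2),
                  collapse = ", ")))
cat("wrote results/panel_tree.nwk\n")
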