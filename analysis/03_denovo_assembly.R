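#!/usr/bin/env Rscript
# Stage 3 — de novo sequencing and cyclic assembly.
#
# (a) Simulates an MS/MS spectrum of the EndoGluC-linearized,
# carbamidomethylated Spat1 and reconstructs its sequence by spectrum-graph
# de novo sequencing (Leu/Ile emitted as J).
# (b) Assembles the ring from the five published fragment evidences and
# resolves Leu/Ile against the acid-hydrolysis amino-acid composition.
# Writes results/assembly.csv and the resolved ring FASTA.

suppressPackageStartupMessages(library(cycloseq))
dir.create("results", showWarnings = FALSE)

linearized <- "SCVYIPCFTSVIGCSCSNKVCYKNGIPCGE"
cfg <- generator_config(seed = 7, msms_retention = 1, msms_jitter_sd = 0)
sp <- simulate_msms(linearized, cfg, list(mod_carbamidomethyl()))
top <- denovo_sequence(sp, modifications = list(mod_carbamidomethyl()))
cat("De novo rank-1 sequence (full-ladder spectrum of the linearized",
    "peptide):\n ", top$sequence[1], "\n")
cat("  matches ground truth up to Leu/Ile:",
    identical(top$sequence[1], gsub("[LI]", "J", linearized)), "\n\n")

recs <- read_fasta(system.file("extdata", "spat1_evidence.fasta",
                               package = "cycloseq"))
ev <- lapply(seq_len(nrow(recs)), function(i) {
  fragment_evidence(recs$sequence[i], enzyme = recs$enzyme[i],
                    form = if (identical(recs$topology[i], "linear"))
                      "linearized" else "cyclic")
})
asm <- assemble_cyclic(ev)
print(asm)
cat("  junction covered by:",
    paste(vapply(Filter(function(p) p$form == "cyclic" &&
                          p$start + p$length - 1L > asm$length,
                        asm$provenance),
                 `[[`, character(1), "sequence"), collapse = ", "), "\n")

hsaa <- simulate_hsaa(gsub("J", "I", asm$ring), generator_config(seed = 7))
res <- resolve_isobaric(asm, hsaa)
cat(sprintf("\nLeu/Ile resolution: L1 distance %g, %d optimum(s); ring:\n",
            res$distance, res$n_optima))
cat("  cyclo-", rotate_ring(res$ring, "GIPC"), "\n", sep = "")

write.csv(data.frame(
  stage = c("denovo_rank1", "assembled_ring", "resolved_ring"),
  sequence = c(top$sequence[1], asm$ring, rotate_ring(res$ring, "GIPC")),
  note = c(sprintf("score %.3f", top$score[1]),
           sprintf("junction_covered=%s", asm$junction_covered),
           sprintf("hsaa_distance=%g", res$distance))),
  "results/assembly.csv", row.names = FALSE)
write_fasta(data.frame(id = "assembled_ring",
                       sequence = rotate_ring(res$ring, "GIPC"),
                       topology = "cyclic", enzyme = NA),
            "results/assembled_ring.fasta")
cat("wrote results/assembly.csv, results/assembled_ring.fasta\n")
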