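#!/usr/bin/env Rscript
# Stage 4 — sequence-level characterization of the assembled ring:
# inter-cysteine loops, bracelet/Moebius subfamily, net charge at pH
# 7.0-7.4, and the Eisenberg hydrophobicity profile. Compares the charge
# with the cycloviolacin O2 (cyO2) charged-residue inventory. Writes
# results/characterization.csv.

suppressPackageStartupMessages(library(cycloseq))
dir.create("results", showWarnings = FALSE)

ring_file <- "results/assembled_ring.fasta"
ring <- if (file.exists(ring_file)) read_fasta(ring_file)$sequence else
  read_fasta(system.file("extdata", "spat1.fasta",
                         package = "cycloseq"))$sequence

ann <- annotate_loops(ring)
cat("Inter-cysteine loops (loop 1 anchored on the conserved Glu):\n")
print(ann$loops)
sub <- classify_subfamily(ann)
q <- net_charge(ring, "cyclic")
q_cyo2 <- net_charge_from_composition(c(K = 2, R = 1, E = 1))
prof <- hydrophobicity_profile(ring)
cat(sprintf("\nSubfamily: %s (Pro in loop 5: %s)\n", sub,
            grepl("P", ann$loops[["loop5"]])))
cat(sprintf("Net charge at pH 7.0-7.4: %+d (cyO2 charged set: %+d)\n",
            q, q_cyo2))
cat(sprintf("Mean Eisenberg hydrophobicity: %.3f\n", prof$mean))

write.csv(data.frame(
  quantity = c(paste0("loop", 1:6), "subfamily", "net_charge",
               "net_charge_cyo2_set", "mean_hydrophobicity"),
  value = c(unname(ann$loops), sub, q, q_cyo2, round(prof$mean, 4))),
  "results/characterization.csv", row.names = FALSE)
cat("wrote results/characterization.csv\n")
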