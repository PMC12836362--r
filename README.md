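# cycloseq

An R package and analysis workflow for the discovery and de novo
characterization of **cyclotides** — plant peptides of 28–37 residues with
a head-to-tail cyclic backbone and a cystine knot of three disulfides
among six conserved cysteines. It is written for peptidomics researchers
who screen plant extracts by MALDI-TOF mass spectrometry and need the
computational chain from raw peak lists to a characterized cyclic
sequence to be explicit, tested and reproducible.

## What it computes

The pipeline rests on the diagnostic mass arithmetic of the cyclotide
scaffold. For a peptide with $n_{\mathrm{Cys}}$ cysteines in
$n_{\mathrm{SS}}$ disulfides:

* reduction + complete carbamidomethylation shifts the mass by
  $\Delta = n_{\mathrm{Cys}} \times 57.021464 + 2\,n_{\mathrm{SS}} \times 1.007825$ Da
  (nominal **+348 Da** for the 6-Cys/3-S-S scaffold);
* a single endoproteinase GluC cleavage of the cyclic backbone adds one
  water, **+18.011 Da** (+366 cumulative) — the signature of a circular
  backbone;
* neutral masses: linear $M = \sum m_i + m_{\mathrm{H_2O}}$, cyclic
  $M = \sum m_i$ (no termini), minus $2 m_{\mathrm{H}}$ per disulfide;
  $[M+H]^+ = M + 1.007276$.

Around this core the package provides: mass-window and shift-pair
candidate screening of peak-list triples; in-silico EndoGluC / trypsin /
chymotrypsin digestion of circular backbones with missed cleavages;
theoretical b/y ion ladders, MS/MS annotation with backbone-bond coverage,
and spectrum-graph de novo sequencing (Leu/Ile emitted as `J`);
multi-enzyme cyclic sequence assembly with junction-coverage evidence and
Leu/Ile resolution against acid-hydrolysis amino-acid composition
(Asn→Asx, Gln→Glx, Cys/Trp unobservable); inter-cysteine loop annotation,
bracelet/Möbius subfamily call, net charge at pH 7.0–7.4 and Eisenberg
hydrophobicity; identity-filtered p-distance neighbor-joining phylogeny
with seeded bootstrap supports and Newick I/O; LC99.9 calling from
serial-dilution kill curves and %PI-uptake normalization; and seeded
synthetic-data generators for every input, so the whole pipeline is
testable offline.

## Worked example

Assemble the cyclotide Spat1 from its five enzymatic fragment sequences
(`J` marks Leu/Ile-ambiguous positions), resolve the ambiguity with the
hydrolysate composition, and characterize the ring:

```r
library(cycloseq)

recs <- read_fasta(system.file("extdata", "spat1_evidence.fasta",
                               package = "cycloseq"))
ev <- lapply(seq_len(nrow(recs)), function(i)
  fragment_evidence(recs$sequence[i], enzyme = recs$enzyme[i],
                    form = if (identical(recs$topology[i], "linear"))
                      "linearized" else "cyclic"))
asm <- assemble_cyclic(ev)
asm
#> <cyclic_sequence> cyclo-CFTSVJGCSCSNKVCYKNGJPCGESCVYJP (30 aa, 6 Cys, junction covered)

res <- resolve_isobaric(asm, simulate_hsaa(gsub("J", "I", asm$ring)))
rotate_ring(res$ring, "GIPC")
#> [1] "GIPCGESCVYIPCFTSVIGCSCSNKVCYKN"

annotate_loops(res$ring)$loops
#>    loop1    loop2    loop3    loop4    loop5    loop6
#>    "GES"   "VYIP" "FTSVIG"      "S"   "SNKV" "YKNGIP"
classify_subfamily(res$ring)
#> [1] "bracelet"
net_charge(res$ring, "cyclic")
#> [1] 1
```

The assembly is a 30-residue six-cysteine ring whose cyclization is
evidenced by a junction-spanning tryptic fragment; the hydrolysate fit
(L1 distance 0, unique optimum) places isoleucine at all three ambiguous
positions; loop 5 (`SNKV`) carries no proline, so the peptide is a
bracelet-subfamily cyclotide, and its two lysines and single glutamate
give net charge +1 at physiological pH. Its native cyclic [M+H]⁺:

```r
mh_plus(peptide_species("GIPCGESCVYIPCFTSVIGCSCSNKVCYKN", "cyclic",
                        n_disulfides = 3))
#> [1] 3150.332
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
sequence, each a thin script over the package functions, writing its
tables under `results/`:

| script | stage | output |
|---|---|---|
| `01_screen.R` | MALDI candidate screening (published + synthetic triples) | `screening_candidates.csv` |
| `02_digest_masses.R` | digestion; theoretical vs observed fragment masses | `fragment_masses.csv` |
| `03_denovo_assembly.R` | de novo sequencing, ring assembly, Leu/Ile resolution | `assembly.csv`, `assembled_ring.fasta` |
| `04_characterize.R` | loops, subfamily, charge, hydrophobicity | `characterization.csv` |
| `05_phylogeny.R` | identity filter, NJ tree, 1000-replicate bootstrap | `panel_tree.nwk` |
| `06_assays.R` | LC99.9 calling, %PI-uptake kinetics | `assays.csv` |

Run them in order with `Rscript analysis/01_screen.R`, etc.

## Documentation

The methods vignette (`vignettes/cyclotide-discovery-methods.Rmd`)
documents the models, tolerances, tie-breaks, generator assumptions and
known limitations; function-level documentation is in the roxygen
comments of `R/`.
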