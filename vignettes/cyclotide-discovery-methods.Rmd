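---
title: "Methods: cyclotide discovery and characterization with cycloseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclotide discovery and characterization with cycloseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloseq)
```

# Scope and model

`cycloseq` implements the computational spine of a cyclotide discovery
campaign: from MALDI-TOF peak lists of a plant peptide extract to a fully
characterized head-to-tail cyclic sequence and its bioassay statistics.
Cyclotides are 28–37-residue plant peptides with a cyclic backbone and a
cystine knot of three disulfides among six conserved cysteines. Two facts
drive everything downstream:

* **Derivatization arithmetic.** Reduction frees each cysteine
  (+1.007825 Da per Cys) and iodoacetamide alkylation adds a
  carbamidomethyl group (+57.021464 Da per Cys). For the 6-Cys/3-S-S
  scaffold this totals a nominal **+348 Da**; a subsequent single
  endoproteinase GluC cleavage of the cyclic backbone adds one water
  (**+18 Da**, +366 cumulative). These shifts are computed
  compositionally from the species model (`peptide_species`), never as
  hard-coded constants, so they generalize to any Cys count.
* **Topology in the mass model.** A linear peptide's neutral mass is the
  residue-mass sum plus one water; a head-to-tail cyclic peptide has no
  termini and omits the water term. Each disulfide removes two hydrogens.
  Protonation uses the monoisotopic proton, 1.007276 Da.

The residue mass table is embedded at 8 decimals, computed from
CODATA/AME monoisotopic atomic masses; `J` denotes the Leu/Ile-ambiguous
residue (isobaric at 113.08406 Da), the alphabet de novo sequencing
naturally works in.

# Tolerances

Two distinct error scales run through the package and must not be mixed:

| comparison | default | why |
|---|---|---|
| theory vs theory | ±0.01 Da | numerical, not instrumental |
| theory vs observed MALDI m/z | ±0.5 Da | external-calibration MALDI-TOF accuracy; published annotations of the same analyte differ by up to ~0.35 Da |
| MS/MS fragment matching | ±0.3 Da | TOF/TOF fragment accuracy |
| screening "literature mode" | ±2.5 Da | accommodates published peak annotations whose internal deltas are off by ~2 Da (e.g. a printed reduced/alkylated intermediate 2.4 Da below its theoretical mass) |

The literature-mode width is a documented reading aid for published
figures, not a recommended instrument setting.

# Screening logic

`call_candidates()` reproduces the three-spectrum decision: a native peak
is a cyclotide candidate iff it falls in the detection window (default
2500–4000 Da, with the 2900–3900 Da observation window as a preset) *and*
shows the +348-type shift into the reduced/alkylated list. The further
+18 shift into the digested list is recorded as cyclic-backbone evidence
rather than being required — mirroring the candidate/confirmation split of
screening practice; a `require_ring_evidence` switch makes it a gate.
Matching pairs each native peak to its best treated peak (smallest
absolute error, then lowest m/z), which makes results independent of peak
order.

# In-silico digestion of circular backbones

Cleavage rules are "cut after X unless followed by Y": EndoGluC after Glu
only (ammonium bicarbonate conditions; Asp off), trypsin after Lys/Arg not
before Pro, chymotrypsin after Phe/Tyr/Trp not before Pro (a
low-specificity switch adds Leu/Met). On a cyclic parent the successor of
the last position is the first; *k* cut sites yield *k* linear fragments,
and a single site yields the full-length ring opening. Offsets are
reported on the canonical (lexicographically smallest) rotation so that
digesting any rotation gives identical output. The observed chymotryptic
fragment pair of the reference peptide requires one missed cleavage (at
an internal Phe), hence `max_missed = 1` by default. Fragments are
emitted reduced (no disulfides) and re-acquire residue-targeted fixed
modifications at full occupancy — digestion in this workflow happens after
reduction/alkylation. Digests default to the cyclic parent: the
junction-spanning tryptic 26-mer observed in practice can only arise from
a parent that is still circular at trypsinolysis.

# De novo sequencing

`denovo_sequence()` formalizes manual b-/y-series alignment as a spectrum
graph. Nodes are putative prefix-residue masses: 0, the total residue
mass (precursor − water − proton), b peaks minus a proton, and y peaks
through the complement transform; nodes closer than half the tolerance
merge, a b/y pair voting for the same backbone bond therefore supports
one node twice. Edges join nodes differing by one residue mass (with
fixed modifications, e.g. Cys+CAM when sequencing the alkylated peptide).

Scoring needs care. The complement transform mirrors every true prefix
mass *p* to a spurious value *total + water − p* whose own b/y ions
coincide exactly with observed peaks, so raw supporting-ion counts reward
mirror and chimera paths, and longer paths that insert near-isobaric
residue pairs (e.g. Gly+Ala for Gln) accumulate more votes. Two measures
neutralize this without abandoning presence-based scoring:

1. during the beam search, paths are ordered by votes minus two per bond
   (two ions are expected per bond), which caps all fully supported paths
   at the same value regardless of length, and ties fall to accumulated
   mass error — zero only on the exact ladder;
2. complete paths are finally ranked by the *fraction* of their
   theoretical b/y ions matched by observed peaks, ties again by summed
   error.

Only singly charged b/y ions are modeled, matching the ion series used in
manual MALDI-TOF/TOF annotation; intensity weighting is available but the
default score is presence-based, as manual annotation is. With full
ladders the rank-1 path equals the true sequence up to Leu/Ile (emitted
as `J`) — the round-trip property the test suite verifies on 100 seeded
peptides of length 8–30.

# Cyclic assembly and Leu/Ile resolution

`assemble_cyclic()` builds the ring from a full-length ring-opened
evidence (the single-Glu EndoGluC product) and verifies every other
fragment as a substring of the doubled ring, with `J ≡ L ≡ I` in both
directions. The junction-coverage flag records whether some fragment
spans the ring-closure bond — the evidence that the backbone is truly
cyclic rather than assumed so. The canonical rotation is the
lexicographic minimum (the literature's display rotation is available via
`rotate_ring()`); this convention is arbitrary but deterministic, and
nothing downstream depends on it.

Acid hydrolysis deamidates Asn→Asp and Gln→Glu and destroys Cys/Trp, so
`hydrolysis_transform()` reports pooled `Asx`/`Glx` keys and drops C/W —
but the method does distinguish Leu from Ile. `resolve_isobaric()`
enumerates all I/L assignments over the `J` positions (≤ 2^k, refused
above 16) and minimizes the L1 distance to the observed composition;
tied optima leave positions unresolved rather than guessing. Counts are
the default fit currency (duplicate-run means in practice); a
mole-fraction mode suits noisier data.

# Characterization

Loops 1–6 are the inter-cysteine segments of the six-Cys ring, numbered
so that loop 1 contains the conserved glutamic acid (the residue
implicated in phosphatidylethanolamine recognition); rings without Glu
fall back to anchoring the smallest loop as loop 4, with a warning. The
bracelet/Möbius call is the sequence-level proxy — Pro in loop 5 —
documented as a heuristic since no conformation is computed. Net charge
counts K/R as +1 and D/E as −1 with His neutral in the pH 7.0–7.4 band
(His pKa ≈ 6); cyclic peptides get no terminal charges, and linear
termini cancel (+1 N-terminal, −1 C-terminal). A Henderson–Hasselbalch
fractional mode exists but is non-default, because the integer model is
what the ±1/+2 literature comparisons use. Hydrophobicity uses the
embedded Eisenberg consensus scale with a cyclic-wrapping window average.

# Phylogeny

The homolog-panel procedure is reproduced, not the published taxon set —
that tree rests on an external BLAST hit set and alignment that are not
redistributable. Percent identity excludes both-gap columns always and
one-sided gap columns by default; the identity filter takes lower and
upper bounds because selection windows in practice state both ("≥75%
identity", "≤86% similarity"). Distances are p-distances under pairwise
deletion — the simplest defensible choice where the original tool's
setting is unstated; a Poisson correction is a flag away. Tree building
delegates to the Saitou–Nei implementation in `ape::nj` (negative branch
lengths clamped to zero, count recorded); bootstrap resampling of
alignment columns and the mapping of bipartition frequencies onto the
full-data tree are implemented here, with supports reported in [0, 1] on
the full-data NJ tree (the "consensus values" display convention, not a
majority-rule consensus topology). Everything is seeded; identical seeds
give identical supports.

# Assay statistics

`lc999()` applies the serial-dilution rule: the lowest concentration with
≥99.9% kill of the inoculum *and* ≤10 colonies. There is an arithmetic
tension in that conjunction: 99.9% kill of 1 × 10^6 CFU/mL leaves
~100 colonies on a 100 µL undiluted plate, an order of magnitude above
the colony gate, so the colony criterion is the stricter one near the
endpoint. Both sub-criteria are therefore individually switchable, the
conjunction is the default, and the colony gate is read against the
undiluted plate (the dilution it refers to being unstated in the source
protocols). `pi_uptake_percent()` is the exact normalization
100 × (Px − Po)/(P100 − Po); it is affine-invariant, undefined when the
lysis control equals the baseline (an error, not an NA), and not clipped
to [0, 100] by default so that noisy-control excursions stay visible.

# Synthetic data: what it emulates, and what it does not

The generators in `synthetic-data.R` define the conditions under which
the pipeline is exercised:

* `random_cyclotide()` — 6 Cys, 3 disulfides, 28–37 residues, one Glu in
  loop 1 and (an idealization) none elsewhere, so EndoGluC linearization
  is single-site as in the reference peptide. Loop lengths are uniform on
  1–7 with rejection to the total-length window.
* `simulate_screen_triple()` — exact chemistry for the three planted
  peaks, per-peak Gaussian calibration jitter (default sd 0.2 Da, the
  scatter seen among published annotations of one analyte), Poisson
  background peaks (mean 5) with log-normal intensities.
* `simulate_msms()` — full b/y ladders thinned at 85% ion retention with
  0.05 Da jitter by default; the de novo round-trip tests use retention 1
  and zero jitter because that property is stated for full ladders.
* `simulate_hsaa()`, `simulate_pi()` (logistic uptake between the intact
  and lysed controls), `simulate_kill()` (log-linear kill above a planted
  LC99.9 over a 1 × 10^6 CFU/mL inoculum, 100 µL plated, concentrations
  bracketing 20 µM).

Passing tests on these fixtures demonstrates the *logic* — recall under
calibration error, round-trip identifiability, endpoint recovery — not
instrument realism: no isotope envelopes, detector saturation, adduct
peaks, nonspecific cleavage, or partial-digest abundances are modeled,
and real MALDI noise is neither uniform in m/z nor Poisson in count.

# Numerical and determinism choices

All tie-breaks are explicit: best shift match by error then m/z; de novo
path order by score, error, then lexicographic; canonical ring rotation
by lexicographic minimum; NJ tie handling as implemented by `ape`.
Every stochastic routine takes one seed and is bitwise reproducible.
Problem sizes in the shipped tests and analysis scripts — 100-seed round
trips, 50 random trees of ≤12 taxa, 200–1000 bootstrap replicates on
panels of 4–7 sequences — were chosen as the smallest sizes at which the
statistical properties are sharp (recovery probabilities at 100%,
supports at 1.0), and complete in seconds.

# Known limitations

* De novo sequencing assumes singly charged b/y ions; spectra dominated
  by a/x ions, neutral losses, or multiply charged fragments will yield
  incomplete paths (flagged, not guessed).
* Assembly requires a full-length linearized evidence; tiling a ring from
  short overlapping fragments alone is reported as ambiguity, not solved
  heuristically.
* The subfamily call is sequence-only; a cis-Pro in loop 5 is inferred,
  never observed.
* Disulfide connectivity (the knot itself) is not determined — it is not
  measurable from the data types this package consumes.
* The phylogeny module consumes alignments; it does not build them, and
  p-distance NJ is a procedure reproduction, not a claim that it is the
  best estimator for cyclotide evolution.
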