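Package: cycloseq
Title: Cyclotide Discovery and Characterization from Mass-Spectrometry Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for the discovery and de novo
    characterization of cyclotides, the head-to-tail cyclic cystine-knot
    peptides of plants. Implements exact monoisotopic mass arithmetic for
    cyclic and linear peptides with disulfides and chemical derivatization,
    MALDI mass-window and derivatization-shift candidate screening,
    in-silico proteolysis of circular backbones (EndoGluC, trypsin,
    chymotrypsin), b/y-ion ladders with spectrum-graph de novo sequencing,
    multi-enzyme cyclic sequence assembly with Leu/Ile resolution from
    acid-hydrolysis amino-acid composition, sequence-level characterization
    (inter-cysteine loops, bracelet/Moebius call, net charge, Eisenberg
    hydrophobicity), neighbor-joining phylogeny with bootstrap supports,
    and bactericidal (LC99.9) and propidium-iodide membrane-permeabilization
    assay statistics, together with seeded synthetic-data generators that
    emulate every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
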