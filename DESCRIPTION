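Package: tcwch2
Title: Detection and Sequence Analysis of Tandem CWCH2 Zinc-Finger Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scanning protein sequences for tandem CWCH2 (tCWCH2)
    zinc-finger motifs: a PROSITE/PHI-BLAST-style pattern engine with bounded
    variable-length wildcards, a C2H2/CWCH2 zinc-finger annotator that pairs
    adjacent CWCH2 fingers into tandem motifs and extracts their inter-finger
    linker, the hydrophobic-biased positions following the first histidine of
    each finger, intra-cysteine insertions and canonical TGE(K/R)P linkers,
    summary statistics and hypothesis tests on the annotated motifs
    (linker-length comparisons, position-specific residue frequencies against
    a general C2H2 background, tryptophan conservation), consensus derivation
    from multiple alignments with gap-column filtering, and a seeded
    synthetic-data generator that emulates the motif's reported sequence
    statistics with per-record ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
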