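# tcwch2

Detection and sequence analysis of **tandem CWCH2 (tCWCH2) zinc-finger
motifs** in protein sequences.

## The problem

Most C2H2 zinc fingers (Cys-X<sub>n</sub>-Cys-X<sub>n</sub>-His-X<sub>n</sub>-His)
are DNA-binding modules strung together by the canonical five-residue
TGE(K/R)P linker. A distinct subclass — the **CWCH2** finger — carries a
tryptophan two residues after its first zinc-chelating cysteine
(Cys-X-**Trp**-X<sub>n</sub>-Cys-…). When two CWCH2 fingers sit next to
each other, their tryptophans pack into a shared hydrophobic core and the
pair behaves as one structural unit that mediates *inter-finger*
interaction rather than DNA binding: the tandem CWCH2 motif, found in
Zic/Gli/Glis, Arid2/Rsc9, PacC, Mizf, Aebp2, Zap1/ZafA and related
transcription-factor and chromatin-remodeling families across animals,
fungi and amoebae. Loss of a single tryptophan (the pathogenic W→G class
of mutations) destroys the unit.

The motif has a quantitative signature beyond the tryptophans, and this
package is built for working with it:

* a bounded-gap search pattern,
  `xCxWx(2,35)Cx(5,15)Hx(2,5)Hx(5,25)CxWx(1,3)Cx(5,17)Hx(2,5)Hx`,
  in PROSITE/PHI-BLAST wildcard grammar (`x(m,n)` = m to n arbitrary
  residues), plus a looser variant;
* **longer, TGE(K/R)P-free linkers** between the paired fingers
  (11.8 ± 4.4 aa versus 8.1 ± 5.0 aa for general C2H2 fingers, which carry
  TGE(K/R)P in ~65% of sequences);
* a **hydrophobic bias at the φ1/φ2 positions** immediately C-terminal of
  each finger's first histidine (V/L/I at φ1 ≈ 34/22/35%; V/L/I/M at φ2 ≈
  14/14/39/24%, against a general-C2H2 background of only ~4–10% each);
* occasional **extra-sequence insertions** between the two cysteines
  (beyond the canonical four intervening residues).

## What the package provides

| Area | Functions |
|---|---|
| Pattern grammar | `parse_phi_pattern()`, `render_phi_pattern()`, `match_pattern()`, `tcwch2_pattern()` |
| Finger annotation | `spacing_config()`, `find_c2h2()`, `annotate_tandems()`, `has_tgekp()`, `parse_segment_headers()`, `linker_from_segment_headers()` |
| Statistics | `linker_summary()`, `mann_whitney()`, `f_variance_test()`, `chi2_vs_background()`, `phi_frequency()`, `tryptophan_conservation()`, `pdoc00028_phi_freqs()` |
| Consensus | `protein_alignment()`, `filter_gap_columns()`, `modal_consensus()`, `column_frequencies()` |
| Synthetic data | `generator_config()`, `generate_dataset()`, `mutate_decoy()`, `generator_spacing()`, `perturb_alignment()` |
| I/O & pipeline | `read_fasta()`, `write_fasta()`, `read_alignment()`, `run_pipeline()`, plus the `inst/scripts/tcwch2` command-line wrapper |

All reported coordinates are 1-based inclusive.

## Worked example

The package ships a 64-residue tCWCH2 consensus sequence
(`tcwch2_consensus()`, also in `inst/extdata/consensus64.fasta`) that
contains exactly one tandem motif:

```r
library(tcwch2)
annotate_tandems(tcwch2_consensus(), spacing_config("strict"))
#>   zf1_c1 zf1_c2 zf1_h1 zf1_h2 zf2_c1 zf2_c2 zf2_h1 zf2_h2 zf1_cwch2 zf2_cwch2
#> 1      3      8     22     27     36     41     55     59      TRUE      TRUE
#>   linker_len linker_seq phi1 phi2 extra1 extra2 has_tgekp
#> 1          8   VGTQLEYT    V    I      0      0     FALSE
```

The two fingers are anchored at C3/C8/H22/H27 and C36/C41/H55/H59; the
8-residue linker `VGTQLEYT` carries no TGE(K/R)P; the φ positions hold
valine and isoleucine; neither finger has an intra-cysteine insertion.
The grammar engine agrees anchor for anchor:

```r
match_pattern(tcwch2_pattern("strict"), tcwch2_consensus())$anchors[[1]]
#>  [1]  3  5  8 22 27 36 38 41 55 59     # C,W,C,H,H of each finger
```

Synthetic data with ground truth, and parameter recovery:

```r
cfg <- generator_config(seed = 42, n_records = 500)
ds  <- generate_dataset(cfg)
td  <- do.call(rbind, lapply(ds$records$sequence,
                             annotate_tandems, cfg = generator_spacing(cfg)))
linker_summary(td$linker_len)
#> <linker_stats> n=500  mean=11.67 aa  sd=4.36  range=5..25

phi_frequency(td)$phi1
#> <freq_table> n=500
#>     I     V     L     E     G     K     T ...
#> 0.352 0.334 0.206 0.012 0.012 0.012 0.012 ...

cfgb <- generator_config(seed = 43, n_records = 500, linker_preset = "background")
dsb  <- generate_dataset(cfgb)
tdb  <- do.call(rbind, lapply(dsb$records$sequence,
                              annotate_tandems, cfg = generator_spacing(cfgb)))
mann_whitney(td$linker_len, tdb$linker_len)
#> <motif_test> Mann-Whitney U (normal approximation)
#>   statistic = 1.823e+05, p = 3.056e-36
```

The tandem-preset linkers are recovered at their configured mean and are
significantly longer than background linkers even at n = 500 per arm.

## Command line

```sh
Rscript inst/scripts/tcwch2 scan --input inst/extdata/consensus64.fasta --outdir out
Rscript inst/scripts/tcwch2 simulate --outdir sim --seed 1 --n-records 100
```

Each stage writes versioned TSV plus JSON reports and a `run.log` with
the package version, seed and configuration hash.

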