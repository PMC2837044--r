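---
title: "Methods: models, parameters and design choices in tcwch2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tcwch2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcwch2)
```

This vignette is the package's own account of what it computes and why
the pieces are built the way they are. It covers the motif model, the
pattern-matching semantics, the annotator's spacing bounds and
tie-breaking, the statistical procedures, the synthetic-data generator's
emulation model, and the known limitations of each.

## 1. The motif model

A C2H2 zinc finger is the unit Cys-X~n~-Cys-X~n~-His-X~n~-His; a CWCH2
finger additionally carries tryptophan exactly two residues after the
first cysteine; a tandem CWCH2 (tCWCH2) motif is two adjacent CWCH2
fingers whose tryptophans anchor a shared hydrophobic core. The package
characterizes a tandem by:

* the eight anchor positions (C1, C2, H1, H2 of each finger);
* the **linker** — residues strictly between the last histidine of
  finger 1 and the first cysteine of finger 2;
* the **φ1/φ2 residues** at position H1 + 1 of each finger. The biased
  position is described structurally as the region C-terminal of the
  first histidine; the worked 64-aa consensus carries V and I exactly at
  H1 + 1, matching the top-ranked residue frequencies, so the package
  defines φ as that single site;
* the **extra sequences**: the canonical CWCH2 finger has four residues
  between its cysteines (X-W-X-X), so `extra = (C2 − C1 − 1) − 4`,
  floored at zero;
* presence of the canonical `TGE(K/R)P` pentamer in the linker.

## 2. Pattern grammar and matching semantics

`parse_phi_pattern()` reads the PROSITE/PHI-BLAST wildcard dialect:
uppercase literals, classes `[KR]` or `(K/R)` (both accepted because both
notations circulate; normalized to `[KR]`), `x`, `x(m)` and `x(m,n)`.
Repeat bounds require `1 ≤ m ≤ n`. Parsing errors name the 1-based
offset of the offending token.

Pattern-constrained search tools do not document how they resolve
multiple placements of a pattern inside one subject, so the package
*defines* the semantics rather than imitating an unspecified one:

* **mode `all`** — every distinct *anchor tuple* (one subject position
  per literal element) that can be realized with the wildcard runs within
  their cumulative bounds, ordered by (start, anchor tuple). Wildcard
  runs between two literals are collapsed to their summed bounds, so two
  internal splits of the same run are one match, not two.
* **mode `nonoverlapping`** — a deterministic reduction: greedy
  left-to-right selection of span-disjoint matches, preferring the
  lexicographically smallest anchor tuple at each start.

The reported span uses minimal wildcard context (smallest leading and
trailing run lengths). An `X` in the subject satisfies any literal,
because database sequences contain unknown residues and excluding them
would silently drop true sites. The matcher is validated against a
brute-force placement enumerator — exhaustively for every sequence up to
length 6 over a four-letter alphabet and by seeded sampling at lengths
7–15. Exhausting length 15 (4^15 ≈ 10^9 sequences) is not informative
per unit of compute; the sampled lengths exercise the same code paths.

## 3. Finger detection and pairing

`spacing_config()` carries the residue-count bounds of the search
pattern, per finger: strict preset `zf1_cc` 4–37, `zf1_ch` 5–15,
`zf2_cc` 3–5, `zf2_ch` 5–17, `hh` 2–5, linker 5–25 (the loose preset
widens `zf1_cc` to 3–37, `zf2_cc` to 3–8, `zf2_ch` to 5–31, linker to
5–42). `find_c2h2()` scans left to right with the per-position *union*
of the two fingers' bounds, taking at each candidate cysteine the
lexicographically smallest feasible (C2, H1, H2) — a deterministic
tie-break that reproduces the unique assignment on the worked example.
`annotate_tandems()` then enforces the finger-specific bounds at pairing
time. This split makes the strict-preset tandem calls coincide
anchor-for-anchor with full matches of the strict pattern, which the
test suite verifies on hundreds of synthetic records.

A finger joins at most one tandem, resolved left to right; proteins with
two tandems (e.g. four CWCH2 fingers as ZF1-2 and ZF3-4) decompose into
disjoint pairs, consistent with the known two-tandem families.

For conservation scoring (`tryptophan_conservation()`) pairing runs with
the tryptophan requirement relaxed, so that a family member whose
tryptophan has mutated away still contributes its finger pair and is
scored non-conserved; records with no locatable pair are counted
non-conserved with a warning rather than dropped, which is conservative.

**Linker arithmetic from alignment headers.** PROSITE-style headers
(`NAME/start-end`) give finger segments; the linker between consecutive
segments is taken as `next start − previous end − 1`, i.e. residues
*strictly between* segments, matching the His→Cys linker definition
(a literal "start minus end" differs by one and would make abutting
segments a linker of 1 rather than 0). Lengths above 41 are discarded —
they indicate a missed intervening finger rather than a real linker —
and negative lengths (overlapping segments) are discarded with a
warning.

## 4. Statistics

* `linker_summary()` uses sample moments (n−1 denominator; the SD is
  undefined at n = 1).
* `mann_whitney()` is two-sided, exact by enumeration of all rank
  assignments when the pooled size is ≤ 12 with no ties, otherwise a
  normal approximation with tie correction and continuity correction; U
  is reported for the first sample. The two branches agree within 0.02
  for splits 4+8 through 8+4 of a pooled 12 — the suite verifies this
  exhaustively — but at extreme splits (2+10, 3+9) the normal
  approximation itself deviates from the exact tail by up to 0.035;
  that is a property of the approximation, not of the implementation.
* `f_variance_test()` is the two-sided variance-ratio test
  (`var(a)/var(b)`, F distribution); it matches `stats::var.test` and
  its p-values are uniform under the null (checked by simulation).
* `chi2_vs_background()` collapses residue counts into inside/outside a
  hydrophobic set (defaults: {V,L,I} for φ1, {V,L,I,M} for φ2 — the
  residue groups whose summed frequencies characterize each position)
  and tests against background expectations with one degree of freedom
  via `stats::chisq.test`; the full per-residue goodness-of-fit is
  exposed as a secondary statistic because the two-category construction
  is a modeling choice, not the only defensible one.
* p-values below double precision are reported as the string
  `"< 1e-300"` alongside the 0.0 float.
* No multiple-testing correction is applied anywhere; the package
  reports per-test p-values only.

## 5. Consensus from alignments

`filter_gap_columns()` removes columns whose gap fraction is *strictly*
greater than the threshold (default 0.5), so a 50%-gap column survives;
the operation is idempotent and records the kept column indices.
`modal_consensus()` takes the most frequent non-gap residue per column;
gaps count toward column frequency vectors but are never chosen as
consensus residues (a consensus is a sequence, not an alignment row),
and ties break to the lexicographically smallest residue for
determinism. With the default threshold an all-gap column cannot survive
filtering, so the modal step only errors on deliberately unfiltered
degenerate input. Alignment construction itself (ClustalX, MAFFT, …) is
out of scope: alignments are inputs, which keeps the consensus step
reproducible without bundling an aligner.

## 6. The synthetic-data generator

`generate_dataset()` emulates the sequence statistics that characterize
the motif, with per-record ground truth, so every pipeline stage is
testable without any database access. Each intact record is

```
flank — C x W [2+extra1 residues] C — spacer(5..15, central F) — H φ1 x x H
      — linker — (same structure for finger 2, extra2) — flank
```

* **Linker lengths** follow a discretized truncated normal. Presets:
  `tcwch2` mean 11.8, sd 4.4 aa on support 5–37; `background` mean 8.1,
  sd 5.0 aa on support 1–41. The underlying (μ, σ) are moment-matched
  numerically so the *generated* distribution has the stated mean and sd:
  with a lower bound this close to the mean, naive round-and-reject
  sampling at the nominal parameters would inflate the realized mean by
  ≈ 0.5 aa (tcwch2) to 0.7 aa (background), and the stated moments are
  the quantity the recovery checks target.
* **φ residues** are drawn from `phi_freq_preset()`; only the V/L/I(/M)
  entries are tabulated upstream, so the remaining mass is spread
  uniformly over the other residues — excluding C and H, which at a φ
  position could create spurious anchors. All free positions (flanks,
  spacers, linkers, insertions) likewise exclude C and H, making the
  planted anchors the only ones by construction.
* **TGE(K/R)P** (K or R with equal odds) replaces the first five linker
  residues of background records. The configured rate (preset 0.65) is
  the *sequence-level* fraction; since insertion needs a linker of ≥ 5
  residues and the background support starts at 1, the per-linker odds
  among eligible linkers are raised to `rate / P(len ≥ 5)` so the
  marginal rate matches without touching the length distribution. Truth
  records the realized pentamer presence (a random linker can contain it
  spontaneously at rate ~10⁻⁵).
* **Insertions**: `extra1` is 0 with probability 0.85 with a geometric
  tail to 30 (insertions are observed mostly in the first finger and
  "mostly four residues" is the canonical intra-cysteine count);
  `extra2` is 0 or 1 (probability 0.9/0.1), keeping finger 2 within its
  strict bounds.
* **Decoys** (`mutate_decoy()`): `w_to_g` replaces the ZF1 tryptophan
  with glycine — fingers remain, the tandem call disappears, mirroring
  the pathogenic tryptophan loss; `spacing_violation` stretches the
  linker 15 residues beyond the pairing bound (absent under strict,
  present under loose); `single_finger` truncates after finger 1.
* **Self-check**: every record is re-scanned with
  `generator_spacing()` — the strict preset, with linker bounds widened
  to the generator's support where that support extends outside the
  strict pattern (background: 1–41). A record whose scan disagrees with
  its truth is redrawn (bounded retries). Under the `tcwch2` preset the
  check uses the strict preset itself, so the ≈ 0.1% of linker draws
  above the strict pairing bound of 25 are resampled; the realized
  linker law is thus additionally conditioned on the pairing bound,
  shifting the mean by well under 0.02 aa. Flank lengths are uniform on
  3–15 — enough context for the pattern's leading/trailing wildcards
  without bloating records.

Generation is deterministic given the seed (one `set.seed()` per
dataset; integer sampling paths).

**What passing recovery tests shows — and does not.** Recovery of the
planted parameters demonstrates that the annotator extracts linkers, φ
residues and insertions exactly as defined and that the statistics are
computed correctly on data *matching the generator's assumptions*:
independent records, exact spacing bounds, composition-neutral flanks,
no homology, no alignment error. Real proteomes violate all of these —
fingers abut other domains, compositions are biased, families are
phylogenetically correlated — so perfect recall here does not promise
perfect recall on real databases; it promises the arithmetic and the
definitions are right.

## 7. Problem sizes and numerical choices

The validation suite uses: 10,000 records for φ-frequency recovery
(binomial SE ≈ 0.5 percentage points at the observed frequencies), 5,000
per arm for linker means (SE ≈ 0.06–0.07 aa) and their rank-sum
comparison, 2,000 for the pentamer rate, 1,000 for the recall/precision
round trip, and 200 rows for consensus recovery at 10% substitutions and
up to 40% per-column gaps (the modal residue is then wrong with
probability < 10⁻⁶ per column). Tolerances on recovered parameters are
three standard errors plus a small discretization allowance for means
(0.15 aa tcwch2, 0.3 aa background). Tie-breaks are lexicographic
everywhere a choice is arbitrary; all randomness flows from a single
integer seed per dataset.

## 8. Known limitations

* The pattern engine scores nothing: no E-values, no approximate
  matching — a deliberate non-goal, as the grammar defines membership,
  not similarity.
* Only C2H2-class fingers are modeled; other zinc-finger classes and
  flanking domain annotation are out of scope.
* The all/nonoverlapping match semantics are this package's definition;
  other pattern-search implementations may resolve overlaps differently.
* Whether PROSITE segment coordinates delimit exactly C1..H2 is not
  guaranteed by the header format; the linker arithmetic assumes the
  segments end at the last histidine and start at the first cysteine.
* The background φ table interpolates the untabulated residues
  uniformly; per-residue χ² statistics against it should be read
  accordingly (the two-category test depends only on the tabulated
  V/L/I/M mass).
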