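---
title: "Methods: small RNA profiling, novel miRNA prediction and differential expression with mirskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling, novel miRNA prediction and differential expression with mirskin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirskin)
```

`mirskin` re-implements, as a tested and reusable pipeline, the classic
two-library small RNA sequencing workflow used to profile miRNAs in skin of
animals of contrasting coat color (a "white" and a "brown" condition, one
pooled library each). This vignette is the package's own account of the
methods: the models and rules each stage implements, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the original description left
the design open.

## Read cleaning and tag collapsing

Raw reads are adapter-flanked inserts. `clean_reads()`:

* locates the 3' adapter as the leftmost read suffix that is an exact prefix
  of the adapter, requiring a seed of at least 6 nt (`seed_len`), and trims
  it. Reads with no such suffix are discarded: with an 18–30 nt insert window
  and typical small-RNA read lengths, an untrimmable read implies an insert
  longer than the window. Adapter sequences are configuration inputs
  (Illumina small-RNA defaults ship with the package) because library
  chemistry varies.
* discards reads containing the 5' adapter (ligation artifacts), reads with
  any base call below Q20 (`min_qual`, a pass-through when qualities are
  absent), reads with N calls, and inserts outside 18–30 nt.

Each read is accounted to exactly one drop reason, so
`raw = clean + sum(dropped)` holds exactly — the suite checks this
conservation on simulated libraries. Clean reads are collapsed by
`collapse_tags()` into unique *tags* carrying per-library counts; collapsing
then expanding reproduces the clean-read multiset, and every downstream
statistic is invariant to read order.

`length_distribution()` reports the read-weighted histogram (18–30 nt), and
`match_genome()` the fraction of clean reads whose tag (either strand)
occurs in a genome reference. Matching is exact by default
(`max_mismatch = 0`); the substring search is a compiled scan whose contract
is equality with the naive position-by-position scan, which the tests
enforce on multi-kilobase instances.

## Priority annotation

Small RNA pools are dominated by degradation fragments of structural RNAs,
so a tag matching several references must be assigned once, deterministically.
`classify_tags()` applies the fixed priority

> GenBank ncRNA > Rfam ncRNA > known miRNA > repeat > exon > intron,

with "match" defined as the tag being a substring of a reference record on
either strand (degradation-fragment logic; `max_mismatch` is configurable,
default 0). GenBank- and Rfam-derived ncRNA are kept as two separate sets so
the precedence between them is honored. The known-miRNA class consults
hairpin precursors as well as mature sequences, so templated isomiRs that
extend a few bases past the annotated mature still annotate as miRNA. Ties
inside a category report the lexicographically smallest reference id; the
category is unaffected. `class_frequencies()` returns unique-tag and
read-weighted percentages, each summing to 100.

## Conserved miRNA identification and isomiR analysis

`match_conserved()` aligns each tag against a catalog of mature miRNAs with
an ungapped sliding alignment allowing terminal overhangs (shifts up to
`max_shift = 5` nt, overlap at least `min_overlap = 16` nt). A tag is a
conserved hit when

* mismatches (substitutions in the overlap) ≤ 2, **or**
* identity = matched positions / alignment columns > 0.90.

The two-rule disjunction is the inclusive reading of a threshold description
that is internally redundant for typical tag lengths (on a 22-mer, identity
> 0.90 already requires ≥ 20 matches); keeping both rules configurable
covers catalogs with shorter matures. The overlap floor exists because a
2-mismatch rule applied to short chance overlaps would fire spuriously on
random tags; 16 nt keeps every realistic isomiR while making chance hits
(~`choose(16,2)·(3/4)^2·(1/4)^14` per window) negligible. Each tag keeps its
best hit — fewest mismatches, then highest identity, then smallest catalog
id — so results are independent of tag and catalog order. Gapped alignment
was deliberately left out: terminal heterogeneity dominates isomiR variation
and internal indels in 22-mers are rare relative to sequencing error.

`mirna_family()` normalizes ids to family stems (species prefix, star
marker, `-3p/-5p` arm, single-digit paralog copy and trailing letter
variants are stripped; the rule table is user-extensible), and
`group_families()` aggregates member counts, conserving read totals.

`end_heterogeneity()` maps tags exactly within a precursor and keys isoforms
by their 5' and 3' offsets against the annotated mature; the predominant
isoform is the count maximum. `detect_arm_switch()` folds the precursor,
takes the innermost base pair as the terminal loop, assigns reads wholly 5'
of the loop to the 5p arm and wholly 3' to the 3p arm (loop-straddling reads
are excluded), and flags a switch when the dominant arm differs from the
annotated one; ties keep the annotated arm.

## Differential expression

Counts are normalized to NEL — reads per million clean reads,
`count / total · 10^6` — the convention consistent with the magnitudes of
published two-library skin comparisons; per library the NELs of all tags sum
to exactly 10^6. The fold change is `max(NEL) / min(NEL)` with the enriched
library as direction, so FC ≥ 1 by construction and swapping libraries
flips only the direction.

Significance of a count difference uses the Audic–Claverie posterior: under
equal relative abundance, the second library's count given the first is
negative binomial with size `x + 1` and probability `n1 / (n1 + n2)`; the
two-sided p-value is `2 · min(lower tail, upper tail)` capped at 1. This
test is count-native and standard for un-replicated two-library comparisons;
a two-proportion z-test is available behind `method = "proportion"`.
Benjamini–Hochberg FDRs are reported alongside raw p-values. The default
call gate is FC ≥ 2 and p ≤ 0.01. Features with a zero count in one library
get a reported fold change from a half-minimum pseudo-NEL (reporting only —
the test always sees raw counts); zero-in-both features are dropped. The
tests verify the p-value against direct summation of the posterior mass
function (≤ 10^-6 for counts ≤ 50) and an empirical type-I error ≤ 0.015 at
alpha 0.01 on 10^4 null features.

qPCR validation uses the Livak comparative-CT closed form,
`RQ = 2^-ΔΔCT`, normalized to a reference assay (U6 by default) and a
calibrator condition; `qpcr_relative_quantity()` applies it to a tidy CT
table. Amplification-efficiency correction beyond the Livak assumption is
out of scope.

## Novel miRNA prediction

Candidate tags are mapped exactly onto the genome (both strands), overlapping
mapped tags are merged into loci, and each locus's most abundant tag becomes
the putative mature. Two flanking windows are extracted — far flank 100 nt
upstream (mature near the window 3' end) and 100 nt downstream (mature near
the 5' end), each with a 15 nt near-side margin — both are folded, and the
lower-MFE hairpin is kept. Six criteria are then evaluated:

1. mature 20–24 nt, residing on a stem arm (entirely outside the terminal
   loop, ≥ half its bases paired);
2. mature read count ≥ 5 ("not below 5", so 5 passes);
3. MFE ≤ −18 kcal/mol (−18.0 passes);
4. largest bulge within the mature span ≤ 4 nt;
5. mature/star length difference ≤ 5 nt **and** mature-to-star spacing
   (intervening loop span) ≤ 35 nt — the reading adopted for a tersely
   stated two-number rule ("5 nucleotides and 35 nucleotides"); both bounds
   are configurable;
6. duplex asymmetry — |unpaired bases in mature − unpaired bases in star| —
   ≤ 5 nt.

The star is the region paired with the mature in the fold. When no stem is
detected, the stem-dependent criteria fail but the candidate is retained with
its flags.

MFE statistics: `AMFE = |MFE|/length · 100` and `MFEI = AMFE / GC%` with GC
on the 0–100 scale; both are reported positive, matching the convention of
published tables. The MFEI filter keeps candidates with MFEI ≥ 0.97;
candidates are deduplicated across libraries by exact mature-sequence
equality (the least-assumptive identity), the filter being applied after
merging. Per-library predictions, the intersection, and the
inclusion–exclusion union count are reported by `merge_libraries()`.

### The folding engine

The criteria need one deterministic energy scale, not a reproduction of any
particular thermodynamic parameter set, so the default engine is the
package's own dynamic program over nested structures with stacking energies:
a pair stacked directly on the adjacent pair contributes −3 (G:C) or −1
(A:U, G:U wobble); loop-closing and lone pairs contribute 0; hairpin loops
are ≥ 3 nt. This model is monotone in stem quality, favors contiguous
helices, is exactly reproducible everywhere the package runs, and defines
the −18/0.97 thresholds used both by the filter and by the generator's
build-time verification. `engine = "vienna"` delegates to an installed
`RNAfold` binary (nearest-neighbor thermodynamics) and is used in the suite
as an independent qualitative cross-check on designed stems. Published MFEI
values obtained with other folders are treated as formula inputs, never
re-derived through folding.

## Target prediction

`scan_transcript()` scores every miRNA-length window of a transcript as an
ungapped antiparallel duplex (the published rule set mentions no bulges, so
site length equals miRNA length): Watson–Crick pairs are matches, G:U
wobbles count 0.5 mismatches, everything else 1. A window passes when

* total mismatches ≤ 4;
* no mismatch at positions 10–11 (miRNA 5' numbering);
* no run of ≥ 3 mismatched positions within 2–12 (the reading of "no more
  than two adjacent mismatches");
* mismatches within 1–12 ≤ 2.5;
* duplex energy ≥ 75% of the perfect-complement energy, with pair energies
  GC −3, AU −2, GU −1, mismatch 0. The 75% rule is a ratio, so any
  consistent pair-energy scale honors it; a perfect complement scores
  exactly 1.

Scanning is sense-strand only (inputs are mRNA/3'UTR sequences; whether to
scan full cDNA or UTRs only is the user's choice). The scanner's contract is
equality with the brute-force all-windows recount, which the suite enforces
on 2 kb instances. Rule evaluation is monotone: adding a mismatch never
turns a failing window into a passing one.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates: two
libraries of 10^5 reads at desk scale (the sequenced libraries were ~10^7;
the scale-down keeps the full suite and the acceptance script within minutes
on one CPU, and every rate-based property is scale-free), tag lengths
concentrated at 22 nt, ~40% of clean reads from 30 planted miRNA loci,
contaminant ncRNA/repeat/exon/intron fragments, ~25% random background
(including out-of-window lengths that exercise the length filter), planted
fold changes of 5 and 8 (four per direction — inside the published 2–48
range, large enough to be unambiguous at this depth), and a per-base
substitution rate of 0.005, a realistic Illumina error scale.

Design choices worth stating:

* **Planted precursors are verified, not assumed.** Each designed stem-loop
  (mature + inert A/C-only loop and flanks + exact-complement star) is
  folded and pushed through `evaluate_criteria()` and `compute_mfei()` at
  build time; a design failing MFE ≤ −18, MFEI ≥ 0.97 or any criterion is
  redrawn. Inert loops/flanks (A and C cannot pair with each other) make the
  designed stem the unique optimum, so the planted arm annotation is exact.
* **Multinomial, not negative-binomial, sampling**: the emulated study
  sequenced one pooled library per condition, so there is no replicate
  dispersion to model. Fold changes are encoded symmetrically
  (`sqrt(FC)` up / down) and rescaled by a common factor per library, so
  realized cross-library proportion ratios equal the planted FCs exactly in
  expectation.
* **End-offset noise is 3'-biased** (5' offset 0/±1 with probability
  0.9/0.05/0.05; 3' offset 0/±1/±2 with 0.7/0.1/0.1/0.05/0.05), reproducing
  the empirical observation that miRNA 5' ends are more constrained than 3'
  ends; the isomiR tests recover exactly this asymmetry.
* **Repeat decoys are AT-rich** and planted into the genome with abundant
  reads, so the hairpin module's precision is measured against loci that
  map, are sequenced deeply, and fold poorly — the realistic failure mode.
* The qPCR table encodes each planted miRNA's expression as
  `CT_target = CT_ref − log2(expression) + offset + noise`, so the Livak
  path recovers planted ratios exactly at zero noise and within 30% for ≥
  95% of assays at 0.2-cycle noise and four replicates.

What the generator does **not** emulate: real quality-score profiles (bases
are Q40 with a planted low-quality fraction), indel errors, multi-mapping
tags, cross-mapping between miRNA families, RNA editing, and sequencing at
the real 10^7 depth. Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under clean planted truth, not its
robustness to every artifact of real libraries.

## Recovery studies and problem sizes

`de_recovery_study()` (20 replicates, 10^5 reads/library) measures recall of
planted FC ≥ 5 miRNAs and the false-call rate among planted FC = 1 miRNAs
under the default FC ≥ 2 / p ≤ 0.01 gate; `hairpin_recovery_study()`
(5 replicates) measures recovery of planted precursors with sequenced mature
count ≥ 5 and the precision of passing candidates. These sizes are the
package's chosen desk-scale study conditions; the acceptance script
recomputes both studies from scratch.

## Known limitations

* The stacking fold model ranks hairpins correctly but its absolute energies
  are not ViennaRNA/mFold energies; thresholds are calibrated within the
  package's own scale.
* Exon/intron annotation uses sequence sets, not genomic intervals; repeat
  discovery is out of scope (repeats are an input set).
* Without replicates, the Audic–Claverie p-value measures sampling noise
  only — biological variance between animals is not captured, which is why
  published headline counts (e.g. numbers of conserved or differential
  miRNAs in real libraries against a full catalog) are not reproduction
  targets at desk scale.
* One published novel-miRNA table row appears twice under the same name with
  two MFEI values, and one published fold-change entry is inconsistent with
  its own printed NEL pair at the fourth decimal; both are carried as
  printed and noted where they surface.
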