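---
title: "Methods: miRNA target prediction, degradome validation, and expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target prediction, degradome validation, and expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircleave)
```

# Scope

`mircleave` chains four analyses that together make up the classic
genome-free plant miRNA workflow: two-channel microarray differential
expression, weighted-complementarity target prediction against a
reference transcriptome, degradome-tag validation of predicted cleavage
sites, and `2^-ddCt` qRT-PCR quantification. Each stage has a
synthetic-data generator that emits inputs with the statistical
structure the stage assumes, together with a truth table, so the whole
pipeline runs and verifies at desk scale.

# Target scoring model

Plant miRNAs direct cleavage of near-perfectly complementary mRNA
sites, so target prediction reduces to a penalized antiparallel
alignment. The penalty scheme (`scoring_scheme()`):

| state | penalty | core multiplier |
|---|---|---|
| Watson–Crick pair (A:U, G:C) | 0 | — |
| G:U wobble | 0.5 | ×2 |
| mismatch | 1 | ×2 |
| single-nucleotide bulge (either strand) | 1 | not doubled |

The *core segment* defaults to miRNA positions 2–13 counted from the 5′
end; 5′ complementarity is what licenses slicing, and mispairing there
is penalized double. The 2–13 bounds follow the widely used
Jones-Rhoades & Bartel weighting convention; they are a configurable
default, not a biological constant. Sites with total penalty at most 4
(default cutoff) are reported. Doubling of *bulge* penalties in the
core is off by default — the scheme doubles only mismatch and wobble
penalties, a literal reading of the weighting rule — but
`double_core_bulges = TRUE` enables it for comparison.

## Search algorithm

`find_sites()` enumerates every band-1 placement of the full miRNA on
the transcript: the ungapped frame plus, for each allowed miRNA
position, a one-nucleotide bulge on the miRNA or the transcript strand.
With at most one indel this enumeration *is* the band-1 dynamic
program's search space, and the direct form is simpler to verify; an
independently coded brute-force enumerator serves as the test oracle.
Scoring is vectorized through a per-position penalty lookup profile, so
a 1–2 kb transcript scans in milliseconds.

Bulges are forbidden opposite miRNA positions 9–12 so that nucleotide
10 is always paired and the expected cleavage position — the transcript
base paired to miRNA nucleotide 10, i.e. `E - 9` for an ungapped site
ending at `E` — is always defined. Published target tables that report
22-nt alignment ranges with the cleavage site at `E - 10` imply a
transcript-side bulge 3′ of the cleavage region or a 22-nt miRNA; this
package always reports the paired-to-position-10 convention and lets
the pairing map speak for itself.

Overlapping placements collapse to the best one: lowest score, then
fewest bulges, then leftmost start, then miRNA-bulge shapes before
transcript-bulge shapes. The last tie-break only matters when two
equal-score one-bulge shapes share a start; it is fixed so results are
byte-reproducible.

# Degradome validation

Degradome (PARE) tags are 5′ fragments of uncapped, polyadenylated
mRNAs, so a tag 5′ end marks a cleavage product. `map_tags()` matches
tags exactly and full-length on the transcript sense strand; every
occurrence credits the tag's full abundance at its 5′ position
(fractional splitting across multi-mapped occurrences is available via
`multi_map = "split"` but full crediting is the default, the simplest
reproducible convention). Internally all transcripts are joined into a
single subject separated by `N` runs longer than any tag, so one exact
PDict scan per tag width suffices.

`extract_t_signature()` returns the 30-nt window (15 upstream, 14
downstream, focal position 16th) used to summarize a cleavage
signature; truncation at transcript ends is flagged rather than padded.

Cleavage-site tiers follow the three-level convention of
degradome-validation pipelines, made explicit because no published
verbal definition is precise enough to re-implement:

* **I** — site abundance equals the transcript-wide maximum;
* **II** — strictly between the median over occupied positions and the
  maximum;
* **III** — at or below the median.

`validate_targets()` requires at least `min_reads` (default 1) tag ends
exactly at the expected position; the tiers already down-weight
singleton noise, so the default threshold is permissive.

# Microarray analysis

Spot foregrounds are background-subtracted and clamped at zero
(negative intensities must never reach a logarithm); probes with any
clamped spot, a mean below three background SDs, or spot CV ≥ 0.5 in
either channel are dropped as undetectable.

Dye bias is removed in MA space: `M = log2(B/A)` is regressed on
`A = (log2 A + log2 B)/2` with `stats::lowess` — Cleveland's locally
weighted regression with tricube weights and bisquare robustifying
iterations — and the fit is subtracted. Span `f = 0.4` with 3 robust
iterations is the default (typical for a few hundred spots; exposed as
arguments). The back-transformation preserves each spot's A-value
exactly, so normalization never reorders overall intensities.

Significance per probe is a paired two-tailed t-test on spotwise
`log2(B) - log2(A)` differences with `n - 1` degrees of freedom,
computed from the textbook statistic; zero-variance differences
degenerate to `p = 1` (zero mean) or `p = 0`. No multiple-testing
correction is applied by default — raw-p practice for small
single-chip panels — with Benjamini–Hochberg available via `adjust =
"BH"`.

Calls apply thresholds to log2 ratios rounded half-away-from-zero to 2
decimals, so printed-table semantics are reproducible: a published 1.00
(from an unrounded 0.9982) passes a threshold of 1. Two named presets
cover the two threshold pairs in common use, `strict_fold` (p < 0.05,
threefold) and `unit_log2` (p < 0.01, |log2| ≥ 1); `fold_only` mode
serves summary tables that carry no replicate detail.

# qRT-PCR quantification

Pure `2^-ddCt` with amplification efficiency fixed at 2: `dCt =
Ct_target - Ct_reference` per sample, `ddCt = dCt_test -
dCt_calibrator`, ratio `2^-ddCt`. Replicate aggregation takes mean Ct
per (sample, assay) pooled across experiments for the point estimate,
and computes per-experiment ratios only for the SD — matching the
standard three-independent-experiments error bar. The calibrator sample
is always explicit; there is no default.

# Synthetic data: what it does and does not emulate

All generators take a seed and are bit-reproducible; pipeline-level
seeding derives fixed per-stage offsets from one integer (kept below
2^31).

* `gen_transcriptome()` — i.i.d. residues at a controlled GC fraction.
  Real transcripts have codon structure, UTR composition gradients and
  repeats; none are modeled, and none are needed to exercise exact
  matching and alignment scoring.
* `implant_site()` — writes the reverse complement of a miRNA and then
  realizes requested mismatch/wobble/bulge states. The designed penalty
  is an *upper bound*: with several edits the finder can occasionally
  explain the same locus more cheaply (e.g. a wobble edit's G pairing
  with a shifted neighbor), so round-trip tests assert
  reported ≤ designed with equality in the typical case.
* `sim_degradome()` — signal tags exactly at expected cleavage
  positions over a uniform Poisson background (default 20 reads/site,
  0.01 background tags per nt, 20-nt tags; tag length in real libraries
  is enzyme-defined and short, and 20 nt is a representative choice).
  No ligation bias, positional decay, or sequencing error — sufficient
  for testing the category rule, not a model of real libraries.
* `sim_microarray()` — log-normal base intensities, planted alternating
  ± log2 fold changes, multiplicative log-normal spot noise, and a dye
  bias linear in underlying log2 intensity. Real chips add saturation,
  print-tip and spatial effects that are out of scope.
* `sim_qpcr()` — Ct values around known ratios with Gaussian cycle
  noise. With one Ct per sample/assay/experiment and three experiments,
  a single run's recovered ratio has ≈6% relative SD at 0.05-cycle
  noise, so recovery is asserted on the mean across seeded replicates
  (within 10%) plus a per-run 0.5-log2 sanity band.

Consequently, passing tests demonstrate the correctness of the
arithmetic, the search, the classification rules, and parameter
recovery under the stated noise models — not robustness to the
artifacts of real chips, libraries, or assays.

# Problem sizes and numerical choices

Test and verification runs use desk-scale sizes chosen to make the
statistics meaningful while keeping the suite fast: 50 transcripts of
0.5–1.5 kb with one planted site each and 20 seeded degradome
replicates; 500 probes with 50 planted |log2FC| = 2 at noise SD 0.15
and 3 replicate spot pairs; 20 seeded qPCR replicates. Determinism is
asserted byte-for-byte on generator output and pipeline artifacts.

Numerical conventions worth knowing: rounding is half-away-from-zero
(printed-table style, unlike `round()`'s half-to-even); the LOWESS fit
is evaluated at each spot by interpolation with averaged ties and
constant extrapolation at the A-range ends; degenerate t-tests follow
the explicit zero-variance convention above; `N` never pairs (always a
mismatch) and miRNAs containing `N` are rejected outright.

# Known limitations

* Transcript-space only: no genome alignment, splicing, or isoform
  handling.
* No thermodynamic (minimum-free-energy) duplex evaluation and no
  conservation filtering; penalty score is the only ranking.
* Translational-repression targets leave no cleavage signature and are
  invisible to degradome validation by construction.
* Degradome categories depend on raw counts; no per-million
  normalization is applied (tiering is scale-free within a transcript,
  but cross-library comparisons of site counts are not supported).
* qPCR assumes perfect doubling; no standard-curve efficiency
  correction.
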