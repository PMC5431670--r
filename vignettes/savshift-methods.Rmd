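---
title: "savshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{savshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savshift)
```

`savshift` compares distributions of predicted functional-effect scores
across classes of single amino acid variants (SAVs). This vignette is
the package's account of the underlying models, the conventions and
defaults it commits to, and what its synthetic benchmark can and cannot
show.

## The score scale and the variant classes

All distribution machinery works on a score axis from −100 (confidently
neutral) to +100 (strong effect on molecular function), with 0 the
default binary boundary. Scores on other native scales (a 0–1
deleteriousness probability, an unbounded raw score, a categorical
call) enter through `method_config()` objects that define the binary
projection and, for correlation, an optional `1 − score` inversion for
methods whose raw score *decreases* with effect.

Within-human variants are classified by allele frequency:
rare (< 1%), uncommon (1% ≤ AF < 5%), common (≥ 5%); the 5% boundary
belongs to common and the 1% boundary to uncommon, so the three classes
partition [0, 1]. A missing frequency is an error, never a default
class: cross-species, random and disease sets legitimately carry no
frequency, and silently classifying them would corrupt a comparison.
Counting is per unique SAV, not per carrier — duplicates of the same
(protein, position, ref, alt) within a set collapse to one record — so
heavily genotyped variants do not dominate.

## Cross-species SAVs and the back-mutation convention

Residue differences between a human protein and an ortholog are turned
into SAVs through a global alignment. The conventions, chosen to match
the EMBOSS `needle` defaults, are:

* BLOSUM62 substitution matrix; a gap of length $k$ costs
  $\mathrm{open} + (k-1)\cdot\mathrm{extend}$ with open = 10,
  extend = 0.5 (both in matrix units);
* end gaps are not penalised by default (`end_gaps = TRUE` switches to
  fully penalised global alignment);
* pairs whose percent identity over gap-free columns (`pide_nogap`)
  falls below `min_pide = 0.70` are discarded;
* among multiple candidate orthologs the one with the highest
  *ungapped sequence identity* wins, ties broken by smallest id.

"Ungapped sequence identity" has no universal definition; here it is
identical columns divided by the length of the shorter sequence, while
the filter quantity `pide_nogap` is identities over gap-free columns
(the "excluding gaps" reading). Both are reported on every
`alignment_result` so the distinction stays visible. A pair so
dissimilar that the optimal ends-free alignment is empty has no
gap-free column at all; its PIDE is NA and it fails every filter.

Each mismatching gap-free column (human residue $h$ at human coordinate
$p$, ortholog residue $o$) becomes the SAV $o \to h$ at position $p$,
evaluated on a *back-mutated context*: the human sequence with $o$
substituted at $p$. Applying the variant to its context reproduces the
human sequence exactly — a round trip asserted in the tests. Human
coordinates are obtained by counting non-gap human characters, so each
coordinate occupies exactly one column and the extracted count equals
the number of mismatching gap-free columns by construction.

The dynamic programming itself is delegated to
`Biostrings::pairwiseAlignment`; the wrapper converts between gap-cost
parameterisations and reconstructs full-length aligned strings. Its
optimality is checked against exhaustive enumeration of all global
alignments for short sequences, an oracle that shares no code with the
implementation.

## SNV reachability

The "SNV-possible" background contains only substitutions reachable by
one nucleotide change: $(a, b)$ is reachable iff some sense codon of
$a$ and some sense codon of $b$ differ at exactly one position. Stop
codons never participate. The relation is deliberately *codon-agnostic*
(existential over all codons of the reference residue) because the
proteins being mutated in silico carry no transcript; the actual codon
at a genomic site could make fewer substitutions reachable. This is the
main open modelling choice in the module and the reason the codon table
is a data-driven text resource rather than hard-coded: alternative
codes can be supplied, though no special case is made for
selenocysteine. Random backgrounds are drawn uniformly without
replacement from the pooled candidates of all proteins, so long
proteins contribute proportionally more — consistent with sampling from
a superset of all possible SAVs.

## Distribution statistics

**Cumulative effect curves.** `fraction(t) = #{s ≥ t}/n` on the integer
grid −100…100 ("at or above", matching the usual reading of a
threshold like ≥ +50). The neutral side of accuracy curves uses ≤ t
symmetrically. Useful named thresholds are −42, +50 and +75 (the points
where a well-calibrated predictor reaches ~85% neutral, ~85% effect and
~88% effect accuracy respectively); the full grid is always computed.

**Bootstrap SEM.** The dataset is resampled with replacement `n_boot`
times (default 100), resample size equal to the original $n$; the SEM
is the standard deviation (denominator `n_boot − 1`) of the resample
means. The conventional confidence band is the curve shifted ±3·SEM
*along the score axis*, materialised as threshold offsets. All
randomness flows from one explicit seed.

**Kolmogorov–Smirnov.** $D$ is the supremum over pooled sample values
of the ECDF difference — exact under ties. The p-value uses the
asymptotic Kolmogorov series at effective size $nn'/(n+n')$; values
below 2.2e-16 are floored and printed as "< 2.2e-16". For the large-n
comparisons this package targets, the asymptotic approximation is the
appropriate regime; no exact small-sample p is attempted.

**Correlations.** Pearson $r$ on pairwise-complete scores, with
$SE_r = \sqrt{(1-r^2)/(n-2)}$ and $n$ the complete-pair count. Listwise
deletion is available but never the default.

**Effect AUC** is the *empirical* mass of the distribution strictly
above 0 — a fraction on the same scale as binary effect percentages —
not a kernel-density integral, which would introduce an unstated
bandwidth. `effect_auc(s) + mean(s ≤ 0) = 1` exactly.

**Error-corrected fractions.**
$N_{eff}^* = N_{eff} - FPR\cdot N_{eff} + FNR\cdot N_{neu}$ and
symmetrically for $N_{neu}^*$; total mass is conserved to machine
precision. The rates are user inputs with defaults 0.22/0.23, the
complements of a sustained 78% positive and 77% negative accuracy at
the default threshold. The formula is read as multiplication by a rate;
treating FPR as 1 − positive predictive accuracy is one of two
plausible readings and is documented here rather than hidden.

**Accuracy curves** report NA, never a silent 0 or 1, at thresholds
whose denominator is empty.

## Enrichment

The per-protein filter — at least `min_count` SAVs of a class and a
fraction of strong predictions (score > 50) meeting `min_fraction` —
keeps the strict/non-strict fraction comparison as an explicit switch,
because "more than one … over 50%" and "≥ 2 … ≥ 50%" describe two
subtly different filters and collapsing them would change which
proteins pass at the boundary. Localization folds are
observed/expected category fractions over *unweighted* proteins (not
SAV-count-weighted); raw labels can be united into groups such as
secreted + cell membrane. A category present in the subset but absent
from the background yields an infinite fold, flagged rather than
crashed. An optional coverage predicate (distinct SAV positions /
protein length) supports residue-coverage style subsets.

## The synthetic benchmark

The generators emulate the statistical structure the analysis needs,
with known ground truth:

* **Proteomes**: uniform sequences over the 20 standard residues,
  lengths uniform on 80–300 by default — long enough for alignment and
  coverage filters to be non-trivial, short enough for desk-scale runs.
* **Variant sets**: default class counts 7530/29/40
  (rare/uncommon/common) preserve the extreme rare-dominance of large
  exome collections (≈ 99% rare) at 1/1000 scale; allele frequencies
  are uniform within each class band (common capped at 0.5, a typical
  minor-allele ceiling), and class membership is consistent with the
  classifier for every record by construction.
* **Scores**: two-component Gaussian mixtures, neutral mean −40 and
  effect mean +40 with sd 20 by default, truncated to [−100, 100] *by
  resampling* (clipping would put probability atoms on the boundaries
  and bias AUC checks). With ±40/20 components the mass above 0 is
  within half a point of the effect fraction, so the generating
  `effect_fraction` is directly recoverable as the effect AUC. Default
  effect fractions: common 0.61, rare 0.48 (the values real predictor
  output shows for these classes), random 0.50, cross-species 0.30,
  disease 0.90.
* **Orthologs**: per-residue substitution at a configurable rate with
  no indels, so alignment recovers exactly the substituted positions.
  Default rates — chimp 0.01, mouse 0.10, fly 0.25 — bracket the
  PIDE ≥ 70% filter realistically.
* **Seeding**: every generator is a pure function of (config, seed),
  under R's default Mersenne-Twister generator. Sub-seeds are derived
  by a stable string hash, so enlarging a configuration does not
  reshuffle the streams of existing records; a test asserts that adding
  proteins leaves earlier sequences untouched.

What the benchmark does *not* emulate: real predictor score shapes
beyond two components, nucleotide-level mutation processes (no
transition/transversion bias, no CpG effects), indels, domain
structure, or any correlation between a protein's identity and its
scores. Passing tests therefore demonstrate that the *machinery* is
correct and that known distribution shifts are recovered at the stated
sample sizes — not that any particular biological claim holds on real
data.

## Problem sizes and reproducibility

The shipped analyses run at desk scale by choice: effect-AUC recovery
and the common-vs-rare KS comparison use n = 10,000 scores per class
(recovery within ±0.02 and p < 1e-6 at these sizes); the orchestrated
pipeline defaults to 40 proteins, ~7,600 SAVs and a random background
of 2,000; oracle checks use 500 KS pairs (n ≤ 12) and 200 alignment
pairs (length ≤ 6), where exhaustive enumeration is feasible.
`run_comparison()` is a pure function of its configuration — re-running
it reproduces the report identically, which is how the "every reported
number is recomputable" guarantee is tested.

## Known limitations

* The SNV-reachability relation is codon-agnostic (see above); with
  real transcripts some listed substitutions would be unreachable at a
  given site.
* The affine-gap wrapper inherits Biostrings' traceback tie-break; it
  is deterministic, but equal-scoring alignments may differ from other
  tools' output (the score is identical).
* The asymptotic KS p-value is inaccurate for very small samples; D is
  always exact.
* FPR/FNR error correction assumes class-independent error rates.
* No multiple-testing correction is applied to the pairwise KS matrix;
  the comparisons are descriptive.
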