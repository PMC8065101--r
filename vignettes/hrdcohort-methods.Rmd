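---
title: "Methods: carrier classification, signature refitting and genomic scar scoring in PTV breast-tumour cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier classification, signature refitting and genomic scar scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdcohort)
```

`hrdcohort` characterises breast tumours from carriers of
protein-truncating variants (PTVs) in the homologous-recombination genes
*PALB2*, *BRCA1* and *BRCA2*, against a non-carrier background. This
vignette is the package's own account of the methods: the rules and
models, the parameters that matter, what the synthetic cohort does and
does not emulate, and where the design was genuinely open.

## Carrier groups and biallelic status

A PTV is any stop-gain, frameshift or canonical splice-site variant;
pathogenicity is consequence-based only, with no curation step. Samples
are assigned one group each with germline > somatic > missense
precedence: a germline PTV in a studied gene defines (gene, germline); a
somatic PTV defines (gene, somatic); a missense variant in a studied gene
with no PTV excludes the sample from carrier/non-carrier contrasts; and
everything else is a non-carrier. PTVs in two studied genes raise an
error rather than being silently resolved — the combination is
biologically possible but so unusual that it deserves the analyst's eyes.

Biallelic inactivation means both copies lost. The resolution rule
combines three kinds of evidence:

1. a **somatic second hit** (a distinct somatic PTV in the same gene) is
   biallelic outright;
2. the **ASCN locus call**: LOH iff the allele-specific copy-number
   segment containing the variant's own position has minor copy number 0
   (no gene lookup table — the locus is the variant's coordinate);
3. the **VAF shift**: LOH iff the tumour allele fraction exceeds the
   germline allele fraction by more than 0.20 — read as 20 *percentage
   points*, strictly greater. A relative reading (tumour > 1.2 × germline)
   would call LOH at fractions as close as 0.13 vs 0.10, where no copy
   number change is plausible; the absolute reading matches the expected
   shift under loss of the wild-type allele, which is purity/2.

When the two locus calls agree, they decide. When they disagree, a
shallow-WGS copy-number state at the locus breaks the tie (biallelic iff
`loss`). Any remaining combination — either method `unknown`, or
disagreement with no usable tie-break — is monoallelic with an
`insufficient_evidence` flag, because downstream contrasts dichotomise
and the conservative side of the dichotomy is retaining an intact allele.
For somatic-only carriers there is no germline fraction to compare, so
the ASCN call alone decides (or a second somatic PTV). The full
54-combination decision table is enumerated in the test suite, along with
a monotonicity property: strengthening LOH evidence can never flip a
biallelic call back to monoallelic.

## Mutation catalogues and signature refitting

Somatic SNVs are binned into the 96 trinucleotide substitution channels
(classes C>A … T>G × 16 flanking contexts, lexicographic), with
purine-reference variants reverse-complemented to the pyrimidine strand.
Catalogues with fewer than `min_snvs = 15` mutations are excluded from
signature analysis rather than refit on noise.

Exposures are obtained by re-implemented greedy refitting against a fixed
96 × K signature matrix:

1. normalise the catalogue to a probability spectrum;
2. seed with the single signature of minimal squared error — the empty
   weight vector is not a spectrum, so the stopping rule cannot apply to
   the first step (without the seed, spiky signature profiles can make
   every single-signature reconstruction worse than "nothing", stalling
   the fit immediately);
3. repeatedly golden-section-search, for every signature, the weight
   increment that minimises the SSE between the spectrum and the
   renormalised reconstruction, apply the single best increment, and stop
   when an iteration improves SSE by less than `tol = 1e-3`;
4. normalise the weights to sum to one, then zero weights below
   `weight_cutoff = 0.06` **without renormalising**, so reported weights
   may sum to less than 1.

The cutoff and the absence of renormalisation follow the documented
defaults of the widely used per-sample refitting tool this re-implements.
No trinucleotide-frequency (exome) adjustment is applied; none is exposed
because the package's inputs are already pre-called variant lists and the
adjustment is a property of the capture design, not of the refit.

Two numerical consequences are worth knowing. The greedy stop at
`tol = 1e-3` trades accuracy for robustness at low mutation counts: below
roughly 125 SNVs the multinomial noise floor is of the same order as
`tol`, and fitted weights can be off by several points even when the
model is exactly right — the test suite therefore checks *stratum means*,
not individual low-burden samples. And the brute-force check is a full
0.01-resolution grid search over the weight simplex for K ≤ 3: the fitted
SSE must match the grid optimum within the slack implied by `tol` and the
grid resolution.

The packaged 96 × 13 matrix carries the breast-cancer signature panel's
*names* but **synthetic profiles** (generated deterministically; the
signature-3 stand-in is near-flat like the diffuse HRD signature, the
rest full-support with pronounced peaks). Any 96 × K matrix in the same
TSV dialect can be substituted, and should be for real data.

## Genomic scar scores

All three scores operate on validated, per-chromosome sorted segment
tables with 1-based inclusive coordinates; runs of same-status segments
are merged only when abutting (gap ≤ 1 bp).

- **LOH score**: maximal runs of minor copy number 0 (with at least one
  major copy — homozygous deletions are deletions, not LOH) strictly
  longer than 15 Mb, excluding runs spanning an entire chromosome. The
  cited criterion excludes whole chromosomes only, so whole *arms* still
  count; this is implemented as stated.
- **TAI score**: merged allelic-imbalance runs (major ≠ minor) at least
  11 Mb long that reach a chromosome end, stay on one side of the
  centromere interval, and span less than the whole chromosome.
- **LST score**: per arm — segments overlapping the centromere are split
  at its boundaries, segments shorter than 3 Mb removed, identical-state
  neighbours closer than 3 Mb merged — count breakpoints whose flanks are
  each ≥ 10 Mb and separated by < 3 Mb.

The 15/11/10/3 Mb constants follow the published score definitions as
operationalised by the standard scar-scoring package. Ploidy is not
used (no near-tetraploid LST adjustment) — a documented limitation.
HRD-sum is the plain sum and is asserted, not recomputed, downstream.

## Expression indices

The expression matrix is log2(x + 1); linear values are recovered as
2^v − 1. CYT is the geometric mean of linear GZMA and PRF1 with a 0.01
offset, so double-zero expression floors at 0.01 instead of collapsing to
zero. The immune score is a rank-based single-sample enrichment: genes
are ranked within each sample (descending, average ties) and the score
sums the gap between the rank-weighted in-set cumulative distribution
(weights rank^α, α = 0.25, the cited immune-score convention) and the
uniform out-of-set one. Being rank-based it is invariant to monotone
transforms of a sample's expression — so the log scale of the input is
immaterial to it. The stromal/purity component of the cited
tumour-purity framework is out of scope; the packaged immune set is a
synthetic stand-in and user-replaceable.

Per-sample pathway-expression summaries have no single established
convention; `geneset_mean_z` (mean over set genes of per-gene z-scores)
is this package's choice, because it is scale-free per gene and centres
at zero across the cohort by construction.

## Group statistics and the bootstrap size-correction

Carrier strata (gene × allelic status) are compared against non-carriers
with the two-sided Mann–Whitney U test: exact null distribution when
n₁·n₂ ≤ 400 with no ties, otherwise the normal approximation with tie and
continuity corrections (the same switch as base R's implementation, which
the tests cross-check, plus a full-enumeration oracle at n ≤ 10).
Categorical contrasts use Pearson's chi-square without continuity
correction. No multiple-testing adjustment is applied across metrics.

Because strata of 3–16 tumours face a pool of hundreds of non-carriers,
a bootstrap size-correction is reported alongside the raw p: draw 30
controls from the pool *without replacement* (with replacement would
duplicate patients), compute the two-sided Mann–Whitney p against the
stratum, repeat 1000 times, and report the median iteration p (standard
even-count interpolation). The correction is conservative by
construction; the suite verifies calibration (null rejection at 0.05
within one-sided binomial error over 200 replicates) and power under a
large location shift. Whether a headline contrast should quote the raw or the corrected p is
an analyst's choice, so both are always reported side by side.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` reproduces the *statistical structure* the analysis
assumes, in the exact file dialects the readers consume, with a
ground-truth table for recovery testing. The defaults describe the
emulated cohort: 9/16/14 PTV tumours (6+3, 10+6, 11+3 germline+somatic) with
biallelic subsets 3/7/7 (one PALB2 tumour biallelic via somatic second
hit, the rest via LOH) and 500 non-carriers; per-stratum SNV medians
125/146/214 (biallelic), 74/42/68 (monoallelic) and 46 (non-carrier)
under a negative binomial with dispersion 1.0 (only medians are
targeted; the mean is solved numerically so the distribution's median
hits the target); per-stratum signature-3 means 48.9/44.4/39.5%, 18.8/15.1/
30.6% and 8.2% (Beta-distributed per sample, concentration 30, mixed
with an ageing-like background signature so weights sum to 1); scar-event
Poisson medians LOH 14/19/13, TAI 27/26/19, LST 22/26/21 (biallelic) vs
6/9/7 (non-carriers). Monoallelic scar medians are fixed intermediate
values (8/12/10), chosen once. Tumour
purity defaults to 0.7 and germline VAFs are Normal(0.5, 0.02), shifted
to 0.5 + purity/2 at LOH loci — so the default separation (0.35) clears
the 0.20 rule with margin, and setting the noise to zero makes
classification recovery exact.

The genome is a reduced synthetic one: 22 autosomes with realistic
lengths and centromere intervals, no sex chromosomes (the autosomal focus
of breast-tumour scar scoring). Implanted scar events are isolated from
each other and from the diploid baseline by uncovered gaps wider than the
LST smoothing length, so each implanted event contributes exactly one
count to exactly one score — this is what makes "noise off ⇒ scores equal
implanted counts" an exact, non-circular oracle. Event-count draws are
truncated at the genome's physical capacity (two telomeres per
chromosome for TAI; finite arm space for interior events), which bounds
real scores the same way; medians are unaffected. Gene loci are fixed
synthetic coordinates per gene carried in the generator, because real
transcript coordinates are irrelevant to the algorithms.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: subclonality and purity mixtures (every somatic
VAF is centred at purity/2), segmentation noise and uncovered-region
patterns of real ASCN callers, indel context realism (indels are counted
in burden but carry no catalogue channel), correlated immune/expression
structure beyond a single log2 shift on immune genes in *BRCA1* tumours
and reduced expression of the mutated gene itself, and any association
between mutation burden and scar burden within a sample (they are drawn
independently given the stratum).

## Problem sizes and determinism

The test suite exercises: the full 54-entry evidence decision table; 24
hand-counted scar fixtures plus exact recovery on noise-free synthetic
genomes (small cohorts of 8 non-carriers plus the 39 carriers); signature
recovery at n = 5000 SNVs over 20 seeds and grid-oracle equivalence at
n = 3000; bootstrap calibration with 200 null replicates at the default
1000 iterations; Mann–Whitney enumeration for every partition up to
n = 10; and byte-identical repetition of the full default pipeline
(simulate + all stages, 539 samples) under one seed. All randomness flows
from explicit seeds; `bootstrap_compare` restores the caller's RNG state,
and repeated runs of any stage with the same seed produce byte-identical
files.

## Known limitations

- PTV status is consequence-based; no ClinVar-style curation.
- No ploidy-aware LST adjustment; scores on near-tetraploid genomes will
  differ from ploidy-corrected implementations.
- The packaged signature matrix and immune gene set are synthetic
  stand-ins, adequate for validating the machinery but not for biological
  interpretation — substitute real resources for real cohorts.
- The exact Mann–Whitney path requires tie-free data; tied data fall back
  to the corrected normal approximation, as in base R.
- Low-burden samples (< ~125 SNVs) carry refit noise of several points in
  individual signature weights; interpret per-sample weights cautiously
  and prefer stratum means.
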