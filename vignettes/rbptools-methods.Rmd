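---
title: "Methods: harmonized RBP interactomes and post-transcriptional regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized RBP interactomes and post-transcriptional regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbptools)
```

# The problem

A recurring question in post-transcriptional regulation is whether an
RNA-binding protein (RBP) — for example a yeast hnRNP K-like protein —
specifically binds a functionally coherent group of mRNAs (such as the
transcripts encoding nuclear-pore-complex subunits) and, if so, what that
binding does to the targets: does it change their abundance, their
translation, or the turnover of the proteins they encode? Answering this
requires stitching together very different measurements: genome-wide
binding datasets produced by incompatible technologies, targeted
RIP-qPCR validation, polysome-gradient fractionation, western-blot
densitometry of cycloheximide chases, and two-color microarray
comparisons. `rbptools` implements each of those analysis stages as a
small, contract-checked module, and pairs them with a seeded synthetic-data
generator that carries the full ground truth, so that every stage can be
validated end to end by parameter recovery rather than by eye.

# Harmonizing heterogeneous binding datasets

Three assay families are harmonized into one matrix:

* **CRAC-style crosslink counts.** Raw counts confound binding with
  transcript abundance and sequencing depth. The pipeline applies three
  steps in a fixed order: *hits per million* within each library (removes
  depth); a *per-transcript unit normalization* — each transcript's vector
  of hpm values across **all** CRAC experiments is scaled to unit Euclidean
  norm (sum of squared entries = 1) — which cancels abundance because
  abundance inflates a transcript's counts in every library by a common
  factor; and a *min–max rescale to [0, 1]* per experiment so columns are
  comparable. The unit norm is applied across all CRAC experiments jointly
  (all RBPs and replicates) rather than within one RBP's replicates: within
  a single RBP the binding signal itself would cancel and only noise would
  remain, so the joint scope is the only one under which the step does what
  it is meant to do.
* **RIP microarray scores.** Continuous scores are consumed as given and
  only categorized (see below); no score is retained in the matrix because
  scores from different platforms are not on a comparable scale.
* **CLIP binary calls.** Published bound/unbound calls pass through
  unchanged as `BOUND`/`UNBOUND`.

Scored experiments are cut into four equal-sized binding categories
(`HIGH`, `MEDIUM`, `LOW`, `VERY_LOW_NONE`) by descending score. When the
transcript count is not divisible by four, the extra members go to the
highest categories first, so category sizes are non-increasing from top to
bottom and never differ by more than one. Ties are broken by a stable sort
with the transcript id as the final key; an all-tied experiment is
categorized in id order with a warning rather than an error. Transcripts
with an all-zero CRAC vector cannot be normalized; they keep score 0, are
flagged in the normalization log, and are always categorized
`VERY_LOW_NONE`.

## What the count simulator emulates — and the panel design

`simulate_binding_experiments()` draws per-transcript expression from a
lognormal prior (`sdlog = 1.5` by default, so abundance spans orders of
magnitude and genuinely dominates raw counts) and per-RBP affinities from
lognormal priors. CRAC counts are gamma-mixed (negative binomial) draws
with expectation `depth x affinity x expression / sum(affinity x
expression)`; `dispersion = 0` switches to deterministic half-up rounding
of the expectation so the zero-noise limit is exact.

The default panel (`default_binding_panel()`) is *not* three
interchangeable RBPs. It contains one highly specific RBP (affinity
`sdlog = 1.3`) and two general binders (`sdlog = 0.5`). This mirrors real
interactome panels, which combine a specific factor of interest with bulk
mRNA-metabolism factors (export and packaging proteins) that associate with
most transcripts roughly in proportion to abundance. The design matters
statistically: the per-transcript unit norm divides each experiment by the
pooled signal of the whole panel, and the general binders' libraries are
what anchors that pool to abundance. With three equally specific RBPs the
normalized score of each one is distorted by the equally variable signals
of the other two, and the rank agreement between normalized score and true
affinity plateaus around 0.77 even without noise; with the specific-plus-
general design the specific RBP's normalized score recovers its affinity
ranks at Spearman ≈ 0.84–0.88 under realistic count noise while its
correlation with expression stays below 0.1.

# Gene-set enrichment

Whether a gene set concentrates among an RBP's preferred targets is tested
with the classic running-sum statistic over the ranked binding profile:
walking the ranking from the top, members increment the sum by
`1/set_size` (unweighted form; a `|score|^p` weighted form is available
behind `weighting_exponent`), non-members decrement it by
`1/(N - set_size)`, and the enrichment score (ES) is the excursion of
maximum absolute magnitude, signed. The unweighted default is used because
only the ranking, not the score scale, is trustworthy after
harmonization.

The null is gene-label permutation — random same-size sets — which is the
only null available for a single ranked profile (there are no phenotype
replicates to permute). The p-value uses the add-one estimator against the
**same-sign side** of the null:
`p = (1 + #(null ES >= obs)) / (1 + #(null ES >= 0))` for a positive
observed ES, mirrored for a negative one. Conditioning on the sign makes
the estimator exchangeable-rank valid — under the null the observed ES is
one more draw among the same-sign permutation scores, so
`P(p <= alpha) ≈ alpha` — whereas comparing a signed observation against
the full two-sign null would double the type-I rate. The estimator never
returns 0; the smallest attainable p is `1/(n_perm + 1)`.

For permutation speed the unweighted ES is computed in `O(set_size)` per
permutation from the member positions alone: between consecutive members
the running sum decreases monotonically, so its extrema occur only
immediately before or after a member. The test suite verifies this fast
path against the literal walk and against exhaustive enumeration of all
`C(8,3)` sets of a toy universe.

# RIP-qPCR quantification

Ct values convert to relative quantities as
`quantity = dilution_factor x E^(-Ct)` with amplification efficiency
`E in (1, 2]` (default 2, perfect doubling, since no per-primer
efficiencies are assumed); technical replicates are averaged on the Ct
scale first, and a spread above 0.5 cycles raises a warning. Recovery is
expressed as percent of input,
`100 x IP / (input / input_fraction)`, where `input_fraction` is the share
of material the input aliquot represents. Fold enrichment divides each
percent-of-IP by its sample's bait recovery and then by the bait-normalized
no-tag value for the same target, so the no-tag control is exactly 1. The
two normalization orders (bait first or no-tag first) differ only by a
constant per target and leave folds unchanged; bait-first is implemented.
The synthetic Ct generator inverts this arithmetic exactly, so the
zero-noise roundtrip recovers planted folds to floating-point precision,
and under Ct noise the fold error is lognormal with
`sd(log fold) = ln(E) x ct_sd / sqrt(n_replicates) x 2` (four Ct means
enter each fold), which the test suite checks empirically.

# Polysome-gradient summaries

A 14-fraction sucrose gradient is summarized per transcript as a
distribution over fractions. Quantities are first corrected by the
spike-in RNA added equally to every fraction: each fraction's quantities
are divided by `spike(f) / mean(spike)`, the *relative* spike recovery, so
the correction is unit-free and preserves between-target ratios within a
fraction. The corrected quantities are normalized to sum to 1.

Fraction classes follow the standard gradient anatomy: fractions 1–6 hold
free untranslated mRNPs (`LIGHT`), 7–8 span the 80S monosome
(`MONOSOME`), 9–13 hold polysomes (`POLYSOME`), and the last fraction is
`UNASSIGNED`. The **translated proportion** is the distribution mass in
`POLYSOME` fractions; monosome and unassigned mass stays in the
denominator but in neither numerator, because 80S-associated mRNAs cannot
be cleanly assigned to either the repressed or the actively translated
population. The heavy-polysome proportion (default fractions 11–13, the
part of the gradient with four or more ribosomes per mRNA) is reported
alongside; the exact fraction-to-ribosome mapping is gradient-specific and
therefore configurable rather than fixed.

The simulator models each transcript's gradient mass as a two-component
mixture: a share `1 - theta` in a discretized Gaussian bump at the light
peak (fraction 3) and `theta` in a bump at the polysomal peak (fraction
11). The bump width defaults to 1.0 fractions. This width was chosen so
that essentially all (≈99%) of each bump's mass falls inside its fraction
class: the translated-proportion summary reads class mass, so if the
polysomal bump bled appreciably into the monosome/unassigned fractions the
planted `theta` would be systematically under-recovered and the recovery
contract (±0.05 under 10% noise and ±30% spike perturbation) could not be
met by any estimator that respects the class map. With width 1.0 the
recovery bias is below 0.01 for all `theta`.

# Protein turnover

Densitometry signals are calibrated against a serial dilution of a
reference sample by a least-squares line through the origin (zero protein
gives zero signal; a free-intercept variant exists for films with a
background offset), then divided by per-lane loading factors and by the
t = 0 amount. Decay is fitted by ordinary least squares of `log2(amount)`
on time with a free intercept — anchoring the intercept at exactly 1 would
let t = 0 measurement noise bias the rate. The decay constant is
`k = -slope x ln 2` per minute, clipped at 0 with a warning when the
fitted slope is positive (apparent growth), and the half-life is
`ln 2 / k`, reported as `Inf` in the no-decay limit. The single-exponential
model is this package's formalization of relative chase curves; reports
label it as a model fit, not as a model the underlying blots prove.

# Dye-swap microarray analysis

Two-color comparisons replicated with a dye swap store the swapped
replicate's log2 ratio with its sign flipped; `combine_dye_swap_replicates`
flips it back before averaging, so the swap is an involution. The
between-replicate standard deviation uses the n−1 denominator (two
replicates give `|difference| / sqrt(2)`). Genes with SD strictly above
0.5 log2 units are removed — a gene at exactly 0.5 is retained — and genes
with a single replicate are removed with a distinct flag since their
consistency cannot be assessed. Filtered genes are then stratified by their
binding category and each category is compared to the `VERY_LOW_NONE`
baseline with the Mann–Whitney–Wilcoxon rank test (Welch's t-test is
available); a degenerate comparison (all values tied) reports p = 1. No
multiple-testing correction is applied across the three category-versus-
baseline tests by default, matching single-test reporting practice; a
Benjamini–Hochberg switch exists.

The corresponding generator places a gene's two oriented replicates at
`true ± d/sqrt(2)`, so the planted per-gene inconsistency `d` *is* the
between-replicate SD at zero noise and the filter's behavior can be checked
exactly: genes with `d > 0.5` are removed, all others retained.

# Consensus-motif scanning

Transcript sequences are scanned for fixed IUPAC consensus strings (such
as the CA-rich octamer `CAUCAUCA`) and triplet repeats (`CNN` repeated six
times). `N` matches any base, `U` and `T` are interchangeable on input, and
only the mRNA sense strand is scanned since the targets are mRNAs.
Coordinates are reported 1-based inclusive, matching the probe-naming
convention of molecular biology (a BED-style 0-based half-open export is
provided). Matching is delegated to `Biostrings::matchPattern()` with
IUPAC semantics; the test suite holds it to zero discrepancies against an
independent naive position-by-position matcher on 1,000 random 500-nt
sequences. With `overlap_allowed = FALSE` overlapping hits are resolved
greedily left to right. De novo motif discovery is out of scope; users
supply known consensus strings.

# Reproducibility model

All randomness flows from one integer seed. Each simulation stage derives
a child seed by a fixed documented formula
(`child_seed()`: `(seed + 1000003 x stage_offset) mod (2^31 - 1)`), and
condition or protein labels offset the stage seed so that, e.g., wild-type
and mutant gradients receive independent noise while remaining individually
reproducible. `run_pipeline()` executes the stages in dependency order,
writes only plain-text outputs (TSV, YAML, JSON, FASTA), and records a
per-stage report with parameters, record counts, collected warnings and MD5
checksums; running the same configuration and seed twice yields
byte-identical outputs. A stage failure is recorded and aborts all
downstream stages, leaving no partial downstream outputs.

# Problem sizes used in the shipped checks

The package's own validation runs at sizes chosen to make the statistical
properties sharp while keeping the suite quick on a laptop: 2,000
transcripts and 3 RBPs x 2 replicates for the confound-removal study; 1,000
null rankings (universe 500, set 7, 199 permutations) for type-I
calibration and 200 seeded runs for power; 10 transcripts per planted
translated proportion; 100 seeded chase series; 200 seeded dye-swap runs;
1,000 random sequences for the scanner oracle; and a 200-transcript
end-to-end pipeline run executed twice for determinism. These sizes are the
package's choices, stated here so they can be scaled up.

# What passing the synthetic checks does and does not show

The generator reproduces the statistical *structure* each stage assumes —
abundance-confounded overdispersed counts, bimodal gradient distributions
with fraction-specific recovery, exponential decay with multiplicative
noise, Ct arithmetic, dye-swap orientation with per-gene inconsistency —
but none of the *biology*: no sequence-driven binding, no fragment-level
crosslink positions, no ribosome-loading mechanics, no array-specific
spatial artifacts, and noise magnitudes are plausible choices rather than
estimates fitted to any real dataset. Recovery of planted parameters
therefore validates the arithmetic and the statistical calibration of the
pipeline, not the biological correctness of any particular published
dataset processed with it.

# Known limitations

* RIP scores are categorized per experiment; pooling across studies is not
  attempted because cross-platform score scales are incomparable.
* The enrichment module reports a single set's ES and p; multi-set FDR and
  leading-edge extraction are out of scope.
* The polysome module consumes per-fraction quantities; A254 trace
  processing and peak detection are upstream of it.
* The decay model is single-exponential; two-phase decay is not fitted.
* Calibration lines are per-blot; no cross-blot signal harmonization is
  attempted.
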