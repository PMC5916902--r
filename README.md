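# rbptools

Analysis toolkit for asking whether an RNA-binding protein (RBP)
specifically binds a group of mRNAs — such as the transcripts encoding
nuclear-pore-complex subunits — and what that binding does to them:
steady-state abundance, translation, or turnover of the encoded proteins.

The package implements, as small contract-checked modules:

* **Interactome harmonization** — CRAC crosslink counts, RIP microarray
  scores and CLIP binary calls are merged into one 0–1 binding matrix
  with four quartile binding categories per experiment. CRAC counts are
  normalized as hits per million within each library, then each
  transcript's vector across all CRAC experiments is scaled to unit
  Euclidean norm (&sum;<sub>i</sub> x<sub>i</sub>² = 1, cancelling
  transcript abundance), then min–max rescaled to [0, 1] per experiment.
* **Gene-set enrichment** — the classic unweighted running-sum statistic
  (members add 1/m, non-members subtract 1/(N−m), ES is the signed maximal
  excursion) with a gene-label permutation null and the add-one estimator
  on the same-sign side: p = (1 + #{ES<sub>null</sub> ≥ ES}) /
  (1 + #{same-sign ES<sub>null</sub>}).
* **RIP-qPCR quantification** — quantity = dilution × E<sup>−Ct</sup>,
  percent of IP = 100 · IP / (input / input_fraction), and fold over a
  no-tag control after bait-recovery normalization (no-tag ≡ 1).
* **Polysome-gradient summaries** — spike-corrected per-fraction
  distributions, translated proportion (mass in polysome fractions 9–13 of
  a 14-fraction gradient), heavy-polysome proportion, and wt-vs-mutant
  shift reports.
* **Protein turnover** — serial-dilution densitometry calibration and
  log-linear single-exponential decay fits: k = −slope·ln 2,
  t<sub>1/2</sub> = ln 2 / k.
* **Dye-swap microarray analysis** — sign-corrected replicate averaging,
  the SD &gt; 0.5 replicate-consistency filter, and binding-category
  stratification with Mann–Whitney–Wilcoxon tests.
* **Consensus-motif scanning** — IUPAC consensus and triplet-repeat
  scanning (e.g. `CAUCAUCA`, (CNN)₆) with 1-based inclusive coordinates
  and BED export.
* **Synthetic data with ground truth** — every assay above has a seeded
  generator planting known affinities, expression levels, translated
  proportions, half-lives, fold enrichments and replicate inconsistencies,
  so each stage is validated by parameter recovery.

## Worked example

Simulate a panel of binding experiments (one specific RBP, two general
binders), harmonize it, and test a gene set for enrichment among the
specific RBP's targets:

```r
library(rbptools)

cfg <- sim_config(n_transcripts = 500, seed = 42)
sim <- simulate_binding_experiments(cfg)
bm  <- assemble_binding_matrix(sim$experiments)
bm
#> <binding_matrix> 500 transcripts x 6 experiments
#>   assays: CRAC_COUNT=6
#>   normalization steps: hits_per_million -> unit_norm_per_transcript ->
#>     rescale_unit_interval -> categorize_quartiles

tx     <- bm$transcripts
scores <- setNames(bm$score[, 1], tx)            # first rbp_a replicate
top25  <- names(sort(sim$truth$affinity[tx, "rbp_a"],
                     decreasing = TRUE))[1:25]   # a planted target set
permutation_p_value(scores, top25, n_perm = 10000, seed = 7)
#> <enrichment_result> es = 0.8063, p = 0.0002036 (10000 permutations, seed 7)
#>   set 25 / universe 500, weighting exponent 0
```

The enrichment score 0.81 means the set piles up near the top of the
ranking; p is the add-one permutation estimate against the same-sign side
of the null — here the observed score exceeds every positive permutation
score, so p sits at its floor of 1/(1 + #positive nulls). The normalized score tracks the planted binding affinity and not
transcript abundance:

```r
cor(scores, sim$truth$affinity[tx, "rbp_a"], method = "spearman")  # 0.87
cor(scores, sim$truth$expression[tx],        method = "spearman")  # -0.01
```

Translation and turnover of a target, wild type versus mutant:

```r
wt  <- simulate_polysome_profiles(cfg, c(nup_mrna = 0.25), condition = "wt")$profile
mut <- simulate_polysome_profiles(cfg, c(nup_mrna = 0.70), condition = "mutant")$profile
s_wt  <- summarize_translation(wt)[[1]]
s_mut <- summarize_translation(mut)[[1]]
compare_conditions(s_wt, s_mut)
#> <translation_shift> nup_mrna: wt -> mutant, delta translated +0.419, delta heavy +0.281

fit_exponential_decay(simulate_chase_series(cfg, half_life = 30, condition = "mutant"))
#> <decay_fit> protein [mutant]: k = 0.02365 /min, half-life = 29.31 min (n = 6)
```

The recovered translated proportions (0.248 and 0.667 for planted 0.25 and
0.70) and the fitted half-life (29.3 min for a planted 30 min under 5%
noise) are the recovery checks the test suite runs at scale.

The full synthetic pipeline — simulate → harmonize → enrich → RIP →
polysome → turnover → transcriptome → scan — runs from one seed:

```r
report <- run_pipeline(default_pipeline_config(seed = 1), outdir = "pipeline_out")
```

or from a shell via `Rscript inst/cli/pipeline.R --seed 1 --outdir out`.
All outputs are plain text (TSV/JSON/YAML/FASTA) with MD5 checksums in
`run_report.json`; identical seeds give byte-identical outputs.

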