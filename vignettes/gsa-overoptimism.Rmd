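---
title: "Quantifying overoptimism from analysis choices in gene set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying overoptimism from analysis choices in gene set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene set analysis (GSA) asks whether predefined sets of genes — pathways,
ontology terms — show coordinated expression differences between two
conditions. Between the raw count matrix and the final table of enriched
sets lies a chain of steps at which several options are defensible:
prefiltering, duplicate-ID removal after gene ID conversion,
transformation and normalization, the differential expression (DE)
statistic, the gene set database, the ORA background ("universe"), the
gene-level ranking metric, the enrichment-score weighting, and the
permutation scheme behind the p-values. An analyst who tries a few options
and keeps whatever makes the result look best — more enriched sets, or a
smaller p-value for a favorite pathway — is cherry-picking, usually
without malice. `gsaverse` turns that behavior into an algorithm so its
effect can be measured: how much better do results get when each choice is
greedily tuned toward a goal, on data where the true answer is *nothing is
enriched*?

The null ground truth comes from sample-label permutation: expression
stays exactly as it is, only the condition labels are shuffled (preserving
group sizes), so any "improvement" obtained by tuning is pure
overoptimism.

## The synthetic data generator

No real dataset ships with the package; everything runs on synthetic
counts from `simulate_counts()`. The generative model is deliberately
simple and fully documented — it is a stand-in, not a claim about real
transcriptomes:

* per-gene baseline means are drawn log2-uniformly (default range 3–9),
  counts are negative binomial with one common dispersion (default 0.2,
  so the variance is $\mu + 0.2\mu^2$);
* per-sample library-size factors are log-uniform in `[0.7, 1.3]`;
* gene–gene dependence is block-wise: genes are partitioned into blocks
  (default 40 genes) and, within a block, share a latent Gaussian factor
  with correlation $\rho$; the latent Gaussians are mapped through the
  negative-binomial quantile function (a Gaussian copula). We chose the
  copula over an additive latent log-mean shift because it leaves the
  *marginal* count distribution identical for every $\rho$: comparisons
  between $\rho = 0$ and $\rho > 0$ then isolate the effect of dependence
  itself;
* designated gene sets can carry a true signal, a log2 group-mean
  difference applied to the reference condition;
* ID-conversion tables (`simulate_id_table()`) collapse a configurable
  fraction of targets onto two source rows each, so the duplicate-removal
  choice is genuinely exercised; gene set databases
  (`simulate_database()`) have uniform sizes and exact, controlled overlap
  between consecutive sets.

One master seed drives everything; each artifact derives a child seed
(`child_seed()`), so counts, databases and permutations are independently
reproducible.

The correlation structure is the load-bearing part. Sample-permutation
nulls respect gene–gene correlation (each permuted dataset keeps the full
expression matrix intact), so enrichment methods built on them stay
calibrated. Gene-permutation nulls assume exchangeable genes; with
correlated blocks the observed enrichment scores of block-aligned sets are
far more variable than their gene-shuffled null, and false discoveries
follow. This is the structural reason the preranked archetype is both
miscalibrated and the most rewarding target for tuning.

What the generator does **not** emulate: gene-specific dispersion,
mean–variance trends, batch effects, more than two conditions, count
sparsity patterns of single-cell data, and realistic pathway topology.
Passing tests therefore demonstrate internal correctness and the claimed
qualitative mechanisms, not quantitative agreement with any real dataset.

## The GSA archetypes

Four self-contained archetypes cover the ORA and FCS families. They are
archetypes, not re-implementations of the published tools; their
behavioral differences (input type, null scheme, threshold convention) are
what the optimizer exploits.

* **`ora_test()`** — upper-tail hypergeometric probability of the overlap
  between a DE gene list (BH-adjusted DE p < 0.05) and each set, given a
  universe; fold enrichment as the effect statistic.
* **`gsea_sample_perm()`** — the weighted Kolmogorov–Smirnov enrichment
  score: walking down the ranked gene list, set members add
  $|r_g|^{p_w}/N_R$ and non-members subtract $1/(N - N_h)$; the ES is the
  signed maximum deviation (magnitude ties resolve to the positive
  extreme). The null relabels samples and recomputes the entire ranking
  each time. `p_w` is 1 (weighted, default) or 0 (equal weights).
* **`gsea_preranked()`** — the same score on a fixed ranked list, with a
  null that permutes gene labels on that list (one shared permutation per
  iteration across sets, standard practice).
* **`weighted_fcs()`** — gene-frequency weights
  $w_g = 1 + \sqrt{(f_{max} - f_g)/(f_{max} - f_{min})}$ (genes appearing
  in many sets count less), set score the weighted mean of |moderated t|,
  assessed against a sample-permutation null.

Shared machinery: permutation p-values use the pseudocount estimator
$(1 + b)/(1 + B)$ so they are never 0; the normalized enrichment score
divides the ES by the mean same-sign null ES (sets with an empty same-sign
null class get p = 1 with a note); multiplicity is controlled by
Benjamini–Hochberg across sets. The classic preranked interface declares
enrichment at q < 0.25 while package-style tools use BH-adjusted p < 0.05;
both conventions travel in `method_spec()`. We deliberately apply the
0.25 threshold to BH-adjusted permutation p-values rather than
reproducing the ratio-of-tails q estimator: it is deterministic, simpler,
and the threshold convention — the thing that matters to the optimizer —
is preserved.

Set-size bounds default to 5–500 after intersection with the analyzed
genes; the running-sum methods additionally require a set to be a proper
subset of the analyzed genes. The moderated t shrinks per-gene pooled
variances toward their mean with a fixed prior weight of four
pseudo-observations — a documented, testable stand-in for empirical-Bayes
shrinkage. The signal-to-noise ratio floors each group SD at
$0.2\,|\bar{x}|$ (and $10^{-8}$), mirroring common practice, and carries
no p-value: it is valid only as a ranking metric, and configurations that
need a p-value from it fail, which the optimizer treats as non-improving.

### Relative rank

For the rank goal, sets are densely ranked by ascending adjusted p (ties
share a rank) and the target's rank is divided by the maximum assigned
rank. Dense ranking was chosen over competition ranking because it
guarantees the boundary property that an adjusted p of 1 yields a relative
rank of exactly 1, for any number of sets and ties.

## The choice space and the optimizer

`build_choice_space()` declares the steps in a fixed a-priori order that
follows the natural workflow, with one deliberate exception: the DE method
is placed *before* prefiltering, because different DE pipelines prescribe
different prefilters, so an analyst settles the DE method first.

| step | default | alternatives | applies to |
|---|---|---|---|
| dedup | keep_first | keep_highest_mean | all |
| de_method | welch_t | moderated_t, wilcoxon_z (+ snr for ranked FCS) | ora, ranked FCS |
| prefilter | total_count(10) | none, cpm(1, ≥2 samples) | all |
| transform | log2_cpm(0.5) | median_ratio_log, cpm | expression FCS |
| geneset_db | first db | remaining dbs | goal 1 only |
| universe | all_measured | post_filter, all_annotated | ora |
| gene_metric | statistic | signed_logp, log2fc | ranked FCS |
| pvalue_calc | sample_perm | gene_perm | gsea_sample_perm |
| weight | p_w = 1 | p_w = 0 | ranked FCS |

Defaults are declared, not hard-coded; where the field has a convention we
follow it (weighted ES, i.e. `p_w = 1`, is the default and *equal*
weighting is the exploitable alternative), and where none exists the
default is set once and documented here. The database step applies only
when maximizing the DEGS count — a target set from one database has no
counterpart in another. The p-value-calculation choice is exposed as
sample- versus gene-permutation for the sample-permutation archetype;
published descriptions of this "p-value calculation" choice are vague, and
this is our concrete reading of it.

`stepwise_optimize()` starts from the all-default configuration and sweeps
the steps once, in order. At each step every alternative is evaluated with
all other steps held at their current choices; the strictly best improving
alternative is adopted (equal improvements resolve to the earlier-declared
option; equality with the incumbent is never an improvement), otherwise
the incumbent stays. A crashing option is recorded and treated as
non-improving — a well-intentioned analyst abandons a variant that errors
— and never aborts the optimization. The trajectory records every
evaluation, so the audit identity holds: number of evaluations =
1 + the number of alternatives across applicable steps.

Two numerical conventions matter for fairness. First, one permutation
seed is shared by **all** evaluations of a trajectory, not just within a
step: options are compared on identical permutation streams, and the
incumbent objective carried from a previous step remains comparable
without Monte-Carlo drift. Second, when a target set is filtered out of a
result (for instance by the set-size bounds after aggressive
prefiltering), the objective takes its worst value (adjusted p = 1,
relative rank = 1) rather than being undefined, keeping the greedy
comparison total.

Goal-directed monotonicity — the optimized objective is never worse than
the default — follows structurally from the strict-improvement rule and is
still asserted on every run. On toy spaces with independent
(additive) step effects the greedy result provably equals the global
optimum; with interacting steps it can only fall short, never exceed it,
and the tests verify both facts against exhaustive enumeration.

## The study grid

`study_design()` / `enumerate_settings()` build the full experiment: one
optimization process per combination of goal, dataset, label assignment
(true labels plus P random permutations) and method, with two target sets
per dataset for the targeted goals and web-interface (`manual_only`)
methods excluded from the rank goal. The reference seven-method panel —
three ORA variants, one weighted FCS, two sample-permutation
enrichment-score methods (one using the q < 0.25 convention) and one
preranked method — with 2 datasets, 10 permutations + truth and 2 target
sets yields 638 settings. `run_study()` executes them resumably (records
are appended as they complete and existing records are skipped), derives
per-setting seeds from the master seed so any setting can be re-run in
isolation, and `summarize_study()` reports default-vs-optimized
objectives, improvement fractions and which steps triggered the changes.

## Problem sizes and tolerances

The simulations shipped in the tests and in `scripts/acceptance.R` use
2000 genes, 50 sets and 10 + 10 samples for calibration and inflation
checks (20 replicates), 50 replicates for signal recovery, and a
scaled-down study (1000 genes, 25 sets, 2 permutations + truth, four
methods) for the end-to-end overoptimism numbers; these sizes were chosen
as the smallest at which the qualitative effects are unambiguous.
Permutation counts are 100–200, putting the p-value floor at
$\approx 0.005$–0.01; exact oracle comparisons (hypergeometric
enumeration, brute-force running sums, the step-up formula) use tolerance
$10^{-12}$, and Monte-Carlo checks use wide bands stated next to each
test.

## Limitations

* The DE options are scoring archetypes (Welch t, moderated t with a
  fixed prior, rank-sum z, SNR), not the model-based pipelines used in
  practice; the optimizer needs interchangeable options with genuinely
  different behavior, which these provide, but absolute DE performance is
  out of scope.
* The q < 0.25 convention is applied to BH-adjusted permutation p-values,
  not to a ratio-of-tails q estimate.
* Greedy single-sweep optimization is a model of *plausible* analyst
  behavior; it neither explores the full multiverse nor combines multiple
  goals.
* All quantitative results are statements about the synthetic generator
  described above.
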