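---
title: "Methods: ranking SNP panels for population assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking SNP panels for population assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelrank)
```

## The problem

Genetic stock identification asks: given a *baseline* of reference
populations genotyped at a set of biallelic SNPs, to which population does
a new individual belong? Genotyping cost scales with the number of loci,
so practitioners assemble fixed-size panels (commonly 48 or 96 SNPs, the
sizes of standard genotyping plates) from a larger candidate set. This
package implements and compares five ways of ranking candidate loci, and
two ways of measuring how well the resulting panels assign individuals.

## Data model

The core object is the `genotype_table`: an individuals-by-loci matrix of
reference-allele dosages (2 = homozygous reference, 1 = heterozygous,
0 = homozygous alternate, `NA` = missing), with population labels and an
optional population-to-region mapping. Genepop-format files (2- or 3-digit
allele codes) are read and written losslessly for biallelic data.

Before any ranking, standard quality control applies: individuals missing
more than 10% of calls are removed, and loci monomorphic across all
populations are dropped (they carry no assignment information and leave
the Weir–Cockerham estimator undefined). Per-locus QC statistics —
Hardy–Weinberg chi-square tests, rarefied allelic richness, permutation
G-tests of linkage disequilibrium, and Holm's sequential-Bonferroni
correction — are available for dataset characterization.

## The five locus rankings

**Weir–Cockerham θ.** The method-of-moments estimator of F_ST from the
1984 variance-component formulation: θ = a / (a + b + c), where a, b, c
are the among-population, among-individual and within-individual
components computed from per-population sample sizes, allele frequencies
and observed heterozygosities. Multilocus and pairwise estimates combine
components as ratios of sums, not averages of ratios. Negative estimates
are preserved (they are informative about sampling noise around zero
differentiation); a locus monomorphic overall is flagged undefined.

**Rosenberg's informativeness for assignment (I_n).** A mutual-information
style statistic: for each allele with mean frequency $\bar p$ across $K$
populations, the contribution is $-\bar p \log \bar p + \sum_k (p_k / K)
\log p_k$, with natural logarithms and $0 \log 0 = 0$. It is 0 for
identical populations and reaches $\log 2$ for a fixed difference.

**Locus contribution to principal components (LC).** Populations-by-loci
allele frequencies are column-centered (not scaled — a biallelic frequency
is already on a common scale) and decomposed by PCA. A locus's
contribution to an axis is its squared loading; LC is the unweighted mean
contribution over the first five axes. Contributions sum to 1 per axis, so
mean LC is exactly 1/L — only relative values matter.

**Jackknife / minimum-panel ranking (WHICHLOCI-style).** Simulated
individuals are drawn from the training baseline's smoothed frequencies;
each locus is scored by the loss in assignment accuracy when it is left
out. Loci are ranked by score and the smallest top-k prefix attaining a
target accuracy (default 95%) is reported.

**Backward elimination (BELS-style).** Starting from all loci, each round
removes the locus whose removal best preserves simulated assignment
accuracy; a locus's rank is the reverse of its removal order (the
last survivor ranks first).

For both simulation rankers the package uses *common random numbers*: one
shared simulated cohort is drawn, per-locus genotype log-likelihoods are
precomputed, and every leave-one-out panel is evaluated on the same cohort
by subtracting the locus's contribution. This removes between-panel Monte
Carlo noise from within-round comparisons — two loci with identical
frequencies get exactly equal scores — and makes backward elimination on
~100 loci tractable.

## Assignment and panel evaluation

Assignment is maximum likelihood under Hardy–Weinberg: an individual's
log-likelihood in population $k$ is the sum over loci of its genotype
probability under $k$'s frequencies. Baseline frequencies are smoothed as
$(x + 0.5) / (n + 1)$ (gene-copy counts), so no genotype has zero
likelihood. Exact ties (within $10^{-9}$ on the log scale) are flagged; in
empirical evaluation they resolve to the first population in baseline
order, while simulated evaluation awards fractional credit $1/t$ for a
$t$-way tie that includes the true population.

Panels are evaluated two ways:

- **Empirical:** baseline from the training half, assignment of the
  holdout half. Individuals are split per population into
  $\lceil n/2 \rceil$ training and $\lfloor n/2 \rfloor$ holdout, so
  ranking never sees the evaluated individuals (Anderson's training/holdout
  bias control).
- **Simulated (f_ORCA):** the probability of correct assignment for
  individuals simulated from the holdout half's smoothed frequencies,
  estimated over 500 replicates of 1000 individuals (allocated evenly
  across populations), or computed exactly by enumerating all $3^L$
  genotypes for small panels.

The drop-off curve removes the five worst average-rank loci at a time down
to five loci, tracking mean and quartiles of per-population empirical
accuracy. Rank lists are compared by Spearman correlation and paired
Wilcoxon tests; panel score groups by one-way ANOVA with Tukey HSD; and
distance matrices (for example pairwise F_ST versus geography) by the
Mantel permutation test.

## The synthetic generator

Because real baselines are rarely redistributable, the package ships a
hierarchical Balding–Nichols generator with full ground truth. For each
locus, an ancestral frequency $p_0 \sim U(0.05, 0.95)$ is drawn; each
region draws $p_r \sim \mathrm{Beta}(p_0 (1-F_R)/F_R,\,
(1-p_0)(1-F_R)/F_R)$; each population inside a region repeats the draw
around $p_r$ with drift $F_P$. Genotypes are Binomial(2, $p_k$) under
Hardy–Weinberg, with missing calls planted independently at 1%. The
per-locus total differentiation $F = F_R + (1 - F_R) F_P$ is stored in a
truth record alongside every frequency actually used.

Key parameter choices:

- **Base drift** `f_region = 0.08`, `f_pop = 0.04`, giving total
  differentiation near 0.117 before calibration — a regional-pairs design
  in which populations within a region are roughly half as diverged from
  each other as regions are.
- **Per-locus dispersion** (`locus_f_dispersion = 1`): per-locus drift is
  scaled by a shared lognormal multiplier with log-sd 1, spreading true
  per-locus F over roughly 0.03–0.5 around a 0.114 mean. Real SNP panels
  that mix neutral and high-divergence candidate markers show this kind of
  order-of-magnitude spread; it also makes per-locus differentiation
  identifiable, so estimated θ can be checked against the generator's
  truth. A frequency that fixes at 0 or 1 stays fixed downstream (the
  degenerate Beta limit).
- **Calibration**: `calibrate_to_mean_fst()` bisects a joint scale on both
  drift parameters until the realized mean per-locus θ (measured on a
  large calibration sample) hits a target, default 0.114.
- **The standard benchmark** (`paperlike_dataset()`): 12 populations in 6
  regional pairs, 110 polymorphic loci, sample sizes 61–93, ~1% missing,
  calibrated mean θ 0.114. Since assembled SNP panels contain only
  validated polymorphic markers, the benchmark simulates a surplus of loci
  and keeps the first 110 that are polymorphic in the sample.

What the generator does *not* emulate: linkage between loci (loci are
independent given the frequency hierarchy), isolation-by-distance beyond
the two-level hierarchy, ascertainment bias in allele-frequency spectra,
genotyping error, and non-equilibrium demography. Conclusions about
ranking-method behavior under those conditions are out of scope.

## Numerical choices

- **Log floor.** Genotype log-probabilities are clamped at −10^12 rather
  than −∞, so vectorized likelihood sums never produce 0 × (−∞) = NaN;
  exponentiating the floor underflows to exactly 0 where probabilities are
  reconstructed.
- **Tie tolerance.** Log-likelihood ties are declared within 10^−9, well
  above accumulated rounding at 110 loci but far below any real
  likelihood difference.
- **Smoothing constant.** The (x + 0.5)/(n + 1) rule is the posterior mean
  under a symmetric Jeffreys-like prior; it keeps every genotype possible
  in every population without materially distorting well-sampled
  frequencies.
- **Reduced benchmark scale.** The resampling rankers default to 200
  simulated individuals per population and 250 replicates. The package's
  own benchmark runs (tests, acceptance script) use 50 and 20 — chosen so
  backward elimination over 110 loci completes in tens of seconds — and
  treat Monte Carlo noise explicitly: order-stability checks require score
  differences to exceed three combined standard errors before treating a
  rank flip as an error.
- **Seeded everything.** Every stochastic step takes an explicit seed and
  restores the RNG state afterwards, so results are reproducible and
  independent of call order.

## Known discretionary decisions

Where the underlying methods leave room, the package chooses: PCA of
frequencies is centered but unscaled; simulated cohorts allocate
individuals evenly across populations (remainder to the first ones);
random panels draw independently per size rather than nesting; empirical
tie-breaks go to the first population in baseline order (a deterministic,
documented convention). Each of these is tested as documented behavior.

## A small worked example

```{r example, eval = FALSE}
dat <- paperlike_dataset()
study <- run_panel_study(dat$table, split_seed = 1,
                         ranker_config = ranker_config(sim_pop_size = 50,
                                                       iterations = 20),
                         seed = 1)
head(study$ranks)
study$evaluations$average_96
study$dropoff
```

(The chunk is not evaluated at build time; at the reduced ranker scale it
runs in well under a minute.)
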