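---
title: "Models and methods behind endoclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind endoclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoclone)
```

`endoclone` analyzes somatic mutations called in many individual glands of
normal endometrium (or comparable multi-sample normal-tissue designs). This
vignette explains the statistical models, the assumptions behind them, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The data model

The unit of observation is one somatic call in one gland: chromosome,
position, ref/alt, total and mutant-supporting read counts in the gland and
in matched blood, the reference-strand trinucleotide context, a coding
consequence, and a maximum population frequency. Glands carry a spatial grid
label and coverage summaries. Because a gland is (nearly) monoclonal, a
clonal heterozygous mutation sits at mutant allele frequency (MAF) ≈ 0.5;
the empirical MAF distribution is trimodal and `classify_maf()` encodes the
operational thresholds: subclonal < 0.25 ≤ clonal, and ≥ 0.75 for clonal
mutations with allelic imbalance. `binomial_imbalance_test()` is the exact
two-sided binomial test of MAF against 0.5 used to call imbalance.

Call-level filtering (`filter_somatic_calls()`) applies, in a fixed order
used for rejection attribution: variant-quality pass (the upstream caller's
empirical score exceeding −10·log₁₀(0.05) = 13.0103, modeled as a boolean
flag — callers are not re-implemented here), population frequency < 0.001,
depth ≥ 20, ≥ 8 mutant reads, MAF ≥ 0.25, and blood MAF ≤ 0.05. Target-panel
mode applies only the first two, the read-level criteria being the panel
caller's responsibility. Gland QC requires more than 70% of the target
covered at ≥ 20 reads.

CNMC — the cumulative number of menstrual cycles — is a clock covariate.
The exact construction varies between studies, so it is an explicit,
configurable model here: `cycles_per_year × (age − menarche_age) −
cycles_lost_per_parity × parity`, floored at zero, with defaults of 13
cycles/year (a ~28-day cycle) and 15 cycles suppressed per pregnancy
(gestation plus typical postpartum amenorrhea). Both parameters are
arguments of `compute_cnmc()`; conclusions that hinge on CNMC should be
checked against the study's own definition.

## Mutation burden and covariate association

Burden pools glands within a subject:
$$b_i = \frac{\sum_j n_{ij} \times 10^6}{\sum_j l_{ij}},$$
with \(n_{ij}\) the high-MAF SNV count and \(l_{ij}\) the bases callable at
≥ 20 reads in gland \(j\). Pooling numerators and denominators makes the
estimate invariant to how mutations are split among glands. Unadjusted
association with a covariate is the Pearson correlation (two-tailed test)
plus the OLS slope with its 95% CI. "Adjusted for age" is ambiguous between
a partial correlation and a multiple-regression coefficient; both are
informative, so `covariate_association(adjust_age = TRUE)` reports the
residual–residual (partial) correlation as `r` and the covariate
coefficient of `response ~ covariate + age` as the slope.

## Spectra and signature exposures

SNVs are classified into the 96 classes formed by the six pyrimidine-strand
substitutions and the 5′/3′ flanking bases; purine-reference records are
reverse-complemented at classification time (contexts are stored on the
reference strand). Exposure fitting maximizes the multinomial likelihood of
the observed spectrum under a mixture of reference signature columns,
constrained to the exposure simplex, via multiplicative EM-style updates
(monotone in the log-likelihood; tolerance 1e-8 on the log-likelihood,
maximum 10,000 iterations, uniform start). Uncertainty comes from a
multinomial bootstrap of the spectrum (default 1,000 replicates, 90%
percentile intervals), and a signature is called significantly active when
the interval's lower limit exceeds 0.01. A Bayesian treatment with HPD
intervals would be the natural alternative; the bootstrap-MLE route was
chosen to keep the fit fast, deterministic given a seed, and free of
posterior-sampling machinery, and it applies the same lower-bound
significance rule. With duplicate (or nearly collinear) signature columns
the split of their total exposure is not identifiable; the fit warns and
the sum remains meaningful.

## Trinucleotide-context Poisson dN/dS

Counts of missense, nonsense and synonymous SNVs in context class \(i\) are
modeled as
$$n_i^m \sim \mathrm{Pois}(t\, r_i\, L_i^m\, \omega^m),\quad
  n_i^n \sim \mathrm{Pois}(t\, r_i\, L_i^n\, \omega^n),\quad
  n_i^s \sim \mathrm{Pois}(t\, r_i\, L_i^s).$$

`count_site_opportunities()` enumerates \(L_i^j\) exactly: every CDS
position admits three substitutions, each translated and classified; the
counts conserve \(\sum L = 3 \times\) CDS length. Stop-loss substitutions
are counted as missense — they are rare, and a separate class would leave
many genes with empty cells. Relative rates \(r_i\) come from a large
noncoding SNV catalog divided by the available context opportunities and
normalized to mean one; whether such catalogs should additionally be
normalized by genomic trinucleotide abundance is not settled, so the
opportunity vector is an explicit argument (uniform by default) and the
overall scale is irrelevant because \(t\) is calibrated so that total
expected equals total observed counts. That calibration also makes the
\(\omega\) estimate invariant to any shared rescaling of the expectations.

With expected counts \(E\) in hand, the maximum-likelihood
\(\hat\omega = (n_{obs}/E_{obs})/(n_{syn}/E_{syn})\) under a shared-scale
Poisson model (the scale plays the role of a regression intercept; whether
the original regressions carried an intercept is unknowable from the text,
and the ratio-of-ratios form is invariant to it). The 95% CI is Wald on
\(\log\omega\) with variance \(1/n_{obs} + 1/n_{syn}\), switching to the
profile-likelihood interval when either count is below 5 (the Wald interval
is unreliable for small counts). The p-value is the likelihood-ratio test
of \(\omega = 1\) against the free model (χ², 1 df). When a gene has no
synonymous hits, \(\omega\) is undefined and dN and dS are reported
separately. Per-gene screening tests only genes with at least five high-MAF
coding SNVs and only classes whose observed count exceeds expectation, then
applies Benjamini–Hochberg FDR (threshold 0.1) within each class. The
driver fraction is \(f = (\omega - 1)/\omega\), floored at zero. Indels and
splice SNVs are outside the substitution framework and are excluded.

## Clonal structure, space and phylogeny

The MAF matrix compiles every mutation site against every gland of a
subject (absent = 0; sites with blood MAF > 0.05 excluded as germline).
Informative sites for clustering need MAF ≥ 0.25 in at least two glands;
glands at MAF ≥ 0.10 are marked as co-sharing supporters. Clustering is
agglomerative (average linkage, Euclidean distance — both arguments) on the
gland columns, but clusters are *called* by a defining-mutation rule rather
than a dendrogram height cut: descending from the root, a subtree becomes a
clone cluster when all its glands share at least `min_shared = 2` mutations
at MAF ≥ 0.25. This mirrors how such clusters are defined scientifically —
by identically shared clonal mutations — and removes the cut height as a
tuning parameter; linkage, metric and thresholds remain configurable.
Cluster footprints on the rectangular sampling lattice are tested for
4-neighborhood contiguity.

Within a cluster, mutations partition into public (present in all member
glands), partially shared, and private (exactly one gland), with presence
meaning MAF ≥ 0.25 by default (the clonal threshold; a lower presence
threshold can be passed when subclonal carriers matter). Phylogenies use
binary presence/absence profiles: pairwise Hamming distances, classic
neighbor joining (exact for additive matrices; negative branch lengths are
clamped to zero with a warning), and Fitch small-parsimony scores.

## CN-LOH detection and event timing

For copy-neutral LOH the allelic-imbalance signal is the absolute log odds
ratio of variant-allele counts between gland and blood at germline
heterozygous sites. The mean over sites outside known CNA regions is
subtracted (zero baseline) and a centered 100-site moving average is taken
per chromosome. The bundled segment caller — maximal runs of ≥ 100 sites
above a threshold of 0.2 — is deliberately simple tooling for synthetic
signals; production copy-number callers estimate the cellular fraction
\(\rho\), which is therefore an *input* everywhere it is needed downstream.

Timing assumes a constant per-lineage mutation rate from birth to sampling.
The most recent clonal expansion of a cluster is
$$T_{CE} = \mathrm{Age} \times \frac{MB_{pub}}{MB_{pub} + MB_{ps} + MB_{priv}},$$
computed from mutations outside CNA regions, with the binomial normal
approximation \(p \pm 1.96\sqrt{p(1-p)/m}\) scaled by age for the 95% CI
(clipped to \([0, \mathrm{Age}]\)). The sharing counts must come from the
*full* site-by-gland matrix: informative-site selection drops private
mutations and would bias \(T_{CE}\) upward.

A CN-LOH inside the cluster's history is timed from the public SNVs in the
affected region. A pre-event mutation is homozygous in affected cells
(per-read success probability \(\rho_i\) in gland \(i\)); a post-event
mutation sits on one of the two duplicated copies (\(\rho_i/2\)). The joint
binomial likelihoods across glands (log-space; the binomial coefficient
cancels) give per-SNV weights \(w^{pre}, w^{post}\). Because pre-event
mutations on the lost allele vanished, the pre count is doubled:
\(MB_{pre} = 2 \times\) pre-assigned SNVs. Over 10,000 resampling
iterations each SNV is assigned by Bernoulli(\(w^{pre}\)), and
$$T_{CNLOH} = T_{CE} \times \frac{MB_{pre}}{MB_{pre} + MB_{post}}$$
is computed per iteration together with a 95% CI that propagates both
proportions through the independent-product identity
\(V(XY) = V(X)V(Y) + E(X)^2V(Y) + E(Y)^2V(X)\); the reported estimate and
CI are the means over iterations (a percentile CI across iterations would
ignore the within-iteration binomial variances, so it is not the default).
All resampling is seeded and fully deterministic given the seed.

## The synthetic-cohort generator

`simulate_cohort()` emulates exactly the structure the analyses assume:
per-subject clone clusters occupying contiguous cells of a rectangular
grid (snake ordering, so consecutive cells are 4-adjacent), clock-like
accrual of cluster-lineage SNVs at `snvs_per_year` (default 8/year, giving
a few hundred mutations per mid-life cluster — WGS-scale counts restricted
to callable regions), a public fraction equal to the expansion-to-sampling
age ratio, partially shared mutations on contiguous gland blocks, private
and unrelated singleton-gland mutations, trinucleotide contexts drawn from
a signature mixture (half reported on the purine strand to exercise
pyrimidine collapsing), pure binomial read sampling at Poisson depth
(default mean 100), blood samples free of somatic variants, and arm-level
CN-LOH with a planted event age, per-gland \(\rho\), MAF \(\rho\) vs
\(\rho/2\) for pre/post mutations, and the factor-two thinning of pre-event
mutations that the timing estimator's doubling corrects.

Defaults were chosen once as realistic study conditions: ages spanning
25–50, menarche at 12, six glands per cluster, expansion at half the age,
30 callable Mb, depth 100. What the generator does **not** emulate —
sequencing error, mapping artifacts, overdispersed read counts (a
beta-binomial knob exists but defaults off so recovery oracles stay exact),
subclonal copy-number changes, gland polyclonality, or emergent clone
spatial dynamics (clusters are specified, not grown) — bounds what passing
recovery tests show about real data: they validate the estimators under
the stated model, not robustness to artifacts the model excludes.

## Numerical choices and degenerate inputs

- All likelihood products (CN-LOH weights, EM) run in log space; softmax
  normalization subtracts the max term.
- \(0 \log 0 = 0\) conventions are applied explicitly in binomial and
  Poisson log-likelihoods.
- EM mixture probabilities are floored at 1e-300 to avoid −Inf on classes
  with zero fitted mass.
- Ties/degeneracies: identical MAF columns cluster together trivially; an
  all-tied rank-sum comparison returns p = 1 by convention; a star-shaped
  distance matrix resolves with zero-length internal branches.
- Collinearity of a covariate with age (e.g. CNMC computed from age alone)
  is detected by a relative-variance threshold on the residuals and raises
  an error rather than returning a meaningless partial correlation.

## Problem sizes used by the test suite

The recovery tests run at sizes chosen to make their statistical criteria
sharp while keeping the suite quick: 200 replicate catalogs per \(\omega\)
value over a 20-gene / 1,200-bp-CDS target space for dN/dS recovery and
type-I error; 100 replicate single-subject cohorts (two 6-gland clusters,
depth 100) for timing coverage and CN-LOH bias; 50 random additive 4–8
taxon matrices for neighbor joining; exhaustive-oracle parsimony on 5-leaf
trees; 10⁴ mutations for signature exposure recovery; depth 60 for the
two-clone clustering benchmark.

## Known limitations

- The dN/dS model shares one \(r_i\) vector across genes; no per-gene
  covariate model of regional mutation-rate variation is attempted.
- CN-LOH timing assumes the event happened once, before the most recent
  clonal expansion, in a region with reliable \(\rho\); glands with
  differing \(\rho\) are handled through their per-gland likelihood terms,
  but subclonal events within single glands are not modeled.
- The normal-approximation CI for \(T_{CE}\) is anti-conservative for
  public fractions very close to 0 or 1 with few mutations.
- Exposure intervals are frequentist percentile intervals, not posterior
  HPDs; with strongly correlated signatures they can undercover for the
  individual components.
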