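---
title: "Methods: kinship-aware co-variation networks for pluripotent cell states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship-aware co-variation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices
behind them. It states no empirical numbers beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The problem

Bulk molecular profiles of human iPSC lines are mixtures over pluripotency
states, and the mixture proportions differ between lines. Across a cohort
that variation makes state-responsive genes co-vary and the regulatory
elements behind them co-accessible, so genome-wide co-variation networks
recover state biology — provided relatedness between donors is handled.
Family cohorts share genetic background, which inflates naive pairwise
correlations; the package therefore tests every feature pair under a
linear mixed model whose random effect has covariance proportional to the
kinship matrix.

## Pairwise mixed model

For each unordered feature pair, the response (the higher-index feature)
is regressed on the predictor plus nuisance covariates:

$$ y = C\gamma + \beta x + u + \epsilon, \qquad
   u \sim N(0, \sigma_g^2 K), \quad \epsilon \sim N(0, \sigma_e^2 I). $$

With the eigendecomposition $K = U D U^\top$, rotating all quantities by
$U^\top$ gives independent observations with variance
$\sigma_g^2 (d_i + \delta)$ where $\delta = \sigma_e^2/\sigma_g^2$, so the
ML likelihood profiles down to a one-dimensional search in $\delta$ and
every fit at fixed $\delta$ is a weighted least squares. Numerical
choices:

* $\delta$ is optimized on the natural-log scale over $[e^{-10}, e^{10}]$
  with Brent's method (tolerance $10^{-6}$), with the interval endpoints
  checked explicitly so boundary optima (no genetic variance, or no
  residual variance) are not missed.
* ML rather than REML, and Wald $z = \beta/\mathrm{se}$ rather than a
  likelihood-ratio test — matching the z-based inference of standard
  kinship-LMM software. The residual scale uses $n - p$ degrees of
  freedom, which makes the fast path agree exactly with a textbook GLS
  (and with OLS when $K = I$).
* `mode = "per_response"` (default) estimates $\delta$ once per response
  from the covariates-only null model and reuses it for all predictors —
  the standard plug-in approximation that makes $O(p^2)$ scans tractable.
  `mode = "exact"` re-optimizes per pair and exists mainly for oracle
  comparisons; on null data the two agree closely.
* p-values are floored at $10^{-300}$ to keep downstream `log10` finite.
* With $K = I$ the two variance components are not identifiable
  individually; their sum equals the ML residual variance, which is the
  contract the estimator guarantees.

The independent oracle is `glsOracle`: explicit whitening by the Cholesky
factor of an arbitrary covariance. The test suite drives both paths over
random instances at shared $\delta$ and requires $|\beta|$ agreement to
$10^{-6}$.

Multiple testing follows the two analysis dialects: gene co-expression
edges use Bonferroni-adjusted p < 0.05, peak co-accessibility edges use a
fixed raw threshold of $5\times10^{-8}$; both require $\beta > 0$, so only
positive co-variation becomes an edge.

## Modules

Leiden community detection with the modularity objective is used because
the study design reports modularity Q alongside resolutions well above 1.
The sweep records, per parameter combination, Q, the fraction of nodes in
major modules, the module count and a permutation p, and then selects the
combination maximizing the major-module fraction among those with
permutation p < 0.05 and Q at least `q_min` (default 0.3), breaking ties
by higher Q then smaller resolution. This codifies as a lexicographic
rule what is otherwise a by-eye choice of "decent modularity, high
fraction captured".

The permutation null permutes node-to-module labels uniformly while
preserving module sizes and compares the observed count of intra-module
edges; this directly tests the claim that the partition groups co-varying
features better than chance, and is far cheaper than degree-preserving
rewiring with a re-run of Leiden per replicate (the alternative reading;
not implemented). Its p-value is bounded below by $1/(n_{perm}+1)$.

Major modules use a size rule (genes: > 100 members; peaks: ≥ 500 —
both are arguments). Each node's intramodular degree counts only edges
internal to its module; the Pareto set of a module is its top
$\lceil 0.2\,|m|\rceil$ members by intramodular degree (ties: global
degree, then ID), and a sample's module score is the sum of its
inverse-normal values over the Pareto set.

For the module-pair co-membership heatmap, the 2×2 cell for modules
(A, B) contrasts the edge density of the A–B node-pair block (within-A
pairs on the diagonal) against the density over all remaining node pairs.
The alternative reading — within-A edges versus A–B edges in one table —
makes every off-diagonal cell of a well-partitioned graph look enriched,
contradicting the expected depleted off-diagonal, so the block-vs-rest
construction is used.

## Preprocessing

Counts are TMM-normalized (delegated to `edgeR::calcNormFactors`, whose
reference-sample and double-trimming rules match the definition stated in
the documentation; a feature-by-feature reimplementation of the trimmed
weighted mean serves as the test oracle), filtered by the "at least
`min_value` in at least 20% of samples" rule with a `ceiling` count, and
mapped feature-wise to normal quantiles $\Phi^{-1}((r-0.5)/n)$ with
average ranks for ties. The rank-based transform is used in place of the
quantile-normalize-then-qnorm chain: both deliver the stated contract
(per-feature mean 0, sd 1) and the rank form has no dialect ambiguity. It
is idempotent on tie-free data.

## Deconvolution

Signature matrices take the top half of features per direction by Welch t
on $\log_2(x+1)$ — "most differential" is the only contract, so the
t ranking stands in for a negative-binomial Wald ranking without changing
the selected set materially. Mixing fractions come from nonnegative least
squares on the two signature columns with sum-to-one renormalization;
with exactly two states the estimand is a single mixing fraction, where
constrained least squares and support-vector regression variants coincide
on clean data (the ν-SVR variant is an explicit non-goal). Features
missing from a sample are dropped (with a floor of 50% signature
coverage), never imputed.

## Interval annotation

Coordinates are BED 0-based half-open on disk and `GRanges` 1-based in
memory; a narrowPeak summit is `start + summit_offset`. Target genes are
the closest TSS within 100 kb (distance 0 inside the peak, else gap
length; the 100,000 bp boundary is inclusive), ties resolved by highest
reference expression then gene ID. Chromatin states are resolved at the
summit and collapsed 12→5 (active promoters stay; TssAFlnk joins the
enhancers; TxFlnk joins transcription; bivalent and polycomb states merge
within their groups); summits in gaps or in ZNF/repeat, heterochromatin
or quiescent states are unassigned. Reciprocal overlap is inclusive at
the threshold on both intervals. Reference-peak selection bins exclusion-
filtered peaks into equal-count score quantiles, spreading any remainder
over the top bins (ties broken by coordinate) and keeping bins 8–20 by
default.

TF-group collapsing clusters motifs by the Euclidean distance between
rows of their bound-site Jaccard similarity matrix (average linkage). The
tree is cut at an absolute height of 0.75: rows of unrelated motifs
differ in their own diagonal entries, putting them at distance about
$\sqrt{2}$ independent of the motif count, so an absolute 0.75 separates
unrelated motifs while merging near-clones. A cut relative to the maximum
merge height (`relative = TRUE`) is also available, but it merges
unrelated motifs whenever the tallest merge exceeds the unrelated-motif
distance, which contradicts the intended clone-collapsing behaviour.

## Exact tests

`fisher2x2` reports the hypergeometric exact p (two-sided: summing table
probabilities no larger than the observed one) and the *sample* odds
ratio $(ad)/(bc)$ with the Haldane 0.5 correction when a cell is zero —
chosen over the conditional-MLE OR so that heatmap effect sizes are the
familiar ratio; the p-value is unaffected. Displayed $\log_2$ OR clipping
(±3.5) is a plotting concern; stored values are unclipped. The binomial
imbalance test uses the minlike two-sided convention (the standard exact
binomial test), with a doubled one-sided variant behind a flag. The
Hardy-Weinberg test is the conditional exact test given allele counts.
The Mann-Whitney comparisons are one-sided (greater), exact for combined
n ≤ 30 without ties, otherwise the tie-corrected normal approximation
without continuity correction. All four are validated bit-for-bit against
full-enumeration oracles for totals ≤ 60.

ASCA thresholds ("minimum of 5 heterozygous individuals", "at least 50
reads", "at least 10 per allele") are inclusive; the MAF filter defaults
to inclusive (≥ 0.05) with a strict option, reflecting the two readings
of the filter description. The allelic imbalance fraction is defined as
$\max(\mathrm{ref},\mathrm{alt})/(\mathrm{ref}+\mathrm{alt})$ — no formula
is stated in the source analyses; this symmetric form lies in [0.5, 1]
and equals 0.5 exactly when the test's p-value is 1.

## The synthetic cohort generator

The generator defines the study conditions for every test; its defaults
are fixed once:

* **Cohort**: 150 samples in 30 families of 5 (the scale of the ATAC
  cohort: ~150 samples, tens of families), kinship from expected pedigree
  coefficients (1 self, 0.5 within family, 0 otherwise) — same covariance
  structure as a genotype-derived matrix without needing genotypes.
* **Latent state**: per-sample formative fraction $s \sim Beta(2, 5)$
  (most lines low, a tail of high-formative lines, matching a
  deconvolution view where most samples carry a minority formative
  subpopulation).
* **Features**: 600 features in 3 planted modules of 200. Module 1 loads
  $+\lambda$ on the standardized latent state, module 2 $-\lambda$
  (yielding the positively and negatively state-associated modules seen
  in score-vs-proportion fits), and further modules get independent
  standard-normal factors with the same loading. A literal
  "$\lambda_m s$ for every module" cannot produce more than two separable
  modules — all state-loaded modules would be mutually correlated and
  merge under community detection — hence the independent factors.
* **Noise**: per-feature genetic effect $g \sim N(0, \sigma_g^2 K)$
  (default $\sigma_g^2 = 0.2$), residual log-scale noise
  $\sigma_e^2 = 0.25$, lognormal(0, 0.3) per-sample depth multipliers,
  Poisson counts. Default loading $\lambda = 1.5$.
* **Alleles**: per-SNP heterozygosity 0.4 across 20 individuals, Poisson
  per-individual depth (default mean 12, i.e. roughly 100 aggregated
  reads per SNP), binomial allele splits at 0.5 or at `pi_alt` = 0.7 for
  the planted imbalanced fraction.

What the generator does *not* emulate: per-sample batch structure,
within-line replicate correlation (replicate libraries are treated as
independent samples, as no replicate-variance estimate is available),
peak-length effects, GC or mappability bias, linkage between SNPs, and
reference-mapping bias in allele counts. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
generative structure, not robustness to those real-data artifacts.

One property deliberately asserted after normalization: with the state
effect and kinship variance set to zero, features are exchangeable *given
depth* — raw counts still share the depth multiplier, so the
exchangeability check (pairwise correlations centered at zero) is made on
TMM-normalized values.

## Calibration and recovery conditions used by tests and the acceptance script

* Mixed-model type-I error under the null generator and binomial-test
  type-I error at $\pi = 0.5$ are required to sit within three binomial
  standard errors of 0.05 (about 2,000 tests each).
* The full pipeline on the default cohort must recover the planted
  modules with adjusted Rand index ≥ 0.9, the state-loaded module's score
  must correlate with the true latent state at r ≥ 0.8, and two-state
  deconvolution at 10% noise must reach a mean absolute error < 0.05.
* Variance-ratio recovery: with $\sigma_g^2 = \sigma_e^2 = 1$ on
  family-block kinship the ML estimate of $\delta$ is median-unbiased at
  n = 200, but its sampling spread leaves roughly a fifth of seeds
  outside [0.5, 2] at that size; coverage tightens at n = 500 and the
  tests assert exactly that pattern rather than a tighter bound the
  estimator cannot attain at n = 200.
* Problem sizes (600 features, 199 permutations, 2,000 null tests, 100
  oracle instances) were chosen to make the whole suite run in well under
  a minute of compute per stage while leaving the statistical assertions
  comfortably powered.

## Known limitations

* The per-response plug-in $\delta$ is an approximation; pairs whose
  predictor explains a large share of variance can shift the optimal
  $\delta$, though the Wald screen is insensitive to this at the effect
  sizes that matter here.
* Orientation of a pair (which feature is the response) is fixed by
  column order; the mixed model is not symmetric in the two roles, but
  orientation effects are second-order for screening and halving the
  test count dominates.
* The deconvolution supports exactly two states; multi-state mixtures and
  batch correction are out of scope.
* `intervalFisherBP` treats base pairs as exchangeable units, as the
  bedtools test does; correlated neighbouring bases make its p-values
  anti-conservative, so it is an effect-size screen more than a
  calibrated test.
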