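# statenet

Kinship-aware co-expression and co-accessibility network analysis for
cohorts of pluripotent stem cell lines.

Human iPSC lines grown under conventional conditions are mixtures of
interconvertible pluripotency states (formative and primed). Across a
cohort of lines, the varying mixture proportions induce coordinated
variation: genes in the same pathway co-vary in bulk RNA-seq, and the
regulatory elements driving them co-vary in bulk ATAC-seq. `statenet`
turns that observation into a pipeline for cohorts of *related* donors,
where family structure would otherwise produce spurious co-variation:

1. **Pairwise mixed-model association.** For features *j*, *k* measured in
   sample *i*,

   Y<sub>ij</sub> = β<sub>k</sub> Y<sub>ik</sub> + Σ<sub>m</sub> γ<sub>m</sub> PC<sub>im</sub> + Σ<sub>p</sub> γ<sub>p</sub> C<sub>ip</sub> + u<sub>i</sub> + ε<sub>ik</sub>,&emsp;u ~ N(0, σ<sub>g</sub>² K), ε ~ N(0, σ<sub>e</sub>² I),

   with K a kinship matrix. Fits use the spectral trick: rotating by the
   eigenvectors of K diagonalizes the covariance, so the ML profile over
   δ = σ<sub>e</sub>²/σ<sub>g</sub>² is one-dimensional and each pair is a
   weighted regression (an explicit GLS oracle backs the fast path in
   tests). Edges are Wald tests of β<sub>k</sub>.
2. **Network modules.** Significant positive associations become edges;
   Leiden community detection (modularity objective) is swept over
   resolution, refinement randomness and iterations, validated against a
   size-preserving label-permutation null, and each module is summarized
   by its Pareto members (top 20% by intramodular degree) and per-sample
   module scores.
3. **Cell-state deconvolution.** Two-state signature matrices built from
   replicate reference profiles (Welch-t ranked, balanced directions) and
   nonnegative least-squares mixing-fraction estimates.
4. **Epigenomic annotation.** Peak-to-target-gene assignment (closest TSS
   within 100 kb, expression tie-break), chromatin-state collapsing at the
   peak summit (12 states to 5), 25% reciprocal overlap, MACS2-score
   quantile reference-peak selection, TF-group collapsing from predicted
   bound-site overlap, and bedtools-fisher style base-pair enrichment.
5. **Allele-specific chromatin accessibility (ASCA).** MAF/exact-HWE SNP
   filters, aggregation of allele read counts over heterozygous
   individuals, exact two-sided binomial tests at p = 0.5 with BH
   correction, allelic-imbalance-fraction (AIF) comparisons between
   modules or TF groups (one-sided Mann-Whitney U), and TFBS enrichment.
6. **Synthetic cohorts.** A generator that plants family-block kinship, a
   latent per-sample formative fraction loading on feature modules,
   lognormal library sizes and binomially sampled allele counts, so the
   whole pipeline is testable end to end without any cohort download.

## Worked example

```r
library(statenet)

sc  <- simulateCohort(cohortConfig(seed = 11))   # 150 samples, 600 features
inm <- inverseNormal(filterExpressed(tmmNormalize(cohortCounts(sc))))
pa  <- pairwiseAssociation(inm, cohortCovariates(sc), cohortKinship(sc))
g   <- buildNetwork(pa, "bonferroni_0.05", nodes = colnames(inm))
sw  <- sweepAndSelect(g, resolution_grid = c(0.5, 1, 2.25),
                      beta_grid = c(0.01, 0.05), iter_grid = 10,
                      n_perm = 199, seed = 5, major_min = 50,
                      major_op = ">=")
sw$partition
#> ModulePartition: 600 nodes in 3 modules (Q = 0.667)
#>   major modules: 3 | Pareto sets computed

scores <- moduleScore(inm, sw$partition)
round(cor(scores, latentState(sc)), 3)
#>     [,1]
#> 1  0.944
#> 2 -0.948
#> 3 -0.360
```

The run takes a few seconds. The three detected modules are exactly the
three planted ones (adjusted Rand index 1 against the generator's truth);
the first module's score tracks the true latent formative fraction
(r = 0.94), the anti-loaded module mirrors it (r = -0.95), and the
state-independent module is weakly related. `scoreProportionAssociation`
then attaches slopes and p-values, and the ASCA layer
(`snpFilter` → `aggregateAlleleCounts` → `binomialASCA` →
`groupAIFTest`) handles the allele-count side.

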