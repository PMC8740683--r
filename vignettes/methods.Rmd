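---
title: "Regulatory-network interpretation of noncoding and coding variants: models and design"
author: "ReVarNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory-network interpretation of noncoding and coding variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReVarNet)
```

# Overview

ReVarNet links four analyses around one object, the regulatory-element /
target-gene network (`RETGNetwork`): building the network from chromatin
loops and accessibility peaks, testing GWAS enrichment of the network,
detecting REs whose predicted openness differs between cases and controls
from personal genomes, and combining noncoding and coding evidence at the
gene-set level. This vignette records the models, their assumptions, the
tunable parameters, and the design decisions that were genuinely open.

# The regulatory network

Loop calls arrive as BEDPE with an FDR q-value per loop; only loops with
q < 0.01 (`qThreshold`) enter the network, mirroring standard loop-caller
output. Each anchor is tiled into consecutive 1-kb windows (`tileWidth`)
from its 5' end, the last tile truncated so tiles exactly cover the anchor
— truncation rather than extension or deletion conserves anchor coverage,
which the tiling property tests assert. A tile is *open* when it overlaps
at least one ATAC peak by ≥ 1 bp; no minimum overlap is imposed because
peak and tile widths are on the same scale and a stricter rule would make
openness depend on arbitrary peak trimming.

Promoters are the 2 kb (`upstream`) immediately 5' of the TSS, strand
aware, clipped at the chromosome start. A loop links a gene when either
anchor overlaps the gene's promoter by any amount; the opposite anchor's
tiles become that gene's REs. Genes with at least one open linked anchor
tile are OpenLoop; with linked tiles but none open, NonOpenLoop; otherwise
NoLoop. A gene with both open and nonopen REs is OpenLoop (any-open wins):
the category asks whether *any* accessible regulatory input exists.
Promoter REs participate in openness scoring but never in categorization,
which is defined by loop linkage alone.

Coordinates: all interval files are 0-based half-open on disk (BED
convention) and converted to 1-based closed `GRanges` in memory, the
native convention of the Bioconductor stack this package is built on.
Readers and writers perform the conversion, so no other code needs to
know about it.

The silencer comparison uses a two-sided Fisher exact test computed by
point-probability summation (the `stats::fisher.test` definition); the
sidedness was not fixed upstream, and two-sided is the neutral choice for
comparing two networks in either direction.

# GWAS network enrichment

Per SNP j the effect prior is a spike and slab,

$$\beta_j \sim \pi_j\,N(0, \sigma_j^2) + (1-\pi_j)\,\delta_0,
\qquad \pi_j = \theta_0 + a_j\theta,
\qquad \sigma_j^2 = \sigma_0^2 + a_j\sigma^2,$$

with $a_j = 1$ when SNP j lies within a closed ±50 kb window of any
network RE or target-gene body (the boundary is closed because "within"
is naturally inclusive; one test pins the boundary at exactly 50 kb).
The "network" here is its loop-linked part: target genes reached through
loops and the REs attached to them — a gene whose only RE is its own
promoter is not network evidence, and including all promoters would make
every annotation resemble the near-gene control. θ₀ and θ live directly
on the probability scale, matching the prior's formula literally; grids
are validated so every π_j ∈ (0, 1).

The likelihood is the standard summary-statistics regression form
$\hat\beta \mid \beta \sim N(SRS^{-1}\beta,\; SRS)$ with S the diagonal
of standard errors and R the LD correlation matrix (regularized by adding
1e-6 to the diagonal when not positive definite). The posterior is
approximated per grid point by mean-field coordinate-ascent variational
inference with a spike-and-slab variational family; the converged
evidence lower bound (ELBO) serves as the approximate log marginal
likelihood. Coordinates are updated in descending |β̂_j/s_j| order, fixed
for determinism; convergence is a relative ELBO change below 1e-7 with a
1,000-sweep cap; non-converged points are flagged and excluded from model
averaging with a warning. The inner loop is compiled (Rcpp) because
coordinate ascent is inherently sequential. Correctness anchors: for a
single SNP the family contains the true posterior, so the ELBO equals the
closed-form mixture marginal; under identity LD the mean-field bound is
exact; under AR(1) LD the gap to exact 2^p enumeration
(`exactBFOracle`, p ≤ 12) stays well below 0.1 nat on the tested
instances, and the bound never exceeds the exact value.

Model-level marginal likelihoods average `exp(logML)` uniformly over the
grid points each model allows (M0: θ = 0, σ² = 0; M11: θ > 0, σ² = 0;
M12: θ > 0, σ² > 0; M1: θ > 0 or σ² > 0); uniform weights are the neutral
choice where no averaging rule was fixed. Bayes factors are ratios of
these averages, computed in log space. Note the average builds in an
Occam penalty: under a null dataset BF(M11:M0) sits below 1 by an amount
that grows with the span of the θ grid, so null-behavior checks use a θ
axis emphasizing small enrichments, as the default grid does
(θ ∈ {0, 1e-3, 1e-2, 0.05}).

# Differential openness

The openness scorer is a contract: a deterministic function from (RE,
set of carried alternate alleles inside the RE) to a real score. The
packaged `LinearScorer` — base level per RE plus additive per-variant
weights — stands in for a trained sequence-to-accessibility model while
honouring the same interface; `scoreCohort` dispatches through the
`scoreRE` generic, with a sparse-matrix fast path for the linear case. An
individual *carries* a variant at dosage ≥ 1; no phasing is attempted
because the predictor consumes one personal sequence per individual.
Missing genotypes impute to the baseline allele and are counted.

The baseline genome carries the cohort major allele at every site
(alternate included homozygously when its frequency exceeds 0.5; the
reference allele at an exact 0.5 tie, so the baseline is stable under
resampling); a reference-genome baseline (empty variant set) is the mode
used with external control panels. An individual is *nonbaseline* at an
RE when its score differs from the baseline score by more than 1e-9 —
with additive weights that are sums of exactly representable values the
flag is effectively exact.

Per RE, the one-sided Fisher exact test (computed as a vectorized
hypergeometric tail, identical to `fisher.test(alternative = "greater")`)
asks whether nonbaseline individuals are enriched among cases; the
two-sided Wilcoxon rank-sum test (normal approximation with continuity
correction — scores tie by construction, making the exact null
unavailable) compares openness among nonbaseline cases vs nonbaseline
controls only, following the source procedure literally. Fisher's method
combines the two (χ²₄). When no individual is nonbaseline the RE is
reported with p = 1 and flagged `skipped`; when only one group has
nonbaseline individuals the rank-sum side is undefined and the combined
p falls back to the exact-test p alone (χ²₂ of one component), flagged
`fisher_only`.

Per gene, the k = 5 linked REs with the smallest combined p ("highest
differential open scores" read as −log p, the only monotone reading that
needs no extra definition) are combined with χ²_{2m}; skipped REs never
contribute, genes with no tested RE are omitted, and Benjamini–Hochberg
runs across the tested genes of one cell type at a time.

`augmentControls` replaces the original controls with n = 500 external
samples drawn to match the case cohort's sex ratio by largest-remainder
apportionment, deterministically per seed, and removes variants carried
only by external samples; cohort variants missing from the external call
set get dosage 0 there.

# Coding burden and gene sets

Per-SNV deleteriousness is the mean of up to three predictor scores in
[0, 1]; missing predictors are averaged over, and SNVs with no score are
dropped with a count. Rare means cohort allele frequency < 0.01
(configurable; "rare" had no number upstream). The burden of gene i in
sample m sums the scores of carried rare nonsynonymous SNVs; dosage 2
counts once under the carrier model (the formula sums per SNV), with a
`dosageWeighted` switch. The per-gene test is a one-tailed Welch t test
(case mean higher); Welch because burden variances differ between groups
by construction, and genes with zero variance in both groups report
p = 1.

At the gene-set level the coding side uses an upper Poisson tail:
λ = |term| × rate, where rate is the fraction of scored genes with
burden p ≤ 0.05 (threshold configurable, universe defaulting to the
scored genes — the neutral reading where the expectation's universe was
unspecified). The noncoding side is an internal upper hypergeometric
tail over the significant target genes, with fold enrichment
(overlap/|targets|)/(|term|/|universe|) — an in-package replacement for
an external web enrichment service, preserving the statistic's role
without a network dependency. The two sides combine with Fisher's method
(χ²₄) and are FDR-ranked. GMT sets are used flat; no ontology
propagation (synthetic sets have no hierarchy).

# The synthetic data generator

Every generator is a pure function of (config, stage name): the global
seed fans out to per-stage streams via a documented hash, so each stage
regenerates independently and byte-identically.

The defaults are the study conditions of the motivating design: 268
cases and 133 controls; a four-chromosome toy genome with ~300 genes;
5-kb loop anchors on a fixed 5-kb genomic grid (as loop callers bin the
genome — this also means anchors from different loops either coincide or
are disjoint, never partially overlapping near-duplicates, which would
create spuriously correlated REs); about 70% of genes loopable with at
most two loops each, keeping per-gene RE multiplicity realistic; 10% of
loop q-values above 0.01 to exercise the filter; anchor-level openness
(an anchor is open with probability `fraction_open` = 0.6 and its tiles
with probability 0.7 within open anchors), since accessibility is
regional; OpenLoop genes drawn from a higher log-normal FPKM than the
other categories.

Variant effects on openness are sparse: only `re_weight_frac` = 30% of
anchor REs carry weighted variants (2–3 each, weights on a 1/16 grid so
scores are exactly representable), the rest carry inert variants — most
individuals equal the baseline genome-wide. The 20 planted REs carry one
variant each with weight 0.7, at carrier frequency 0.15 in cases vs 0.03
in controls, grouped two REs per target gene: a disease gene is
typically perturbed through several of its REs, which is exactly what
the top-k combination aggregates, and a single planted RE leaves the
one-sided exact test underpowered for reliable q < 0.01 recovery at
these cohort sizes. Allele frequencies follow Beta(0.5, 5) truncated to
[0.001, 0.5] with Hardy–Weinberg genotypes. Planted burden genes receive
eight case-private rare SNVs at 2% carrier frequency among cases — low
enough that their cohort allele frequency stays under the 1% rare
threshold. One GO term is seeded with the planted target and burden
genes. GWAS summary statistics are generated under the enrichment prior
itself (θ₀ = 0.01, θ = 0.1, σ₀² = 9/n with n = 20,000, p = 500 SNPs,
block AR(1) LD with ρ = 0.3) so hyperparameter recovery is testable.

What the generator does not emulate: realistic LD from reference panels,
mutation spectra, sequence context inside REs, population structure, or
relatedness. Passing tests therefore demonstrate the statistical
machinery and its calibration under the generating model, not
performance on real cohorts.

# Calibration, problem sizes, and known limitations

The null-calibration analysis uses 200 cases / 100 controls with 2,000
anchor REs (all weighted, so every RE is actually tested) over 10 seeds;
planted-recovery and Bayes-factor analyses use the default configuration
over 10 seeds; oracle comparisons use p ≤ 10 SNPs where 2^p enumeration
is exact. These sizes keep every check to desk scale while leaving the
statistics interpretable.

One calibration property deserves emphasis: the RE-level combined
p-value is *not* uniform under the null, and cannot be at these sample
sizes. Its exact-test component is discrete — a valid one-sided exact p
satisfies P(p ≤ t) ≤ t with equality only at the atoms of the
hypergeometric support, whose spacing is governed by a count standard
deviation of ~4 at 300 individuals regardless of carrier rates. The
pooled null distribution is therefore visibly sub-uniform (KS D ≈
0.05–0.08 over thousands of REs), i.e. conservative: the fraction of
null REs with p < 0.05 sits slightly below 0.05, and gene-level BH false
positives are correspondingly rare. A distribution-level uniformity test
rejects this by design; the direction of the deviation is protective.

The top-5 gene combination treats selected RE p-values as independent
χ² components after selection, which is anti-conservative for genes with
many tested REs; at realistic multiplicities (≤ ~11 REs per gene) the
exact-test conservatism more than offsets it, but hub promoters in real
data would warrant a permutation calibration. Other limitations: the
linear scorer cannot represent epistasis between variants in an RE or
TF-expression effects; the enrichment model assumes the LD matrix is the
one that generated the summary statistics; and Bayes factors depend on
the hyperparameter grid, so grids must be reported alongside them.
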