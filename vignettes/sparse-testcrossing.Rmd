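---
title: "Simulating sparse testcrossing for genomic prediction of combining ability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sparse testcrossing for genomic prediction of combining ability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hybrid maize breeding improves two closed heterotic pools by reciprocal
recurrent selection on general combining ability (GCA): a line's mean hybrid
performance over the complementary pool. Early-stage testing usually crosses
every candidate line to a *single* common tester, which is logistically
simple but samples only one genotype's worth of the opposite pool — under
dominance, much of what the testcross phenotype measures is specific
combining ability (SCA) with that one tester. *Sparse testcrossing* keeps
the budget of one testcross per candidate but distributes candidates over
`k` testers and relies on genomic relationships to tie the testcrosses
together, so marker effects (haplotypes) are evaluated against a broader
sample of the opposite pool.

`sparsecross` is a stochastic simulator of this system: founder genomes with
linkage disequilibrium, a quantitative trait with directional dominance,
doubled-haploid (DH) line development, the testcross designs, the
marker-effect models, and the two evaluation protocols (GCA prediction
accuracy on a common baseline program, and realized hybrid genetic gain over
15 cycles of selection).

## Genetic model

A single quantitative trait is controlled by `Q` biallelic QTN. Per locus
with additive effect $a_i$ and dominance effect $d_i$, genotypes aa/Aa/AA
contribute $-a_i$, $d_i$, $+a_i$; values are summed over loci (no
epistasis). Raw $a_i$ are standard normal; dominance degrees
$\delta_i \sim N(\mu_\delta, 0.2)$ give $d_i = \delta_i |a_i|$, so
$\mu_\delta \in \{0.1, 0.5, 0.9\}$ produces directional dominance with 2%,
13% and 41% of loci overdominant ($\delta_i > 1$; closed form
$1-\Phi((1-\mu_\delta)/\sqrt{0.2})$). The $a_i$ are rescaled once so the
founder additive genetic variance — by default the genic variance
$\sum_i 2 p_i q_i \alpha_i^2$ with average effects
$\alpha_i = a_i + d_i(q_i - p_i)$; the empirical variance of founder
breeding values is available as an alternative basis — equals
$\sigma^2_A = 20$. Because $\alpha_i$ is linear in the common scale factor,
the rescaling is exact.

True GCA of a homozygous line is its mean hybrid value over the opposite
pool's lines; since the hybrid value is per-locus linear in the partner
allele, it reduces exactly to a marginalisation over opposite-pool allele
frequencies. The mean of the full factorial between two pools, used to
measure genetic gain, has the same per-locus closed form. SCA variance is
defined as hybrid-value variance minus the two pools' summed GCA variances
(population variances, so the decomposition is exact and SCA variance is
identically zero under pure additivity). Pool divergence is tracked by
Nei's minimum distance $\frac{1}{n}\sum_i (p_i^f - p_i^m)^2$ over
union-polymorphic QTN, mid-parent heterosis $\sum_i d_i (p_i^f - p_i^m)^2$
(the Hardy–Weinberg mid-parent convention), and the fractions of QTN fixed
for the same or opposite alleles.

## Founder genomes and what the generator does (and does not) emulate

Each of 10 chromosomes is 2×10⁸ bp / 200 cM (uniform map, 1 cM = 10⁶ bp);
only a down-sampled grid of sites is tracked, since physical positions
matter solely through the genetic map. Founder LD is generated by a
forward-in-time Wright–Fisher burn-in at `Ne = 100` diploids with
Poisson-crossover meiosis (no interference, Haldane model), per-site
mutation at 1.25×10⁻⁸, and initial allele frequencies drawn from a
truncated neutral spectrum ∝ 1/(pq), i.e. standing variation inherited from
a large ancestral population. Eighty founders are drawn per chromosome
independently, and only sites segregating among them are kept.

Two properties guided the defaults. First, the frequency spectrum of sites
*conditional on still segregating* is quasi-stationary — nearly uniform,
with E[pq] ≈ 1/6 — after roughly `Ne` generations, for either initial
spectrum; burn-ins much longer than that only lose sites to fixation
(survival drops from ≈21% at 200 generations to ≤9% at 500) while the
short-range LD they add saturates. The default burn-in is therefore
2·`Ne` = 200 generations, with a 10× site oversampling margin. Second,
because all sites on a chromosome share one genealogy, the surviving-site
count fluctuates between seeds far more than a binomial would; the pipeline
retries the founder draw with derived seeds when a chromosome falls short.

The generator emulates: distance-dependent LD (adjacent-site r² well above
long-range r²), a realistic U-shaped-to-uniform allele-frequency spectrum,
family structure from three rounds of half-diallel crossing with 20 DH
lines per cross and random parent recycling, and drift-induced divergence
of the two pools. It does *not* emulate the exact coalescent history of
maize (domestication bottleneck, admixture, recombination hotspots), sequence-level
realism, multi-allelic loci, epistasis, or genotype-by-environment
interaction. Consequences visible in the results are discussed under
*Fidelity limits* below.

## Breeding scheme

Founders are inbred (one haplotype per chromosome doubled), split 40/40
into female and male pools, and each pool passes through three rounds of:
60 half-diallel crosses among 40 parents (every parent used at least once),
20 DH lines per cross (one meiosis, gamete doubled), 40 random lines as the
next parents. This yields two 1,200-line pools with family structure and
appreciable between-pool drift.

Each selection cycle then: generates 1,200 new DH lines per pool the same
way; draws `k` testers at random from the *opposite* pool's current lines;
partitions lines uniformly into `k` equal subsets, one per tester (1,200/k
crosses per tester — the designs use k ∈ {1, 2, 3, 4, 5, 10, 20, 50, 100,
600, 1200}, plus an incomplete-factorial comparator that randomly pairs the
two pools one-to-one); simulates testcross phenotypes by adding
N(0, σ²ₑ) noise to hybrid genetic values, with σ²ₑ calibrated once at the
first cycle so broad-sense heritability is 0.3 among all 40×40 = 1,600
parental hybrids and frozen thereafter; predicts GCA from markers; and
keeps the top 40 lines per pool as new parents.

## Marker-effect models

With a single tester, SCA cannot be separated from GCA and the *testcross
model* is used: $y = 1\mu + Z\alpha + e$ with lines coded 0/2 at 1,000 SNP
markers (QTN are never visible to the models) and i.i.d. normal marker
effects. The variance ratio is estimated by exact single-component REML via
the spectral decomposition of $ZZ^\top$ (a one-dimensional profiled
likelihood), and effects are the ridge BLUPs; observation-space and
marker-space solutions agree to numerical precision.

With k ≥ 2 testers the *pool-specific additive + dominance model* is used:

$$y = 1\mu + Z_1 a_1 + Z_2 a_2 + W 1 \mu_d + W d^* + e,$$

with line and tester alleles coded 0/1, `W` the hybrid heterozygosity
incidence (1 exactly where line and tester alleles differ), $\mu_d$ a fixed
mean dominance effect carried by the heterozygous-locus count, and
$a_1, a_2, d^*$ independent i.i.d. random marker-effect vectors. The three
variance components plus the residual are estimated by average-information
REML with step-halving against the restricted likelihood and an EM fallback
(cap 200 iterations, relative tolerance 10⁻⁶). Components pinned at the
zero boundary with downhill gradients are held fixed within an iteration —
without this the joint AI step is poisoned and the fit degenerates into
slow EM crawling. With a constant tester column the corresponding BLUP is
exactly zero (the projected covariance vanishes), so a single-tester input
degrades gracefully; a constant heterozygosity count drops $\mu_d$ with a
warning.

GCA allele effects combine the pieces with the opposite pool's allele
frequencies, $\hat\alpha_1 = \tfrac12[\hat a_1 + \hat d (q_2 - p_2)]$ (and
symmetrically), where $\hat d = d^* + \hat\mu_d$ and frequencies are
computed from the full current-cycle line pools (not the testers or the
parents — the natural reading of "allele frequencies in the pool", and
config-visible). Line GCA scores are genotype–effect dot products; ranking,
hence selection, is invariant to centring.

## Evaluation protocols

*Accuracy protocol*: a baseline program crosses every line to the same
three testers, selects on testcross-model predictions from per-line mean
phenotypes, and provides a single shared population trajectory. At cycles
1, 2, 3, 5, 10, 15 every design is applied to the same lines with freshly
drawn testers; genomic accuracy is the Pearson correlation of predicted
with true GCA, phenotypic accuracy that of the design's single testcross
phenotype with true GCA. Design evaluations are seeded independently of the
baseline stream and never feed back into selection (asserted by test).

*Gain protocol*: the full program is run separately per design from
identical initial pools; gain at cycle c is the full-factorial hybrid mean
minus its initial value, and designs are compared as percent differences.

## Numerical and design choices

* One root seed; every stage draws a child seed from a string-keyed 31-bit
  hash, so perturbing one stage leaves the others' streams intact, and all
  C++ randomness flows through R's RNG (platform-stable).
* Selection ties break by ascending line index; half-diallel plans resample
  until every parent is covered; tester loads must divide the line count
  exactly (no rounding).
* Hybrid-pair variances are enumerated exactly up to 10⁶ pairs, then
  Monte-Carlo sampled (10⁵ pairs, chunked to bound memory).
* Degenerate inputs (constant phenotypes, monomorphic QTN panels,
  zero-variance genotypes) return typed warnings/errors rather than NaN.

## Problem sizes

Three profiles ship with the package: `paper` (1,200 lines/pool, 5,000 QTN
+ 5,000 SNP), `desk` (400 lines/pool, 40 parents, 40 crosses × 10 DH,
1,000 QTN + 1,000 SNP), and `mini` (200 lines/pool, 20 parents, 50+50 loci
per chromosome) for tests and examples. The shipped evaluation scripts and
the test suite use the desk profile (with 2,000 QTN for the variance-ratio
study), 8–20 replicates depending on the quantity; these sizes are the
package's standard reduced-scale study conditions, chosen so a complete
evaluation runs on a single CPU in well under half an hour.

## Fidelity limits

The desk-scale runs reproduce most qualitative findings: cycle-1 GCA
accuracy increases with tester number, most under high dominance, and
plateaus by ~10 testers; genomic beats phenotypic GCA accuracy; accuracy
declines over cycles for every design as heritability erodes; pools diverge
monotonically (Nei distance, heterosis, opposite-allele fixation), faster
under high dominance; and the single-tester design fixes alleles and erodes
within-pool diversity fastest. Three quantitative limits of the scaled-down
backend are worth knowing.

First, no single founder frequency spectrum reproduces all three published
cycle-1 SCA/GCA ratios under the per-locus variance decomposition; with the
quasi-uniform spectrum the medium ratio matches (≈0.22 vs 0.23), the high
ratio sits ≈14% low and the low-dominance ratio ≈40% high.

Second, the cycle-1 accuracy advantage of sparse designs is attenuated at
desk scale (roughly half the published percentages) and amplified at full
scale (our single-tester model lands lower than the published one there),
bracketing the published values; the package reports the desk-scale numbers
consistently rather than mixing scales per quantity.

Third, the *long-run gain* advantage of sparse designs does not survive
this down-scaling: although the ten-tester design predicts cycle-1 GCA more
accurately, its realized selection differential on true GCA is no better
than the single tester's at 400 lines and 1,000 markers, and over 15 cycles
the paired gain contrast is slightly negative (≈ −5% ± 3 for ten vs one
tester under high dominance, ≈ −2% ± 2 for two vs one under medium). With
fewer markers and observations the pool-specific model's variance
components are estimated noisily — late-cycle accuracy under the sparse
designs degrades faster than under the simpler testcross model — so the
full-scale ranking of designs should not be inferred from desk-scale gain
runs. Gain runs therefore use common random numbers across designs (shared
founders, trait, cross plans and phenotype errors) so these contrasts are
at least measured under matched noise.

## Using the package

```{r example}
library(sparsecross)
cfg <- experiment_config(scenario = "high", designs = c(1, 2, 10),
                         n_cycles = 5, eval_cycles = c(1, 5),
                         scale = "mini", root_seed = 1)
fnd <- make_foundation(cfg, replicate = 1)
ctx <- make_trait_context(fnd, cfg)
gain_k1 <- run_gain_program(cfg, "1", 1, fnd, ctx)
gain_k10 <- run_gain_program(cfg, "10", 1, fnd, ctx)
acc <- run_accuracy_program(cfg, 1, fnd, ctx)
aggregate_replicates(acc$evaluations)
```
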