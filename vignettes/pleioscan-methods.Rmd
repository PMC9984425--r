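---
title: "pleioscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pleioscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

`pleioscan` chains six statistical components into a prioritization
pipeline for pleiotropic regulatory variants, with a synthetic-data module
that generates every input the pipeline consumes. This vignette is the
package's own account of the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology was
genuinely open.

## Summary-statistic standardization

All downstream statistics consume per-variant `(beta, se, p, n)` tuples
oriented to a reference panel. Three standardization operations matter:

* **SE recovery.** Sources reporting beta and P but no SE are completed
  with `se = |beta| / Q(1 - p/2)`, `Q` the standard normal quantile. The
  upper-tail form of `qnorm` is used so that P values down to `1e-300`
  round-trip (p → se → z → p) to 10 decimal digits of relative accuracy.
* **OR conversion.** Odds ratios become `beta = log(OR)`, with SE from the
  log-scale confidence bounds when present, otherwise from P.
* **Harmonization.** After harmonization every beta is expressed per copy
  of the panel's **alt** allele: one fixed orientation for all downstream
  math. Direct matches are kept (sign-flipped when the reported effect
  allele is the panel ref), complementary-strand matches are
  base-complemented first, and palindromic (A/T, C/G) variants are dropped
  unconditionally — allele-frequency information is often absent from
  summary files, so strand cannot be resolved safely. Records at sites
  absent from the panel, with unresolvable alleles, or missing both
  coordinates and identifier are dropped with a per-reason count;
  `kept + dropped` always equals the input count.

Coordinates are 1-based inclusive throughout the package; BED input and
output convert to and from the 0-based half-open convention at the file
boundary. Genome-build liftover is out of scope: inputs are assumed to be
on one build. Monomorphic panel sites are excluded everywhere — a
correlation with a constant genotype is undefined.

## Single-causal fine-mapping

Blocks are the analysis unit: LD blocks that contain at least one
genome-wide significant variant (`P <= 5e-8`) are selected as causal
blocks. Under the assumption of exactly one causal variant per block, the
multi-variant model reduces to per-variant evidence ratios, and the
Wakefield approximate Bayes factor is the closed form:

$$\mathrm{ABF} = \sqrt{\frac{V}{V+W}}\;
  \exp\!\left(\frac{z^2}{2}\frac{W}{V+W}\right),
  \qquad V = \mathrm{se}^2,\; z = \beta/\mathrm{se}.$$

With a uniform prior over which variant is causal,
`PP_i = ABF_i / Σ_j ABF_j`, and the 95% credible set is the shortest
PP-descending prefix with cumulative PP ≥ 0.95 (ties broken by input
order for determinism). All Bayes-factor arithmetic is in log space with
log-sum-exp normalization, because |z| beyond 40 occurs routinely in
autoimmune GWAS and would overflow the natural scale.

**Prior variance `W`** (default 0.04, i.e. prior SD 0.2 on the per-allele
effect in trait units) is exposed rather than fixed: no single value is
canonical, and the default is the common choice for quantitative traits.
The tests verify the posteriors against brute-force enumeration of the
single-causal model (direct normal-density ratios) to `1e-12` on blocks of
up to 10 variants.

## Pairwise pleiotropy posteriors

For a pair of traits and one block, five models are compared: no
association (0), trait 1 only (1), trait 2 only (2), one shared causal
variant (3), two distinct causal variants (4). With per-variant Bayes
factors `BF1`, `BF2` and joint shared-causal factors `BFj`, the
unnormalized block scores are

$$S_0 = 1,\quad S_1 = \pi_1\sum_i BF1_i,\quad S_2 = \pi_2\sum_i BF2_i,$$
$$S_3 = \pi_3\sum_i BFj_i,\quad
  S_4 = \pi_4 \sum_i\sum_{j\neq i} BF1_i\,BF2_j,$$

normalized to posteriors `pp0..pp4`. A block with `pp3 >= 0.9` (inclusive)
is called a shared genetic effect.

**Priors.** Genome-wide empirical-Bayes estimation of the per-variant
priors needs thousands of blocks; a desk-scale run on one or a few blocks
cannot support it. The package therefore uses fixed, configurable
per-variant priors (defaults `pi1 = pi2 = 1e-4`, `pi3 = 1e-5`,
`pi4 = 1e-6`), ordered so that trait-specific association is more likely
a priori than shared causality, which is more likely than a coincidental
pair. The defaults give `pp0 > 0.99` on a fully null block of typical
size.

**Cohort overlap.** Two scans drawn from overlapping samples have
correlated null Z scores. For disease pairs measured in the same cohort
the expected correlation `C` is set from the MeSH hierarchy: the
relationship level is the length of the longest common prefix of the two
diseases' tree numbers (capped at 5), and `C = 0.09 × level`, the
0.09/0.18/0.27/0.36/0.45 ladder — e.g. ulcerative colitis
(`C06.405.469.432.249`) and Crohn's disease (`C06.405.469.432.500`) share
a four-component prefix, level 4, `C = 0.36`. Distinct-cohort pairs get
`C = 0`. The correction enters through the joint shared-causal Bayes
factor: in Z space the null is `N(0, Σ)` with `Σ = [[1, C], [C, 1]]` and
the alternative adds the per-trait prior variance ratios on the diagonal,
so the joint BF is a ratio of two bivariate normal densities (evaluated in
closed 2×2 form, in log space). At `C = 0` it factorizes exactly into the
product of the two marginal Wakefield ABFs. Trait-wise BFs are left
unadjusted; this is an approximation to a full bivariate treatment of all
five models, adequate because the correlation matters most where both
traits show signal at one variant. A property test confirms the
correction's direction: under a correlated null (`C = 0.45`), using the
correct `C` yields a lower false shared-effect rate than assuming
independence, seed-for-seed.

## RTC colocalization

The regulatory trait concordance score asks whether a GWAS sentinel and an
eQTL in one recombination-hotspot interval share a causal signal. For each
of the interval's `N_int` variants, expression is residualized on the
covariates plus that variant's dosage and the eQTL lead's association is
recomputed on the residuals; variants are ranked ascending by the residual
statistic (a variant that better extinguishes the eQTL ranks earlier), and
`RTC = (N_int − Rank_sentinel)/N_int`, colocalized at `RTC >= 0.9`.

Design choices: the ranking statistic is the squared t statistic from a
simple linear regression of residuals on lead dosage — monotone in P at
fixed degrees of freedom, with no distributional edge cases; rank ties are
broken by genomic position; expression is rank-inverse-normal transformed
by default (standard eQTL practice, and it stabilizes the rank statistic);
covariates are injected, not derived — genotype PCs are provided
(`genotype_pcs`, deterministic up to a fixed sign convention), but
expression-factor covariates (PEER-style) are accepted as a user-supplied
matrix because factor-count rules are dataset-specific. Self-extinction is
exact: when the sentinel *is* the lead, residualizing on it removes its own
linear signal entirely, so Rank = 0 and RTC = 1.

## Causal inference test

For a triplet (variant dosage `L`, cis expression `G`, trans expression
`T`), triplets whose cis and trans expression are weakly correlated
(Pearson test P > 0.05) are filtered out first. The causal direction
`L → G → T` is then supported by four conditions, each oriented so small
P supports the model:

1. `p1`: L associated with T (`T ~ L`);
2. `p2`: L associated with G given T (`G ~ L + T`);
3. `p3`: G associated with T given L (`T ~ G + L`);
4. `p4`: L conditionally independent of T given G.

The omnibus P value for a direction is the maximum of its four components
(intersection-union logic), the reactive direction is the same test with
G and T exchanged (so swapping them swaps the two omnibus values exactly),
and with Bonferroni level `alpha = 0.05/n_tests`: causal iff
`p_causal < alpha <= p_reactive`, reactive for the mirror image, otherwise
independent — including when both directions are significant.

**Component 4 is the delicate one.** It must *support* the causal model
when a null hypothesis (conditional independence) is *true*, which an
ordinary significance test cannot do: the observed F statistic for L in
`T ~ G + L` is, under the causal model, an ordinary draw from its own
permutation null, so a permutation tail proportion is uniform there and
never concentrates near zero. The package therefore uses an equivalence
formulation: the observed conditional F is referred to a noncentral F
whose noncentrality is the *marginal* L–T association strength (the
test-1 F statistic) minus a leakage baseline estimated from seeded
permutations of L within tertile bins of G (these preserve the coarse
L–G structure while destroying any direct L–T link).
`p4 = P(F_ncp <= F_obs)` is then small exactly when the conditional
association is far below what the marginal association would imply without
mediation — i.e. when G explains the L–T link — and remains moderate under
the independent model, blocking false causal calls. Genotype is treated as
a numeric additive dosage throughout, matching the linear models used in
the rest of the pipeline.

Calibration and power at the package's test conditions (unit-variance
noise): with `a = b = 1` and n = 500, ≥ 90% of causal-generator triplets
are classified causal and ≥ 90% of reactive-generator triplets reactive
(the residual misses are the ~5% of datasets where the reactive
direction's uniform component happens to fall below 0.05); under the
independent generator at n = 300 the false causal rate stays within
binomial error of the nominal 0.05.

## Evidence aggregation and target genes

A variant is a candidate causal regulatory variant when all four flags
hold, every threshold inclusive as printed: shared-model posterior
`pp3 >= 0.9` for at least one trait pair; membership in a 95% credible set
for at least one trait; `RTC >= 0.9` for at least one eQTL dataset; and
regulatory potential — regBase PHRED `>= 15` and cepip combined `>= 0.6`
and RegulomeDB category at least `2c` on the published `1a…7` ladder. The
external scoring tools themselves are not re-implemented: the package owns
thresholding and aggregation, consuming score tables as input. A variant
absent from an evidence table fails that flag (a logged gap, not an
error) — improving any single score can therefore only add candidates,
never remove them. Candidates are ranked by the number of distinct shared
diseases, ties broken by genomic position.

Target genes are the union of three tagged routes: bait genes of
promoter-capture Hi-C interaction regions overlapping the variant with
interaction score **strictly** greater than 5; eGenes of colocalized
eQTLs; and genes whose protein function or splicing the variant alters
directly.

## Networks

The variant–gene bipartite network stores disease labels on variants;
compressing all variants of one disease into a single node yields the
disease–gene network, with edge weights equal to the number of supporting
variants (weights are an extension — the bipartite construction itself
does not define them). The shared-gene summary reports the percentage of
genes connected to at least three diseases, rounded to two decimals. The
optional layout is a plain Fruchterman–Reingold iteration (natural spring
length `k = sqrt(1/n)`, repulsion `k²/d`, attraction `d²/k`, linear
cooling), implemented directly so that the two-node fixed point —
separation at the natural spring length — holds exactly and layouts are
deterministic per seed. The layout is decorative: no inference rests on
coordinates.

## Transcript-usage QTL

A gene's transcripts are split at a breakpoint — typically the chromatin
contact locus with the highest interaction frequency — in a strand-aware
way: a transcript is *long* when its TSS lies upstream of the breakpoint
in the gene's transcription sense (plus strand: TSS < breakpoint; minus
strand: TSS > breakpoint), otherwise *short*. A TSS exactly at the
breakpoint classifies short (the downstream-promoter side) with a warning;
the strand-aware formalization keeps the operation gene-general while
reducing to the simple plus-strand rule for the motivating IRF5 case. The
breakpoint is a parameter, since contact peaks are regions rather than
single bases. Group TPM values are per-sample sums — the two groups
partition the transcripts, so long + short equals the gene total — and
genotype association is ordinary least squares on dosage. Expression is
consumed as TPM; re-quantification from reads is out of scope.

## The synthetic-data module

The generators are pure functions of their arguments and a seed; a
top-level seed expands into per-stage child seeds by fixed offsets.

* **Reference panel.** Haplotypes are latent multivariate normal with
  block-constant correlation, thresholded at the block's allele frequency;
  two haplotypes pair into a diploid dosage. Thresholding attenuates
  correlation, so the latent correlation is calibrated numerically (1-D
  quadrature + root-finding on the phi coefficient) to hit the requested
  *genotype* LD. All variants in a block share one allele frequency drawn
  from `maf_range`: with unequal frequencies the requested LD can be
  mathematically unattainable, which would make the generator's contract
  dishonest. Monomorphic draws are redrawn; variants get non-palindromic
  ref/alt pairs so harmonization keeps every site.
* **Paired GWAS.** Phenotypes are quantitative:
  `y_t = effect_t · dosage + e_t` with unit-variance noise, because all
  downstream statistics operate on beta/SE/Z, which the linear model
  supplies directly — case-control liability adds nothing at this scale.
  Cohort overlap is modeled as correlated trait noise on fully shared
  samples, which makes the null Z-score correlation equal the requested
  `C` — exactly the quantity the pleiotropy correction consumes.
* **eQTL, triplets, transcript usage.** Expression is
  `effect · dosage + covariates + noise` with covariates returned
  explicitly; triplets follow the three generating structures the CIT
  distinguishes; transcript usage shifts expression reciprocally between
  the short and long groups by the usage effect per alt allele (defaults:
  baselines 50/30 TPM, noise SD 5 TPM — TPM-scale values typical of a
  moderately expressed gene's promoter groups).

What the generators do **not** emulate: realistic human haplotype
structure (hotspot-scale recombination, allele-frequency spectra),
binary-trait ascertainment, imputation uncertainty, expression count
noise, or batch structure. Passing tests therefore demonstrate that the
statistical machinery is correct under its stated model, not that the
pipeline is robust to every artifact of real cohort data.

## Problem sizes and numerical choices

The test suite runs the simulation checks at n = 2,000 samples for GWAS
blocks (10 variants), n = 300–500 for CIT triplets (100–500 seeds),
20-variant intervals for RTC (200 null intervals), and 20 seeds for the
end-to-end ranking cohort — sizes chosen so the whole suite completes in a
few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted margins. The end-to-end cohort uses common variants
(MAF 0.2–0.5) and per-allele effects of 0.5 so that the engineered
candidate satisfies all four evidence conditions by design in every seed.

Numerical conventions, gathered in one place: all Bayes-factor arithmetic
in log space; `log(exp(a) − exp(b))` via `log1p` with an exact `-Inf`
guard for single-variant blocks (where the two-distinct-causals score is
identically zero); credible-set and ranking ties broken by input/genomic
order; PC signs fixed by the largest-magnitude loading; collinear
covariates dropped by pivoted QR with a warning; permutation streams
seeded per stage.

## Known limitations

* Pleiotropy priors are fixed, not learned; absolute posterior values
  shift with the priors (the model *ranking* is much less sensitive).
* The overlap correction adjusts only the shared-causal model's joint BF.
* Single-causal fine-mapping understates uncertainty in blocks that truly
  carry multiple causal variants.
* The CIT's linear additive models do not detect non-linear mediation,
  and measurement error in G biases the test toward the independent call.
* RTC depends on the interval definition; hotspot intervals are taken as
  given.
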