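---
title: "Core-instrument sensitivity analysis for two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-instrument sensitivity analysis for two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcore)
```

## Motivation

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics, using genetic variants
as instrumental variables. For polygenic exposures the exclusion-restriction
assumption is fragile: hundreds of genome-wide-significant variants act
through diffuse regulatory ("peripheral") pathways and are more likely to
affect the outcome through routes other than the exposure (horizontal
pleiotropy). The omnigenic/core-gene view suggests a complementary
assumption: a small number of core genes affect the trait directly, and the
variants with the *strongest* exposure associations are the most likely to
act through them. `mrcore` operationalizes this as a sensitivity analysis:
rank instruments by putative coreness, split them into `K` near-equal
groups, and compare causal estimates from the strongest (putative core)
group against estimates that accumulate progressively weaker instruments.
If the trajectory drifts as peripheral instruments pour in, the
all-instrument estimate is suspect; the group-1 estimates are the primary
result.

This is a *sensitivity analysis*, not a test: there is no formal comparison
statistic between core and peripheral estimates, and the coreness ranking
is a proxy, not an annotation of biological function.

## The procedure

### Ranking metrics

Instruments are ranked in descending order of one of four metrics, all
computed from the exposure GWAS:

| criterion | formula | notes |
|---|---|---|
| `abs_beta` (default) | $|\hat\beta_j|$ | per-allele effect size |
| `per_variant_h2` | $f_j(1-f_j)\hat\beta_j^2$ | per-variant heritability up to a constant; symmetric in $f \leftrightarrow 1-f$ |
| `significance` | $|\hat\beta_j|/SE_j$ | the GWAS z-statistic |
| `n_normalized_significance` | $|\hat\beta_j|/(SE_j\sqrt{N_j})$ | differs from the z-statistic in meta-analyses with variant-specific $N_j$ |

Exact metric ties are ordered by a seeded random shuffle. To make results
independent of input row order, records are first put into a canonical
order by `variant_id`; the tie-shuffle then depends only on the seed.

### Partition

The ranked list is cut into `K` contiguous groups. When `J` is not
divisible by `K`, the first `J mod K` groups receive the extra instrument:
the putative core end never under-fills, so the primary estimate is never
computed on the smaller share. `suggest_k()` returns `round(J/7)`, which
keeps 5–10 instruments per group; since any single `K` is somewhat
arbitrary, analyses should be repeated over several values (the CLI accepts
a comma-separated list).

### Estimators

For each group `k` and each cumulative set (groups `1..k`), the package
computes, from the per-instrument Wald ratios
$b_j = \hat\beta_{out,j}/\hat\beta_{exp,j}$ with first-order standard
errors $se_j = SE_{out,j}/|\hat\beta_{exp,j}|$ and weights $w_j = 1/se_j^2$:

* **IVW** — $\hat\theta = \sum w_j b_j / \sum w_j$. The default variance
  model is multiplicative random effects: the fixed-effect standard error
  $\sqrt{1/\sum w_j}$ is inflated by $\sqrt{Q/(J-1)}$ whenever Cochran's
  $Q$ exceeds its degrees of freedom, and never deflated. A fixed-effect
  model is available by flag. With a single instrument the IVW reduces to
  the Wald ratio.
* **Weighted median** — linear interpolation of the sorted ratios at
  standardized cumulative weight $1/2$; consistent when valid instruments
  carry at least half the weight.
* **Weighted mode** — the argmax of a Gaussian-kernel density of the
  ratios with mass $w_j$ at $b_j$; consistent when the largest cluster of
  ratios comes from valid instruments.

Standard errors of the median and mode come from a parametric bootstrap
(resample $b_j^* \sim N(b_j, se_j)$, keep the weights, recompute; default
1000 replicates), which is the approach used in the literature that
introduced these estimators. Confidence intervals and p-values use the
normal approximation throughout.

First-order ratio SEs ignore the exposure-side sampling noise; with strong
instruments the omitted term is a few percent of the ratio variance.
Second-order weighting is deliberately out of scope.

### Instrument strength

Each group is summarized by the mean per-instrument F-statistic
$\bar F = J^{-1}\sum_j(\hat\beta_{exp,j}/SE_{exp,j})^2$. Because ranking by
`significance` sorts exactly on $\sqrt{F_j}$, the core group's mean F is
then mathematically guaranteed to be at least the overall mean; under the
other criteria it typically is. Mean F below roughly 10 flags weak
instrument bias risk.

## Harmonization

Outcome records are aligned to the exposure's effect allele: swapped
alleles flip the outcome beta's sign and complement its allele frequency;
alleles matching only under strand complement are complemented first.
Palindromic variants (A/T, C/G) cannot be strand-resolved from alleles:

* exposure minor allele frequency above the threshold (default **0.42**):
  excluded as frequency-ambiguous;
* at or below the threshold: aligned by frequency concordance, assuming
  the exposure and outcome minor alleles are the same allele;
* a strict mode drops all palindromes.

The minor allele frequency used for adjudication is taken from the
*exposure* table: the instruments are selected in the exposure GWAS, so
its frequencies are the ones guaranteed to be present and on the relevant
ancestry. This is a documented choice; outcome frequencies (when present)
are used only for concordance alignment. Indels and multi-allelic records
are rejected rather than guessed at, and variants missing from one table
are reported, not proxied — proxy search requires an LD reference panel,
which is upstream of this package, as is LD clumping itself.

Every excluded variant lands in a rejection report (`variant_id`, `stage`,
`reason`); harmonized plus harmonization-rejected counts always equal the
intersection count.

## Reproducibility design

All randomness (tie-breaking, bootstraps, simulation replicates) flows
through sub-seeds derived by hashing the master seed with context labels
(`derive_seed(seed, method, k, scope)`), so results are independent of
evaluation order and of input row order. Two consequences worth knowing:

* the cumulative estimate at `k = K` is bit-identical to a direct
  all-instrument call with the corresponding derived seed;
* at `k = 1` the group and cumulative sets coincide, so both rows are one
  computation (both are emitted for table regularity).

## Numerical choices

* **Mode bandwidth** — modified Silverman rule
  $h = \phi\,0.9\,\min(s_w, \mathrm{MAD}_w/0.6745)\,J^{-1/5}$ with
  $\phi = 1$ by default, on the weighted ratio distribution. When more
  than half the weight sits at a single value the weighted MAD collapses
  and $h$ is floored at $10^{-8}$ with a warning.
* **Mode grid** — 512 points (configurable upward) spanning
  $[\min(b)-3h, \max(b)+3h]$; the estimate is exact only up to one grid
  step, and density ties resolve toward the lower mode.
* **Weighted median interpolation** — cumulative weights
  $p_j = \sum_{i\le j} s_i - s_j/2$; outside $[p_1, p_J]$ the nearest end
  value is returned.
* **Small groups** — the median and mode require 3 instruments
  (configurable); smaller groups yield a missing estimate with a reason
  rather than aborting the trajectory.
* **Confidence intervals** — $\hat\theta \pm z_{0.975}\,se$ everywhere.

## The simulator

`simulation_scenario()` encodes the core-gene architecture as a generative
model: per-allele exposure effects $b_j \sim N(0, \sigma_c^2)$ for core and
$N(0, \sigma_p^2)$ for peripheral instruments (defaults
$\sigma_c = 0.1$, $\sigma_p = 0.02$ in SD units of a unit-variance trait,
with 10 core and 90 peripheral instruments — a small core set within a
polygenic background, each class strong enough to be detectable at
GWAS sample sizes of $10^5$); allele frequencies uniform on
$[0.05, 0.95]$; direct variant–outcome effects $a_j$ per the pleiotropy
model; true outcome effect $\theta b_j + a_j$; observed statistics add
independent noise with the standard unit-variance-trait approximation
$se_j = 1/\sqrt{2 f_j (1-f_j) N}$, so per-variant F is about
$1 + 2f(1-f)b^2N$ and doubling $N$ shrinks every SE by exactly $\sqrt 2$.

Directional pleiotropy deserves a note. A nonzero *mean* direct effect is
only defined relative to an allele orientation — flipping the reported
allele of a variant flips both $b_j$ and $a_j$, so with signs drawn
independently a "directional" mean would cancel out of every ratio and be
indistinguishable from balanced pleiotropy. The simulator therefore draws
$a_j \sim N(\mu_a, \sigma_a^2)$ *in the orientation of the
exposure-increasing allele* (multiplied by $\mathrm{sign}(b_j)$), which is
what directional pleiotropy means in practice: the direct effects push the
per-instrument ratios coherently in one direction. Defaults
$\mu_a = 0.02$, $\sigma_a = 0.01$ place the typical pleiotropic ratio
distortion ($a/b \approx 0.4$–$1$ for peripheral instruments) well above
the estimation noise while remaining small on the trait scale.

What the simulator does **not** emulate: LD between instruments (inputs
are post-clumping by assumption), overlap between the two GWAS samples,
binary outcomes on the liability scale, winner's-curse selection of
instruments from a discovery scan, population stratification, and allele
frequency differences between samples. Passing benchmarks therefore
demonstrate correctness of the estimators and of the core-grouping logic
under the stated architecture — they do not certify behavior on real data
with those complications.

## Benchmarks and what they show

`run_benchmark()` repeats simulate → harmonize → rank → estimate and
aggregates bias, empirical SD, RMSE, CI coverage, and rejection rate for
group-1 versus all-instrument estimates. The package's own calibration
runs (also recomputed by `scripts/acceptance.R`) use 100–200 replicates
with bootstrap size 200 — sizes chosen to keep Monte-Carlo standard errors
a few times smaller than the effects being measured:

* **Valid instruments** (100 strong instruments, $\theta = 0.3$,
  $N = 10^5$): all estimators' mean estimates sit within Monte-Carlo error
  of 0.3, and CI coverage is near nominal.
* **Directional pleiotropy on peripherals** ($\theta = 0$, 10 core + 90
  peripheral): the all-instrument IVW is strongly biased (bias
  $\approx 0.2$) and rejects the true null almost always, while the
  group-1 estimates stay close to zero and the group-1 weighted median
  keeps its type-I error near the nominal 5%.

One honest caveat from these runs: bootstrap confidence intervals for the
**weighted mode** are conservative. The mode's sampling distribution is
heavy-tailed (occasionally the kernel-density argmax jumps between nearby
bumps), and the parametric bootstrap reproduces exactly that instability,
so per-replicate SEs track the *conditional* difficulty of each dataset;
across replicates this yields coverage above 0.98 in the all-instrument
valid-instrument setting. This mirrors what the mode-based-estimation
literature reports for its own simulations. The mode's point estimates
remain unbiased; its intervals are simply not anti-conservative, which for
a sensitivity analysis is the safer direction of error.

## Limitations

* The coreness ranking is a heuristic proxy for core-gene action; strong
  pleiotropic variants (e.g. in pleiotropic hub genes) can rank high.
* No formal core-vs-peripheral heterogeneity test is provided; trajectories
  are meant to be inspected, typically with `plot_trajectory()`.
* Only SNVs are harmonized; indels are rejected.
* MR-Egger, RAPS, PRESSO, contamination-mixture and the simple
  median/mode variants are not included; the `records → estimate`
  contract makes them straightforward to add.
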