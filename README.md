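# mrcore

Core-instrument sensitivity analysis for two-sample Mendelian
randomization (MR) of polygenic exposures.

MR estimates the causal effect of an exposure on an outcome using genetic
variants as instrumental variables. For polygenic exposures, many of the
hundreds of available instruments act through peripheral regulatory
pathways and are prone to horizontal pleiotropy, which biases estimates
based on all instruments — even with robust estimators. Under the
core-gene hypothesis, variants with the strongest exposure associations
are the most likely to act through core genes and to be valid instruments.
`mrcore` turns this into a sensitivity analysis:

1. rank the J instruments by putative *coreness* — by default the
   per-allele effect size |β̂<sub>j</sub>|, alternatively the per-variant
   heritability f<sub>j</sub>(1−f<sub>j</sub>)β̂<sub>j</sub>², the
   significance |β̂<sub>j</sub>|/SE<sub>j</sub>, or the sample-size-normalized
   significance |β̂<sub>j</sub>|/(SE<sub>j</sub>√N<sub>j</sub>);
2. partition the ranking into K near-equal groups (group 1 = putative
   core);
3. for each group k and each cumulative set 1..k, estimate the causal
   effect θ with the inverse-variance weighted (IVW), weighted median, and
   weighted mode estimators built on per-instrument Wald ratios
   b<sub>j</sub> = β̂<sub>out,j</sub>/β̂<sub>exp,j</sub>, and attach each
   group's mean instrument-strength F-statistic.

The group-1 estimates are the primary result; a trajectory that drifts as
weaker instruments accumulate is the signature of pleiotropy among
peripheral instruments. The package also harmonizes exposure/outcome GWAS
summary statistics (allele swaps, strand flips, a palindromic-variant
minor-allele-frequency filter at 0.42), simulates summary statistics with
an explicit core/peripheral pleiotropy architecture for validation, and
ships a command-line interface.

## Worked example

Simulate a null exposure–outcome pair (θ = 0) where the 90 peripheral
instruments carry directional pleiotropy and the 10 core instruments are
valid, then run the analysis:

```r
library(mrcore)

scen <- simulation_scenario(n_core = 10, n_peripheral = 90, theta = 0,
                            pleiotropy_model = "directional", seed = 11)
sim <- simulate_summary_stats(scen)
h <- harmonize(sim$exposure, sim$outcome)
res <- mr_core(h, K = 10, seed = 1)
res
#> Core-instrument MR sensitivity analysis: J = 100 instruments, K = 10 groups, criterion = abs_beta
#> Group-1 (putative core) mean F = 336.7; overall mean F = 43.7
#> Primary (group-1) estimates:
#>           method n_instruments          beta         se      ci_low    ci_high      pval
#>              ivw            10  0.0324586516 0.04299213 -0.05180437 0.11672167 0.4502546
#>  weighted_median            10 -0.0007111489 0.02626084 -0.05218144 0.05075915 0.9783958
#>    weighted_mode            10 -0.0169728624 0.03591013 -0.08735543 0.05340970 0.6364641
```

All three primary (core-group) estimates correctly cover the true θ = 0,
and the core group is also the strongest instrument set (mean F 337 vs 44
overall). The cumulative IVW trajectory shows what instrument accumulation
does:

```r
tr <- trajectory_table(res)
subset(tr, method == "ivw" & scope == "cumulative" & k %in% c(1, 5, 10))
#>   k n_instruments       beta      ci_low   ci_high         pval f_statistic
#>   1            10 0.03245865 -0.05180437 0.1167217 0.4502546299   336.68284
#>   5            50 0.15567289  0.06641496 0.2449308 0.0006300617    85.10659
#>  10           100 0.20594876  0.08172709 0.3301704 0.0011562822    43.71995
```

With all 100 instruments the IVW reports a confidently positive effect
(0.21, p = 0.001) — pure pleiotropy bias; the putative core instruments
alone give the right answer. `plot_trajectory(res)` draws the
corresponding two-panel (group-specific / cumulative) error-bar figure.

The same pipeline runs from the shell on real summary-statistic TSVs:

```sh
inst/exec/mrcore run --exposure exp.tsv --outcome out.tsv \
    --k 10,20 --rank beta --seed 1 --out results/myrun
```

producing `myrun.instruments.tsv`, `myrun.groups.tsv`,
`myrun.trajectory.tsv` (one block per K, `k_total` column),
`myrun.rejects.tsv`, and a provenance manifest `myrun.manifest.json`.

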