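# coalsel

Simulation-based selection among competing demographic hypotheses for
phylogeographic data, with the spatial analyses that usually accompany
it.

Neotropical seasonally dry forests are today disjunct nuclei, and
several biogeographic hypotheses describe what a dry-forest tree's range
did between the Last Glacial Maximum (~21 ka) and the present: glacial
expansion across Central/Southwest Brazil (the Pleistocene Arc
hypothesis, PLAH), a glacial range centred on the Amazon Basin (PPPH),
both (BOTH), or a range retraction (RETRACTION). `coalsel` encodes each
hypothesis as an explicit structured-coalescent scenario, simulates
genealogies and sequence alignments under it, and scores the scenarios
against observed summary statistics.

## The method

Backward in time over `t = round(21000/15) = 1400` generations, each of
17 demes follows `N(tau) = N0 * exp(g * tau)` with
`g = ln(N1/N0)/t`; every lineage outside the source deme migrates into
it with probability 0.01 per generation; within a deme each lineage pair
coalesces with probability `1/N(tau)` per generation; extinct-flagged
demes shrink to a single copy at the horizon; after the horizon the
source deme persists at its horizon size until the MRCA. Alignments
evolve under HKY+G (cpDNA: 1,742 bp, kappa = 1.5, alpha = 0.0170) or
TIM1+G (ITS: 518 bp, alpha = 0.010). For each scenario `s` and observed
statistic `x_obs` (haplotype diversity `h`, nucleotide diversity `pi`):

    P     = min(1, 2 * #{x_sim > x_obs} / n_sim)
    ln L  = ln( hist_height(x_obs) / max hist_height )
    AIC   = -2 ln L + 2K          (K = 2)
    w_s   = exp(-dAIC_s / 2) / sum_s' exp(-dAIC_s' / 2)

with scenarios at `dAIC < 2` flagged as equally plausible. The package
also provides Nei's `h`, `pi`, segregating sites, one-level AMOVA
`phiST` with permutation tests, Mantel tests of isolation by distance
(linearized `phi/(1-phi)` against log10 great-circle distance),
palaeo-suitability stability and range-centroid analyses, and exact
simple-linear quantile regression.

## Worked example

```r
library(coalsel)

tpl     <- study_template(scenario_name = "PPPH", seed = 1)  # 17 pops, 257 seqs
bundle  <- generate_dataset(tpl)
aln     <- bundle$alignments$cpDNA
obs     <- list(cpDNA = list(h  = haplotype_diversity(haplotype_counts(aln)),
                             pi = nucleotide_diversity(aln)))
samples <- sample_config(tpl$populations$n, tpl$populations$deme)
fit     <- fit_scenarios(obs, default_scenarios(), tpl$partitions["cpDNA"],
                         samples, n_sim = 500, seed = 2)
summary(fit)
```

```
Best scenario per statistic:
 partition statistic scenario delta_AIC      AICw
     cpDNA         h     PPPH         0 0.9448572
     cpDNA        pi     PPPH         0 0.5771144

Total AIC (summed over statistics and partitions):
      BOTH       PLAH       PPPH RETRACTION 
    15.902        Inf      9.059        Inf 

Best-supported scenario overall: PPPH
```

The synthetic study was generated under the Amazon-refugium scenario,
and the fit recovers it: PPPH takes `dAIC = 0` for both statistics (an
infinite AIC means the observation fell outside that scenario's entire
simulated distribution). `print(fit)` shows the full per-scenario table
of `P`, `lnL`, `AIC`, `dAIC` and `AICw`; `coef(fit)` returns the Akaike
weights; `plot(fit)` draws each scenario's simulated distribution with
the observed value marked.

A thin CLI covers the same pipeline:
`Rscript -e 'coalsel::coalsel_cli()' synth --seed 42 --out bundle`, then
`stats`, `compare`, `spatial` (see `?coalsel_cli`).

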