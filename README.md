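# paleodemog

Multi-model inference of species demographic history from coalescent
simulation and paleodistribution ensembles.

`paleodemog` is for population geneticists and phylogeographers who want to
ask: *which demographic history -- stability, retraction, expansion, or
multiple refugia across the last glacial cycle -- best explains the genetic
diversity of modern populations?*  It couples two lines of evidence:

1. **Structured coalescent simulation.** Six explicitly parameterised
   demographic hypotheses for a 20-deme microsatellite system, anchored at
   the present, the mid-Holocene (500 generations) and the Last Glacial
   Maximum (1,750 generations at 12 yr/generation), with per-deme sizes
   interpolated exponentially between anchors
   (N(t) = N(t_a)·(N(t_b)/N(t_a))^((t−t_a)/(t_b−t_a))), backward migration
   at 0.01/generation and strict stepwise mutation at mu = 10⁻² per allele
   per generation.  The genealogy core is in C++ and validates against the
   stepwise-model equilibrium He = 1 − 1/√(1 + 2θ), the 2N pairwise
   coalescence time, and an independent coalescent implementation.
2. **Ensemble suitability-map post-processing.** TSS-weighted consensus
   maps, range-size dynamics classified against the ±199-cell stability
   cut-off, refugium mapping (cells suitable in all periods at threshold
   0.3), hierarchical ANOVA variance partitioning (algorithm and AOGCM
   nested in time), and association tests.

Between the two sit the classical genetic summaries (Nei gene diversity,
rarefied allelic richness, Weir–Cockerham F<sub>IS</sub>/F<sub>ST</sub>/F<sub>IT</sub>, Slatkin's
R<sub>ST</sub>, permutation tests), closed-form coalescent conversions
(θ = 4μN<sub>e</sub>, TMRCA = (θ/μ)·generation time), simulation-based model
selection (relative support, two-tailed P = 2·min(RS, 1−RS), AIC weights
from empirical frequency distributions), and spatial genetics (Mantel
tests, exact check-loss quantile-regression envelopes).  A synthetic-data
module generates genotypes, coordinates and map stacks with planted truth,
so everything is testable without the original (undeposited) data.

## Worked example

Simulate an "observed" dataset under a known truth (6–0 ka expansion with
within-population inbreeding 0.21), summarise it, and ask which scenario
explains it:

```r
library(paleodemog)

spec <- synthetic_study_spec(n_populations = 6, sample_sizes = rep(20, 6),
                             n_loci = 11, inbreeding = 0.21,
                             truth_scenario = "Expansion_6_0", seed = 7)
gd   <- gen_observed_dataset(spec)
summ <- summarise_populations(gd)
attr(summ, "fstats")
#>          FIS          FST          FIT
#> 0.2231536926 0.0005107171 0.2235504413

obs <- summ$He[summ$pop == "Mean"]   # 0.9434
cfg <- simulation_config(rep(20, 6), n_loci = 11)
rank_models(obs, c("Expansion_6_0", "Stability_21_0", "Retraction_21_6"),
            cfg, R = 60, seed = 99, n_demes = 6)
#>             model n_replicates    RS     P likelihood  AICw estimable
#> 1   Expansion_6_0           60 0.717 0.567     0.7868 0.984      TRUE
#> 2 Retraction_21_6           60 0.900 0.200     0.0128 0.016      TRUE
#> 3  Stability_21_0           60 1.000    NA         NA    NA     FALSE
```

The generating scenario takes almost all of the Akaike weight; the
stability scenario overshoots the observed diversity in every replicate
(RS = 1.000), so its likelihood and P cannot be estimated -- the same
behaviour reported for the retraction/stability hypotheses in the original
analysis.  Estimated F<sub>IS</sub> ≈ 0.22 recovers the planted inbreeding.

Closed-form dating from the overall mutation parameter:

```r
tmrca_from_theta(7.033, mu = 0.01, generation_time = 12)
#> [1] 8439.6      # years, i.e. ~8.44 ka
```

The full pipeline (synthetic inputs → summary table → model selection →
consensus/refugium/uncertainty maps → Mantel and quantile-regression
report, with a reproducibility manifest) runs from one config:

```r
run_pipeline(list(seed = 1, out_dir = "run1"))
```

See `vignettes/paleodemog-methods.Rmd` for the model, its assumptions, and
every numerical choice.

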