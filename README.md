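# demesim

Forward simulation and inference tools for a classic experimental-evolution
question: how do mating system and metapopulation structure shape genetic
drift and sexually antagonistic evolution in the seed beetle
*Callosobruchus maculatus*?

The package is for quantitative/evolutionary biologists who want to

* **simulate a line-propagation protocol exactly as bred in the lab** — 50
  breeders per line (25 females + 25 males), a 2×2 design of mating system
  (enforced monogamy vs. polygamy with 2–3 mates per female) × population
  structure (panmictic vs. 5 demes of 5+5 exchanging one migrant pair per
  deme per generation, a 20% migration rate), 150 inoculated beans sampled
  per line per generation, virgin breeders collected at random — with full
  pedigree and neutral-locus tracking;
* **estimate effective population size (Ne) per selection regime** from that
  protocol, using four estimators: sex ratio `4NmNf/(Nm+Nf)`, family-size
  variance `(nk̄−1)/(k̄−1+Vk/k̄)` combined across sexes, pedigree-inbreeding
  rate `1/(2ΔF)`, and the temporal method `t/(2F̄c)` with
  `Fc=(p0−pt)²/(p̄(1−p̄))` — including infertile-mating scenarios;
* **generate synthetic female fitness records** (longevity, lifetime
  reproductive success, elytron length) from the published fixed-effect
  coefficient tables, with line-level random effects and a negative
  longevity–reproduction residual correlation (cost of reproduction);
* **run the matching inference design**: mean-centered covariates, by-line
  random intercept + slope LMMs (`lme4`), REML coefficient estimates with
  Type II/III Wald chi-square tests on ML fits (`car`), the
  significant-interaction Type III rule, the convergence fallback that drops
  intercept–slope correlations, and parameter-recovery / type-I-error
  studies.

## Worked example

Simulate the structured-polygamy regime and estimate its Ne:

```r
library(demesim)

cfg <- build_regime("polygamy", structured = TRUE)
cfg
#> <regime_config> polygamy, structured
#>   demes: 5 x (5F + 5M); migrant pairs/deme: 1
#>   mates/female: 2-3; infertility: 0; beans/line: 150
#>   generations: 10; neutral loci: 100

monte_carlo_ne(cfg, replicates = 100, seed = 42)
#> <ne_mc> regime SPoly, 99 replicates (1 failed)
#>  regime                    method   median   ci_low  ci_high replicates
#>   SPoly                 sex_ratio 50.00000       NA       NA         NA
#>   SPoly      family_size_variance 48.19672 44.79577 51.52087         99
#>   SPoly       pedigree_inbreeding 44.72273 23.65032      Inf         99
#>   SPoly temporal_allele_frequency 51.37067 38.86418 67.60764         99
```

The medians say: even though each deme holds only 10 beetles, the whole
line drifts like an ideal population of ~45–51 — close to its census of 50,
because every deme contributes a fixed quota of next-generation breeders.
(One replicate "failed": its bean sample left a deme short of one sex, a
real event under this protocol that is counted rather than hidden. The
`Inf` upper CI is a replicate with almost no realized inbreeding — the
estimator's heavy right tail, which is why medians are reported.)

Generate a synthetic medium-conflict assay (272 females across the 16
lines) from the published longevity coefficients and refit it with the
design's mixed model:

```r
rec <- generate_assay(default_models()$medium, seed = 42)
fit <- fit_model(default_model_spec(default_models()$medium), rec)
wald_tests(fit, type = "auto")
#>                         term    chisq df        p
#> 1                (Intercept) 238.8645  1 6.95e-54
#> 2              mating_system   0.5756  1 4.48e-01
#> 3                 structured   0.2174  1 6.41e-01
#> 4                 generation   4.1063  1 4.27e-02
#> 5             age_at_entry_c   0.1059  1 7.45e-01
#> 6                n_matings_c   0.0856  1 7.70e-01
#> 7                body_size_c  73.7294  1 8.96e-18
#> 8   mating_system:structured   0.6626  1 4.16e-01
#> 9  mating_system:body_size_c   8.2368  1 4.10e-03
#> 10    structured:body_size_c   0.5777  1 4.47e-01
#> test type: III
```

Coefficient estimates come from the REML fit (`fit$coefficients`), the
table above from the ML fit; `auto` chose Type III here because an
interaction term crossed p < 0.05 in this replicate. A single dataset at
this sample size has roughly 50% power for the generating regime
interaction of −3.90 days, which is why conclusions rest on
`recovery_study()` over hundreds of replicates rather than one draw.

A thin CLI wrapping the same functions ships in `inst/cli/demesim`
(subcommands `simulate`, `estimate-ne`, `generate`, `fit`, `recover`,
`pipeline`).

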