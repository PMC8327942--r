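---
title: "Breeding-protocol simulation, effective population size, and the random-slope inference design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breeding-protocol simulation, effective population size, and the random-slope inference design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demesim)
```

`demesim` models the computational core of a metapopulation x mating-system
experimental-evolution design in the seed beetle *Callosobruchus maculatus*:
a forward Monte Carlo simulator of the exact line-propagation protocol, used
for protocol-aware effective-population-size (Ne) estimation; a synthetic
generator of female fitness records with the statistical structure the
study's mixed models assume; and the inference design itself — mean-centered
covariates, by-line random intercept and slope LMMs, REML estimates with
maximum-likelihood Wald chi-square tests. This vignette explains the models,
the defaults and why they were chosen, the numerical decisions, and what the
package's simulation checks do and do not establish.

## The breeding protocol as a stochastic process

Each selection line carries 50 breeders (25 females, 25 males) per
generation. The 2x2 design crosses mating system (enforced monogamy vs.
polygamy) with metapopulation structure (one panmictic population vs. five
demes of 5 + 5 connected by migration), giving regimes labelled `NSPoly`,
`SPoly`, `NSMono`, `SMono`, four lines each. One generational cycle in
`run_line()` is:

1. **Migration** (structured lines): each deme sends one randomly chosen
   virgin female and one male to another deme along a uniformly sampled
   derangement, so every deme both sends and receives exactly one pair and
   no pair stays home. That is 2 immigrants among 10 residents per deme — a
   20% migration rate. The protocol fixes in/out degree 1 per deme but not
   the cycle structure, hence the uniform derangement.
2. **Mating**: monogamy is a uniformly random perfect matching of females to
   males within each deme. Under polygamy each female mates with `m ~
   uniform{2, 3}` distinct males of her deme; males can serve several
   females. Paternity is shared equally among a female's fertile mates by
   default; a last-male-precedence rule is available but not default, as no
   precedence value is established for these lines.
3. **Infertility** (scenario knob, default 0): each female-male pairing
   fails independently with the configured probability, and shares are
   renormalized over the fertile mates. Observed infertility in this system
   is below 3%, exposed as the 0.03 scenario preset.
4. **Egg laying and bean sampling**: each female with a fertile mate lays
   `Poisson(40)` eggs, one per bean; 150 beans per line are sampled
   uniformly without replacement, and each yields one emerging adult with
   sex assigned 50:50. Beans are ad libitum in the protocol, so there is no
   female-female competition and only the relative variance of the
   fecundity distribution matters after downsampling.
5. **Breeder collection**: the next generation's census is drawn uniformly
   without replacement from the emerged adults — per deme in structured
   lines. Emergence-day spread is collapsed into this uniform draw because
   collection in the protocol is randomized precisely to avoid selection on
   development time.

Pedigree kinship is propagated exactly (offspring inbreeding equals the
kinship of its parents; the kinship matrix advances by the standard
recursion), and 100 unlinked neutral biallelic loci are tracked with
founder allele frequency 0.5 under random union of gametes. Every run is a
pure function of `(config, seed)`; per-line and per-replicate seeds derive
deterministically from a master seed.

Occasionally (roughly 5% of 10-generation structured replicates) a deme's
share of the 150 beans contains fewer than five emerged adults of one sex;
the protocol then cannot fill that deme's census. `run_line()` raises this
as a shortfall error naming line and generation; `monte_carlo_ne()` counts
such replicates and summarizes over the rest.

## Effective population size

Four estimators are implemented:

* **Sex ratio**: `Ne = 4 Nm Nf / (Nm + Nf)` — 50 for the equal-sex default.
* **Family-size variance**: per sex, `Ne = (n k̄ - 1)/(k̄ - 1 + Vk/k̄)`,
  combined as `4 NeF NeM / (NeF + NeM)`, fed with the realized per-sex
  breeder counts per parent averaged over generations. Equalized families
  (`Vk = 0`) give ~2N; Poisson families give ~N.
* **Pedigree inbreeding**: `Ne = 1/(2 dF)` with
  `dF = 1 - ((1 - F_T)/(1 - F_b))^{1/(T-b)}` from mean pedigree inbreeding
  at the final generation `T` against a burn-in baseline `b`.
* **Temporal**: standardized drift variance
  `Fc = (p0 - pt)^2 / (p̄(1 - p̄))` averaged over segregating loci,
  `Ne = t/(2 F̄c)`, computed from founder vs. final census frequencies. The
  simulator observes true frequencies, so the sampling-correction terms of
  published temporal methods are deliberately omitted.

`monte_carlo_ne()` runs 500 replicates of 10 generations per regime by
default and reports per-method medians with 2.5–97.5 percentile intervals —
medians because the per-replicate Ne estimates have a heavy right tail (a
replicate with little realized drift gives a very large estimate).

### The burn-in for the inbreeding-rate estimator

Founders are artificially unrelated, so early pedigree inbreeding does not
reflect the asymptotic process the estimator targets. In a subdivided line
this matters a lot: with migration rate `m` and deme census `N_d`, mean
pedigree F first climbs toward a within-deme quasi-equilibrium excess
(approximately `α* ≈ 0.08` under the default 5 demes of 10 with `m = 0.2`),
approaching it at a per-generation rate of roughly
`(1 - m)^2 (1 - 1/(2 N_d)) ≈ 0.61`. Measured from generation 1, `dF` over a
10-generation horizon is dominated by this transient and *understates*
structured-regime Ne by ~40%, inverting the true regime ordering. After
five generations the transient has decayed to under 10% of its amplitude,
so `monte_carlo_ne()` defaults to a 5-generation burn-in; with it, all four
regime medians sit near the census (low-to-mid 40s for polygamy, around 50
for monogamy) and the structured regimes come out slightly higher, as the
underlying drift process implies. `ne_from_inbreeding()` itself keeps
`burn_in = 1` as its generic default for logs without internal structure.

### Which estimator for which question

The drift-based estimators (pedigree, temporal) answer "how fast is this
line losing variation"; their medians carry Monte Carlo noise of a couple
of individuals at 500 replicates, and the pedigree estimator retains a
small (~7%) downward residual-transient bias for structured regimes at the
10-generation horizon. The family-size-variance estimator measures the same
realized breeding inequality almost deterministically (its median varies by
less than 0.5 across master seeds). Directional regime comparisons — does
subdivision or enforced monogamy raise Ne? — are therefore checked on the
family-size estimator, whose orderings (SMono > NSMono, SPoly > NSPoly,
monogamy > polygamy within structure, margins of 4–8 individuals) agree
with the temporal estimator. The envelope check (most regime medians
between 41 and 51) uses the pedigree estimator at its defaults.

Mechanistically, polygamy lowers Ne because male mating success is
unequal (a male drawn by 2–3 females compounds into overdispersed
paternity), while subdivision raises it because each deme contributes
exactly its quota of breeders, which caps between-family variance at the
line level — the same reason migrant quotas equalize lineage contributions.

## The synthetic fitness generator

`generative_model` presets in `default_models()` carry the published
fixed-effect (REML) coefficient vectors for each assay and response:
single-mating assays (low conflict, harm and resistance perspectives),
the variable-mating-rate assay (medium conflict; longevity only, since
those females had no oviposition substrate), and lifelong-cohabitation
assays (extreme conflict). A record is generated as

```
response = β'x(centered covariates, regime indicators) + b0_line + ε
```

with `b0_line ~ N(0, sd_line)`, optional by-line random slopes, and `ε`
drawn jointly with the companion fitness trait's residual at correlation
`trade_off_rho` — the cost-of-reproduction channel that makes longevity and
reproductive output negatively associated within lines.

Unprinted quantities carry documented defaults, chosen once as plausible
for this system and not revisited:

* line intercept SD = 10% of the intercept magnitude (2.4 days for the
  medium assay, ~300 on the LRS coefficient scale);
* residual SD = 4 days for longevity responses, 800 for LRS-scale
  responses; random-slope SDs default to 0;
* `trade_off_rho = -0.3`;
* elytron length ~ N(1.9 mm, 0.1 mm) for both sexes; age at entry 1–3
  days; the medium assay generates 7 females per line at the earlier
  generation (12 mating opportunities) and 10 at the later one (10
  opportunities), 272 records in total against the study's 262 analyzed
  (the generator does not model the handful of exclusions);
* mating counts lose 0–2 opportunities at random (rate 0.1 per
  opportunity pair), which keeps the mating-count covariate from being
  perfectly aliased with the generation indicator.

One scale subtlety: the published LRS-response models analyzed squared
LRS — hence intercepts in the thousands — while the longevity models use
raw LRS counts as a covariate. Each preset therefore generates its
*response* on the printed coefficient scale and the *companion* trait on
its raw assay scale; the squared-back-transform is deliberately not
applied, since inverting printed coefficients through a square is
ambiguous. Covariates are stored raw in the records; centering is an
analysis step, and the generator's linear predictor centers at the known
generative means, so generated and fitted intercepts agree.

## The inference design

`fit_model()` reproduces the analysis protocol: treatment indicators with
monogamy and no-structure as reference levels, covariates mean-centered
(`center_covariates()`), a by-line random intercept plus a random slope for
centered female body size (control covariates — age, generation, mating
count — never receive slopes), intercept–slope correlations included, and
the estimate/test split: coefficients reported from REML fits, Wald
chi-square tables computed on ML fits. If the correlated random structure
fails to converge, the model is refitted with correlations removed and
flagged `correlations_dropped` — the published tables report exactly this
fallback for several models. Singular fits (a variance component estimated
at zero, which is expected when generating with zero slope variance) are
reported, not treated as failures.

`wald_tests()` computes Type II or Type III Wald chi-square tables (via
`car::Anova` on the ML fit) and implements the selection rule: `auto`
computes the Type III table first and keeps it if any interaction term has
p < 0.05, otherwise reports Type II. Tests are computed in the indicator
parameterization — the same convention as the published tables, whose main
effects are simple effects at the reference levels — rather than after
re-coding to centered contrasts; the interaction term, the only one any
calibration check uses, is identical under either convention. P-values are
asymptotic chi-square with 1 df and no small-sample correction, matching
the reported tests.

`recovery_study()` closes the loop: generate → fit → test over seeded
replicates, reporting per-coefficient bias, RMSE, and 95% CI coverage
against the generating values, plus the interaction's rejection rate. With
the treatment-null generator it doubles as a type-I-error harness — and
that harness exposes a real cost of the ML-testing convention at this
design size. The regime interaction is identified from only 16 lines, and
the four regime parameters consume line-level degrees of freedom that ML
(unlike REML) does not account for, so the ML variance components are
biased downward and the interaction's Wald z is overdispersed (its null SD
is ~1.25 rather than 1 here). The type-I-error study therefore measures a
null rejection rate well above the nominal 0.05 — roughly double — for the
ML-based test, while the identical Wald statistic computed from the REML
fit is close to nominal. The package keeps the published convention (tests
on ML fits) and reports the calibration study's rate rather than hiding
it; anyone applying this design to 16-line data should read the
interaction's p-value with that inflation in mind, or compute the Wald
table from the REML fit. The random slopes guard against a different
problem — pseudo-replication from by-line covariate-effect heterogeneity —
and do not address this small-sample ML bias.

## Problem sizes and reproducibility

The package's own checks run at the scales the analyses use: 500
replicates x 10 generations per regime for Ne (a few minutes on one core),
200 replicates for coefficient recovery at the published sample sizes, and
1,000 replicates for test calibration. All randomness flows from explicit
master seeds through documented per-line/per-replicate derivation;
`run_pipeline()` records seeds, config fingerprints (order-invariant MD5
of the canonicalized config), package version, and outputs in a JSON
manifest, and re-running a plan with the same seed reproduces identical
CSVs.

## What the checks show — and what they do not

Passing recovery and calibration checks show that the *design* — this
generator plus this estimator — is unbiased and near-nominally calibrated
under the generator's assumptions: Gaussian residuals, linear covariate
effects, exchangeable lines. They do not validate those assumptions for
real assay data: true LRS is an overdispersed count, longevity is
right-skewed with possible censoring, lines may differ in residual
variance, and real covariates are not independent of regime. Similarly,
the simulator reproduces the protocol's drift process, not the biology it
selects on: no fitness variation among genotypes, no harm/resistance
dynamics, no egg-to-adult mortality, no overlapping generations — these
are out of scope by design, so its Ne estimates quantify the neutral
consequences of the breeding scheme only.
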