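Package: demesim
Title: Breeding-Design Simulation, Effective Population Size, and
    Random-Slope Mixed-Model Inference for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Monte Carlo simulation of line-propagation protocols used
    in experimental evolution of the seed beetle Callosobruchus maculatus,
    covering a 2x2 design of mating system (enforced monogamy vs. polygamy)
    and metapopulation structure (one panmictic population vs. five demes
    connected by a 20% migration rate). Tracks pedigrees and neutral loci to
    estimate effective population size (Ne) with sex-ratio, family-size
    variance, pedigree-inbreeding, and temporal allele-frequency estimators,
    including infertile-mating scenarios. Also provides a synthetic generator
    of female fitness records (longevity, lifetime reproductive success, body
    size) with line-level random effects and a longevity-fecundity trade-off,
    and the matching inference design: mean-centered covariates, by-line
    random intercept and slope linear mixed models, REML estimates with
    maximum-likelihood Wald chi-square tests (Type II, or Type III when
    interactions are significant), plus parameter-recovery and type-I-error
    simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
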