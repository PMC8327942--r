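# Shared fixtures: small configurations and hand-built rosters used across
# test files. Everything is generated in code; no stored data.

default_regimes <- function() {
  list(NSMono = build_regime("monogamy", FALSE),
       SMono  = build_regime("monogamy", TRUE),
       NSPoly = build_regime("polygamy", FALSE),
       SPoly  = build_regime("polygamy", TRUE))
}

# near-ideal Wright-Fisher conditions: one panmictic deme, wide polygamy,
# Poisson-family offspring pool
wf_config <- function(...) {
  build_regime("polygamy", FALSE,
               overrides = list(mates_per_female = c(10L, 10L), ...))
}

# a two-breeder roster whose kinship matrix is set by hand (for pedigree
# arithmetic checks); ids 1 (F) and 2 (M)
tiny_roster <- function(kin12, config = build_regime("monogamy", FALSE,
                          overrides = list(females_per_deme = 1L,
                                           males_per_deme = 1L,
                                           beans_per_line = 10L))) {
  r <- init_population(config, "tiny", seed = 1)
  r$kin[1, 2] <- r$kin[2, 1] <- kin12
  r
}

# synthetic pedigree log with a prescribed mean-F trajectory
fake_log <- function(f_by_gen) {
  G <- length(f_by_gen) - 1L
  structure(list(
    summary = data.frame(generation = 0:G, n_breeders = 50L,
                         mean_f_ped = f_by_gen, mean_het = NA_real_,
                         kbar_f = NA_real_, vk_f = NA_real_,
                         kbar_m = NA_real_, vk_m = NA_real_),
    freq = matrix(0.5, nrow = G + 1L, ncol = 2L),
    config = build_regime("monogamy", FALSE), line_id = "fake", seed = 0L),
    class = "pedigree_log")
}
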