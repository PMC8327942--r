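test_that("closed-form estimators match their defining formulas", {
  expect_equal(ne_sex_ratio(25, 25), 50)
  expect_equal(ne_sex_ratio(10, 10), 20)
  expect_equal(ne_sex_ratio(1, 25), 100 / 26)
  expect_error(ne_sex_ratio(0, 25), "at least one")

  # equalized families double Ne; Poisson families recover the census
  expect_equal(ne_family_size(25, 2, 0), 49)
  expect_equal(ne_family_size(25, 2, 2), 24.5)
  expect_equal(ne_family_size(25, 2, 6), 49 / 4)
  expect_equal(combine_sexes(49, 49), 98)
  expect_equal(combine_sexes(24.5, 24.5), 49)
  expect_error(ne_family_size(25, 0, 2), "k_bar")
})

test_that("the inbreeding estimator inverts the defining recurrence", {
  # F_t = 1 - (1 - 1/100)^t corresponds to Ne = 50 at any burn-in
  f <- 1 - (1 - 1 / 100)^(0:10)
  expect_equal(ne_from_inbreeding(fake_log(f), burn_in = 1), 50)
  expect_equal(ne_from_inbreeding(fake_log(f), burn_in = 5), 50)
  # no accrual: infinite Ne
  expect_identical(ne_from_inbreeding(fake_log(rep(0, 11))), Inf)
  expect_error(ne_from_inbreeding(fake_log(c(0, 0, 0)), burn_in = 5),
               "at least")
})

test_that("the temporal estimator matches hand evaluation and edge cases", {
  expect_identical(ne_temporal(c(0.4, 0.6), c(0.4, 0.6), t = 5), Inf)
  # single locus: Fc = 0.01 / 0.2475, Ne = t / (2 Fc)
  expect_equal(ne_temporal(0.5, 0.6, t = 1), 0.2475 / 0.02, tolerance = 1e-10)
  expect_equal(ne_temporal(0.5, 0.6, t = 1), 12.375)
  expect_error(ne_temporal(c(0, 1), c(0, 1), t = 2), "fixed")
  expect_error(ne_temporal(c(0.5, 0.5), 0.5, t = 1), "equal length")
})

test_that("pedigree and temporal estimators agree near Wright-Fisher", {
  # reduced scale here; the full 500-replicate check lives in the
  # acceptance suite
  cfg <- wf_config(neutral_loci = 60L)
  mc <- monte_carlo_ne(cfg, replicates = 80, seed = 99)
  ped <- mc$summary$median[mc$summary$method == "pedigree_inbreeding"]
  tmp <- mc$summary$median[mc$summary$method == "temporal_allele_frequency"]
  expect_lt(abs(ped - tmp) / ped, 0.25)
  expect_lt(abs(ped - 50) / 50, 0.2)
  expect_lt(abs(tmp - 50) / 50, 0.2)
  # the percentile CI brackets the median
  s <- mc$summary[mc$summary$method == "pedigree_inbreeding", ]
  expect_lte(s$ci_low, s$median)
  expect_gte(s$ci_high, s$median)
})

test_that("monte_carlo_ne validates inputs and is seed-reproducible", {
  cfg <- build_regime("monogamy", FALSE, list(neutral_loci = 10L,
                                              n_generations = 8L))
  expect_error(monte_carlo_ne(cfg, replicates = 1), "replicates")
  a <- monte_carlo_ne(cfg, replicates = 5, seed = 3)
  b <- monte_carlo_ne(cfg, replicates = 5, seed = 3)
  expect_identical(a$summary, b$summary)
})

test_that("infertility scenarios share seeds and depress monogamous Ne", {
  cfg <- build_regime("monogamy", FALSE, list(neutral_loci = 20L))
  tab <- infertility_scenario(cfg, rates = c(0, 0), replicates = 4, seed = 5)
  ped <- tab[tab$method == "pedigree_inbreeding", ]
  expect_equal(ped$median[1], ped$median[2])

  # at a high rate the loss of whole monogamous pairs must cut Ne: the
  # direction is unambiguous at rate 0.5 (the simulator is its own oracle
  # for the small observed-rate effect)
  tab2 <- infertility_scenario(cfg, rates = c(0, 0.5), replicates = 30,
                               seed = 8)
  ped2 <- tab2[tab2$method == "pedigree_inbreeding", ]
  expect_lt(ped2$median[ped2$rate == 0.5], ped2$median[ped2$rate == 0])

  # rate 1: every replicate fails by shortfall, summarized rather than raised
  tab3 <- infertility_scenario(cfg, rates = 1, replicates = 3, seed = 9)
  expect_equal(unique(tab3$n_failed), 3L)
  expect_true(all(is.na(tab3$median[tab3$method == "pedigree_inbreeding"])))
})

test_that("doubling the census roughly doubles protocol Ne", {
  small <- build_regime("monogamy", FALSE,
                        list(neutral_loci = 30L, n_generations = 8L))
  big <- build_regime("monogamy", FALSE,
                      list(females_per_deme = 50L, males_per_deme = 50L,
                           beans_per_line = 300L, neutral_loci = 30L,
                           n_generations = 8L))
  ne_s <- monte_carlo_ne(small, replicates = 60, seed = 21, burn_in = 3)
  ne_b <- monte_carlo_ne(big, replicates = 60, seed = 21, burn_in = 3)
  ratio <- ne_b$summary$median[ne_b$summary$method == "pedigree_inbreeding"] /
    ne_s$summary$median[ne_s$summary$method == "pedigree_inbreeding"]
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})
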