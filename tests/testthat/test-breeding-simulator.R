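test_that("founders fill the census, are unrelated, and start at p ~ 0.5", {
  cfg <- build_regime("monogamy", TRUE, list(neutral_loci = 200L))
  r <- init_population(cfg, "L1", seed = 42)
  ind <- r$individuals
  expect_equal(nrow(ind), 50L)
  expect_equal(as.integer(table(ind$deme)), rep(10L, 5L))
  expect_true(all(table(ind$deme, ind$sex) == 5L))
  expect_true(all(ind$f_ped == 0))
  expect_true(all(is.na(ind$dam_id)))
  # per-locus frequency is binomial over 100 allele copies: SE ~ 0.05;
  # the mean over 200 loci has SE ~ 0.0035
  p <- demesim:::roster_allele_freq(r)
  expect_lt(abs(mean(p) - 0.5), 0.015)
  expect_lt(abs(stats::sd(p) - 0.05), 0.02)
})

test_that("migration relocates exactly one pair per deme along a derangement", {
  cfg <- build_regime("monogamy", TRUE)
  for (s in 1:20) {
    r <- init_population(cfg, "L1", seed = s)
    before <- r$individuals$deme
    m <- demesim:::with_seed(s + 100, migrate(r))
    ind <- m$individuals
    # census and sex ratio unchanged
    expect_true(all(table(ind$deme, ind$sex) == 5L))
    # every deme holds exactly 1 immigrant of each sex: 20% of residents
    imm <- table(factor(ind$deme[ind$is_migrant], levels = 0:4),
                 ind$sex[ind$is_migrant])
    expect_true(all(imm == 1L))
    expect_equal(sum(ind$is_migrant) / nrow(ind), 0.2)
    # migrants really moved (no pair stayed home)
    expect_true(all(ind$deme[ind$is_migrant] != before[ind$is_migrant]))
  }
  expect_error(migrate(init_population(build_regime("monogamy", FALSE),
                                       seed = 1)), "structured")
})

test_that("monogamy mates every breeder exactly once as a perfect matching", {
  cfg <- build_regime("monogamy", FALSE)
  r <- init_population(cfg, "L1", seed = 7)
  ev <- demesim:::with_seed(8, form_matings(r))
  expect_length(ev, 25L)
  males <- vapply(ev, function(e) e$male_ids, integer(1))
  females <- vapply(ev, function(e) e$female_id, integer(1))
  expect_equal(sort(males), sort(r$individuals$id[r$individuals$sex == "M"]))
  expect_equal(sort(females),
               sort(r$individuals$id[r$individuals$sex == "F"]))
})

test_that("polygamous females receive 2-3 distinct males from their own deme", {
  cfg <- build_regime("polygamy", FALSE)
  r <- init_population(cfg, "L1", seed = 3)
  ev <- demesim:::with_seed(4, form_matings(r))
  slots <- sum(lengths(lapply(ev, `[[`, "male_ids")))
  expect_gte(slots, 50L)
  expect_lte(slots, 75L)

  cfg3 <- build_regime("polygamy", TRUE,
                       list(mates_per_female = c(3L, 3L)))
  r3 <- init_population(cfg3, "L1", seed = 5)
  ev3 <- demesim:::with_seed(6, form_matings(r3))
  for (e in ev3) {
    expect_length(e$male_ids, 3L)
    expect_equal(anyDuplicated(e$male_ids), 0L)
    demes <- r3$individuals$deme[match(c(e$female_id, e$male_ids),
                                       r3$individuals$id)]
    expect_equal(length(unique(demes)), 1L)
    expect_equal(sum(e$paternity_shares), 1)
  }
})

test_that("infertility flags follow the configured Bernoulli rate", {
  cfg <- build_regime("polygamy", FALSE)
  r <- init_population(cfg, "L1", seed = 1)
  ev <- demesim:::with_seed(2, form_matings(r))
  ev0 <- demesim:::with_seed(3, apply_infertility(ev, 0))
  expect_true(all(unlist(lapply(ev0, `[[`, "fertile"))))
  ev1 <- demesim:::with_seed(3, apply_infertility(ev, 1))
  expect_false(any(unlist(lapply(ev1, `[[`, "fertile"))))
  expect_error(apply_infertility(ev, -0.1), "\\[0, 1\\]")

  # 10,000 pairings at rate 0.03: infertile count within the binomial
  # 99.9% interval [245, 358] (qbinom at 0.0005 / 0.9995)
  many <- rep(list(list(female_id = 1L, male_ids = c(2L, 3L),
                        fertile = c(TRUE, TRUE),
                        paternity_shares = c(0.5, 0.5))), 5000L)
  flagged <- demesim:::with_seed(11, apply_infertility(many, 0.03))
  n_inf <- sum(!unlist(lapply(flagged, `[[`, "fertile")))
  expect_gte(n_inf, 245L)
  expect_lte(n_inf, 358L)
})

test_that("bean sampling yields the configured cohort and pedigree F", {
  cfg <- build_regime("monogamy", FALSE)
  r <- init_population(cfg, "L1", seed = 9)
  ev <- demesim:::with_seed(10, form_matings(r))
  pool <- demesim:::with_seed(11, produce_offspring(r, ev))
  expect_equal(nrow(pool$individuals), 150L)
  expect_equal(pool$individuals$generation, rep(1L, 150L))

  # a dam-sire pair with kinship 0.25 (full sibs from unrelated
  # grandparents) gives offspring F_ped = 0.25
  tr <- tiny_roster(0.25)
  ev2 <- list(list(female_id = 1L, male_ids = 2L, fertile = TRUE,
                   paternity_shares = 1))
  pool2 <- demesim:::with_seed(12, produce_offspring(tr, ev2))
  expect_true(all(pool2$individuals$f_ped == 0.25))

  # equal paternity shares split eggs evenly: binomial 99% interval
  cfgp <- build_regime("polygamy", FALSE,
                       list(fecundity_mean = 10000, beans_per_line = 9000L))
  rp <- init_population(cfgp, "L1", seed = 13)
  fem <- rp$individuals$id[rp$individuals$sex == "F"][1]
  mal <- rp$individuals$id[rp$individuals$sex == "M"][1:2]
  ev3 <- list(list(female_id = fem, male_ids = mal,
                   fertile = c(TRUE, TRUE), paternity_shares = c(0.5, 0.5)))
  pool3 <- demesim:::with_seed(14, produce_offspring(rp, ev3,
                                                     sample_beans = FALSE))
  share <- mean(pool3$individuals$sire_id == mal[1])
  n <- nrow(pool3$individuals)
  expect_gt(share, qbinom(0.005, n, 0.5) / n)
  expect_lt(share, qbinom(0.995, n, 0.5) / n)
})

test_that("breeder collection fills the census or fails loudly", {
  cfg <- build_regime("monogamy", FALSE)
  r <- init_population(cfg, "L1", seed = 20)
  ev <- demesim:::with_seed(21, form_matings(r))
  pool <- demesim:::with_seed(22, produce_offspring(r, ev))
  sel <- demesim:::with_seed(23, select_breeders(pool))
  expect_equal(sum(sel$individuals$sex == "F"), 25L)
  expect_equal(sum(sel$individuals$sex == "M"), 25L)

  # a pool of exactly the required census is selected as the identity set
  pool_exact <- pool
  f_idx <- which(pool$individuals$sex == "F")[1:25]
  m_idx <- which(pool$individuals$sex == "M")[1:25]
  keep <- sort(c(f_idx, m_idx))
  pool_exact$individuals <- pool$individuals[keep, ]
  pool_exact$geno <- list(a1 = pool$geno$a1[, keep], a2 = pool$geno$a2[, keep])
  sel2 <- demesim:::with_seed(24, select_breeders(pool_exact))
  expect_setequal(sel2$individuals$id, pool_exact$individuals$id)

  # missing a sex in a deme is a shortfall error
  pool_short <- pool_exact
  pool_short$individuals <- pool_exact$individuals[
    pool_exact$individuals$sex == "F", ]
  expect_error(demesim:::with_seed(25, select_breeders(pool_short)),
               "shortfall")
})

test_that("runs are reproducible and keep the census constant", {
  cfg <- build_regime("monogamy", FALSE, list(neutral_loci = 20L))
  a <- run_line(cfg, "L1", seed = 31)
  b <- run_line(cfg, "L1", seed = 31)
  expect_identical(a$summary, b$summary)
  expect_identical(a$freq, b$freq)
  expect_true(all(a$summary$n_breeders == 50L))
  expect_false(identical(a$freq, run_line(cfg, "L1", seed = 32)$freq))
})

test_that("allele frequencies are a martingale when all offspring are kept", {
  cfg <- build_regime("polygamy", FALSE,
                      list(females_per_deme = 5L, males_per_deme = 5L,
                           neutral_loci = 25L, mates_per_female = c(2L, 3L)))
  dp <- demesim:::with_seed(77, {
    unlist(lapply(1:300, function(r) {
      ros <- init_population(cfg, "L1")
      ev <- form_matings(ros)
      pool <- produce_offspring(ros, ev, sample_beans = FALSE)
      p0 <- demesim:::roster_allele_freq(ros)
      p1 <- 0.5 * (rowMeans(pool$geno$a1) + rowMeans(pool$geno$a2))
      p1 - p0
    }))
  })
  expect_lt(abs(mean(dp)), 3 * stats::sd(dp) / sqrt(length(dp)))
})

test_that("expected heterozygosity decays in structured and unstructured runs", {
  # Monte Carlo property: H declines on average, not per replicate
  for (cfg in list(build_regime("monogamy", FALSE, list(neutral_loci = 30L)),
                   build_regime("polygamy", TRUE, list(neutral_loci = 30L)))) {
    drop <- vapply(1:25, function(r) {
      log <- tryCatch(run_line(cfg, "L", seed = 1000 + r),
                      error = function(e) NULL)
      if (is.null(log)) return(NA_real_)
      s <- log$summary
      s$mean_het[1] - s$mean_het[nrow(s)]
    }, numeric(1))
    expect_gt(mean(drop, na.rm = TRUE), 0)
  }
})

test_that("pedigree logs export to tidy CSV with JSON metadata", {
  cfg <- build_regime("monogamy", FALSE,
                      list(neutral_loci = 10L, n_generations = 4L))
  log <- run_line(cfg, "L1", seed = 5, keep_pedigree = TRUE)
  dir <- withr::local_tempdir()
  paths <- write_pedigree_log(log, dir)
  expect_true(all(file.exists(paths)))
  summ <- utils::read.csv(paths[1])
  expect_equal(nrow(summ), 5L)
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$seed, 5L)
  expect_equal(meta$config$beans_per_line, 150L)
  ped <- utils::read.csv(paths[4])
  expect_equal(nrow(ped), 50L * 5L)
})
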