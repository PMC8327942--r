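test_that("covariate centering is exact, idempotent, and guarded", {
  d <- data.frame(x = c(1, 2, 3), line_id = "a")
  out <- center_covariates(d, "x")
  expect_equal(out$x_c, c(-1, 0, 1))
  expect_equal(out$x, c(1, 2, 3)) # original preserved
  # centering an already-centered column changes nothing
  out2 <- center_covariates(out, "x_c")
  expect_equal(out2$x_c_c, out$x_c)
  expect_warning(center_covariates(data.frame(z = rep(2, 5)), "z"),
                 "constant")
  expect_error(center_covariates(d, "missing_col"), "not found")
  expect_error(center_covariates(data.frame(s = letters[1:3]), "s"),
               "not numeric")
})

test_that("control covariates are refused random slopes", {
  expect_error(model_spec("longevity", "mating_system",
                          random_slopes = "n_matings_c"), "control")
})

test_that("a noiseless dataset is interpolated exactly", {
  m <- generative_model(
    "medium", "longevity",
    beta = c(intercept = 20, ms = 2, struct = 3, "ms:struct" = -4),
    sd_line = 0, sd_resid = 1e-3, trade_off_rho = 0)
  rec <- generate_assay(m, n_per_line = 4L, seed = 7)
  spec <- model_spec("longevity",
                     c("mating_system", "structured",
                       "mating_system:structured"))
  fit <- fit_model(spec, rec)
  cf <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(cf["(Intercept)"]), 20, tolerance = 1e-3)
  expect_equal(unname(cf["mating_systempolygamy"]), 2, tolerance = 1e-3)
  expect_equal(unname(cf["structuredyes"]), 3, tolerance = 1e-3)
  expect_equal(unname(cf["mating_systempolygamy:structuredyes"]), -4,
               tolerance = 1e-3)
})

test_that("estimates come from REML and Wald tables from ML", {
  rec <- generate_assay(default_models()$medium, seed = 9)
  spec <- default_model_spec(default_models()$medium)
  fit <- fit_model(spec, rec)
  expect_equal(unique(fit$coefficients$source), "REML")
  expect_true(lme4::isREML(fit$reml))
  expect_false(lme4::isREML(fit$ml))
  # REML-only fits refuse to produce Wald tables
  fit_reml <- fit_model(spec, rec, estimation = "REML")
  expect_error(wald_tests(fit_reml), "ML")
})

test_that("Wald statistics equal the quadratic-form oracle", {
  rec <- generate_assay(default_models()$medium, seed = 15)
  fit <- fit_model(default_model_spec(default_models()$medium), rec)
  wt3 <- wald_tests(fit, type = "III")
  # independent hand computation for the interaction from the ML fit
  b <- lme4::fixef(fit$ml)
  V <- as.matrix(stats::vcov(fit$ml))
  term <- "mating_systempolygamy:structuredyes"
  chisq_hand <- b[term]^2 / V[term, term]
  row <- wt3[wt3$term == "mating_system:structured", ]
  expect_equal(row$chisq, unname(chisq_hand), tolerance = 1e-8)
  expect_equal(row$df, 1L)
  expect_equal(row$p,
               stats::pchisq(unname(chisq_hand), 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # a 1-df term with estimate b and SE s gives chisq (b/s)^2; check the
  # tail-probability mapping at chisq = 4 -> p ~ 0.0455
  expect_equal(stats::pchisq(4, 1, lower.tail = FALSE), 0.0455,
               tolerance = 5e-4)
})

test_that("Type II and Type III agree on the highest-order term", {
  rec <- generate_assay(default_models()$medium, seed = 17)
  fit <- fit_model(default_model_spec(default_models()$medium), rec)
  t2 <- wald_tests(fit, type = "II")
  t3 <- wald_tests(fit, type = "III")
  # the treatment x covariate interactions are the model's maximal terms
  for (trm in c("mating_system:body_size_c", "structured:body_size_c"))
    expect_equal(t2$chisq[t2$term == trm], t3$chisq[t3$term == trm],
                 tolerance = 1e-8)
})

test_that("the auto rule selects Type III exactly when an interaction is significant", {
  m <- default_models()$medium
  spec <- default_model_spec(m)
  # strong interaction: III must be chosen (power check over replicates)
  m_strong <- m
  m_strong$beta["ms:struct"] <- -12
  picks <- vapply(1:12, function(r) {
    rec <- generate_assay(m_strong, seed = demesim:::derive_seed(60, r))
    attr(wald_tests(fit_model(spec, rec), "auto"), "test_type")
  }, character(1))
  expect_gt(mean(picks == "III"), 0.9)
  # and the choice is consistent with the replicate's own Type III table
  rec <- generate_assay(m, seed = 61)
  fit <- fit_model(spec, rec)
  t3 <- wald_tests(fit, "III")
  auto <- wald_tests(fit, "auto")
  has_sig_inter <- any(t3$p[grepl(":", t3$term)] < 0.05)
  expect_identical(attr(auto, "test_type"), if (has_sig_inter) "III" else "II")
})

test_that("dropping correlations simplifies the random structure", {
  rec <- generate_assay(default_models()$medium, seed = 19)
  spec <- default_model_spec(default_models()$medium)
  spec$correlations <- FALSE
  fit <- fit_model(spec, rec, estimation = "REML")
  vc <- as.data.frame(fit$varcorr)
  # no correlation rows between intercept and slope
  expect_false(any(!is.na(vc$var2)))
  full <- fit_model(default_model_spec(default_models()$medium), rec,
                    estimation = "REML")
  if (!full$correlations_dropped) {
    vc_full <- as.data.frame(full$varcorr)
    expect_gte(nrow(vc_full), nrow(vc))
  }
})

test_that("recovery studies validate inputs and count failures", {
  m <- default_models()$medium
  expect_error(recovery_study(m, replicates = 1), "replicates")
  rs <- recovery_study(m, replicates = 4, seed = 3, tests = FALSE)
  expect_equal(rs$n_failed, 0L)
  expect_true("mating_systempolygamy:structuredyes" %in% rs$summary$term)
  row <- rs$summary[rs$summary$term == "mating_systempolygamy:structuredyes", ]
  expect_equal(row$truth, -3.90)
  # reproducible
  rs2 <- recovery_study(m, replicates = 4, seed = 3, tests = FALSE)
  expect_identical(rs$summary, rs2$summary)
})
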