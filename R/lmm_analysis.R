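#' The random-slope mixed-model inference design
#'
#' Implements the analysis protocol applied to every fitness assay:
#' covariates mean-centered; linear mixed models with a by-line random
#' intercept plus random slopes for the covariate of interest (control
#' covariates never receive slopes); intercept-slope correlations included
#' unless the full model fails to converge, in which case they are dropped;
#' parameter estimates from REML fits and Wald chi-square tests computed on
#' maximum-likelihood fits, Type II by default and Type III when an
#' interaction is significant.
#'
#' @name lmm_analysis
NULL

#' Mean-center covariates
#'
#' Subtracts the grand mean from each named covariate, storing the result
#' in a new `<name>_c` column; the original columns are preserved. A
#' zero-variance covariate centers to all zeros with a warning.
#'
#' @param records a data frame.
#' @param covariates character vector of numeric column names.
#' @return the data frame with `<name>_c` columns appended.
#' @export
center_covariates <- function(records, covariates) {
  for (v in covariates) {
    if (!v %in% names(records))
      stop("covariate not found in records: ", v, call. = FALSE)
    x <- records[[v]]
    if (!is.numeric(x))
      stop("covariate is not numeric: ", v, call. = FALSE)
    if (stats::var(x, na.rm = TRUE) == 0)
      warning("covariate '", v, "' is constant; centered column is all zero",
              call. = FALSE)
    records[[paste0(v, "_c")]] <- x - mean(x, na.rm = TRUE)
  }
  records
}

#' Specify a mixed model in the assay design's vocabulary
#'
#' @param response response column (`"longevity"` or `"lrs"`).
#' @param fixed character vector of fixed-effect terms in formula syntax
#'   (referring to record columns, centered covariates as `<name>_c`).
#' @param center covariate columns to mean-center before fitting.
#' @param random_slopes covariate terms receiving by-line random slopes
#'   (control covariates such as age, generation, and mating count must not
#'   appear here).
#' @param correlations include intercept-slope correlations (dropped
#'   automatically on non-convergence).
#' @param group grouping column for the random effects (default the
#'   selection line).
#' @return a `model_spec`.
#' @export
model_spec <- function(response, fixed, center = character(0),
                       random_slopes = character(0), correlations = TRUE,
                       group = "line_id") {
  control <- c("age_at_entry_c", "generation", "n_matings_c")
  bad <- intersect(random_slopes, control)
  if (length(bad))
    stop("control covariates never receive random slopes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(response = response, fixed = fixed, center = center,
                 random_slopes = random_slopes,
                 correlations = isTRUE(correlations), group = group),
            class = "model_spec")
}

#' Default analysis specification for a generative model
#'
#' Mirrors the generative model's fixed-effect structure: regime indicators
#' and their interaction, centered covariates, treatment x covariate
#' second-order terms, and a by-line random intercept plus a random slope
#' for centered female body size.
#'
#' @param model a [generative_model()].
#' @return a [model_spec()].
#' @export
default_model_spec <- function(model) {
  stopifnot(inherits(model, "generative_model"))
  nm <- names(model$beta)
  cross_col <- if (model$response == "longevity") "lrs" else "longevity"
  map <- c(ms = "mating_system", struct = "structured",
           "ms:struct" = "mating_system:structured",
           female_size = "body_size_c", male_size = "male_size_c",
           cross = paste0(cross_col, "_c"), age = "age_at_entry_c",
           generation = "generation", matings = "n_matings_c",
           "ms:female_size" = "mating_system:body_size_c",
           "ms:male_size" = "mating_system:male_size_c",
           "ms:cross" = paste0("mating_system:", cross_col, "_c"),
           "struct:female_size" = "structured:body_size_c",
           "struct:male_size" = "structured:male_size_c",
           "struct:cross" = paste0("structured:", cross_col, "_c"))
  fixed <- unname(map[setdiff(nm, "intercept")])
  center <- character(0)
  if ("female_size" %in% nm) center <- c(center, "body_size")
  if ("male_size" %in% nm) center <- c(center, "male_size")
  if ("cross" %in% nm) center <- c(center, cross_col)
  if ("age" %in% nm) center <- c(center, "age_at_entry")
  if ("matings" %in% nm) center <- c(center, "n_matings")
  slopes <- if ("female_size" %in% nm) "body_size_c" else character(0)
  model_spec(response = model$response, fixed = fixed, center = center,
             random_slopes = slopes)
}

spec_formula <- function(spec) {
  bar <- if (length(spec$random_slopes)) {
    paste("1 +", paste(spec$random_slopes, collapse = " + "))
  } else "1"
  op <- if (spec$correlations) "|" else "||"
  stats::as.formula(paste(
    spec$response, "~", paste(spec$fixed, collapse = " + "),
    "+ (", bar, op, spec$group, ")"))
}

prepare_records <- function(spec, records) {
  if (!spec$response %in% names(records))
    stop("response column '", spec$response, "' not found", call. = FALSE)
  records <- records[!is.na(records[[spec$response]]), , drop = FALSE]
  records$mating_system <- factor(records$mating_system,
                                  levels = c("monogamy", "polygamy"))
  records$structured <- factor(ifelse(records$structured, "yes", "no"),
                               levels = c("no", "yes"))
  if ("generation" %in% names(records))
    records$generation <- factor(records$generation)
  center_covariates(records, spec$center)
}

lmm_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  code <- fit@optinfo$conv$opt
  conv_fail <- any(grepl("failed to converge|unable to evaluate|degenerate",
                         msgs, ignore.case = TRUE))
  isTRUE(code == 0) && !conv_fail
}

fit_one <- function(formula, data, reml) {
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore")),
    warning = function(w) {
      if (grepl("converge|Hessian|gradient", conditionMessage(w),
                ignore.case = TRUE))
        invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
}

#' Fit the design's mixed model
#'
#' Fits the specified model by REML (for coefficient estimates) and/or ML
#' (for Wald tests), after mean-centering the specified covariates. If the
#' full random structure with intercept-slope correlations fails to
#' converge, the model is refitted with the correlations removed and the
#' result flagged `correlations_dropped`. Singular fits (a variance
#' estimated at zero) are reported, not treated as failures.
#'
#' @param spec a [model_spec()].
#' @param records a data frame of fitness records.
#' @param estimation `"both"` (default), `"REML"`, or `"ML"`.
#' @return a `lmm_fit`: list with `reml` and/or `ml` (merMod fits),
#'   `coefficients` (REML fixed-effect estimates and SEs; from the ML fit
#'   if REML was not requested), `varcorr`, `converged`,
#'   `correlations_dropped`, `spec`, and `data` (the prepared records).
#' @export
fit_model <- function(spec, records, estimation = c("both", "REML", "ML")) {
  estimation <- match.arg(estimation)
  stopifnot(inherits(spec, "model_spec"))
  dat <- prepare_records(spec, records)
  if (length(unique(dat[[spec$group]])) < 2L)
    stop("need at least 2 groups (lines) for a mixed model", call. = FALSE)
  want <- c(REML = estimation %in% c("both", "REML"),
            ML = estimation %in% c("both", "ML"))
  fits <- list(reml = NULL, ml = NULL)
  dropped <- FALSE
  for (crit in c("reml", "ml")[c(want[["REML"]], want[["ML"]])]) {
    use_spec <- spec
    use_spec$correlations <- spec$correlations && !dropped
    f <- tryCatch(fit_one(spec_formula(use_spec), dat, crit == "reml"),
                  error = function(e) e)
    ok <- !inherits(f, "error") && lmm_converged(f)
    if (!ok && use_spec$correlations && length(spec$random_slopes)) {
      use_spec$correlations <- FALSE
      f <- tryCatch(fit_one(spec_formula(use_spec), dat, crit == "reml"),
                    error = function(e) e)
      ok <- !inherits(f, "error") && lmm_converged(f)
      if (ok || !inherits(f, "error")) dropped <- TRUE
    }
    if (inherits(f, "error"))
      stop("mixed-model fit failed (", crit, "): ", conditionMessage(f),
           call. = FALSE)
    fits[[crit]] <- f
  }
  est_fit <- fits$reml %||% fits$ml
  cf <- lme4::fixef(est_fit)
  se <- sqrt(diag(as.matrix(stats::vcov(est_fit))))
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se),
                      source = if (!is.null(fits$reml)) "REML" else "ML",
                      stringsAsFactors = FALSE)
  converged <- all(vapply(Filter(Negate(is.null), fits), lmm_converged,
                          logical(1)))
  structure(list(reml = fits$reml, ml = fits$ml, coefficients = coefs,
                 varcorr = lme4::VarCorr(est_fit),
                 loglik = as.numeric(stats::logLik(est_fit)),
                 converged = converged, correlations_dropped = dropped,
                 spec = spec, data = dat),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", x$spec$response, " ~ ",
      paste(x$spec$fixed, collapse = " + "), "\n", sep = "")
  cat("  estimates from ", x$coefficients$source[1],
      if (x$correlations_dropped) "; intercept-slope correlations dropped",
      if (!x$converged) "; NOT CONVERGED", "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wald chi-square tests on the maximum-likelihood fit
#'
#' Type II tests respect marginality (each term tested after the others at
#' its order); Type III tests each term in the full parameterization, with
#' the regime indicators coded 0/1 and covariates mean-centered so main
#' effects are simple effects at the reference levels, matching the
#' published convention. `"auto"` applies the design's rule: compute the
#' Type III table first and report it if any interaction term has p < 0.05,
#' otherwise report Type II. P-values are asymptotic chi-square with no
#' small-sample correction.
#'
#' @param fit an [fit_model()] result that includes an ML fit.
#' @param type `"auto"`, `"II"`, or `"III"`.
#' @return a `wald_table` data frame: `term`, `chisq`, `df`, `p`, with the
#'   selected `test_type` as an attribute and column.
#' @export
wald_tests <- function(fit, type = c("auto", "II", "III")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(fit$ml))
    stop("Wald tests require an ML fit; refit with estimation = 'both' or 'ML'",
         call. = FALSE)
  if (!fit$converged)
    stop("refusing to test a non-converged fit", call. = FALSE)
  tab3 <- NULL
  if (type %in% c("auto", "III")) tab3 <- anova_table(fit$ml, 3)
  chosen <- switch(type,
    III = "III",
    II = "II",
    auto = {
      inter <- grepl(":", tab3$term, fixed = TRUE)
      if (any(inter & tab3$p < 0.05, na.rm = TRUE)) "III" else "II"
    })
  tab <- if (chosen == "III") tab3 else anova_table(fit$ml, 2)
  tab$test_type <- chosen
  structure(tab, class = c("wald_table", "data.frame"), test_type = chosen)
}

anova_table <- function(ml_fit, type) {
  a <- car::Anova(ml_fit, type = type, test.statistic = "Chisq")
  data.frame(term = rownames(a),
             chisq = a[["Chisq"]],
             df = a[["Df"]],
             p = a[["Pr(>Chisq)"]],
             stringsAsFactors = FALSE)
}

#' Parameter-recovery / type-I-error simulation study
#'
#' Generates `replicates` seeded datasets from a generative model (or its
#' treatment-null version), fits each with the design's mixed model, and
#' aggregates per-coefficient bias, RMSE, and 95% Wald CI coverage against
#' the generating values, plus the rejection rate of the regime interaction
#' under the requested Wald test. Fit failures are counted and excluded,
#' never silent.
#'
#' @param model a [generative_model()].
#' @param spec a [model_spec()]; default [default_model_spec()] of `model`.
#' @param replicates number of simulated datasets (>= 2; 50+ for stable
#'   summaries).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param n_per_line females per line passed to the generator.
#' @param null if `TRUE`, generate from the treatment-null model (the
#'   generating value of every treatment coefficient is then 0).
#' @param tests if `TRUE`, compute the interaction Wald test per replicate
#'   (requires ML fits); if `FALSE`, only REML estimates are collected.
#' @param estimation fitting criterion per replicate when `tests = TRUE`:
#'   `"both"` (REML estimates + ML tests, the design's split) or `"ML"`
#'   (single ML fit per replicate — halves the cost when only test
#'   calibration matters). With `tests = FALSE` only REML fits are run.
#' @param test_type Wald test type for the rejection rate.
#' @param alpha nominal level for rejection and CI coverage.
#' @return a `recovery_study`: list with `summary` (per-coefficient mean
#'   estimate, generating value, bias, Monte Carlo SE, RMSE, coverage),
#'   `interaction` (term name, rejection rate, replicates used), `estimates`
#'   (replicate x coefficient matrix), `p_values`, and `n_failed`.
#' @export
recovery_study <- function(model, spec = default_model_spec(model),
                           replicates = 200L, seed = 1L, n_per_line = NULL,
                           null = FALSE, tests = TRUE,
                           estimation = c("both", "ML"),
                           test_type = "III", alpha = 0.05) {
  if (replicates < 2L)
    stop("need at least 2 replicates", call. = FALSE)
  estimation <- match.arg(estimation)
  est_mode <- if (!tests) "REML" else estimation
  design <- build_default_design()
  gen_fun <- if (null) generate_null else generate_assay
  truth <- generating_values(model, spec, null)
  inter_term <- "mating_system:structured"
  est <- se <- matrix(NA_real_, nrow = replicates, ncol = length(truth),
                      dimnames = list(NULL, names(truth)))
  pvals <- rep(NA_real_, replicates)
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, r)
    rec <- gen_fun(model, design, n_per_line, seed = rs)
    fit <- tryCatch(fit_model(spec, rec, estimation = est_mode),
                    error = function(e) e)
    if (inherits(fit, "error")) { n_failed <- n_failed + 1L; next }
    cf <- fit$coefficients
    idx <- match(names(truth), cf$term)
    est[r, ] <- cf$estimate[idx]
    se[r, ] <- cf$se[idx]
    if (tests) {
      wt <- tryCatch(wald_tests(fit, type = test_type),
                     error = function(e) NULL)
      if (!is.null(wt)) {
        row <- match(inter_term, wt$term)
        if (!is.na(row)) pvals[r] <- wt$p[row]
      }
    }
  }
  ok <- stats::complete.cases(est)
  mean_est <- colMeans(est[ok, , drop = FALSE])
  mc_se <- apply(est[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
  bias <- mean_est - truth
  rmse <- sqrt(colMeans((est[ok, , drop = FALSE] -
                           rep(truth, each = sum(ok)))^2))
  z <- stats::qnorm(1 - alpha / 2)
  cover <- colMeans(abs(est[ok, , drop = FALSE] -
                          rep(truth, each = sum(ok))) <=
                      z * se[ok, , drop = FALSE])
  summ <- data.frame(term = names(truth), truth = unname(truth),
                     mean_estimate = unname(mean_est), bias = unname(bias),
                     mc_se = unname(mc_se), rmse = unname(rmse),
                     coverage = unname(cover), stringsAsFactors = FALSE)
  p_ok <- !is.na(pvals)
  structure(list(summary = summ,
                 interaction = list(term = inter_term,
                                    rejection_rate = if (any(p_ok))
                                      mean(pvals[p_ok] < alpha) else NA_real_,
                                    replicates = sum(p_ok)),
                 estimates = est, p_values = pvals,
                 n_failed = n_failed, replicates = replicates,
                 seed = seed, alpha = alpha),
            class = "recovery_study")
}

#' @exportS3Method base::print
print.recovery_study <- function(x, ...) {
  cat("<recovery_study> ", x$replicates, " replicates",
      if (x$n_failed > 0) paste0(" (", x$n_failed, " failed)"), "\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.na(x$interaction$rejection_rate))
    cat("  interaction rejection rate at alpha ", x$alpha, ": ",
        signif(x$interaction$rejection_rate, 3), " (",
        x$interaction$replicates, " tests)\n", sep = "")
  invisible(x)
}

# map generating beta names onto fitted coefficient names
generating_values <- function(model, spec, null = FALSE) {
  beta <- model$beta
  if (null) beta[treatment_terms(beta)] <- 0
  cross_col <- if (model$response == "longevity") "lrs" else "longevity"
  gen_last <- if (!is.null(model$gen_table))
    model$gen_table$label[nrow(model$gen_table)] else "NA"
  map <- c(intercept = "(Intercept)",
           ms = "mating_systempolygamy", struct = "structuredyes",
           "ms:struct" = "mating_systempolygamy:structuredyes",
           female_size = "body_size_c", male_size = "male_size_c",
           cross = paste0(cross_col, "_c"), age = "age_at_entry_c",
           generation = paste0("generation", gen_last),
           matings = "n_matings_c",
           "ms:female_size" = "mating_systempolygamy:body_size_c",
           "ms:male_size" = "mating_systempolygamy:male_size_c",
           "ms:cross" = paste0("mating_systempolygamy:", cross_col, "_c"),
           "struct:female_size" = "structuredyes:body_size_c",
           "struct:male_size" = "structuredyes:male_size_c",
           "struct:cross" = paste0("structuredyes:", cross_col, "_c"))
  stats::setNames(as.numeric(beta), unname(map[names(beta)]))
}
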