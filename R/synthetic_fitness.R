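#' Generative model for assay-level female fitness records
#'
#' A `generative_model` holds everything needed to simulate one assay's
#' female fitness data with the statistical structure the inference design
#' assumes: fixed-effect coefficients on the 2x2 selection-regime indicators
#' (polygamy and metapopulation-structure indicators plus their reversal
#' interaction) and on mean-centered covariates, line-level random
#' intercepts (and optional random slopes), a residual SD, and a negative
#' residual correlation between longevity and reproduction (the cost of
#' reproduction).
#'
#' Coefficient names used in `beta`: `intercept`, `ms` (polygamy
#' indicator), `struct` (subdivided indicator), `ms:struct`, `female_size`,
#' `male_size`, `cross` (the companion fitness trait used as covariate: LRS
#' in longevity models, longevity in LRS models), `age`, `generation`
#' (later-generation indicator), `matings`, and the second-order terms
#' `ms:female_size`, `ms:male_size`, `ms:cross`, `struct:female_size`,
#' `struct:male_size`, `struct:cross`.
#'
#' @param assay assay label: `"low"`, `"medium"`, or `"extreme"`.
#' @param response `"longevity"` (days) or `"lrs"` (adult offspring; LRS
#'   response models are on the published coefficient scale).
#' @param beta named numeric vector of fixed-effect coefficients.
#' @param sd_line SD of the by-line random intercept (default 10% of the
#'   intercept magnitude).
#' @param sd_slope named numeric vector of by-line random-slope SDs (terms
#'   among the covariate names above); default none.
#' @param sd_resid residual SD.
#' @param trade_off_rho residual correlation between the response and the
#'   companion trait, in `(-1, 0]`; default -0.3.
#' @param size_mean,size_sd elytron length distribution (mm) used for both
#'   female and male body size.
#' @param age_mean,age_sd age at assay entry (days).
#' @param cross_mean,cross_sd distribution of the companion fitness trait.
#' @param gen_table for multi-generation assays: data frame with columns
#'   `label`, `n_per_line`, `matings`.
#' @param n_per_line default females per line when no `gen_table` is set.
#' @param perspective `"resistance"` (focal females x tester males) or
#'   `"harm"` (tester females x focal males); informational.
#' @return a `generative_model`.
#' @export
generative_model <- function(assay, response, beta,
                             sd_line = 0.1 * abs(beta[["intercept"]]),
                             sd_slope = numeric(0),
                             sd_resid,
                             trade_off_rho = -0.3,
                             size_mean = 1.9, size_sd = 0.1,
                             age_mean = 2, age_sd = 0.5,
                             cross_mean = NA_real_, cross_sd = NA_real_,
                             gen_table = NULL,
                             n_per_line = 10L,
                             perspective = "resistance") {
  stopifnot(response %in% c("longevity", "lrs"),
            "intercept" %in% names(beta))
  if (sd_resid <= 0) stop("residual SD must be positive", call. = FALSE)
  if (abs(trade_off_rho) >= 1)
    stop("trade_off_rho must lie in (-1, 1)", call. = FALSE)
  if (sd_line < 0 || any(sd_slope < 0))
    stop("random-effect SDs must be non-negative", call. = FALSE)
  structure(list(assay = assay, response = response, beta = beta,
                 sd_line = sd_line, sd_slope = sd_slope,
                 sd_resid = sd_resid, trade_off_rho = trade_off_rho,
                 size_mean = size_mean, size_sd = size_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 cross_mean = cross_mean, cross_sd = cross_sd,
                 gen_table = gen_table, n_per_line = as.integer(n_per_line),
                 perspective = perspective),
            class = "generative_model")
}

#' @exportS3Method base::print
print.generative_model <- function(x, ...) {
  cat("<generative_model> ", x$assay, " assay, response ", x$response,
      " (", x$perspective, ")\n", sep = "")
  cat("  fixed effects: ", paste0(names(x$beta), "=", x$beta,
                                  collapse = ", "), "\n", sep = "")
  cat("  sd_line ", x$sd_line, ", sd_resid ", x$sd_resid,
      ", trade_off_rho ", x$trade_off_rho, "\n", sep = "")
  invisible(x)
}

#' Preset generative models anchored to the published coefficient tables
#'
#' One preset per published model: the fixed-effect vectors equal the
#' printed REML estimate columns for the single-mating (low conflict,
#' male-harm and female-resistance perspectives), variable-mating-rate
#' (medium conflict; longevity only, as females could not lay eggs), and
#' lifelong-cohabitation (extreme conflict) assays. Unprinted variance
#' components carry documented defaults: by-line intercept SD at 10% of the
#' intercept magnitude, residual SD 4 days for longevity and 800 for
#' LRS-scale responses, and a longevity-reproduction residual correlation
#' of -0.3. LRS-response models are on the published (squared-scale)
#' coefficient metric; longevity models use raw LRS counts as covariate.
#'
#' @return named list of [generative_model()]s with keys
#'   `low_harm_longevity`, `low_harm_lrs`, `low_res_longevity`,
#'   `low_res_lrs`, `medium`, `extreme_harm_longevity`, `extreme_harm_lrs`,
#'   `extreme_res_longevity`, `extreme_res_lrs`.
#' @examples
#' default_models()$medium$beta[["ms:struct"]]  # -3.90
#' @export
default_models <- function() {
  medium_gens <- data.frame(label = c("12", "30"),
                            n_per_line = c(7L, 10L),
                            matings = c(12L, 10L))
  list(
    low_harm_longevity = generative_model(
      "low", "longevity",
      beta = c(intercept = 8.11, ms = 0.18, struct = 0.25,
               female_size = 2.78, male_size = -0.21, cross = -0.01,
               "ms:struct" = -0.16, "ms:female_size" = 2.66,
               "ms:male_size" = -1.13, "ms:cross" = 0.01,
               "struct:female_size" = -1.37, "struct:male_size" = 1.57,
               "struct:cross" = 0.00),
      sd_resid = 4, age_mean = 2.5, cross_mean = 70, cross_sd = 15,
      perspective = "harm"),
    low_harm_lrs = generative_model(
      "low", "lrs",
      beta = c(intercept = 3205.43, ms = -146.83, struct = -223.80,
               female_size = 965.45, male_size = 3970.13, cross = -151.92,
               "ms:struct" = 451.58, "ms:female_size" = 2351.27,
               "ms:male_size" = -2478.79, "ms:cross" = 11.80,
               "struct:female_size" = -369.27, "struct:male_size" = 2982.37,
               "struct:cross" = 21.61),
      sd_resid = 800, age_mean = 2.5, cross_mean = 9, cross_sd = 2,
      perspective = "harm"),
    low_res_longevity = generative_model(
      "low", "longevity",
      beta = c(intercept = 9.17, ms = 0.43, struct = 0.40,
               female_size = 5.49, male_size = -1.17, cross = -0.04,
               "ms:struct" = 0.00, "ms:female_size" = -0.25,
               "ms:male_size" = 0.75, "ms:cross" = -0.01,
               "struct:female_size" = -0.14, "struct:male_size" = 3.07,
               "struct:cross" = 0.01),
      sd_resid = 4, age_mean = 2.5, cross_mean = 70, cross_sd = 15),
    low_res_lrs = generative_model(
      "low", "lrs",
      beta = c(intercept = 4441.01, ms = -197.31, struct = 251.45,
               female_size = 5660.15, male_size = -2366.07, cross = -370.53,
               "ms:struct" = 1040.18, "ms:female_size" = -3573.76,
               "ms:male_size" = 3442.93, "ms:cross" = -195.06,
               "struct:female_size" = 1999.97, "struct:male_size" = 517.87,
               "struct:cross" = -92.33),
      sd_resid = 800, age_mean = 2.5, cross_mean = 9, cross_sd = 2),
    medium = generative_model(
      "medium", "longevity",
      beta = c(intercept = 24.15, ms = 2.01, struct = 2.17,
               generation = 2.21, age = -0.07, matings = -0.38,
               female_size = 30.14, "ms:struct" = -3.90,
               "ms:female_size" = -11.90, "struct:female_size" = -0.58),
      sd_resid = 4, age_mean = 2, age_sd = 0.8,
      gen_table = medium_gens, n_per_line = 17L),
    extreme_harm_longevity = generative_model(
      "extreme", "longevity",
      beta = c(intercept = 7.76, ms = 0.02, struct = 0.69,
               female_size = 3.46, cross = 0.04, age = 1.12,
               "ms:struct" = -0.67, "ms:female_size" = -1.95,
               "ms:cross" = -0.01, "struct:female_size" = 2.38,
               "struct:cross" = -0.01),
      sd_resid = 4, cross_mean = 60, cross_sd = 20, perspective = "harm"),
    extreme_harm_lrs = generative_model(
      "extreme", "lrs",
      beta = c(intercept = 2927.53, ms = -233.94, struct = -531.21,
               female_size = 1604.67, cross = 673.77, age = -748.73,
               "ms:struct" = 1017.32, "ms:female_size" = 1687.08,
               "ms:cross" = -160.97, "struct:female_size" = 1569.93,
               "struct:cross" = -186.16),
      sd_resid = 800, cross_mean = 8, cross_sd = 2, perspective = "harm"),
    extreme_res_longevity = generative_model(
      "extreme", "longevity",
      beta = c(intercept = 7.56, ms = -0.08, struct = -0.03,
               female_size = 0.03, cross = 0.06, age = 0.92,
               "ms:struct" = 0.51, "ms:female_size" = -1.90,
               "ms:cross" = -0.04, "struct:female_size" = 4.95,
               "struct:cross" = -0.02),
      sd_resid = 4, cross_mean = 60, cross_sd = 20),
    extreme_res_lrs = generative_model(
      "extreme", "lrs",
      beta = c(intercept = 5121.78, ms = 221.99, struct = -250.28,
               female_size = 6980.48, cross = 926.77, age = -387.54,
               "ms:struct" = 675.48, "ms:female_size" = 5382.78,
               "ms:cross" = -640.67, "struct:female_size" = 2969.26,
               "struct:cross" = -327.12),
      sd_resid = 800, cross_mean = 8, cross_sd = 2)
  )
}

# names of treatment-bearing coefficients (zeroed by generate_null)
treatment_terms <- function(beta) {
  nm <- names(beta)
  nm[nm %in% c("ms", "struct", "ms:struct") | grepl("^(ms|struct):", nm)]
}

#' Generate synthetic fitness records for one assay
#'
#' Draws by-line random intercepts (and slopes, when modeled), raw
#' covariates (body sizes, age at entry, generation label and mating count
#' for the variable-mating-rate assay), and the response from the model's
#' linear predictor. The predictor applies `beta` to the 0/1 regime
#' indicators and to covariates centered at their generative means;
#' covariates are stored raw, so centering remains the analysis step. The
#' response and companion-trait residuals are drawn jointly with correlation
#' `trade_off_rho`, giving the negative longevity-reproduction association.
#' LRS values are rounded to non-negative integers.
#'
#' @param model a [generative_model()].
#' @param design an `experiment_design` (default: the 16-line 2x2 design).
#' @param n_per_line females per line; `NULL` uses the model default (for
#'   the medium assay, its per-generation table: 7 + 10 per line).
#' @param seed integer seed.
#' @return a data frame of fitness records, one row per female: `line_id`,
#'   `regime`, `mating_system`, `structured`, `female_id`, `assay`,
#'   `generation`, `longevity`, `lrs`, `body_size`, `male_size`,
#'   `age_at_entry`, `n_matings`.
#' @export
generate_assay <- function(model, design = build_default_design(),
                           n_per_line = NULL, seed = 1L) {
  stopifnot(inherits(model, "generative_model"),
            inherits(design, "experiment_design"))
  with_seed(seed, generate_assay_impl(model, design, n_per_line))
}

generate_assay_impl <- function(model, design, n_per_line) {
  b <- function(term) if (term %in% names(model$beta)) model$beta[[term]] else 0
  uses <- function(term) term %in% names(model$beta)
  rows <- list()
  for (id in names(design$lines)) {
    cfg <- design$lines[[id]]
    ms <- as.integer(cfg$mating_system == "polygamy")
    st <- as.integer(cfg$structured)
    # per-line generation layout
    if (!is.null(model$gen_table) && is.null(n_per_line)) {
      gen <- rep(model$gen_table$label, model$gen_table$n_per_line)
      mat <- rep(model$gen_table$matings, model$gen_table$n_per_line)
    } else {
      n <- n_per_line %||% model$n_per_line
      if (n < 1L) stop("n_per_line must be at least 1", call. = FALSE)
      if (!is.null(model$gen_table)) {
        pick <- sample.int(nrow(model$gen_table), n, replace = TRUE,
                           prob = model$gen_table$n_per_line)
        gen <- model$gen_table$label[pick]
        mat <- model$gen_table$matings[pick]
      } else {
        gen <- rep(NA_character_, n)
        mat <- rep(NA_integer_, n)
      }
    }
    n <- length(gen)
    # occasional missed mating opportunities keep the mating count from
    # being aliased with the generation indicator
    if (uses("matings")) mat <- mat - stats::rbinom(n, 2L, 0.1)
    b0_line <- stats::rnorm(1L, 0, model$sd_line)
    slope_line <- vapply(names(model$sd_slope), function(trm)
      stats::rnorm(1L, 0, model$sd_slope[[trm]]), numeric(1))

    fsize <- stats::rnorm(n, model$size_mean, model$size_sd)
    msize <- if (uses("male_size"))
      stats::rnorm(n, model$size_mean, model$size_sd) else rep(NA_real_, n)
    age <- if (!is.null(model$gen_table)) sample(1:3, n, replace = TRUE)
      else pmax(1, round(stats::rnorm(n, model$age_mean, model$age_sd)))
    # joint residuals: companion trait and response share trade_off_rho
    z1 <- stats::rnorm(n)
    z2 <- model$trade_off_rho * z1 +
      sqrt(1 - model$trade_off_rho^2) * stats::rnorm(n)
    cross <- if (uses("cross")) {
      cv <- model$cross_mean + model$cross_sd * z1
      if (model$response == "longevity") pmax(0, round(cv)) else pmax(0.5, cv)
    } else rep(NA_real_, n)

    # linear predictor on indicators and covariates centered at their
    # generative means (records keep the raw values)
    fsz_c <- fsize - model$size_mean
    msz_c <- if (uses("male_size")) msize - model$size_mean else 0
    crs_c <- if (uses("cross")) cross - model$cross_mean else 0
    age_c <- age - model$age_mean
    mat_c <- if (uses("matings"))
      mat - stats::weighted.mean(model$gen_table$matings,
                                 model$gen_table$n_per_line) else 0
    gen_i <- if (uses("generation"))
      as.integer(gen == model$gen_table$label[nrow(model$gen_table)]) else 0

    lp <- b("intercept") + b0_line +
      b("ms") * ms + b("struct") * st + b("ms:struct") * ms * st +
      b("female_size") * fsz_c + b("male_size") * msz_c +
      b("cross") * crs_c + b("age") * age_c +
      b("generation") * gen_i + b("matings") * mat_c +
      b("ms:female_size") * ms * fsz_c + b("ms:male_size") * ms * msz_c +
      b("ms:cross") * ms * crs_c +
      b("struct:female_size") * st * fsz_c +
      b("struct:male_size") * st * msz_c + b("struct:cross") * st * crs_c
    for (trm in names(slope_line)) {
      val <- switch(trm, female_size = fsz_c, male_size = msz_c,
                    cross = crs_c, stop("no random slope for term ", trm))
      lp <- lp + slope_line[[trm]] * val
    }
    resp <- lp + model$sd_resid * z2
    resp <- if (model$response == "lrs") pmax(0, round(resp))
      else pmax(0.5, resp)

    longevity <- if (model$response == "longevity") resp else cross
    lrs <- if (model$response == "lrs") resp else cross
    if (model$assay == "medium") lrs <- rep(NA_real_, n)
    rows[[id]] <- data.frame(
      line_id = id,
      regime = regime_label(cfg),
      mating_system = cfg$mating_system,
      structured = cfg$structured,
      female_id = paste0(id, "_f", seq_len(n)),
      assay = model$assay,
      generation = gen,
      longevity = longevity,
      lrs = lrs,
      body_size = fsize,
      male_size = msize,
      age_at_entry = age,
      n_matings = mat,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Generate records under the treatment-null model
#'
#' Identical to [generate_assay()] but with every treatment coefficient
#' (main effects, their interaction, and all treatment x covariate terms)
#' set to zero; covariate slopes and the random structure are retained.
#' Used for type-I-error calibration of the inference design.
#'
#' @inheritParams generate_assay
#' @return a data frame of fitness records.
#' @export
generate_null <- function(model, design = build_default_design(),
                          n_per_line = NULL, seed = 1L) {
  null_model <- model
  null_model$beta[treatment_terms(model$beta)] <- 0
  generate_assay(null_model, design, n_per_line, seed)
}

#' Write fitness records as tidy CSV with a JSON settings sidecar
#'
#' @param records data frame from [generate_assay()].
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param model the generating [generative_model()] (recorded in the
#'   sidecar so every dataset ships with its variance-component settings).
#' @param seed the seed used.
#' @return invisibly, the CSV path.
#' @export
write_records <- function(records, path, model = NULL, seed = NULL) {
  utils::write.csv(records, path, row.names = FALSE)
  meta <- list(n_records = nrow(records), seed = seed,
               model = if (!is.null(model)) unclass(model))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
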