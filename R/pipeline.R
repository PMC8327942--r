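#' Reproducible multi-stage runs
#'
#' [run_pipeline()] ties the simulator, Ne estimation, data generation,
#' model fitting, and recovery studies into a single logged run: stages
#' execute in order, per-stage seeds derive deterministically from the
#' master seed, every tabular output is CSV, and a JSON manifest records
#' the command, config fingerprints, seed, package version, timestamps,
#' and output files. Re-running with the same inputs and seed reproduces
#' identical outputs.
#'
#' Available stages and their parameters:
#' \describe{
#'   \item{simulate}{`config` (a [regime_config()]), `line_id`,
#'     `replicates`; writes per-replicate pedigree-log summaries.}
#'   \item{estimate_ne}{`config`, `replicates`, `generations`,
#'     `infertility` (vector of rates); writes `ne.csv`.}
#'   \item{generate}{`model` (a [generative_model()] or a preset name from
#'     [default_models()]), `n_per_line`; writes `records.csv`.}
#'   \item{fit}{`model` or `spec` plus `data` (CSV path or data frame),
#'     `tests` (`"auto"`, `"II"`, `"III"`); writes coefficient and Wald
#'     tables.}
#'   \item{recover}{`model`, `replicates`, `null`, `tests`; writes the
#'     recovery summary.}
#' }
#'
#' @param plan ordered list of stage specifications; each element is a list
#'   with `stage` (one of the names above) and stage parameters.
#' @param seed master seed.
#' @param out_dir output directory (created; one manifest per directory).
#' @return a `run_manifest` (also written to `manifest.json`).
#' @export
run_pipeline <- function(plan, seed = 1L, out_dir = "demesim_run") {
  stages <- c("simulate", "estimate_ne", "generate", "fit", "recover")
  if (length(plan)) {
    nm <- vapply(plan, function(s) s$stage %||% NA_character_, character(1))
    bad <- setdiff(nm, stages)
    if (length(bad) || anyNA(nm))
      stop("unknown pipeline stage(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = log_path,
                                append = TRUE)
  manifest <- list(command = "run_pipeline", master_seed = seed,
                   package_version =
                     as.character(utils::packageVersion("demesim")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), outputs = character(0))
  for (i in seq_along(plan)) {
    st <- plan[[i]]
    st_seed <- derive_seed(seed, i)
    log_line("stage ", i, " (", st$stage, ") seed ", st_seed)
    res <- tryCatch(run_stage(st, st_seed, out_dir, i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <- st$stage
      manifest$error <- conditionMessage(res)
      manifest$ended <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      write_manifest(manifest, out_dir)
      stop("pipeline aborted at stage '", st$stage, "': ",
           conditionMessage(res), call. = FALSE)
    }
    manifest$stages[[i]] <- res$meta
    manifest$outputs <- c(manifest$outputs, res$outputs)
  }
  manifest$ended <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest(manifest, out_dir)
  structure(manifest, class = "run_manifest")
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

resolve_model <- function(model) {
  if (inherits(model, "generative_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    presets <- default_models()
    if (!model %in% names(presets))
      stop("unknown generative-model preset: ", model, call. = FALSE)
    return(presets[[model]])
  }
  stop("'model' must be a generative_model or a preset name", call. = FALSE)
}

run_stage <- function(st, st_seed, out_dir, i) {
  prefix <- file.path(out_dir, sprintf("stage%02d_%s", i, st$stage))
  switch(st$stage,
    simulate = {
      cfg <- st$config %||% stop("simulate stage needs a 'config'")
      reps <- st$replicates %||% 1L
      paths <- character(0)
      for (r in seq_len(reps)) {
        log <- run_line(cfg, line_id = st$line_id %||% "line",
                        seed = derive_seed(st_seed, r))
        sub <- paste0(prefix, sprintf("_rep%03d", r))
        paths <- c(paths, write_pedigree_log(log, sub))
      }
      list(meta = list(stage = "simulate", seed = st_seed,
                       fingerprint = config_fingerprint(unclass(cfg)),
                       replicates = reps),
           outputs = paths)
    },
    estimate_ne = {
      cfg <- st$config %||% stop("estimate_ne stage needs a 'config'")
      rates <- st$infertility %||% cfg$infertility_rate
      tab <- infertility_scenario(cfg, rates = rates,
                                  replicates = st$replicates %||% 500L,
                                  generations = st$generations,
                                  seed = st_seed)
      p <- paste0(prefix, "_ne.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      list(meta = list(stage = "estimate_ne", seed = st_seed,
                       fingerprint = config_fingerprint(unclass(cfg))),
           outputs = p)
    },
    generate = {
      model <- resolve_model(st$model %||% stop("generate stage needs a 'model'"))
      rec <- generate_assay(model, n_per_line = st$n_per_line,
                            seed = st_seed)
      p <- paste0(prefix, "_records.csv")
      write_records(rec, p, model = model, seed = st_seed)
      list(meta = list(stage = "generate", seed = st_seed,
                       fingerprint = config_fingerprint(unclass(model))),
           outputs = c(p, paste0(p, ".json")))
    },
    fit = {
      model <- resolve_model(st$model %||% stop("fit stage needs a 'model'"))
      spec <- st$spec %||% default_model_spec(model)
      dat <- st$data
      if (is.character(dat)) dat <- utils::read.csv(dat)
      if (is.null(dat)) stop("fit stage needs 'data'")
      fit <- fit_model(spec, dat)
      wt <- wald_tests(fit, type = st$tests %||% "auto")
      p1 <- paste0(prefix, "_coefficients.csv")
      p2 <- paste0(prefix, "_wald.csv")
      utils::write.csv(fit$coefficients, p1, row.names = FALSE)
      utils::write.csv(as.data.frame(wt), p2, row.names = FALSE)
      list(meta = list(stage = "fit", seed = st_seed,
                       test_type = attr(wt, "test_type"),
                       correlations_dropped = fit$correlations_dropped),
           outputs = c(p1, p2))
    },
    recover = {
      model <- resolve_model(st$model %||% stop("recover stage needs a 'model'"))
      rs <- recovery_study(model, replicates = st$replicates %||% 200L,
                           seed = st_seed, null = st$null %||% FALSE,
                           tests = st$tests %||% TRUE)
      p <- paste0(prefix, "_recovery.csv")
      utils::write.csv(rs$summary, p, row.names = FALSE)
      list(meta = list(stage = "recover", seed = st_seed,
                       rejection_rate = rs$interaction$rejection_rate,
                       n_failed = rs$n_failed),
           outputs = p)
    })
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", length(x$stages), " stage(s), seed ",
      x$master_seed, "\n", sep = "")
  for (o in x$outputs) cat("  - ", o, "\n", sep = "")
  invisible(x)
}
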