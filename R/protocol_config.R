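#' Breeding-design configuration for one selection regime
#'
#' A `regime_config` captures every parameter of one selection line's
#' propagation protocol: the mating system (enforced monogamy vs. polygamy),
#' whether the line is subdivided into demes connected by migration
#' (metapopulation structure), deme layout and census counts, the
#' per-generation migrant exchange, the per-mating infertility probability,
#' and the bean-sampling step that fixes the offspring pool.
#'
#' Under the default protocol every line carries 50 breeders (25 females and
#' 25 males). Structured lines split them into 5 demes of 5 + 5, and each
#' deme exchanges one male-female migrant pair per generation, a 20%
#' migration rate (2 immigrants out of 10 residents per deme).
#'
#' @param mating_system `"monogamy"` or `"polygamy"`.
#' @param structured logical; `TRUE` for a subdivided (metapopulation) line.
#' @param n_demes number of demes (1 when unstructured).
#' @param females_per_deme,males_per_deme breeder census per deme.
#' @param migrant_pairs_per_deme male-female pairs exchanged per deme per
#'   generation (0 when unstructured).
#' @param mates_per_female inclusive integer range `c(low, high)` of distinct
#'   mates per female under polygamy; forced to `c(1, 1)` under monogamy.
#' @param infertility_rate probability in `[0, 1]` that any one female-male
#'   pairing is infertile. Default 0; the observed-rate scenario in the study
#'   system is below 3% (see [infertility_scenario()]).
#' @param beans_per_line inoculated beans (one egg each) sampled per line per
#'   generation; each yields one emerging adult. Default 150.
#' @param n_generations generations to simulate. Default 10.
#' @param neutral_loci number of unlinked neutral biallelic loci tracked.
#'   Default 100.
#' @param fecundity_mean mean of the Poisson egg count per fertile female.
#'   Default 40; only the relative variance matters after bean downsampling.
#' @param paternity character; `"equal"` (default) shares paternity equally
#'   among a female's fertile mates, `"last_male"` gives the last mate a
#'   precedence share set by `last_male_share`.
#' @param last_male_share proportion of paternity taken by the last mate when
#'   `paternity = "last_male"`.
#' @return a validated, immutable `regime_config` object.
#' @seealso [build_regime()] for paper-default construction,
#'   [build_default_design()] for the full 2x2 design.
#' @export
regime_config <- function(mating_system = c("monogamy", "polygamy"),
                          structured = FALSE,
                          n_demes = if (structured) 5L else 1L,
                          females_per_deme = if (structured) 5L else 25L,
                          males_per_deme = if (structured) 5L else 25L,
                          migrant_pairs_per_deme = if (structured) 1L else 0L,
                          mates_per_female = c(2L, 3L),
                          infertility_rate = 0,
                          beans_per_line = 150L,
                          n_generations = 10L,
                          neutral_loci = 100L,
                          fecundity_mean = 40,
                          paternity = c("equal", "last_male"),
                          last_male_share = 0.5) {
  mating_system <- match.arg(mating_system)
  paternity <- match.arg(paternity)
  if (mating_system == "monogamy") mates_per_female <- c(1L, 1L)
  cfg <- structure(list(
    mating_system = mating_system,
    structured = isTRUE(structured),
    n_demes = as.integer(n_demes),
    females_per_deme = as.integer(females_per_deme),
    males_per_deme = as.integer(males_per_deme),
    migrant_pairs_per_deme = as.integer(migrant_pairs_per_deme),
    mates_per_female = as.integer(mates_per_female),
    infertility_rate = as.numeric(infertility_rate),
    beans_per_line = as.integer(beans_per_line),
    n_generations = as.integer(n_generations),
    neutral_loci = as.integer(neutral_loci),
    fecundity_mean = as.numeric(fecundity_mean),
    paternity = paternity,
    last_male_share = as.numeric(last_male_share)
  ), class = "regime_config")
  validate_regime_config(cfg)
  cfg
}

validate_regime_config <- function(cfg) {
  stopifnot(inherits(cfg, "regime_config"))
  err <- function(msg) stop("invalid regime_config: ", msg, call. = FALSE)
  with(cfg, {
    if (is.na(n_demes) || n_demes < 1L) err("n_demes must be a positive integer")
    if (females_per_deme < 1L || males_per_deme < 1L)
      err("each deme must hold at least one breeder of each sex")
    if (structured != (n_demes > 1L))
      err("structured = TRUE if and only if n_demes > 1")
    if (n_demes == 1L && migrant_pairs_per_deme != 0L)
      err("migrant_pairs_per_deme must be 0 when n_demes = 1")
    if (migrant_pairs_per_deme < 0L)
      err("migrant_pairs_per_deme must be non-negative")
    if (migrant_pairs_per_deme > min(females_per_deme, males_per_deme))
      err("migrant_pairs_per_deme exceeds the per-deme census of a sex")
    if (length(mates_per_female) != 2L || any(mates_per_female < 1L) ||
        mates_per_female[1] > mates_per_female[2])
      err("mates_per_female must be an increasing positive integer range (low, high)")
    if (mating_system == "monogamy" && !identical(mates_per_female, c(1L, 1L)))
      err("mates_per_female is forced to (1, 1) under monogamy")
    if (is.na(infertility_rate) || infertility_rate < 0 || infertility_rate > 1)
      err("infertility_rate must lie in [0, 1]")
    if (beans_per_line < 1L) err("beans_per_line must be positive")
    if (n_generations < 1L) err("n_generations must be positive")
    if (neutral_loci < 1L) err("neutral_loci must be positive")
    if (fecundity_mean <= 0) err("fecundity_mean must be positive")
    if (last_male_share < 0 || last_male_share > 1)
      err("last_male_share must lie in [0, 1]")
  })
  invisible(cfg)
}

#' Build a selection-regime configuration with protocol defaults
#'
#' Constructs the [regime_config()] matching one cell of the 2x2 selection
#' design. Unstructured lines are a single population of 25 females and 25
#' males; structured lines hold 5 demes of 5 + 5 with one migrant pair per
#' deme per generation (20% migration). Polygamy defaults to 2-3 distinct
#' mates per female.
#'
#' @param mating_system `"monogamy"` or `"polygamy"`.
#' @param structured logical; metapopulation structure.
#' @param overrides named list of `regime_config` fields to override. Unknown
#'   names are rejected.
#' @return a validated `regime_config`.
#' @examples
#' build_regime("polygamy", structured = TRUE)$n_demes   # 5
#' build_regime("monogamy", structured = FALSE)$mates_per_female  # c(1, 1)
#' @export
build_regime <- function(mating_system, structured = FALSE, overrides = list()) {
  known <- names(formals(regime_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown regime_config field(s) in overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  args <- c(list(mating_system = mating_system, structured = structured),
            overrides)
  do.call(regime_config, args)
}

#' The full 2x2 experiment design
#'
#' Sixteen selection lines, four per regime, labelled by regime:
#' `NSPoly` (no structure, polygamy), `SPoly` (structured, polygamy),
#' `NSMono` (no structure, monogamy), `SMono` (structured, monogamy), each
#' line carrying its validated [regime_config()].
#'
#' @param lines_per_regime lines per regime (default 4).
#' @param overrides named list of `regime_config` overrides applied to every
#'   line (e.g. `list(infertility_rate = 0.03)`).
#' @return an `experiment_design`: a list with `lines`, a named list of
#'   `regime_config`s keyed by line id (`NSPoly_1` ... `SMono_4`), and
#'   `regimes`, a data frame mapping line id to regime label.
#' @export
build_default_design <- function(lines_per_regime = 4L, overrides = list()) {
  regimes <- list(
    NSPoly = list(mating_system = "polygamy", structured = FALSE),
    SPoly  = list(mating_system = "polygamy", structured = TRUE),
    NSMono = list(mating_system = "monogamy", structured = FALSE),
    SMono  = list(mating_system = "monogamy", structured = TRUE)
  )
  lines <- list()
  meta <- list()
  for (lab in names(regimes)) {
    for (i in seq_len(lines_per_regime)) {
      id <- paste0(lab, "_", i)
      lines[[id]] <- build_regime(regimes[[lab]]$mating_system,
                                  regimes[[lab]]$structured, overrides)
      meta[[id]] <- data.frame(line_id = id, regime = lab,
                               mating_system = regimes[[lab]]$mating_system,
                               structured = regimes[[lab]]$structured,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(lines = lines,
                 regimes = do.call(rbind, c(meta, list(make.row.names = FALSE)))),
            class = "experiment_design")
}

#' @exportS3Method base::print
print.regime_config <- function(x, ...) {
  cat("<regime_config> ", x$mating_system,
      if (x$structured) ", structured" else ", unstructured", "\n", sep = "")
  cat("  demes: ", x$n_demes, " x (", x$females_per_deme, "F + ",
      x$males_per_deme, "M); migrant pairs/deme: ",
      x$migrant_pairs_per_deme, "\n", sep = "")
  cat("  mates/female: ", x$mates_per_female[1], "-", x$mates_per_female[2],
      "; infertility: ", x$infertility_rate,
      "; beans/line: ", x$beans_per_line, "\n", sep = "")
  cat("  generations: ", x$n_generations, "; neutral loci: ",
      x$neutral_loci, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", length(x$lines), " lines (",
      paste(unique(x$regimes$regime), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# realized per-deme migration rate implied by a structured config
migration_rate <- function(cfg) {
  if (!cfg$structured) return(0)
  2 * cfg$migrant_pairs_per_deme / (cfg$females_per_deme + cfg$males_per_deme)
}

#' Write / read an experiment design as a YAML configuration file
#'
#' One YAML document per design: a `lines` mapping of line id to
#' `regime_config` fields, all fields named exactly as in [regime_config()].
#' Unknown keys are rejected on read, and reading back a written design
#' reproduces it exactly.
#'
#' @param design an `experiment_design`.
#' @param path file path.
#' @return `read_design()` returns an `experiment_design`;
#'   `write_design()` returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  doc <- list(lines = lapply(design$lines, unclass))
  # yaml can't round-trip length-2 integer vectors unambiguously unless listed
  doc$lines <- lapply(doc$lines, function(l) {
    l$mates_per_female <- as.list(l$mates_per_female)
    l
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(names(doc), "lines"))
    stop("design file must contain exactly one top-level 'lines' mapping",
         call. = FALSE)
  known <- names(formals(regime_config))
  lines <- lapply(doc$lines, function(l) {
    bad <- setdiff(names(l), known)
    if (length(bad))
      stop("unknown regime_config field(s) in design file: ",
           paste(bad, collapse = ", "), call. = FALSE)
    l$mates_per_female <- as.integer(unlist(l$mates_per_female))
    do.call(regime_config, l)
  })
  meta <- lapply(names(lines), function(id) {
    cfg <- lines[[id]]
    data.frame(line_id = id,
               regime = regime_label(cfg),
               mating_system = cfg$mating_system,
               structured = cfg$structured, stringsAsFactors = FALSE)
  })
  structure(list(lines = lines,
                 regimes = do.call(rbind, c(meta, list(make.row.names = FALSE)))),
            class = "experiment_design")
}

regime_label <- function(cfg) {
  paste0(if (cfg$structured) "S" else "NS",
         if (cfg$mating_system == "polygamy") "Poly" else "Mono")
}
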