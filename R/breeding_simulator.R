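#' Forward simulation of the line-propagation protocol
#'
#' These functions implement one selection line's generational cycle exactly
#' as the breeding protocol prescribes: optional migrant exchange between
#' demes, mating (enforced monogamy or free polygamy within demes),
#' per-pairing infertility, egg laying on ad libitum beans, uniform sampling
#' of a fixed number of inoculated beans per line (one egg, hence one
#' emerging adult, per bean), and uniform random collection of virgin
#' breeders for the next generation. Pedigree kinship and unlinked neutral
#' biallelic loci are tracked throughout, so the resulting [run_line()] log
#' feeds every effective-population-size estimator in the package.
#'
#' All stochastic steps draw from R's global RNG; [run_line()] wraps the
#' whole cycle in a per-line seeded stream so a run is a pure function of
#' `(config, line_id, seed)`.
#'
#' @name breeding_simulator
NULL

new_roster <- function(individuals, kin, geno, config, line_id, generation) {
  rownames(kin) <- colnames(kin) <- as.character(individuals$id)
  structure(list(individuals = individuals, kin = kin, geno = geno,
                 config = config, line_id = line_id, generation = generation),
            class = "breeder_roster")
}

#' @exportS3Method base::print
print.breeder_roster <- function(x, ...) {
  cat("<breeder_roster> line ", x$line_id, ", generation ", x$generation,
      ": ", nrow(x$individuals), " breeders in ",
      length(unique(x$individuals$deme)), " deme(s)\n", sep = "")
  invisible(x)
}

#' Found a line with unrelated breeders
#'
#' Draws the generation-0 breeder roster: founders are mutually unrelated
#' (pedigree inbreeding 0), sexes and demes are filled exactly to the
#' configured census, and each neutral locus receives alleles by random
#' union of gametes at frequency 0.5.
#'
#' @param config a [regime_config()].
#' @param line_id line identifier carried through logs.
#' @param seed optional integer; when given, the draw is made under this seed
#'   without disturbing the caller's RNG.
#' @return a `breeder_roster`.
#' @export
init_population <- function(config, line_id = "line", seed = NULL) {
  validate_regime_config(config)
  if (!is.null(seed)) return(with_seed(seed, init_population(config, line_id)))
  nf <- config$females_per_deme
  nm <- config$males_per_deme
  n <- config$n_demes * (nf + nm)
  deme <- rep(seq_len(config$n_demes) - 1L, each = nf + nm)
  sex <- rep(c(rep("F", nf), rep("M", nm)), times = config$n_demes)
  ind <- data.frame(id = seq_len(n), sex = sex, deme = deme,
                    dam_id = NA_integer_, sire_id = NA_integer_,
                    generation = 0L, f_ped = 0, is_migrant = FALSE,
                    stringsAsFactors = FALSE)
  kin <- diag(0.5, n)
  L <- config$neutral_loci
  geno <- list(a1 = matrix(stats::rbinom(L * n, 1L, 0.5), nrow = L),
               a2 = matrix(stats::rbinom(L * n, 1L, 0.5), nrow = L))
  new_roster(ind, kin, geno, config, line_id, 0L)
}

# Uniform random derangement of 1..n (no element maps to itself), by
# rejection; for n = 5 the acceptance rate is 44/120.
sample_derangement <- function(n) {
  if (n < 2L) stop("a derangement needs at least 2 elements", call. = FALSE)
  repeat {
    s <- sample.int(n)
    if (all(s != seq_len(n))) return(s)
  }
}

#' Exchange migrant pairs between demes
#'
#' From each deme, `migrant_pairs_per_deme` randomly chosen females and
#' equally many males are relocated along a uniformly sampled derangement of
#' the demes, so every deme sends its pair(s) to, and receives pair(s) from,
#' exactly one other deme and no pair stays home. Deme sizes and sex ratios
#' are unchanged; relocated individuals are flagged `is_migrant`.
#'
#' @param roster a `breeder_roster` from a structured config.
#' @return the roster with migrants relocated.
#' @export
migrate <- function(roster) {
  cfg <- roster$config
  if (!cfg$structured)
    stop("migrate() requires a structured (multi-deme) configuration",
         call. = FALSE)
  m <- cfg$migrant_pairs_per_deme
  ind <- roster$individuals
  ind$is_migrant <- FALSE
  if (m == 0L) { roster$individuals <- ind; return(roster) }
  dest <- sample_derangement(cfg$n_demes)
  new_deme <- ind$deme
  for (d in seq_len(cfg$n_demes)) {
    for (sx in c("F", "M")) {
      res <- which(ind$deme == d - 1L & ind$sex == sx)
      if (length(res) < m)
        stop("deme ", d - 1L, " has fewer ", sx, " residents than ",
             "migrant_pairs_per_deme", call. = FALSE)
      mv <- res[sample.int(length(res), m)]
      new_deme[mv] <- dest[d] - 1L
      ind$is_migrant[mv] <- TRUE
    }
  }
  ind$deme <- new_deme
  roster$individuals <- ind
  roster
}

#' Form mating events within demes
#'
#' Monogamy pairs each female with exactly one male through a uniformly
#' random perfect matching within her deme. Polygamy gives each female
#' `m ~ uniform(mates_per_female)` distinct males from her deme (capped at
#' the deme's male census); males may mate with several females. Paternity
#' shares follow the configured rule: equal shares among mates (default) or
#' last-male precedence.
#'
#' @param roster a `breeder_roster`.
#' @return a list of mating events, each a list with `female_id`, `male_ids`
#'   (ordered), `fertile` (per-male flags, all `TRUE` here), and
#'   `paternity_shares`.
#' @export
form_matings <- function(roster) {
  cfg <- roster$config
  ind <- roster$individuals
  events <- list()
  for (d in sort(unique(ind$deme))) {
    fem <- ind$id[ind$deme == d & ind$sex == "F"]
    mal <- ind$id[ind$deme == d & ind$sex == "M"]
    if (length(fem) == 0L || length(mal) == 0L)
      stop("deme ", d, " lacks one sex entirely; no matings possible",
           call. = FALSE)
    if (cfg$mating_system == "monogamy") {
      if (length(fem) != length(mal))
        stop("monogamy requires equal sex counts per deme (deme ", d, ")",
             call. = FALSE)
      fo <- sample(fem)
      mo <- sample(mal)
      for (i in seq_along(fo)) {
        events[[length(events) + 1L]] <-
          list(female_id = fo[i], male_ids = mo[i], fertile = TRUE,
               paternity_shares = 1)
      }
    } else {
      lo <- cfg$mates_per_female[1]; hi <- cfg$mates_per_female[2]
      for (f in fem) {
        m <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        m <- min(m, length(mal))
        mates <- mal[sample.int(length(mal), m)]
        events[[length(events) + 1L]] <-
          list(female_id = f, male_ids = mates, fertile = rep(TRUE, m),
               paternity_shares = paternity_shares(m, cfg))
      }
    }
  }
  events
}

paternity_shares <- function(m, cfg) {
  if (m == 1L) return(1)
  if (cfg$paternity == "equal") return(rep(1 / m, m))
  # last-male precedence: final mate takes last_male_share, the rest split
  s <- rep((1 - cfg$last_male_share) / (m - 1L), m)
  s[m] <- cfg$last_male_share
  s
}

#' Mark pairings infertile at a given rate
#'
#' Each female-male pairing is independently infertile with probability
#' `rate`; paternity shares are renormalized over the remaining fertile
#' mates. An event with no fertile mate contributes no offspring downstream.
#'
#' @param events mating events from [form_matings()].
#' @param rate infertility probability in `[0, 1]`.
#' @return the events with `fertile` flags and renormalized shares.
#' @export
apply_infertility <- function(events, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("infertility rate must be a single value in [0, 1]", call. = FALSE)
  lapply(events, function(ev) {
    n <- length(ev$male_ids)
    ev$fertile <- stats::runif(n) >= rate
    sh <- ev$paternity_shares
    sh[!ev$fertile] <- 0
    tot <- sum(sh)
    ev$paternity_shares <- if (tot > 0) sh / tot else sh
    ev
  })
}

#' Lay eggs and sample the bean cohort
#'
#' Every female with at least one fertile mate lays `Poisson(fecundity_mean)`
#' eggs, one per bean; each egg's sire is drawn from her fertile mates
#' according to their paternity shares. The pooled eggs of the line are then
#' downsampled uniformly without replacement to `beans_per_line` beans, each
#' yielding one emerging adult with sex assigned 50:50, a Mendelian genotype
#' (one allele per parent per locus), and pedigree inbreeding equal to the
#' kinship of its parents.
#'
#' @param roster the parental `breeder_roster`.
#' @param events mating events (after [apply_infertility()] if applicable).
#' @param sample_beans if `FALSE`, the whole egg pool is kept (no bean
#'   sampling) — used for theoretical checks, not part of the protocol.
#' @return an `offspring_pool`.
#' @export
produce_offspring <- function(roster, events, sample_beans = TRUE) {
  cfg <- roster$config
  ind <- roster$individuals
  dam <- integer(0); sire <- integer(0)
  for (ev in events) {
    if (!any(ev$fertile)) next
    n_eggs <- stats::rpois(1L, cfg$fecundity_mean)
    if (n_eggs == 0L) next
    males <- ev$male_ids[ev$fertile]
    sh <- ev$paternity_shares[ev$fertile]
    s <- if (length(males) == 1L) rep(males, n_eggs) else
      sample(males, n_eggs, replace = TRUE, prob = sh)
    dam <- c(dam, rep(ev$female_id, n_eggs))
    sire <- c(sire, s)
  }
  n_pool <- length(dam)
  if (sample_beans) {
    if (n_pool < cfg$beans_per_line)
      stop("offspring shortfall in line ", roster$line_id, " generation ",
           roster$generation + 1L, ": ", n_pool, " eggs < ",
           cfg$beans_per_line, " beans", call. = FALSE)
    keep <- sample.int(n_pool, cfg$beans_per_line)
    dam <- dam[keep]; sire <- sire[keep]
  } else if (n_pool == 0L) {
    stop("no fertile matings: empty offspring pool", call. = FALSE)
  }
  n_off <- length(dam)
  di <- match(dam, ind$id)
  si <- match(sire, ind$id)
  sex <- ifelse(stats::runif(n_off) < 0.5, "F", "M")
  f_ped <- roster$kin[cbind(di, si)]
  off <- data.frame(id = max(ind$id) + seq_len(n_off), sex = sex,
                    deme = ind$deme[di], dam_id = dam, sire_id = sire,
                    generation = roster$generation + 1L, f_ped = f_ped,
                    is_migrant = FALSE, stringsAsFactors = FALSE)
  geno <- list(a1 = mendelian_gamete(roster$geno, di),
               a2 = mendelian_gamete(roster$geno, si))
  structure(list(individuals = off, geno = geno,
                 parent_kin = roster$kin, parent_ids = ind$id,
                 config = cfg, line_id = roster$line_id,
                 generation = roster$generation + 1L),
            class = "offspring_pool")
}

# One gamete per offspring from the parent at column index `pi`:
# each locus transmits one of the parent's two alleles with equal chance.
mendelian_gamete <- function(geno, pi) {
  L <- nrow(geno$a1)
  n <- length(pi)
  pick <- matrix(stats::runif(L * n) < 0.5, nrow = L)
  g1 <- geno$a1[, pi, drop = FALSE]
  g2 <- geno$a2[, pi, drop = FALSE]
  out <- g1
  out[!pick] <- g2[!pick]
  out
}

#' Collect virgin breeders for the next generation
#'
#' Uniform random sample without replacement from the emerged adults,
#' filling the configured per-deme census; structured lines draw each deme's
#' breeders from that deme's own offspring. Emergence-day variation is
#' collapsed into this uniform draw, since collection in the protocol is
#' random precisely to avoid selection on development time.
#'
#' @param pool an `offspring_pool`.
#' @return the next-generation `breeder_roster`, with the kinship matrix
#'   advanced one generation.
#' @export
select_breeders <- function(pool) {
  cfg <- pool$config
  off <- pool$individuals
  take <- integer(0)
  demes <- if (cfg$structured) seq_len(cfg$n_demes) - 1L else 0L
  for (d in demes) {
    in_d <- if (cfg$structured) off$deme == d else rep(TRUE, nrow(off))
    for (sx in c("F", "M")) {
      need <- if (sx == "F") cfg$females_per_deme else cfg$males_per_deme
      cand <- which(in_d & off$sex == sx)
      if (length(cand) < need)
        stop("breeder shortfall in line ", pool$line_id, " generation ",
             pool$generation, ": deme ", d, " has ", length(cand), " ", sx,
             " offspring, needs ", need, call. = FALSE)
      take <- c(take, cand[sample.int(length(cand), need)])
    }
  }
  sel <- off[take, , drop = FALSE]
  rownames(sel) <- NULL
  di <- match(sel$dam_id, pool$parent_ids)
  si <- match(sel$sire_id, pool$parent_ids)
  K <- pool$parent_kin
  M <- 0.5 * (K[di, , drop = FALSE] + K[si, , drop = FALSE])
  newK <- 0.5 * (M[, di, drop = FALSE] + M[, si, drop = FALSE])
  diag(newK) <- 0.5 * (1 + sel$f_ped)
  geno <- list(a1 = pool$geno$a1[, take, drop = FALSE],
               a2 = pool$geno$a2[, take, drop = FALSE])
  new_roster(sel, newK, geno, cfg, pool$line_id, pool$generation)
}

roster_allele_freq <- function(roster) {
  0.5 * (rowMeans(roster$geno$a1) + rowMeans(roster$geno$a2))
}

#' Run one line for its configured number of generations
#'
#' Iterates migrate (structured lines only) -> matings -> infertility ->
#' offspring/bean sampling -> breeder collection for
#' `config$n_generations` generations, logging per-generation breeder
#' summaries, per-sex family-size moments, per-locus allele frequencies,
#' expected heterozygosity, and mean pedigree inbreeding. Fully reproducible
#' from `(config, line_id, seed)`.
#'
#' @param config a [regime_config()].
#' @param line_id line identifier.
#' @param seed integer seed for the line's RNG stream.
#' @param keep_pedigree if `TRUE`, the full breeder pedigree (one row per
#'   breeder per generation) is kept in the log.
#' @return a `pedigree_log`: list with `summary` (one row per generation:
#'   census, family-size means/variances by sex, mean pedigree inbreeding,
#'   mean expected heterozygosity), `freq` (generation x locus allele
#'   frequency matrix), `pedigree` (optional), `config`, `line_id`, `seed`.
#' @export
run_line <- function(config, line_id = "line", seed = 1L,
                     keep_pedigree = FALSE) {
  validate_regime_config(config)
  with_seed(seed, {
    roster <- init_population(config, line_id)
    G <- config$n_generations
    L <- config$neutral_loci
    freq <- matrix(NA_real_, nrow = G + 1L, ncol = L)
    freq[1L, ] <- roster_allele_freq(roster)
    summ <- data.frame(generation = 0:G, n_breeders = NA_integer_,
                       mean_f_ped = NA_real_, mean_het = NA_real_,
                       kbar_f = NA_real_, vk_f = NA_real_,
                       kbar_m = NA_real_, vk_m = NA_real_)
    ped <- if (keep_pedigree) vector("list", G + 1L) else NULL
    fill <- function(g, roster) {
      summ$n_breeders[g + 1L] <<- nrow(roster$individuals)
      summ$mean_f_ped[g + 1L] <<- mean(roster$individuals$f_ped)
      p <- roster_allele_freq(roster)
      freq[g + 1L, ] <<- p
      summ$mean_het[g + 1L] <<- mean(2 * p * (1 - p))
      if (keep_pedigree) ped[[g + 1L]] <<- roster$individuals
    }
    fill(0L, roster)
    for (g in seq_len(G)) {
      if (config$structured) roster <- migrate(roster)
      events <- form_matings(roster)
      if (config$infertility_rate > 0)
        events <- apply_infertility(events, config$infertility_rate)
      pool <- produce_offspring(roster, events)
      nxt <- select_breeders(pool)
      # realized family sizes: next-generation breeders per current parent
      prev <- roster$individuals
      kd <- tabulate(match(nxt$individuals$dam_id, prev$id), nrow(prev))
      ks <- tabulate(match(nxt$individuals$sire_id, prev$id), nrow(prev))
      k <- kd + ks # each parent is one sex; one of the two terms is zero
      fem <- prev$sex == "F"
      summ$kbar_f[g] <- mean(k[fem]);  summ$vk_f[g] <- stats::var(k[fem])
      summ$kbar_m[g] <- mean(k[!fem]); summ$vk_m[g] <- stats::var(k[!fem])
      roster <- nxt
      roster$generation <- g
      fill(g, roster)
    }
    structure(list(summary = summ, freq = freq,
                   pedigree = if (keep_pedigree) do.call(rbind, ped) else NULL,
                   config = config, line_id = line_id, seed = seed,
                   fingerprint = config_fingerprint(unclass(config))),
              class = "pedigree_log")
  })
}

#' @exportS3Method base::print
print.pedigree_log <- function(x, ...) {
  G <- max(x$summary$generation)
  cat("<pedigree_log> line ", x$line_id, ", ", G, " generations, ",
      x$config$neutral_loci, " loci\n", sep = "")
  cat("  final mean F_ped: ", signif(x$summary$mean_f_ped[G + 1L], 4),
      "; final mean H: ", signif(x$summary$mean_het[G + 1L], 4), "\n",
      sep = "")
  invisible(x)
}

#' Export a pedigree log as tidy CSV plus JSON metadata
#'
#' Writes `<line_id>_summary.csv` (generation-level summaries),
#' `<line_id>_freq.csv` (per-locus allele frequencies by generation),
#' optionally `<line_id>_pedigree.csv`, and `<line_id>_meta.json` (config,
#' seed, fingerprint).
#'
#' @param log a `pedigree_log`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_pedigree_log <- function(log, dir) {
  stopifnot(inherits(log, "pedigree_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, log$line_id)
  paths <- paste0(base, c("_summary.csv", "_freq.csv", "_meta.json"))
  utils::write.csv(log$summary, paths[1], row.names = FALSE)
  fr <- as.data.frame(log$freq)
  names(fr) <- paste0("locus_", seq_len(ncol(fr)))
  fr <- cbind(generation = log$summary$generation, fr)
  utils::write.csv(fr, paths[2], row.names = FALSE)
  meta <- list(line_id = log$line_id, seed = log$seed,
               fingerprint = log$fingerprint, config = unclass(log$config))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  if (!is.null(log$pedigree)) {
    p <- paste0(base, "_pedigree.csv")
    utils::write.csv(log$pedigree, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
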