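#' Simulation configuration for a two-set barley breeding program
#'
#' Defines the structure of a synthetic breeding program: two sets of F6
#' lines derived from partially overlapping parent pools, a mapped biallelic
#' marker panel on seven chromosomes, and replicated two-location field
#' trials with additive-genomic, residual-line, genotype-by-environment and
#' plot-residual variance for each trait.
#'
#' Default trait variance components are on the scale observed for seed
#' quality traits in advanced spring barley material (standardized seed
#' weight, protein content, test weight, ergosterol content), plus a grain
#' yield trait so that protein yield can be derived downstream.
#'
#' @param n_parents total number of distinct founder parents.
#' @param n_shared_parents number of parents used in both breeding sets.
#' @param set_sizes integer vector of length 2: lines per breeding set.
#' @param n_crosses crosses per breeding set; lines are assigned to crosses
#'   uniformly at random, so family sizes vary.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length genetic length per chromosome in cM.
#' @param n_markers total markers, spread near-equally over chromosomes.
#' @param n_qtl number of QTL per trait (sampled from the markers).
#' @param traits named list; each element is a numeric vector with entries
#'   `g`, `l`, `c`, `e`: the additive-genomic, residual-line, G-by-E and plot
#'   residual variances on the trait scale. `l = NA` drops the line effect
#'   for that trait.
#' @param trait_means named numeric: intercept per trait (trait units).
#' @param env_spread half-range of the fixed year-by-location effects,
#'   expressed as a multiple of the trait's total SD.
#' @param n_locations locations per year (each set is grown in one year).
#' @param n_replicates replicate plots per line and location.
#' @param selfing_generations generations of selfing after the F1 (5 = F6).
#' @param founder_freq_range range of the uniform distribution of founder
#'   allele frequencies.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param n_checks number of non-genotyped check lines (one plot per trial
#'   and block).
#' @param lines_per_trial lines grouped into one field trial.
#' @param seed RNG seed used by [simulate_dataset()].
#'
#' @return An object of class `sim_config` (a list of the above).
#' @export
#' @examples
#' cfg <- sim_config(set_sizes = c(30, 40), n_markers = 200, seed = 1)
sim_config <- function(n_parents = 104,
                       n_shared_parents = 16,
                       set_sizes = c(119, 190),
                       n_crosses = c(50, 50),
                       n_chromosomes = 7,
                       chromosome_length = 150,
                       n_markers = 3500,
                       n_qtl = 100,
                       traits = NULL,
                       trait_means = NULL,
                       env_spread = 0.5,
                       n_locations = 2,
                       n_replicates = 3,
                       selfing_generations = 5,
                       founder_freq_range = c(0.1, 0.9),
                       missing_rate = 0.01,
                       n_checks = 2,
                       lines_per_trial = 40,
                       seed = NULL) {
  if (is.null(traits)) {
    traits <- list(
      ssw        = c(g = 0.014, l = 0.009, c = 0.006, e = 0.009),
      protein    = c(g = 0.018, l = 0.018, c = 0.055, e = 0.145),
      tw         = c(g = 0.52,  l = 0.13,  c = 0.30,  e = 1.30),
      ergosterol = c(g = 1.16,  l = 0.50,  c = 0.39,  e = 0.39),
      yield      = c(g = 4,     l = 2,     c = 3,     e = 9)
    )
  }
  if (is.null(trait_means)) {
    tm <- c(ssw = 0, protein = 9.2, tw = 68.3, ergosterol = 13.2, yield = 90)
    trait_means <- tm[names(traits)]
    trait_means[is.na(trait_means)] <- 0
    names(trait_means) <- names(traits)
  }
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (!all(c("g", "c", "e") %in% names(v)))
      stop("trait '", tr, "' must supply variances named g, c, e (and l or l = NA)")
    if (any(v < 0, na.rm = TRUE))
      stop("negative variance component for trait '", tr, "'")
  }
  stopifnot(
    n_shared_parents <= n_parents, n_parents >= 2,
    length(set_sizes) == 2, all(set_sizes > 0),
    n_markers >= n_chromosomes, n_chromosomes >= 1,
    n_locations >= 1, n_replicates >= 1, selfing_generations >= 0,
    missing_rate >= 0, missing_rate < 1
  )
  if (chromosome_length <= 0) stop("chromosome_length must be positive")
  structure(list(
    n_parents = n_parents, n_shared_parents = n_shared_parents,
    set_sizes = as.integer(set_sizes), n_crosses = rep_len(n_crosses, 2),
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    n_markers = n_markers, n_qtl = n_qtl,
    traits = traits, trait_means = trait_means, env_spread = env_spread,
    n_locations = n_locations, n_replicates = n_replicates,
    selfing_generations = selfing_generations,
    founder_freq_range = founder_freq_range,
    missing_rate = missing_rate, n_checks = n_checks,
    lines_per_trial = lines_per_trial, seed = seed
  ), class = "sim_config")
}

#' Simulate a genetic map
#'
#' Markers are assigned to chromosomes in near-equal numbers (counts differ
#' by at most one) with positions uniform on `[0, chromosome_length]`,
#' sorted within chromosome.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `marker`, `chromosome`, `position` (cM).
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chromosome_length <= 0) stop("chromosome_length must be positive")
  n_chr <- config$n_chromosomes
  n_m <- config$n_markers
  counts <- rep(n_m %/% n_chr, n_chr)
  extra <- n_m %% n_chr
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  chrom <- rep(seq_len(n_chr), counts)
  pos <- unlist(lapply(counts, function(k) sort(runif(k, 0, config$chromosome_length))))
  data.frame(
    marker = sprintf("M%05d", seq_len(n_m)),
    chromosome = chrom,
    position = pos,
    stringsAsFactors = FALSE
  )
}

## one meiotic gamete from a diploid (two haplotype vectors), crossovers as a
## Poisson process at 1 crossover per 100 cM, no interference
.gamete <- function(h1, h2, chrom_index, chrom_pos, chrom_len) {
  out <- integer(length(h1))
  for (ch in seq_along(chrom_index)) {
    idx <- chrom_index[[ch]]
    n_xo <- rpois(1, chrom_len / 100)
    strand <- rbinom(1, 1, 0.5)
    if (n_xo == 0) {
      out[idx] <- if (strand == 0) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(n_xo, 0, chrom_len))
      seg <- findInterval(chrom_pos[[ch]], xo)
      use2 <- (strand + seg) %% 2 == 1
      out[idx] <- ifelse(use2, h2[idx], h1[idx])
    }
  }
  out
}

#' Simulate genotypes and pedigree for two breeding sets
#'
#' Founder parents are fully inbred lines with allele frequencies drawn
#' uniformly from `founder_freq_range`. Each line descends from a biparental
#' cross of two parents of its breeding set followed by
#' `selfing_generations` rounds of selfing with recombination (Poisson
#' crossovers, 1 per 100 cM, no interference). The two sets share exactly
#' `n_shared_parents` parents.
#'
#' @param config a [sim_config()].
#' @param map output of [simulate_map()].
#' @return list with `calls` (line x marker character matrix of
#'   `AA`/`AB`/`BB` with `NA` missing), `dosage` (line x marker count of the
#'   `B` allele, no missing — the true genotypes), `pedigree` (data.frame
#'   `line`, `parent1`, `parent2`, `set`).
#' @export
simulate_population <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_parents < 2) stop("need at least 2 parents")
  n_m <- nrow(map)
  chrom_index <- split(seq_len(n_m), map$chromosome)
  chrom_pos <- split(map$position, map$chromosome)

  ## inbred founders: one haplotype each, doubled
  p_founder <- runif(n_m, config$founder_freq_range[1], config$founder_freq_range[2])
  parent_ids <- sprintf("P%03d", seq_len(config$n_parents))
  founder_hap <- matrix(
    rbinom(config$n_parents * n_m, 1, rep(p_founder, each = config$n_parents)),
    nrow = config$n_parents, dimnames = list(parent_ids, map$marker)
  )

  ## parent pools: shared parents first, remainder split between the sets
  n_sh <- config$n_shared_parents
  shared <- parent_ids[seq_len(n_sh)]
  rest <- setdiff(parent_ids, shared)
  half <- ceiling(length(rest) / 2)
  pool <- list(c(shared, rest[seq_len(half)]),
               c(shared, rest[setdiff(seq_along(rest), seq_len(half))]))

  lines <- character(0); par1 <- character(0); par2 <- character(0); set <- integer(0)
  hap1 <- matrix(0L, sum(config$set_sizes), n_m)
  hap2 <- matrix(0L, sum(config$set_sizes), n_m)
  row <- 0L
  for (s in 1:2) {
    if (length(pool[[s]]) < 2) stop("fewer than 2 parents in breeding set ", s)
    n_cross <- max(1L, min(config$n_crosses[s], choose(length(pool[[s]]), 2)))
    crosses <- t(replicate(n_cross, sample(pool[[s]], 2)))
    assign <- sample.int(n_cross, config$set_sizes[s], replace = TRUE)
    for (i in seq_len(config$set_sizes[s])) {
      row <- row + 1L
      pa <- crosses[assign[i], 1]; pb <- crosses[assign[i], 2]
      ## F1 from inbred parents, then recurrent selfing
      h1 <- .gamete(founder_hap[pa, ], founder_hap[pa, ], chrom_index, chrom_pos, config$chromosome_length)
      h2 <- .gamete(founder_hap[pb, ], founder_hap[pb, ], chrom_index, chrom_pos, config$chromosome_length)
      if (config$selfing_generations > 0) {
        for (g in seq_len(config$selfing_generations)) {
          n1 <- .gamete(h1, h2, chrom_index, chrom_pos, config$chromosome_length)
          n2 <- .gamete(h1, h2, chrom_index, chrom_pos, config$chromosome_length)
          h1 <- n1; h2 <- n2
        }
      }
      hap1[row, ] <- h1; hap2[row, ] <- h2
      lines <- c(lines, sprintf("L%04d", row))
      par1 <- c(par1, pa); par2 <- c(par2, pb); set <- c(set, s)
    }
  }
  dosage <- hap1 + hap2
  dimnames(dosage) <- list(lines, map$marker)
  calls <- matrix(c("AA", "AB", "BB")[dosage + 1L], nrow = nrow(dosage),
                  dimnames = dimnames(dosage))
  if (config$missing_rate > 0) {
    miss <- runif(length(calls)) < config$missing_rate
    calls[miss] <- NA_character_
  }
  pedigree <- data.frame(line = lines, parent1 = par1, parent2 = par2,
                         set = c("S1", "S2")[set], stringsAsFactors = FALSE)
  list(calls = calls, dosage = dosage, pedigree = pedigree)
}

## fixed year x location effects: deterministic spread around the trait mean
.env_effects <- function(config, env_levels, trait) {
  v <- config$traits[[trait]]
  tot_sd <- sqrt(sum(v, na.rm = TRUE))
  k <- length(env_levels)
  off <- if (k == 1) 0 else seq(-1, 1, length.out = k) * config$env_spread * tot_sd
  setNames(config$trait_means[[trait]] + off, env_levels)
}

#' Simulate replicated field-trial phenotypes
#'
#' Each line is grown in its breeding set's year at `n_locations` locations
#' with `n_replicates` replicate plots. Per trait, `n_qtl` markers are drawn
#' as QTL with i.i.d. normal effects rescaled so the empirical variance of
#' the true breeding values equals the configured additive-genomic variance;
#' a residual line effect, a line-by-environment interaction and a plot
#' residual are added together with a fixed year-by-location effect.
#' Non-genotyped check lines get one plot per trial and block.
#'
#' @param config a [sim_config()].
#' @param pop output of [simulate_population()].
#' @return list with `phenotypes` (plot-level data.frame: `line`, `set`,
#'   `year`, `location`, `trial`, `block`, `plot`, seed-size fraction
#'   weights `f2.8`, `f2.5`, `f2.2` and one column per configured trait) and
#'   `tbv` (line x trait matrix of true breeding values).
#' @export
simulate_phenotypes <- function(config, pop) {
  stopifnot(inherits(config, "sim_config"))
  for (v in config$traits) if (any(v < 0, na.rm = TRUE)) stop("negative variance component")
  if (config$n_qtl > ncol(pop$dosage)) stop("n_qtl exceeds the number of markers")

  ped <- pop$pedigree
  lines <- ped$line
  years <- ifelse(ped$set == "S1", "2014", "2015")
  locations <- paste0("LOC", seq_len(config$n_locations))

  ## plot layout: trials chunk lines within a year; one block per replicate
  plots <- list()
  for (yr in unique(years)) {
    yl <- lines[years == yr]
    trial_of <- ceiling(seq_along(yl) / config$lines_per_trial)
    for (loc in locations) {
      for (rep_i in seq_len(config$n_replicates)) {
        plots[[length(plots) + 1L]] <- data.frame(
          line = yl, set = ped$set[years == yr],
          year = yr, location = loc,
          trial = sprintf("T%s_%s_%02d", yr, loc, trial_of),
          block = rep_i, stringsAsFactors = FALSE
        )
      }
    }
  }
  ph <- do.call(rbind, plots)
  ## check lines: one plot per trial and block
  if (config$n_checks > 0) {
    checks <- sprintf("CHECK%d", seq_len(config$n_checks))
    tb <- unique(ph[c("year", "location", "trial", "block")])
    chk <- tb[rep(seq_len(nrow(tb)), each = config$n_checks), ]
    chk$line <- rep(checks, nrow(tb))
    chk$set <- "CHECK"
    ph <- rbind(ph, chk[names(ph)])
  }
  ph <- ph[order(ph$year, ph$location, ph$trial, ph$block, ph$line), ]
  ph$plot <- seq_len(nrow(ph))
  env <- paste(ph$year, ph$location, sep = ":")
  env_levels <- sort(unique(env))

  coded <- pop$dosage - 1  # -1/0/1
  check_ids <- setdiff(unique(ph$line), lines)
  tbv <- matrix(0, length(lines), length(config$traits),
                dimnames = list(lines, names(config$traits)))
  for (tr in names(config$traits)) {
    v <- config$traits[[tr]]
    sig_g <- v[["g"]]; sig_l <- if (is.na(v["l"])) 0 else v[["l"]]
    sig_c <- v[["c"]]; sig_e <- v[["e"]]
    ## QTL-based breeding values on the scale of the genomic relationship
    ## matrix: effects are rescaled so the empirical TBV variance equals
    ## sig_g times the mean diagonal of the QTL-marker GRM (about 2 for
    ## inbred lines), making the simulated data consistent with the fitted
    ## model g ~ N(0, G sig_g) and its variance-component scale
    g_line <- setNames(numeric(length(lines)), lines)
    diag_scale <- 2
    if (sig_g > 0) {
      qtl <- sample.int(ncol(coded), config$n_qtl)
      Zq <- scale(coded[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
      pq <- (colMeans(coded[, qtl, drop = FALSE]) + 1) / 2
      denomq <- 2 * sum(pq * (1 - pq))
      diag_scale <- mean(rowSums(Zq^2)) / denomq
      eff <- rnorm(config$n_qtl)
      raw <- drop(Zq %*% eff)
      if (sd(raw) > 0)
        g_line[] <- (raw - mean(raw)) / sd(raw) * sqrt(sig_g * diag_scale)
    }
    tbv[, tr] <- g_line
    ## non-genotyped checks: genetic value drawn from the same distribution
    g_all <- c(g_line, setNames(rnorm(length(check_ids), 0,
                                      sqrt(sig_g * diag_scale)), check_ids))
    all_ids <- names(g_all)
    l_eff <- setNames(rnorm(length(all_ids), 0, sqrt(sig_l)), all_ids)
    ce_key <- unique(paste(ph$line, env, sep = "|"))
    c_eff <- setNames(rnorm(length(ce_key), 0, sqrt(sig_c)), ce_key)
    fx <- .env_effects(config, env_levels, tr)
    ph[[tr]] <- fx[env] + g_all[ph$line] + l_eff[ph$line] +
      c_eff[paste(ph$line, env, sep = "|")] +
      rnorm(nrow(ph), 0, sqrt(sig_e))
  }

  ## seed-size fraction weights: strictly monotone decreasing transforms of
  ## the per-plot seed-size trait, so larger seeds mean less mass in the
  ## small-sieve fractions (g per 100 g sample; < 2.2 mm dust excluded)
  size_col <- if ("ssw" %in% names(config$traits)) "ssw" else names(config$traits)[1]
  z <- ph[[size_col]]
  zs <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  f25 <- 100 * plogis(qlogis(0.144) - 0.5 * zs)
  f22 <- 100 * plogis(qlogis(0.025) - 0.5 * zs)
  dust <- 100 * plogis(qlogis(0.010) - 0.3 * zs)
  ph$f2.8 <- 100 - f25 - f22 - dust
  ph$f2.5 <- f25
  ph$f2.2 <- f22
  rownames(ph) <- NULL
  front <- c("line", "set", "year", "location", "trial", "block", "plot",
             "f2.8", "f2.5", "f2.2")
  ph <- ph[c(front, setdiff(names(ph), front))]
  list(phenotypes = ph, tbv = tbv)
}

#' Simulate a complete breeding-program dataset
#'
#' Runs [simulate_map()], [simulate_population()] and
#' [simulate_phenotypes()] under one seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: list with `calls`, `dosage`,
#'   `phenotypes`, `pedigree`, `map`, `tbv`, `true_components`, `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(set_sizes = c(15, 20), n_parents = 12,
#'                                    n_markers = 120, seed = 42))
#' dim(sim$calls)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- simulate_map(config)
  pop <- simulate_population(config, map)
  phe <- simulate_phenotypes(config, pop)
  structure(list(
    calls = pop$calls, dosage = pop$dosage,
    phenotypes = phe$phenotypes, pedigree = pop$pedigree,
    map = map, tbv = phe$tbv, true_components = config$traits,
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated breeding dataset:", nrow(x$calls), "lines x",
      ncol(x$calls), "markers;", nrow(x$phenotypes), "plots;",
      length(x$true_components), "traits\n")
  invisible(x)
}

#' Write a simulated dataset as CSV files
#'
#' Emits `genotypes.csv` (line ID column + one column per marker, calls
#' `AA`/`AB`/`BB`, missing empty), `phenotypes.csv`, `pedigree.csv` and
#' `map.csv` in the dialects the readers in this package expect.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "genotypes.csv")
  gdf <- data.frame(line = rownames(sim$calls), sim$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(gdf, gp, row.names = FALSE, na = "")
  pp <- file.path(dir, "phenotypes.csv")
  write.csv(sim$phenotypes, pp, row.names = FALSE, na = "")
  dp <- file.path(dir, "pedigree.csv")
  write.csv(sim$pedigree, dp, row.names = FALSE)
  mp <- file.path(dir, "map.csv")
  write.csv(sim$map, mp, row.names = FALSE)
  invisible(c(genotypes = gp, phenotypes = pp, pedigree = dp, map = mp))
}
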