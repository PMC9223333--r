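# simulate: coalescent generation of genotype datasets under two-population
# founder-event and admixture demographies, plus the data-degradation
# operators (haploid pairing, pseudo-haploidisation, missingness, thinning).
# The coalescent engine is pluggable; the bundled backend shells out to
# msprime through inst/python/founder_sim.py.

#' Demography configuration for the simulation module
#'
#' Describes the standard validation demography: a target population A and
#' an outgroup O of constant diploid effective size `N_o` that diverged
#' `divergence_time` generations ago; A optionally experiences a bottleneck
#' of size `N_f` for `D_f` generations ending `T_f` generations before
#' sampling (so the bottleneck spans `[T_f, T_f + D_f]` looking backwards).
#' The nominal founder intensity is `I_f = D_f / (2 N_f)`. An optional pulse
#' admixture forms A from two sources at `admixture$time` generations with
#' `admixture$proportions` (summing to 1); the first source doubles as the
#' outgroup.
#'
#' @param N_o Diploid effective size outside the bottleneck (default 12,500).
#' @param N_f,D_f,T_f Bottleneck size, duration and end time (generations
#'   before sampling); all three or none.
#' @param divergence_time Split time of target and outgroup in generations
#'   (default 1,800).
#' @param mutation_rate,recombination_rate Per bp per generation (defaults
#'   1.2e-8 and 1e-8).
#' @param n_chromosomes,chromosome_length_bp Genome layout (default 20
#'   chromosomes of 50 Mb, each with a constant-rate genetic map, i.e.
#'   0.5 Morgans per chromosome at the default recombination rate).
#' @param haploids_per_pop Haploid genomes sampled per population (default
#'   30, paired into 15 diploids).
#' @param admixture Optional `list(time =, proportions = c(p1, p2))`.
#' @param seed Integer seed; all downstream randomness derives from it.
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(N_o = 12500, N_f = NULL, D_f = NULL, T_f = NULL,
                              divergence_time = 1800,
                              mutation_rate = 1.2e-8,
                              recombination_rate = 1e-8,
                              n_chromosomes = 20,
                              chromosome_length_bp = 5e7,
                              haploids_per_pop = 30,
                              admixture = NULL, seed = 1) {
  has_b <- !is.null(N_f) || !is.null(D_f) || !is.null(T_f)
  if (has_b && (is.null(N_f) || is.null(D_f) || is.null(T_f)))
    config_error("specify all of N_f, D_f, T_f or none")
  if (has_b) {
    if (N_f < 1 || D_f <= 0 || T_f < 0)
      config_error("need N_f >= 1, D_f > 0, T_f >= 0")
    if (N_f > N_o)
      config_error("founder scenarios require N_f <= N_o")
    horizon <- if (!is.null(admixture)) admixture$time else divergence_time
    if (T_f + D_f >= horizon)
      config_error(sprintf("bottleneck onset T_f + D_f = %g must predate %g (the %s time)",
                           T_f + D_f, horizon,
                           if (!is.null(admixture)) "admixture" else "divergence"))
  }
  if (!is.null(admixture)) {
    if (!is.list(admixture) || is.null(admixture$time) || is.null(admixture$proportions))
      config_error("admixture must be list(time =, proportions =)")
    if (length(admixture$proportions) != 2 ||
        abs(sum(admixture$proportions) - 1) > 1e-8)
      config_error("admixture proportions must be two values summing to 1")
    if (admixture$time >= divergence_time)
      config_error("admixture must postdate the source divergence")
  }
  if (haploids_per_pop < 4 || haploids_per_pop %% 2 != 0)
    config_error("haploids_per_pop must be an even number >= 4")
  structure(list(N_o = N_o, N_f = N_f, D_f = D_f, T_f = T_f,
                 divergence_time = divergence_time,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 haploids_per_pop = as.integer(haploids_per_pop),
                 admixture = admixture, seed = as.integer(seed),
                 I_f = if (has_b) D_f / (2 * N_f) else NA_real_),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat(sprintf("<demography_config> N_o = %g, divergence %g generations\n",
              x$N_o, x$divergence_time))
  if (!is.null(x$N_f))
    cat(sprintf("  bottleneck: N_f = %g for D_f = %g generations ending T_f = %g (I_f = %.3g)\n",
                x$N_f, x$D_f, x$T_f, x$I_f))
  else cat("  no bottleneck (constant size)\n")
  if (!is.null(x$admixture))
    cat(sprintf("  admixture at %g generations, proportions %s\n",
                x$admixture$time, paste(x$admixture$proportions, collapse = "/")))
  cat(sprintf("  genome: %d x %.3g bp, mu = %g, r = %g, %d haploids/pop, seed %d\n",
              x$n_chromosomes, x$chromosome_length_bp, x$mutation_rate,
              x$recombination_rate, x$haploids_per_pop, x$seed))
  invisible(x)
}

python_binary <- function() Sys.getenv("ASCENDR_PYTHON", "python")

run_backend <- function(config, model) {
  script <- system.file("python", "founder_sim.py", package = "ascendr")
  if (script == "") data_error("bundled simulation script not found")
  cfg <- unclass(config)
  cfg$model <- model
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  prefix <- tempfile("ascendr_sim_")
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(script), shQuote(cfg_path), shQuote(prefix)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    data_error(paste0("coalescent backend failed:\n", paste(out, collapse = "\n")))
  ds <- read_eigenstrat(paste0(prefix, ".geno"), paste0(prefix, ".snp"),
                        paste0(prefix, ".ind"), ploidy = "haploid")
  manifest <- jsonlite::read_json(paste0(prefix, ".manifest.json"))
  unlink(paste0(prefix, c(".geno", ".snp", ".ind", ".manifest.json")))
  unlink(cfg_path)
  attr(ds, "manifest") <- c(manifest, list(config = unclass(config)))
  ds
}

#' Simulate genotypes under the two-population founder model
#'
#' Coalescent simulation of the target population A (optionally with the
#' epoch bottleneck) and the outgroup O, on `n_chromosomes` independent
#' chromosomes with constant-rate genetic maps. Haploid genomes are paired
#' at random without replacement into diploid individuals (see
#' [pair_haploids()]). Only biallelic segregating sites are emitted, and the
#' result is deterministic given the config seed.
#'
#' @param config A [demography_config()].
#' @param return_haploids Return the raw haploid dataset instead of pairing.
#' @return A [genotype_dataset()] with populations `A` (target) and `O`
#'   (outgroup) and a `manifest` attribute recording the seed, engine
#'   version and nominal `(T_f, I_f)`.
#' @export
simulate_founder_model <- function(config, return_haploids = FALSE) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(config$admixture))
    config_error("config has an admixture event; use simulate_admixture_founder()")
  ds <- run_backend(config, "founder")
  if (return_haploids) return(ds)
  pair_haploids(ds, seed = config$seed)
}

#' Simulate an admixed target with an optional founder event
#'
#' Three-population variant: sources A' and B' diverge at
#' `divergence_time`; the target A is formed by a pulse admixture at
#' `admixture$time` with the configured proportions, optionally followed by
#' a bottleneck in A. The first source (A') is returned as the outgroup
#' population `O`.
#'
#' @param config A [demography_config()] with a non-NULL `admixture`.
#' @inherit simulate_founder_model return
#' @export
simulate_admixture_founder <- function(config, return_haploids = FALSE) {
  stopifnot(inherits(config, "demography_config"))
  if (is.null(config$admixture))
    config_error("config has no admixture event; use simulate_founder_model()")
  ds <- run_backend(config, "admixture")
  if (return_haploids) return(ds)
  pair_haploids(ds, seed = config$seed)
}

#' Pair haploid genomes into diploid individuals
#'
#' Combines haploid genomes two at a time, at random without replacement
#' within each population; the diploid genotype is the sum of the two
#' haploid alleles. 30 haploids yield 15 diploids.
#'
#' @param dataset A haploid [genotype_dataset()] (values 0/1).
#' @param seed Optional integer seed for the random matching.
#' @return A diploid [genotype_dataset()].
#' @export
pair_haploids <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (dataset$ploidy != "haploid")
    data_error("pair_haploids expects a haploid dataset")
  pops <- unique(dataset$ind$population)
  cols <- list(); ids <- character(0); popv <- character(0)
  with_seed(seed, {
    for (pop in pops) {
      ix <- which(dataset$ind$population == pop)
      if (length(ix) %% 2 != 0)
        data_error(sprintf("population %s has an odd number of haploids (%d)",
                           pop, length(ix)))
      perm <- sample(ix)
      n_d <- length(ix) / 2
      for (k in seq_len(n_d)) {
        cols[[length(cols) + 1]] <- c(perm[2 * k - 1], perm[2 * k])
        ids <- c(ids, sprintf("%s_%d", pop, k))
        popv <- c(popv, pop)
      }
    }
  })
  geno <- vapply(cols, function(cc)
    dataset$geno[, cc[1]] + dataset$geno[, cc[2]], integer(nrow(dataset$geno)))
  out <- genotype_dataset(geno, dataset$snp,
                          tibble(id = ids, sex = "U", population = popv),
                          ploidy = "diploid")
  attr(out, "manifest") <- attr(dataset, "manifest")
  out
}

#' Pseudo-haploidise a diploid dataset
#'
#' Emulates the genotype calling used for low-coverage ancient DNA: at each
#' heterozygous call one of the two alleles is chosen at random (fair coin)
#' and reported as a homozygous genotype; homozygous and missing calls are
#' unchanged.
#'
#' @param dataset A diploid [genotype_dataset()].
#' @param seed Optional integer seed.
#' @return A [genotype_dataset()] with `ploidy = "pseudo_haploid"`.
#' @export
pseudo_haploidize <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (dataset$ploidy != "diploid")
    data_error("pseudo_haploidize expects a diploid dataset")
  g <- dataset$geno
  het <- which(!is.na(g) & g == 1L)
  g[het] <- with_seed(seed, 2L * rbinom(length(het), 1L, 0.5))
  out <- dataset
  out$geno <- g
  out$ploidy <- "pseudo_haploid"
  attr(out, "manifest") <- attr(dataset, "manifest")
  out
}

#' Set genotypes missing at random
#'
#' Each genotype is independently replaced by missing with probability
#' `rate`; used to emulate the sparse coverage of ancient-DNA datasets
#' (analyses remain reliable up to roughly 70% missingness).
#'
#' @param dataset A [genotype_dataset()].
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The degraded [genotype_dataset()].
#' @export
inject_missingness <- function(dataset, rate, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    config_error("rate must lie in [0, 1]")
  g <- dataset$geno
  if (rate > 0) {
    drop <- with_seed(seed, runif(length(g)) < rate)
    g[drop] <- NA_integer_
  }
  out <- dataset
  out$geno <- g
  attr(out, "manifest") <- attr(dataset, "manifest")
  out
}
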