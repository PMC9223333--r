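# Shared fixtures. Simulated datasets are cached in tempdir() so several
# test files can reuse one coalescent run within a session.

fixture_cached <- function(name, expr) {
  path <- file.path(tempdir(), paste0("ascendr_fixture_", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

# Small deterministic toy: explicit genotypes, one or two chromosomes.
toy_dataset <- function(geno, gpos, chrom = rep("1", length(gpos)),
                        populations = rep("A", ncol(geno)),
                        ploidy = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  genotype_dataset(
    geno,
    data.frame(id = paste0("s", seq_len(n)), chrom = chrom, gpos = gpos,
               ppos = seq_len(n), a1 = "A", a2 = "G"),
    data.frame(id = paste0("i", seq_len(m)), sex = "U",
               population = populations),
    ploidy = ploidy)
}

# Random toy with optional missingness, for oracle comparisons.
random_dataset <- function(n_snp, n_ind, seed, miss = 0,
                           span_M = 0.05, populations = NULL) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n_snp * n_ind, TRUE), n_snp, n_ind)
  if (miss > 0) geno[runif(length(geno)) < miss] <- NA_integer_
  toy_dataset(geno, sort(runif(n_snp, 0, span_M)),
              populations = populations %||%
                rep("A", n_ind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force double-loop profile oracle (correlation mode), mirroring the
# documented skipping rules: pairwise-complete, >= 2 observations, non-zero
# variance in both vectors.
oracle_profile <- function(ds, ids, bins) {
  ps <- build_pair_sharing(ds, ids)
  sh <- ps$sharing
  gp <- ds$snp$gpos * 100
  ch <- ds$snp$chrom
  D <- bins$n
  osum <- numeric(D); ocnt <- numeric(D)
  n <- nrow(sh)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ch[i] != ch[j]) next
    d <- gp[j] - gp[i]
    if (d < bins$min || d >= bins$max) next
    b <- floor((d - bins$min) / bins$step + 1e-9) + 1
    x <- sh[i, ]; y <- sh[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    osum[b] <- osum[b] + cor(x[ok], y[ok])
    ocnt[b] <- ocnt[b] + 1
  }
  list(value = ifelse(ocnt > 0, osum / ocnt, NA_real_), n = ocnt)
}

# Hand-built jackknife summary for exercising the classifier.
fake_jk <- function(tf, tf_se, if_, if_se) {
  est <- tibble::tibble(
    param = c("a", "t", "c", "T_f", "I_f"),
    estimate = c(if_ / exp(1), tf / 100, 0, tf, if_),
    se = c(if_se / exp(1), tf_se / 100, 0, tf_se, if_se))
  est$ci_lo <- est$estimate - 1.96 * est$se
  est$ci_hi <- est$estimate + 1.96 * est$se
  structure(list(estimates = est, n_blocks = 10), class = "jackknife_result")
}

# One moderately sized founder simulation reused by the engine/pipeline
# unit tests: 4 chromosomes x 20 Mb, strong recent event (I_f = 10%).
# Chromosomes are kept at 20 cM so that decay-curve fits see a long enough
# distance window for the affine offset to be identifiable.
founder_fixture <- function() {
  fixture_cached("founder_small", {
    cfg <- demography_config(N_f = 50, D_f = 10, T_f = 10,
                             n_chromosomes = 4, chromosome_length_bp = 2e7,
                             seed = 101)
    simulate_founder_model(cfg)
  })
}
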