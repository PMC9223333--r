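test_that("demography configs are validated", {
  expect_error(demography_config(N_f = 100), "all of N_f, D_f, T_f")
  expect_error(demography_config(N_f = 100, D_f = 20, T_f = 1790),
               "predate")
  expect_error(demography_config(N_f = 20000, D_f = 10, T_f = 10),
               "N_f <= N_o")
  expect_error(demography_config(haploids_per_pop = 7), "even")
  expect_error(demography_config(admixture = list(time = 110,
                                                  proportions = c(0.6, 0.5))),
               "summing to 1")
  expect_error(demography_config(N_f = 100, D_f = 20, T_f = 100,
                                 admixture = list(time = 110,
                                                  proportions = c(0.6, 0.4))),
               "predate")

  # the nominal intensity of the standard strong-founder scenario
  cfg <- demography_config(N_f = 250, D_f = 15, T_f = 30)
  expect_equal(cfg$I_f, 0.03)
  expect_equal(demography_config(N_f = 420, D_f = 15, T_f = 30)$I_f,
               15 / 840)
})

test_that("simulation is seed-deterministic and labelled", {
  cfg <- demography_config(N_f = 50, D_f = 10, T_f = 10, n_chromosomes = 1,
                           chromosome_length_bp = 5e6, seed = 77)
  ds1 <- simulate_founder_model(cfg)
  ds2 <- simulate_founder_model(cfg)
  expect_identical(ds1$geno, ds2$geno)
  expect_identical(ds1$snp$gpos, ds2$snp$gpos)
  expect_identical(sort(unique(ds1$ind$population)), c("A", "O"))
  expect_identical(ds1$ploidy, "diploid")
  expect_identical(dim(ds1$geno)[2], 30L)  # 15 + 15 diploids

  man <- attr(ds1, "manifest")
  expect_equal(man$nominal_I_f, 0.1)
  expect_equal(man$nominal_T_f, 10)
  expect_identical(man$engine, "msprime")

  ds3 <- simulate_founder_model(demography_config(
    N_f = 50, D_f = 10, T_f = 10, n_chromosomes = 1,
    chromosome_length_bp = 5e6, seed = 78))
  expect_false(isTRUE(all.equal(dim(ds3$geno), dim(ds1$geno))) &&
                 identical(ds3$geno, ds1$geno))
})

test_that("haploid pairing sums alleles and uses each haploid once", {
  # constructed haploid dataset with recognisable columns
  set.seed(5)
  h <- matrix(sample(0:1, 20 * 8, TRUE), 20, 8)
  ds <- toy_dataset(h, sort(runif(20, 0, 0.01)),
                    populations = rep(c("A", "O"), each = 4),
                    ploidy = "haploid")
  d <- pair_haploids(ds, seed = 3)
  expect_identical(ncol(d$geno), 4L)     # 8 haploids -> 4 diploids
  expect_identical(d$ploidy, "diploid")
  expect_true(all(d$geno %in% 0:2))
  # allele counts are conserved within each population
  for (pop in c("A", "O")) {
    hcols <- ds$ind$population == pop
    dcols <- d$ind$population == pop
    expect_equal(rowSums(d$geno[, dcols]), rowSums(h[, hcols]))
  }

  odd <- toy_dataset(h[, 1:7], sort(runif(20, 0, 0.01)),
                     populations = rep(c("A", "O"), c(4, 3)),
                     ploidy = "haploid")
  expect_error(pair_haploids(odd, seed = 1), "odd number")
  expect_error(pair_haploids(d, seed = 1), "haploid dataset")
})

test_that("pseudo-haploidisation flips hets to random homozygotes", {
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 4000, TRUE, prob = c(.2, .4, .2, .2)), 1000, 4)
  ds <- toy_dataset(g, sort(runif(1000, 0, 0.5)), ploidy = "diploid")
  ph <- pseudo_haploidize(ds, seed = 13)
  expect_identical(ph$ploidy, "pseudo_haploid")
  expect_false(any(ph$geno == 1L, na.rm = TRUE))
  hom <- !is.na(g) & g != 1L
  expect_identical(ph$geno[hom], g[hom])          # homozygotes unchanged
  expect_identical(is.na(ph$geno), is.na(g))      # missing stays missing
  het <- which(!is.na(g) & g == 1L)
  frac2 <- mean(ph$geno[het] == 2L)
  expect_gt(frac2, 0.45); expect_lt(frac2, 0.55)  # fair coin
  expect_identical(pseudo_haploidize(ds, seed = 13)$geno, ph$geno)
  expect_error(pseudo_haploidize(ph, seed = 1), "diploid")
})

test_that("missingness injection hits the requested rate", {
  set.seed(21)
  ds <- toy_dataset(matrix(sample(0:2, 5000, TRUE), 1000, 5),
                    sort(runif(1000, 0, 0.5)))
  expect_identical(inject_missingness(ds, 0, seed = 2)$geno, ds$geno)
  m <- inject_missingness(ds, 0.7, seed = 2)
  rate <- mean(is.na(m$geno))
  expect_gt(rate, 0.67); expect_lt(rate, 0.73)
  all_gone <- inject_missingness(ds, 1, seed = 2)
  expect_true(all(is.na(all_gone$geno)))
  expect_error(filter_sites(all_gone, "A"), "no informative sites")
  expect_error(inject_missingness(ds, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("admixture simulation runs and validates its spec", {
  cfg <- demography_config(n_chromosomes = 1, chromosome_length_bp = 5e6,
                           admixture = list(time = 110, proportions = c(0.6, 0.4)),
                           seed = 31)
  ds <- simulate_admixture_founder(cfg)
  expect_identical(sort(unique(ds$ind$population)), c("A", "O"))
  expect_gt(nrow(ds$geno), 1000)
  expect_error(simulate_admixture_founder(
    demography_config(n_chromosomes = 1, seed = 1)), "no admixture")
  expect_error(simulate_founder_model(cfg), "admixture")
})

test_that("admixture does not confound the founder-event estimates", {
  # pulse admixture at 110 generations, then a single-generation bottleneck
  # ending 50 generations ago in the admixed target; one ancestral source
  # population doubles as the outgroup
  cfg <- demography_config(N_f = 5, D_f = 1, T_f = 50, n_chromosomes = 5,
                           chromosome_length_bp = 1.2e7,
                           admixture = list(time = 110,
                                            proportions = c(0.6, 0.4)),
                           seed = 515)
  ds <- simulate_admixture_founder(cfg)
  out <- ds$ind$id[ds$ind$population == "O"]
  dsf <- thin_sites(filter_sites(ds, "A", out), 1800, seed = 2)
  fit <- fit_founder_event(allele_sharing_profile(dsf, "A",
                                                  outgroup_ids = out,
                                                  engine = "naive"))
  tf <- tidy(fit)[tidy(fit)$param == "T_f", ]
  expect_true(fit$call$significant)
  expect_lte(tf$ci_lo, 51)
  expect_gte(tf$ci_hi, 50)
})

test_that("a deeply diverged outgroup shows near-zero cross correlation", {
  ds <- founder_fixture()
  out <- select_outgroup(ds, "A", 15, seed = 5)
  dsf <- thin_sites(filter_sites(ds, "A", out), 1200, seed = 6)
  zc <- pool_profile(cross_profile_naive(dsf, "A", out,
                                         distance_bins(0.1, 8, 0.1)))
  expect_lt(max(abs(zc$value), na.rm = TRUE), 0.02)
  expect_lt(abs(mean(zc$value, na.rm = TRUE)), 0.005)
})
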