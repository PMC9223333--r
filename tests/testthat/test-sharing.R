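test_that("sharing_count follows the IBS rules including unphased hets", {
  expect_identical(sharing_count(2L, 2L), 2L)   # identical homozygotes
  expect_identical(sharing_count(0L, 0L), 2L)
  expect_identical(sharing_count(0L, 2L), 0L)   # opposite homozygotes
  expect_identical(sharing_count(1L, 1L), 1L)   # one shared allele, phase-free
  expect_identical(sharing_count(1L, 0L), 1L)
  expect_identical(sharing_count(1L, 2L), 1L)
  expect_identical(sharing_count(NA_integer_, 2L), NA_integer_)
  expect_error(sharing_count(3L, 0L), "genotypes")
})

test_that("expected_heterozygosity is 2p(1-p) with domain checks", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(expected_heterozygosity(0.2), 0.32)
  expect_error(expected_heterozygosity(1.2), "\\[0, 1\\]")
})

test_that("build_pair_sharing enumerates pairs and matches hand counts", {
  # 3 SNPs x 3 individuals, counted by hand
  geno <- rbind(c(0L, 1L, 2L),
                c(2L, 2L, NA),
                c(0L, 0L, 0L))
  ds <- toy_dataset(geno, c(0.001, 0.002, 0.003))
  ps <- build_pair_sharing(ds, ds$ind$id)
  expect_identical(nrow(ps$pair_index), 3L)  # 3 choose 2
  expect_identical(ps$sharing[, 1], c(1L, 2L, 2L))         # i1-i2
  expect_identical(ps$sharing[, 2], c(0L, NA_integer_, 2L)) # i1-i3
  expect_identical(ps$sharing[, 3], c(1L, NA_integer_, 2L)) # i2-i3

  # 4 individuals -> 6 within-population pairs
  ds4 <- random_dataset(5, 4, seed = 1)
  expect_identical(nrow(build_pair_sharing(ds4, ds4$ind$id)$pair_index), 6L)
  expect_error(build_pair_sharing(ds4, data.frame(id1 = "i1", id2 = "nope")),
               "unknown")
})

test_that("sharing is invariant to ref/alt allele swaps", {
  ds <- random_dataset(30, 6, seed = 2, miss = 0.1)
  swapped <- ds
  swapped$geno <- 2L - ds$geno  # relabel alleles at every SNP
  s1 <- build_pair_sharing(ds, ds$ind$id)$sharing
  s2 <- build_pair_sharing(swapped, ds$ind$id)$sharing
  expect_identical(s1, s2)
})

test_that("bin_snp_pairs respects the distance window and chromosomes", {
  snps <- data.frame(chrom = c("1", "1", "1", "2"),
                     gpos = c(0, 0.0007, 0.0015, 0.0016))
  b <- bin_snp_pairs(snps, distance_bins(0.1, 30, 0.1))
  # pair at 0.07 cM excluded; cross-chromosome pairs excluded
  expect_false(any(b$i == 1 & b$j == 2))
  expect_false(any(b$j == 4))
  # pair at 0.15 cM lands in [0.1, 0.2)
  row <- b[b$i == 1 & b$j == 3, ]
  expect_identical(row$bin, 1L)
  expect_equal(row$d_cM, 0.15)
  # 0.08 cM apart (SNPs 2,3): excluded as well
  expect_false(any(b$i == 2 & b$j == 3))
})

test_that("exact within-population profile equals the brute-force oracle", {
  bins <- distance_bins(0.1, 5, 0.1)
  for (seed in c(11, 12, 13)) {
    ds <- random_dataset(40, 7, seed = seed, miss = if (seed == 13) 0.2 else 0)
    prof <- within_profile_naive(build_pair_sharing(ds, ds$ind$id), bins)
    tb <- pool_profile(prof)
    orc <- oracle_profile(ds, ds$ind$id, bins)
    expect_equal(tb$value, orc$value, tolerance = 1e-12)
    expect_equal(as.numeric(tb$n_snp_pairs), orc$n)
    expect_true(all(abs(tb$value) <= 1, na.rm = TRUE))
  }
})

test_that("profiles are invariant to individual order and chromosome order", {
  ds <- random_dataset(60, 6, seed = 21, miss = 0.1)
  ds$snp$chrom <- rep(c("1", "2"), each = 30)
  bins <- distance_bins(0.1, 3, 0.1)
  base <- pool_profile(within_profile_naive(build_pair_sharing(ds, ds$ind$id), bins))

  perm <- rev(ds$ind$id)
  permuted <- pool_profile(within_profile_naive(build_pair_sharing(ds, perm), bins))
  expect_equal(base$value, permuted$value)

  flipped <- genotype_dataset(ds$geno[c(31:60, 1:30), ],
                              ds$snp[c(31:60, 1:30), ], ds$ind)
  flipprof <- pool_profile(within_profile_naive(
    build_pair_sharing(flipped, flipped$ind$id), bins))
  expect_equal(base$value, flipprof$value)
})

test_that("cross profile uses target x outgroup pairs and is role-symmetric", {
  ds <- random_dataset(40, 8, seed = 31,
                       populations = rep(c("A", "O"), c(5, 3)))
  bins <- distance_bins(0.1, 5, 0.1)
  # single outgroup individual, 5 targets -> 5 pairs
  ps <- build_pair_sharing(ds, ascendr:::cross_pairs(
    ds$ind$id[ds$ind$population == "A"], "i6"))
  expect_identical(nrow(ps$pair_index), 5L)

  p1 <- pool_profile(cross_profile_naive(ds, "A", c("i6", "i7"), bins))
  p2 <- pool_profile(cross_profile_naive(ds, "A", c("i7", "i6"), bins))
  expect_equal(p1$value, p2$value)
  expect_error(cross_profile_naive(ds, "A", c("i1", "i6"), bins), "overlaps")
})

test_that("corrected profile is the binwise difference z_w - z_c", {
  ds <- random_dataset(40, 9, seed = 41,
                       populations = rep(c("A", "O"), c(6, 3)))
  bins <- distance_bins(0.1, 5, 0.1)
  zw <- within_profile_naive(
    build_pair_sharing(ds, ds$ind$id[ds$ind$population == "A"]), bins)
  zc <- cross_profile_naive(ds, "A", ds$ind$id[ds$ind$population == "O"], bins)
  z <- corrected_profile(zw, zc)
  tw <- pool_profile(zw); tc <- pool_profile(zc); tz <- pool_profile(z)
  expect_equal(tz$value, tw$value - tc$value)
  # absent in either component -> absent in the difference
  expect_true(all(is.na(tz$value[is.na(tw$value) | is.na(tc$value)])))

  other <- within_profile_naive(
    build_pair_sharing(ds, ds$ind$id[ds$ind$population == "A"]),
    distance_bins(0.1, 4, 0.1))
  expect_error(corrected_profile(zw, other), "different distance bins")
})

test_that("weighted covariance equals cov / (He_i He_j) against a direct loop", {
  ds <- random_dataset(30, 8, seed = 51)
  ids <- ds$ind$id
  bins <- distance_bins(0.1, 4, 0.1)
  he <- rep(0.5, 30)
  prof <- weighted_cov_profile(build_pair_sharing(ds, ids), he, bins)
  expect_identical(prof$mode, "weighted_cov")
  tb <- pool_profile(prof)

  # the statistic is the covariance of shared-allele fractions (counts / 2)
  # normalised by the He product; with He = 0.5 everywhere that is
  # cov(N/2)/0.25 = cov(N)
  sh <- build_pair_sharing(ds, ids)$sharing
  gp <- ds$snp$gpos * 100
  osum <- numeric(bins$n); ocnt <- numeric(bins$n)
  for (i in 1:29) for (j in (i + 1):30) {
    d <- gp[j] - gp[i]
    if (d < bins$min || d >= bins$max) next
    b <- floor((d - bins$min) / bins$step + 1e-9) + 1
    osum[b] <- osum[b] + cov(sh[i, ] / 2, sh[j, ] / 2) / 0.25
    ocnt[b] <- ocnt[b] + 1
  }
  expect_equal(tb$value, ifelse(ocnt > 0, osum / ocnt, NA), tolerance = 1e-12)

  expect_error(weighted_cov_profile(build_pair_sharing(ds, ids),
                                    rep(0, 30), bins),
               "positive")
})
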