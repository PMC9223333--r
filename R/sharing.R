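# sharing_core: IBS sharing counts, SNP-pair distance binning, and the
# within/cross correlation and weighted-covariance profiles.

#' IBS allele-sharing count for genotype pairs
#'
#' Number of alleles shared identical-by-state by two genotypes at one SNP:
#' 2 for identical homozygotes, 0 for opposite homozygotes, and 1 whenever
#' either genotype is heterozygous (one allele is shared regardless of
#' haplotype phase, which is what frees the statistic from phasing).
#' Missing if either genotype is missing.
#'
#' @param g_a,g_b Integer vectors over \{0, 1, 2, NA\} (recycled).
#' @return Integer vector over \{0, 1, 2, NA\}.
#' @examples
#' sharing_count(c(2, 0, 1, 1, NA), c(2, 2, 1, 0, 2))
#' @export
sharing_count <- function(g_a, g_b) {
  ok_a <- is.na(g_a) | g_a %in% 0:2
  ok_b <- is.na(g_b) | g_b %in% 0:2
  if (!all(ok_a) || !all(ok_b))
    data_error("genotypes must be 0, 1, 2 or NA")
  out <- ifelse(g_a == 1L | g_b == 1L, 1L, ifelse(g_a == g_b, 2L, 0L))
  out[is.na(g_a) | is.na(g_b)] <- NA_integer_
  as.integer(out)
}

#' Expected heterozygosity from an allele frequency
#'
#' `2 p (1 - p)` for reference-allele frequency `p`. Used to normalise the
#' weighted allele-sharing covariance for pseudo-haploid or sparse data.
#'
#' @param p Numeric vector of allele frequencies in `[0, 1]`.
#' @return Numeric vector of expected heterozygosities.
#' @examples
#' expected_heterozygosity(c(0, 0.2, 0.5))
#' @export
expected_heterozygosity <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    data_error("allele frequencies must lie in [0, 1]")
  2 * p * (1 - p)
}

# Per-SNP He from a set of samples (rows of geno over 0..ploidy_max).
he_for_samples <- function(dataset, ids) {
  cols <- match(ids, dataset$ind$id)
  g <- dataset$geno[, cols, drop = FALSE]
  denom <- if (dataset$ploidy == "haploid") 1 else 2
  p <- rowMeans(g, na.rm = TRUE) / denom
  p[is.nan(p)] <- NA_real_
  expected_heterozygosity(ifelse(is.na(p), 0, p))
}

# All unordered pairs among ids -> tibble(id1, id2)
within_pairs <- function(ids) {
  if (length(ids) < 2) data_error("need at least 2 individuals to form pairs")
  cmb <- utils::combn(ids, 2)
  tibble(id1 = cmb[1, ], id2 = cmb[2, ])
}

cross_pairs <- function(target_ids, outgroup_ids) {
  if (!length(target_ids) || !length(outgroup_ids))
    data_error("both target and outgroup must be non-empty")
  if (length(intersect(target_ids, outgroup_ids)))
    data_error("outgroup overlaps the target population")
  g <- expand.grid(id1 = target_ids, id2 = outgroup_ids,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble(id1 = g$id1, id2 = g$id2)
}

pairs_to_idx <- function(dataset, pairs) {
  i1 <- match(pairs$id1, dataset$ind$id)
  i2 <- match(pairs$id2, dataset$ind$id)
  if (any(is.na(i1)) || any(is.na(i2)))
    data_error("pair list contains unknown individual ids")
  cbind(i1, i2) - 1L
}

#' Build the pair allele-sharing matrix
#'
#' Applies [sharing_count()] to every SNP for every listed pair of
#' individuals, giving the SNPs x pairs sharing matrix on which the profile
#' statistics operate.
#'
#' @param dataset A [genotype_dataset()].
#' @param pairs Two-column data frame (or matrix) of individual ids, or a
#'   character vector of ids from which all unordered pairs are formed.
#' @return An object of class `pair_sharing`: a list with `pair_index`
#'   (tibble of id pairs), `sharing` (integer SNPs x pairs matrix, `NA` where
#'   either member is missing) and `snp` (the SNP map).
#' @export
build_pair_sharing <- function(dataset, pairs) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.character(pairs)) pairs <- within_pairs(pairs)
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("id1", "id2")
  idx <- pairs_to_idx(dataset, pairs)
  sh <- sharing_matrix_cpp(dataset$geno, idx)
  structure(list(pair_index = as_tibble(pairs[, 1:2]), sharing = sh,
                 snp = dataset$snp),
            class = "pair_sharing")
}

#' Assign SNP pairs to genetic-distance bins
#'
#' Enumerates intra-chromosome SNP pairs `(i, j)`, `j > i`, whose genetic
#' separation falls in `[min_cM, max_cM)` and maps each to its distance bin.
#' Cross-chromosome pairs are excluded (their genetic distance is undefined
#' on a per-chromosome map). Intended for small SNP sets (oracle checks,
#' inspection); the profile engines perform this binning internally.
#'
#' @param snps SNP table with columns `chrom` and `gpos` (Morgans).
#' @param bins A [distance_bins()].
#' @return Tibble with columns `i`, `j` (row indices into `snps`), `d_cM`
#'   and `bin` (1-based bin index).
#' @export
bin_snp_pairs <- function(snps, bins = distance_bins()) {
  stopifnot(inherits(bins, "distance_bins"))
  n <- nrow(snps)
  if (n > 3000)
    data_error("bin_snp_pairs enumerates O(n^2) pairs; use the profile engines for large SNP sets")
  out <- vector("list", 0)
  for (ch in unique(snps$chrom)) {
    ix <- which(snps$chrom == ch)
    if (length(ix) < 2) next
    cmb <- utils::combn(ix, 2)
    d <- (snps$gpos[cmb[2, ]] - snps$gpos[cmb[1, ]]) * 100
    keep <- d >= bins$min - 1e-9 & d < bins$max - 1e-9
    if (!any(keep)) next
    out[[length(out) + 1]] <- tibble(
      i = cmb[1, keep], j = cmb[2, keep], d_cM = d[keep],
      bin = pmax(1L, as.integer(floor((d[keep] - bins$min) / bins$step + 1e-9)) + 1L))
  }
  if (!length(out)) return(tibble(i = integer(), j = integer(),
                                  d_cM = numeric(), bin = integer()))
  dplyr::bind_rows(out)
}

new_sharing_profile <- function(bins, mode, statistic, engine, chrom,
                                snp_per_chrom, w_sum, w_n,
                                c_sum = NULL, c_n = NULL,
                                target = NULL, outgroup = NULL) {
  structure(list(bins = bins, mode = mode, statistic = statistic,
                 engine = engine, chrom = chrom,
                 snp_per_chrom = snp_per_chrom,
                 w_sum = w_sum, w_n = w_n, c_sum = c_sum, c_n = c_n,
                 target = target, outgroup = outgroup),
            class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat(sprintf("<sharing_profile> %s (%s engine, %s mode)\n",
              x$statistic, x$engine, x$mode))
  cat(sprintf("  %d chromosomes, bins %g-%g cM step %g\n",
              length(x$chrom), x$bins$min, x$bins$max, x$bins$step))
  tb <- pool_profile(x)
  cat(sprintf("  usable bins: %d / %d\n", sum(!is.na(tb$value)), nrow(tb)))
  invisible(x)
}

#' Pool a sharing profile over chromosomes
#'
#' Aggregates the per-chromosome per-bin sums and SNP-pair counts into the
#' genome-wide profile: the bin value is the global mean of the per-SNP-pair
#' (or per-mesh-lag) statistic. In correlation mode with an outgroup the
#' corrected value `z = z_w - z_c` is formed after pooling each component.
#' Bins with no usable SNP pairs (in either component) have `NA` value:
#' they are absent, not zero.
#'
#' @param profile A `sharing_profile`.
#' @param drop_chrom Optional chromosome labels to leave out (the jackknife
#'   uses this).
#' @return Tibble with columns `bin_left_cM`, `bin_right_cM`, `d_mid_cM`,
#'   `z_w`, `z_c`, `value` and `n_snp_pairs`.
#' @export
pool_profile <- function(profile, drop_chrom = NULL) {
  stopifnot(inherits(profile, "sharing_profile"))
  keep <- !(profile$chrom %in% drop_chrom)
  if (!any(keep)) data_error("no chromosomes left after dropping")
  ws <- colSums(profile$w_sum[keep, , drop = FALSE])
  wn <- colSums(profile$w_n[keep, , drop = FALSE])
  zw <- ifelse(wn > 0, ws / wn, NA_real_)
  if (!is.null(profile$c_sum)) {
    cs <- colSums(profile$c_sum[keep, , drop = FALSE])
    cn <- colSums(profile$c_n[keep, , drop = FALSE])
    zc <- ifelse(cn > 0, cs / cn, NA_real_)
    value <- zw - zc
  } else {
    zc <- NA_real_
    value <- zw
  }
  tibble(bin_left_cM = profile$bins$left, bin_right_cM = profile$bins$right,
         d_mid_cM = profile$bins$mid, z_w = zw, z_c = zc,
         value = value, n_snp_pairs = wn)
}

#' @export
as_tibble.sharing_profile <- function(x, ...) pool_profile(x)

# Engine dispatcher: per-chromosome bin sums/counts for one pair set.
profile_matrices <- function(dataset, pairs_idx, bins, engine, mode,
                             he = NULL, mesh_cM = 0.001) {
  chroms <- unique(dataset$snp$chrom)
  D <- bins$n
  msum <- matrix(0, length(chroms), D, dimnames = list(chroms, NULL))
  mn <- matrix(0, length(chroms), D, dimnames = list(chroms, NULL))
  mode_i <- if (mode == "correlation") 0L else 1L
  for (k in seq_along(chroms)) {
    idx <- which(dataset$snp$chrom == chroms[k])
    pos_cM <- dataset$snp$gpos[idx] * 100
    span <- pos_cM[length(pos_cM)] - pos_cM[1]
    if (length(idx) < 2 || span <= 0) {
      warn(sprintf("chromosome %s has zero genetic length; skipped", chroms[k]))
      next
    }
    g <- dataset$geno[idx, , drop = FALSE]
    hek <- if (!is.null(he)) he[idx] else rep(0, length(idx))
    if (mode_i == 1L && any(hek <= 0))
      data_error("expected heterozygosity is zero at a used SNP; run filter_sites() on the analysis samples first")
    sh <- sharing_matrix_cpp(g, pairs_idx)
    if (engine == "naive") {
      res <- naive_profile_cpp(t(sh), pos_cM, bins$min, bins$max, bins$step,
                               mode_i, hek)
    } else {
      res <- fft_chromosome(sh, pos_cM, bins, mode_i, hek, mesh_cM)
      if (is.null(res)) {
        warn(sprintf("chromosome %s shorter than the mesh spacing; skipped", chroms[k]))
        next
      }
      # kernel counts (SNP pair x individual pair) terms; rescale to the
      # exact engine's per-SNP-pair accounting
      res$sum <- res$sum / ncol(sh)
      res$n <- res$n / ncol(sh)
    }
    msum[k, ] <- res$sum
    mn[k, ] <- res$n
  }
  list(sum = msum, n = mn, chrom = chroms,
       snp_per_chrom = as.integer(table(factor(dataset$snp$chrom, levels = chroms))))
}

profile_from_pair_sharing <- function(ps, bins, mode, he, statistic, engine = "naive") {
  stopifnot(inherits(ps, "pair_sharing"))
  if (nrow(ps$pair_index) < 2)
    data_error("need at least 2 individual pairs to compute a correlation profile")
  chroms <- unique(ps$snp$chrom)
  D <- bins$n
  msum <- matrix(0, length(chroms), D, dimnames = list(chroms, NULL))
  mn <- matrix(0, length(chroms), D, dimnames = list(chroms, NULL))
  mode_i <- if (mode == "correlation") 0L else 1L
  for (k in seq_along(chroms)) {
    idx <- which(ps$snp$chrom == chroms[k])
    if (length(idx) < 2) next
    hek <- if (!is.null(he)) he[idx] else rep(0, length(idx))
    if (mode_i == 1L && any(hek <= 0))
      data_error("expected heterozygosity is zero at a used SNP; filter sites first")
    res <- naive_profile_cpp(t(ps$sharing[idx, , drop = FALSE]),
                             ps$snp$gpos[idx] * 100,
                             bins$min, bins$max, bins$step, mode_i, hek)
    msum[k, ] <- res$sum
    mn[k, ] <- res$n
  }
  if (all(mn == 0))
    data_error("profile empty: no SNP pair had >= 2 complete observations and non-zero variance in any bin")
  new_sharing_profile(bins, mode, statistic, engine, chroms,
                      as.integer(table(factor(ps$snp$chrom, levels = chroms))),
                      msum, mn)
}

#' Within-population allele-sharing correlation profile (exact engine)
#'
#' For every intra-chromosome SNP pair in a distance bin, the Pearson
#' correlation between the two SNPs' sharing-count vectors is computed
#' across individual pairs (using only pairs non-missing at both SNPs), and
#' the bin value is the unweighted mean of those correlations. SNP pairs
#' with fewer than 2 complete observations, or zero variance in either
#' vector, are skipped and do not count towards the bin.
#'
#' @param sharing A [build_pair_sharing()] result for the within-population
#'   pairs.
#' @param bins A [distance_bins()].
#' @return A `sharing_profile` (statistic `z_w`).
#' @export
within_profile_naive <- function(sharing, bins = distance_bins()) {
  profile_from_pair_sharing(sharing, bins, "correlation", NULL, "z_w")
}

#' Cross-population allele-sharing correlation profile (exact engine)
#'
#' The same estimator as [within_profile_naive()], applied to all target x
#' outgroup individual pairs. Subtracting this from the within profile
#' removes the ancestral sharing common to both populations.
#'
#' @param dataset A [genotype_dataset()].
#' @param target_pop Target population label.
#' @param outgroup_ids Outgroup individual ids (disjoint from the target).
#' @param bins A [distance_bins()].
#' @return A `sharing_profile` (statistic `z_c`).
#' @export
cross_profile_naive <- function(dataset, target_pop, outgroup_ids,
                                bins = distance_bins()) {
  target_ids <- dataset$ind$id[dataset$ind$population == target_pop]
  ps <- build_pair_sharing(dataset, cross_pairs(target_ids, outgroup_ids))
  profile_from_pair_sharing(ps, bins, "correlation", NULL, "z_c")
}

#' Corrected allele-sharing correlation
#'
#' Forms `z(d) = z_w(d) - z_c(d)` from a within-population and a
#' cross-population profile computed on the same bins and chromosomes. Bins
#' absent in either component are absent in the result.
#'
#' @param z_w,z_c `sharing_profile` objects (statistics `z_w` and `z_c`).
#' @return A `sharing_profile` (statistic `z`).
#' @export
corrected_profile <- function(z_w, z_c) {
  stopifnot(inherits(z_w, "sharing_profile"), inherits(z_c, "sharing_profile"))
  if (!same_bins(z_w$bins, z_c$bins))
    data_error("within and cross profiles use different distance bins")
  if (!identical(z_w$chrom, z_c$chrom))
    data_error("within and cross profiles cover different chromosomes")
  if (z_w$mode != "correlation" || z_c$mode != "correlation")
    data_error("corrected profiles are defined for correlation mode")
  new_sharing_profile(z_w$bins, "correlation", "z", z_w$engine, z_w$chrom,
                      z_w$snp_per_chrom, z_w$w_sum, z_w$w_n,
                      c_sum = z_c$w_sum, c_n = z_c$w_n,
                      target = z_w$target, outgroup = z_c$outgroup)
}

#' Weighted allele-sharing covariance profile (exact engine)
#'
#' Replaces the Pearson correlation by the sharing covariance normalised by
#' the product of the two SNPs' expected heterozygosities,
#' `w(i, j) = cov(A_i, A_j) / (He_i He_j)`, where `A` is the *fraction* of
#' shared alleles (0, 1/2, 1; on pseudo-haploid single-allele calls simply
#' the 0/1 match indicator) -- the scale on which the amplitude of `w(d)`
#' maps to founder intensity through the same `e * a` transform as the
#' correlation. Pseudo-haploid calls deplete heterozygotes and inflate the
#' spread of sharing counts, which biases the correlation amplitude (the
#' founder intensity) downward while leaving the decay rate intact; this
#' weighting removes that bias. The covariance is the pairwise-complete
#' sample covariance (denominator `n - 1`).
#'
#' @param sharing A [build_pair_sharing()] result (within-population pairs).
#' @param he Per-SNP expected heterozygosity, all positive (apply
#'   [filter_sites()] first).
#' @param bins A [distance_bins()].
#' @param normalisation `"product"` (the definition above) or `"sqrt"`, an
#'   alternative `cov / sqrt(He_i He_j)` scaling kept for comparison; the
#'   product form is the one whose amplitude maps to founder intensity.
#' @return A `sharing_profile` (statistic `w`, mode `weighted_cov`).
#' @export
weighted_cov_profile <- function(sharing, he, bins = distance_bins(),
                                 normalisation = c("product", "sqrt")) {
  normalisation <- match.arg(normalisation)
  if (length(he) != nrow(sharing$sharing))
    data_error("he must have one entry per SNP")
  if (any(!is.finite(he)) || any(he <= 0))
    data_error("expected heterozygosity must be positive at every used SNP; filter sites first")
  he_eff <- if (normalisation == "product") he else sqrt(he)
  prof <- profile_from_pair_sharing(sharing, bins, "weighted_cov", he_eff, "w")
  prof
}

#' Genome-wide allele-sharing decay profile
#'
#' One-call profile computation for a target population: builds the
#' individual-pair sets, runs the chosen engine per chromosome, and returns
#' the per-chromosome binned profile ready for [fit_founder_event()].
#'
#' @param dataset A [genotype_dataset()], already restricted to informative
#'   sites (see [filter_sites()]).
#' @param target_pop Target population label.
#' @param outgroup_ids Optional outgroup individual ids; when supplied in
#'   correlation mode the corrected profile `z = z_w - z_c` is produced.
#' @param bins A [distance_bins()].
#' @param engine `"fft"` (mesh autocorrelation, the default; exact up to the
#'   mesh discretisation) or `"naive"` (exact SNP-pair loop, quadratic in
#'   SNP count).
#' @param mode `"correlation"` or `"weighted_cov"` (within-population
#'   weighted covariance; no outgroup subtraction).
#' @param mesh_cM Mesh spacing for the FFT engine, in cM (default 0.001,
#'   i.e. 100 mesh points per default 0.1 cM bin).
#' @return A `sharing_profile`.
#' @export
allele_sharing_profile <- function(dataset, target_pop, outgroup_ids = NULL,
                                   bins = distance_bins(),
                                   engine = c("fft", "naive"),
                                   mode = c("correlation", "weighted_cov"),
                                   mesh_cM = 0.001) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  if (dataset$ploidy == "haploid")
    data_error("profiles are computed on diploid or pseudo-haploid data; pair haploids first")
  target_ids <- dataset$ind$id[dataset$ind$population == target_pop]
  if (length(target_ids) < 2)
    data_error(sprintf("target population '%s' has %d individuals; need at least 2",
                       target_pop, length(target_ids)))
  wpairs <- pairs_to_idx(dataset, within_pairs(target_ids))

  if (mode == "weighted_cov") {
    he <- he_for_samples(dataset, target_ids)
    res <- profile_matrices(dataset, wpairs, bins, engine, mode, he, mesh_cM)
    if (all(res$n == 0)) data_error("profile empty: no usable SNP pairs in any bin")
    return(new_sharing_profile(bins, mode, "w", engine, res$chrom,
                               res$snp_per_chrom, res$sum, res$n,
                               target = target_pop, outgroup = NULL))
  }

  res_w <- profile_matrices(dataset, wpairs, bins, engine, mode, NULL, mesh_cM)
  if (is.null(outgroup_ids)) {
    if (all(res_w$n == 0)) data_error("profile empty: no usable SNP pairs in any bin")
    return(new_sharing_profile(bins, mode, "z_w", engine, res_w$chrom,
                               res_w$snp_per_chrom, res_w$sum, res_w$n,
                               target = target_pop))
  }
  cpairs <- pairs_to_idx(dataset, cross_pairs(target_ids, outgroup_ids))
  res_c <- profile_matrices(dataset, cpairs, bins, engine, mode, NULL, mesh_cM)
  if (all(res_w$n == 0) || all(res_c$n == 0))
    data_error("profile empty: no usable SNP pairs in any bin")
  new_sharing_profile(bins, mode, "z", engine, res_w$chrom,
                      res_w$snp_per_chrom, res_w$sum, res_w$n,
                      c_sum = res_c$sum, c_n = res_c$n,
                      target = target_pop, outgroup = outgroup_ids)
}

#' Export a profile as a flat table
#'
#' Tab-separated layout with one block per chromosome plus a pooled `ALL`
#' block; columns `bin_left_cM`, `bin_right_cM`, `d_mid_cM`, `z_w`, `z_c`,
#' `z_or_w`, `n_snp_pairs`, `chromosome`.
#'
#' @param profile A `sharing_profile`.
#' @param path Optional output path; when given, the table is written as TSV.
#' @return The tibble (invisibly when `path` is given).
#' @export
profile_table <- function(profile, path = NULL) {
  one <- function(lab, drop) {
    tb <- pool_profile(profile, drop_chrom = drop)
    tibble(bin_left_cM = tb$bin_left_cM, bin_right_cM = tb$bin_right_cM,
           d_mid_cM = tb$d_mid_cM, z_w = tb$z_w, z_c = tb$z_c,
           z_or_w = tb$value, n_snp_pairs = tb$n_snp_pairs, chromosome = lab)
  }
  out <- dplyr::bind_rows(
    one("ALL", NULL),
    dplyr::bind_rows(lapply(profile$chrom, function(ch)
      one(ch, setdiff(profile$chrom, ch)))))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
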