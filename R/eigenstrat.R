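# genotype_io: EIGENSTRAT triplets, the genotype data model, site filters and
# outgroup selection.

#' Construct a genotype dataset
#'
#' The in-memory container for EIGENSTRAT-style genotype data: a SNPs x
#' individuals genotype matrix over \{0, 1, 2, NA\} together with the SNP map
#' (chromosome, genetic position in Morgans) and individual/population labels.
#' SNPs are sorted by genetic position within each chromosome block
#' (chromosome blocks keep their order of first appearance; ties keep file
#' order).
#'
#' @param geno Integer matrix, SNPs in rows, individuals in columns; values
#'   0/1/2 with `NA` for missing.
#' @param snp Data frame with columns `id`, `chrom`, `gpos` (genetic position
#'   in Morgans), `ppos` (physical position, bp), `a1`, `a2`.
#' @param ind Data frame with columns `id`, `sex`, `population`.
#' @param ploidy `"diploid"`, `"pseudo_haploid"`, `"haploid"` or `NULL` to
#'   autodetect: a dataset with no heterozygous call (code 1) anywhere is
#'   taken to be pseudo-haploid. `"haploid"` (values 0/1, one chromosome copy
#'   per column) is used for simulator output and is never autodetected.
#' @return An object of class `genotype_dataset`.
#' @seealso [read_eigenstrat()], [filter_sites()], [pair_haploids()]
#' @export
genotype_dataset <- function(geno, snp, ind, ploidy = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- as_tibble(snp)
  ind <- as_tibble(ind)
  need <- c("id", "chrom", "gpos", "ppos", "a1", "a2")
  if (!all(need %in% names(snp)))
    data_error(paste0("snp table must have columns: ", paste(need, collapse = ", ")))
  if (!all(c("id", "sex", "population") %in% names(ind)))
    data_error("ind table must have columns: id, sex, population")
  if (nrow(snp) != nrow(geno))
    data_error(sprintf("genotype matrix has %d rows but snp table has %d",
                       nrow(geno), nrow(snp)))
  if (nrow(ind) != ncol(geno))
    data_error(sprintf("genotype matrix has %d columns but ind table has %d",
                       ncol(geno), nrow(ind)))
  if (any(!is.na(geno) & !(geno %in% 0:2)))
    data_error("genotypes must be 0, 1, 2 or NA")
  if (any(is.na(ind$population) | ind$population == ""))
    data_error("every individual must have a non-empty population label")
  snp$chrom <- as.character(snp$chrom)
  snp$gpos <- as.numeric(snp$gpos)
  if (any(is.na(snp$gpos)) || any(snp$gpos < 0))
    data_error("genetic positions must be non-negative numbers (Morgans)")

  # stable sort: chromosome blocks in order of first appearance, then gpos
  chrom_f <- factor(snp$chrom, levels = unique(snp$chrom))
  ord <- order(as.integer(chrom_f), snp$gpos)
  if (!identical(ord, seq_len(nrow(snp)))) {
    snp <- snp[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
  }

  if (is.null(ploidy)) {
    ploidy <- if (nrow(geno) > 0 && !any(geno == 1L, na.rm = TRUE))
      "pseudo_haploid" else "diploid"
  }
  ploidy <- match.arg(ploidy, c("diploid", "pseudo_haploid", "haploid"))
  if (ploidy == "pseudo_haploid" && any(geno == 1L, na.rm = TRUE))
    data_error("pseudo-haploid dataset contains heterozygous calls (code 1)")
  structure(list(geno = geno, snp = snp, ind = ind, ploidy = ploidy),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d SNPs x %d individuals (%s)\n",
              nrow(x$geno), ncol(x$geno), x$ploidy))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snp$chrom), collapse = " ")))
  pops <- table(x$ind$population)
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(pops), pops), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

#' Read an EIGENSTRAT triplet
#'
#' Reads `.geno` (one row per SNP, one character per individual over
#' \{0,1,2,9\}), `.snp` (at least six whitespace-separated columns: id,
#' chromosome, genetic position in Morgans, physical position, two alleles)
#' and `.ind` (id, sex, population) files. Genotype code 9 becomes `NA`.
#' SNPs are sorted by (chromosome block, genetic position). Ploidy is
#' autodetected: a file with no genotype code 1 is flagged pseudo-haploid
#' (override with `ploidy`).
#'
#' @param geno_path,snp_path,ind_path Paths to the three files.
#' @param ploidy Optional override of the autodetected ploidy mode.
#' @return A [genotype_dataset()].
#' @details A dataset whose genetic positions are all zero is rejected: the
#'   decay of allele sharing is measured against the genetic map, and there
#'   is no safe physical-distance fallback (a silent 1 cM/Mb assumption would
#'   bias the inferred founder age). Supply a `.snp` file with real genetic
#'   positions.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = NULL) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) data_error(sprintf("file not found: %s", p))

  snp <- data.table::fread(snp_path, header = FALSE, colClasses = "character",
                           data.table = FALSE, strip.white = TRUE)
  if (ncol(snp) < 6)
    data_error(sprintf(".snp file %s has %d columns; expected at least 6 (id, chrom, genetic pos, physical pos, allele1, allele2)",
                       snp_path, ncol(snp)))
  gpos <- suppressWarnings(as.numeric(snp[[3]]))
  if (any(is.na(gpos))) {
    bad <- which(is.na(gpos))[1]
    data_error(sprintf("unparseable genetic position '%s' at .snp line %d",
                       snp[[3]][bad], bad))
  }
  if (all(gpos == 0))
    data_error("all genetic positions in the .snp file are zero; supply a genetic map (column 3, in Morgans) - physical positions are not a substitute")
  ppos <- suppressWarnings(as.integer(as.numeric(snp[[4]])))
  snp_tbl <- tibble(id = snp[[1]], chrom = snp[[2]], gpos = gpos,
                    ppos = ppos, a1 = snp[[5]], a2 = snp[[6]])

  ind <- data.table::fread(ind_path, header = FALSE, colClasses = "character",
                           data.table = FALSE, strip.white = TRUE)
  if (ncol(ind) < 3)
    data_error(sprintf(".ind file %s must have 3 columns (id, sex, population)", ind_path))
  ind_tbl <- tibble(id = ind[[1]], sex = ind[[2]], population = ind[[3]])

  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp_tbl))
    data_error(sprintf(".geno has %d lines but .snp has %d entries",
                       length(lines), nrow(snp_tbl)))
  geno <- geno_parse_cpp(lines, nrow(ind_tbl))
  genotype_dataset(geno, snp_tbl, ind_tbl, ploidy = ploidy)
}

#' Write an EIGENSTRAT triplet
#'
#' Writes the canonical dialect read back by [read_eigenstrat()]: `.geno`
#' rows are strings over \{0,1,2,9\} (missing written as 9); `.snp` columns
#' are id, chromosome, genetic position (Morgans, full double precision),
#' physical position and the two alleles. Reading a written dataset
#' reproduces it exactly, and rewriting a read file reproduces the bytes.
#'
#' @param dataset A [genotype_dataset()].
#' @param geno_path,snp_path,ind_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_eigenstrat <- function(dataset, geno_path, snp_path, ind_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  tryCatch({
    writeLines(geno_format_cpp(dataset$geno), geno_path)
    s <- dataset$snp
    snp_lines <- sprintf("%s\t%s\t%s\t%d\t%s\t%s", s$id, s$chrom,
                         formatC(s$gpos, digits = 17, format = "g"),
                         s$ppos, s$a1, s$a2)
    writeLines(snp_lines, snp_path)
    i <- dataset$ind
    writeLines(sprintf("%s\t%s\t%s", i$id, i$sex, i$population), ind_path)
  }, error = function(e) {
    data_error(sprintf("failed to write EIGENSTRAT files: %s", conditionMessage(e)))
  })
  invisible(c(geno_path, snp_path, ind_path))
}

#' Keep only sites informative for allele sharing
#'
#' Restricts the SNP set to sites that, across the union of the target
#' population and the (optional) outgroup individuals, have at least one
#' non-missing genotype and at least two distinct observed allele states.
#' Sites monomorphic across the analysis samples carry constant sharing
#' counts, have zero variance, and contribute nothing to any correlation
#' bin, so they are dropped along with all-missing sites. Surviving SNPs
#' keep their order; the operation is idempotent.
#'
#' @param dataset A [genotype_dataset()].
#' @param target_pop Population label of the target group.
#' @param outgroup_ids Optional character vector of outgroup individual ids
#'   included in the informativeness assessment.
#' @return The filtered [genotype_dataset()] (same individuals, fewer SNPs).
#' @export
filter_sites <- function(dataset, target_pop, outgroup_ids = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!target_pop %in% dataset$ind$population)
    data_error(sprintf("target population '%s' not present in dataset", target_pop))
  use <- dataset$ind$population == target_pop
  if (!is.null(outgroup_ids)) {
    missing_ids <- setdiff(outgroup_ids, dataset$ind$id)
    if (length(missing_ids))
      data_error(sprintf("unknown outgroup ids: %s", paste(missing_ids, collapse = ", ")))
    use <- use | dataset$ind$id %in% outgroup_ids
  }
  g <- dataset$geno[, use, drop = FALSE]
  # polymorphic among analysis samples: both a non-zero and a non-max state
  # observed, counting hets as evidence of both alleles
  gmax <- if (dataset$ploidy == "haploid") 1L else 2L
  n_obs <- rowSums(!is.na(g))
  has_ref <- rowSums(g < gmax, na.rm = TRUE) > 0  # allele 2 observed somewhere
  has_alt <- rowSums(g > 0, na.rm = TRUE) > 0     # allele 1 observed somewhere
  keep <- n_obs > 0 & has_ref & has_alt
  if (!any(keep))
    data_error("no informative sites: every SNP is missing or monomorphic across the target and outgroup samples")
  out <- dataset
  out$geno <- dataset$geno[keep, , drop = FALSE]
  out$snp <- dataset$snp[keep, , drop = FALSE]
  out
}

#' Sample a random outgroup set
#'
#' Draws `n_outgroup` individual ids uniformly without replacement from all
#' individuals outside the target population. The default of 15 individuals
#' is the standard panel size for estimating the cross-population
#' allele-sharing correlation.
#'
#' @param dataset A [genotype_dataset()].
#' @param target_pop Target population label (its members are excluded).
#' @param n_outgroup Number of individuals to draw (default 15).
#' @param seed Optional integer; the draw is deterministic given the seed.
#' @return Character vector of individual ids.
#' @export
select_outgroup <- function(dataset, target_pop, n_outgroup = 15, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  candidates <- dataset$ind$id[dataset$ind$population != target_pop]
  if (length(candidates) < n_outgroup)
    data_error(sprintf("only %d individuals outside '%s' but n_outgroup = %d; lower n_outgroup or pass explicit ids",
                       length(candidates), target_pop, n_outgroup))
  with_seed(seed, sample(candidates, n_outgroup))
}

#' Randomly thin sites to a target density
#'
#' Uniform random down-sampling of SNPs, per chromosome, preserving order.
#' This emulates the site density of genotyping arrays (on which this class
#' of analysis is routinely run) when starting from sequence-density
#' simulated data, and makes the exact SNP-pair engine affordable.
#'
#' @param dataset A [genotype_dataset()].
#' @param n_per_chrom Number of SNPs to retain on each chromosome (chromosomes
#'   with fewer SNPs are kept whole).
#' @param seed Optional integer seed.
#' @return The thinned [genotype_dataset()].
#' @export
thin_sites <- function(dataset, n_per_chrom, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(dataset$snp)),
                        factor(dataset$snp$chrom, levels = unique(dataset$snp$chrom))),
                  function(ix) {
                    if (length(ix) <= n_per_chrom) ix
                    else sort(sample(ix, n_per_chrom))
                  }), use.names = FALSE)
  })
  keep <- sort(keep)
  out <- dataset
  out$geno <- dataset$geno[keep, , drop = FALSE]
  out$snp <- dataset$snp[keep, , drop = FALSE]
  out
}
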