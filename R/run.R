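# cli: one-command pipeline -- read, filter, profile, fit, jackknife,
# classify, report. exec/ascend wraps these functions for shell use.

#' Build a run configuration
#'
#' @param genotypename,snpname,indname Paths to the EIGENSTRAT triplet.
#' @param targetpop Target population label.
#' @param outpop Outgroup specification: a population label (or
#'   comma-separated labels), `"RANDOM:n"` for n individuals drawn outside
#'   the target (default `"RANDOM:15"`), or `"NONE"`.
#' @param mindist_cM,maxdist_cM,binsize_cM Distance-bin layout (defaults
#'   0.1, 30, 0.1; use `maxdist_cM = 40` for long-range-LD species such as
#'   dog breeds).
#' @param mesh_cM FFT mesh spacing (default 0.001; must be at most a tenth
#'   of the bin size).
#' @param engine `"fft"` or `"naive"`.
#' @param mode `"auto"`, `"correlation"` or `"weighted_cov"`. `"auto"`
#'   resolves to the weighted within-population covariance (no outgroup
#'   subtraction) for pseudo-haploid data or when `outpop` is `"NONE"`, and
#'   to the outgroup-corrected correlation otherwise.
#' @param max_age Significance threshold on the founder age in generations
#'   (default 200; 300 is sometimes used for ancient samples).
#' @param seed Integer seed (outgroup sampling).
#' @param outprefix Optional path prefix for the output files.
#' @param plot Also write a decay-curve plot (requires `outprefix`).
#' @return A validated list of class `run_config`.
#' @export
ascend_config <- function(genotypename, snpname, indname, targetpop,
                          outpop = "RANDOM:15",
                          mindist_cM = 0.1, maxdist_cM = 30, binsize_cM = 0.1,
                          mesh_cM = 0.001, engine = c("fft", "naive"),
                          mode = c("auto", "correlation", "weighted_cov"),
                          max_age = 200, seed = NULL, outprefix = NULL,
                          plot = FALSE) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  if (missing(genotypename) || missing(snpname) || missing(indname) ||
      missing(targetpop))
    config_error("genotypename, snpname, indname and targetpop are required")
  if (!(mindist_cM < maxdist_cM))
    config_error("mindist_cM must be smaller than maxdist_cM")
  n <- (maxdist_cM - mindist_cM) / binsize_cM
  if (abs(n - round(n)) > 1e-8)
    config_error("binsize_cM must evenly divide maxdist_cM - mindist_cM")
  if (mesh_cM > binsize_cM / 10)
    config_error("mesh_cM must be at most binsize_cM / 10")
  structure(list(genotypename = genotypename, snpname = snpname,
                 indname = indname, targetpop = targetpop, outpop = outpop,
                 mindist_cM = mindist_cM, maxdist_cM = maxdist_cM,
                 binsize_cM = binsize_cM, mesh_cM = mesh_cM,
                 engine = engine, mode = mode, max_age = max_age,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 outprefix = outprefix, plot = isTRUE(plot)),
            class = "run_config")
}

#' Read a run configuration file
#'
#' Plain-text `key = value` (or `key: value`) files; `#` starts a comment.
#' Recognised keys are the arguments of [ascend_config()].
#'
#' @param path Path to the configuration file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad))
    config_error(sprintf("cannot parse config line: '%s'", lines[bad][1]))
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  known_num <- c("mindist_cM", "maxdist_cM", "binsize_cM", "mesh_cM",
                 "max_age", "seed")
  known_chr <- c("genotypename", "snpname", "indname", "targetpop", "outpop",
                 "engine", "mode", "outprefix")
  known_lgl <- "plot"
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% known_num) args[[k]] <- as.numeric(vals[i])
    else if (k %in% known_chr) args[[k]] <- vals[i]
    else if (k %in% known_lgl) args[[k]] <- toupper(vals[i]) %in% c("TRUE", "YES", "1")
    else config_error(sprintf("unknown config key: %s", k))
  }
  do.call(ascend_config, args)
}

resolve_outgroup <- function(dataset, targetpop, outpop, seed) {
  if (is.null(outpop) || identical(toupper(outpop), "NONE")) return(NULL)
  if (grepl("^RANDOM:\\d+$", outpop)) {
    n <- as.integer(sub("^RANDOM:", "", outpop))
    return(select_outgroup(dataset, targetpop, n_outgroup = n, seed = seed))
  }
  pops <- trimws(strsplit(outpop, ",")[[1]])
  unknown <- setdiff(pops, unique(dataset$ind$population))
  if (length(unknown))
    data_error(sprintf("outgroup population(s) not in dataset: %s",
                       paste(unknown, collapse = ", ")))
  if (targetpop %in% pops)
    config_error("outgroup populations must not include the target")
  dataset$ind$id[dataset$ind$population %in% pops]
}

#' Run the full founder-event dating pipeline
#'
#' Reads the EIGENSTRAT triplet, restricts to informative sites, resolves
#' the outgroup and analysis mode, computes the allele-sharing decay
#' profile with the configured engine, fits the exponential decay with
#' chromosome-jackknife uncertainty, classifies the significance of the
#' event, and (when `outprefix` is set) writes the profile table, fit
#' report, jackknife replicates and a run log.
#'
#' @param config A `run_config` from [ascend_config()], or the path to a
#'   configuration file for [read_run_config()].
#' @return An object of class `ascend_run`: list with `profile`
#'   (`sharing_profile`), `fit` (`founder_fit`), `config` (with the
#'   resolved mode and outgroup) and `files` (paths written).
#' @export
run_ascend <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  ds <- read_eigenstrat(config$genotypename, config$snpname, config$indname)

  n_target <- sum(ds$ind$population == config$targetpop)
  if (n_target == 0)
    data_error(sprintf("target population '%s' not in dataset", config$targetpop))
  if (n_target < 2)
    data_error(sprintf("target population has %d individual; at least 2 are required", n_target))
  if (n_target <= 5)
    warn(sprintf("target population has only %d individuals; estimates are reliable for more than 5 samples", n_target))

  mode <- config$mode
  if (mode == "auto") {
    mode <- if (ds$ploidy == "pseudo_haploid" ||
                identical(toupper(config$outpop), "NONE"))
      "weighted_cov" else "correlation"
    if (ds$ploidy == "pseudo_haploid" &&
        !identical(toupper(config$outpop), "NONE"))
      warn("pseudo-haploid genotypes detected: using the within-population weighted allele-sharing covariance; the outgroup is ignored")
  }
  if (mode == "weighted_cov" && !identical(toupper(config$outpop), "NONE") &&
      config$mode != "auto")
    warn("weighted covariance is a within-population statistic; the outgroup is ignored")
  if (mode == "correlation" && ds$ploidy == "pseudo_haploid")
    warn("correlation mode on pseudo-haploid data underestimates the founder intensity; consider mode = weighted_cov")

  outgroup_ids <- if (mode == "correlation")
    resolve_outgroup(ds, config$targetpop, config$outpop, config$seed) else NULL

  ds <- filter_sites(ds, config$targetpop, outgroup_ids)
  bins <- distance_bins(config$mindist_cM, config$maxdist_cM, config$binsize_cM)
  profile <- allele_sharing_profile(ds, config$targetpop,
                                    outgroup_ids = outgroup_ids,
                                    bins = bins, engine = config$engine,
                                    mode = mode, mesh_cM = config$mesh_cM)
  fit <- fit_founder_event(profile, max_age = config$max_age)

  files <- character(0)
  if (!is.null(config$outprefix)) {
    op <- config$outprefix
    profile_table(profile, paste0(op, ".profile.tsv"))
    report <- glance(fit)
    utils::write.table(report, paste0(op, ".fit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fit$jackknife$replicates, paste0(op, ".jackknife.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(
      sprintf("ascendr %s", as.character(utils::packageVersion("ascendr"))),
      sprintf("date: %s", format(Sys.time())),
      sprintf("geno: %s", config$genotypename),
      sprintf("snp: %s", config$snpname),
      sprintf("ind: %s", config$indname),
      sprintf("target: %s (%d individuals)", config$targetpop, n_target),
      sprintf("outgroup: %s", if (is.null(outgroup_ids)) "NONE"
              else paste(outgroup_ids, collapse = ",")),
      sprintf("mode: %s  engine: %s", mode, config$engine),
      sprintf("bins: %g-%g cM step %g; mesh %g cM", config$mindist_cM,
              config$maxdist_cM, config$binsize_cM, config$mesh_cM),
      sprintf("seed: %s", config$seed %||% "NULL"),
      sprintf("snps used: %d", sum(profile$snp_per_chrom)),
      sprintf("significant: %s", fit$call$significant))
    writeLines(log_lines, paste0(op, ".log"))
    files <- paste0(op, c(".profile.tsv", ".fit.tsv", ".jackknife.tsv", ".log"))
    if (config$plot) {
      p <- autoplot(fit)
      ggplot2::ggsave(paste0(op, ".decay.pdf"), p, width = 7, height = 5)
      files <- c(files, paste0(op, ".decay.pdf"))
    }
  }
  config$resolved_mode <- mode
  config$resolved_outgroup <- outgroup_ids
  structure(list(profile = profile, fit = fit, config = config, files = files),
            class = "ascend_run")
}

#' @export
print.ascend_run <- function(x, ...) {
  cat(sprintf("<ascend_run> target %s, mode %s, engine %s\n",
              x$config$targetpop, x$config$resolved_mode, x$config$engine))
  print(x$fit)
  invisible(x)
}
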