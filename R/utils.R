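# Internal helpers: error classes, seeds, distance bins.

config_error <- function(msg, ...) {
  abort(msg, class = "ascendr_config_error", ...)
}

data_error <- function(msg, ...) {
  abort(msg, class = "ascendr_data_error", ...)
}

fit_error <- function(msg, ...) {
  abort(msg, class = "ascendr_fit_error", ...)
}

# Run code under a local RNG state seeded with `seed` (NULL = use current).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    config_error("`seed` must be a single number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Genetic-distance bins for allele-sharing profiles
#'
#' Half-open bins `[left, right)` in centimorgans over which SNP-pair (or
#' mesh-lag) statistics are aggregated. The defaults, 0.1 to 30 cM in steps
#' of 0.1 cM, are the standard analysis window for human data; long-range LD
#' species (e.g. dog breeds) warrant a larger `max_cM` such as 40.
#'
#' @param min_cM Lower edge of the first bin (cM). Pairs closer than this are
#'   excluded; the default 0.1 cM removes the near-zero distances dominated by
#'   ancestral (background) sharing.
#' @param max_cM Open upper edge of the last bin (cM).
#' @param step_cM Bin width (cM). Must evenly divide `max_cM - min_cM`.
#' @return An object of class `distance_bins` with elements `min`, `max`,
#'   `step`, `n` (number of bins) and `mid` (bin midpoints in cM, the
#'   abscissa used when fitting the decay curve).
#' @examples
#' b <- distance_bins()
#' b$n        # 299 bins
#' head(b$mid)
#' @export
distance_bins <- function(min_cM = 0.1, max_cM = 30, step_cM = 0.1) {
  if (!(min_cM >= 0) || !(max_cM > min_cM) || !(step_cM > 0))
    config_error("need 0 <= min_cM < max_cM and step_cM > 0")
  n <- (max_cM - min_cM) / step_cM
  if (abs(n - round(n)) > 1e-8)
    config_error("step_cM must evenly divide max_cM - min_cM")
  n <- as.integer(round(n))
  left <- min_cM + step_cM * (seq_len(n) - 1)
  structure(
    list(min = min_cM, max = max_cM, step = step_cM, n = n,
         left = left, right = left + step_cM, mid = left + step_cM / 2),
    class = "distance_bins")
}

#' @export
print.distance_bins <- function(x, ...) {
  cat(sprintf("<distance_bins> %g-%g cM, step %g cM (%d bins)\n",
              x$min, x$max, x$step, x$n))
  invisible(x)
}

same_bins <- function(a, b) {
  isTRUE(all.equal(c(a$min, a$max, a$step), c(b$min, b$max, b$step)))
}

# 5-smooth FFT length >= n
smooth_length <- function(n) {
  stats::nextn(n, c(2L, 3L, 5L))
}
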