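# broom-style accessors and ggplot2 autoplot methods.

#' Tidy the jackknife parameter table of a founder fit
#'
#' @param x A `founder_fit` (or `jackknife_result`).
#' @param ... Unused.
#' @return A tibble with one row per parameter (`a`, `t`, `c`, `T_f`,
#'   `I_f`): estimate, SE and CI95 bounds.
#' @export
tidy.founder_fit <- function(x, ...) x$jackknife$estimates

#' @rdname tidy.founder_fit
#' @export
tidy.jackknife_result <- function(x, ...) x$estimates

#' One-row summary of a founder fit
#'
#' The flat fit report: founder age and intensity with SEs and CI95s, the
#' affine offset, NRMSD, block count and the significance verdict.
#'
#' @param x A `founder_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.founder_fit <- function(x, ...) {
  tf <- jk_param(x$jackknife, "T_f")
  if_ <- jk_param(x$jackknife, "I_f")
  tibble(
    target = x$target %||% NA_character_,
    outgroup = if (is.null(x$outgroup)) "NONE"
               else paste(x$outgroup, collapse = ","),
    mode = x$mode, engine = x$engine,
    Tf_mean = tf$estimate, Tf_se = tf$se,
    Tf_CI95_lo = tf$ci_lo, Tf_CI95_hi = tf$ci_hi,
    If_mean = if_$estimate, If_se = if_$se,
    If_CI95_lo = if_$ci_lo, If_CI95_hi = if_$ci_hi,
    c = x$fit$c, NRMSD = x$nrmsd, n_blocks = x$jackknife$n_blocks,
    significant = x$call$significant,
    failed_criteria = paste(names(x$call$criteria)[!x$call$criteria],
                            collapse = ";"))
}

#' Plot an allele-sharing decay profile
#'
#' @param object A `sharing_profile`.
#' @param ... Unused.
#' @return A ggplot object: pooled bin values against genetic distance.
#' @export
autoplot.sharing_profile <- function(object, ...) {
  tb <- pool_profile(object)
  ylab <- switch(object$statistic,
                 z = "corrected allele-sharing correlation z(d)",
                 z_w = "within-population allele-sharing correlation",
                 z_c = "cross-population allele-sharing correlation",
                 w = "weighted allele-sharing covariance w(d)")
  ggplot2::ggplot(tb[!is.na(tb$value), ],
                  ggplot2::aes(x = .data$d_mid_cM, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "genetic distance d (cM)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a fitted decay curve
#'
#' Profile points with the fitted exponential overlaid and the inferred
#' founder age/intensity annotated.
#'
#' @param object A `founder_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.founder_fit <- function(object, ...) {
  dat <- object$fit$data
  tf <- jk_param(object$jackknife, "T_f")
  if_ <- jk_param(object$jackknife, "I_f")
  lab <- sprintf("T[f] == %.0f~generations~(%.0f-%.0f)", tf$estimate,
                 tf$ci_lo, tf$ci_hi)
  lab2 <- sprintf("I[f] == '%.2f%%'~('%.2f%%'-'%.2f%%')", 100 * if_$estimate,
                  100 * if_$ci_lo, 100 * if_$ci_hi)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$d_cM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.05, vjust = 1.5,
                      label = lab, parse = TRUE) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.05, vjust = 3.2,
                      label = lab2, parse = TRUE) +
    ggplot2::labs(x = "genetic distance d (cM)",
                  y = if (object$mode == "weighted_cov")
                    "weighted allele-sharing covariance" else
                      "allele-sharing correlation",
                  subtitle = sprintf("NRMSD = %.3f%s", object$nrmsd,
                                     if (object$call$significant) ""
                                     else "  (not significant)")) +
    ggplot2::theme_minimal()
}
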