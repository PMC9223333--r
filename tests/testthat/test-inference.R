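test_that("model curve evaluates I_f e^-(1 + 2dT_f)", {
  expect_equal(model_expected_correlation(0, 30, 0.01), 0)
  expect_equal(model_expected_correlation(0.1, 7, 0), 0.1 * exp(-1),
               tolerance = 1e-12)
  expect_equal(model_expected_correlation(0.1, 50, 0.01), 0.1 * exp(-2),
               tolerance = 1e-12)
  expect_error(model_expected_correlation(-0.1, 1, 0), "non-negative")
})

test_that("noiseless profiles are recovered to optimiser precision", {
  d <- seq(0.15, 29.95, by = 0.1)
  for (true in list(c(a = 0.0367879, t = 0.30, c = 0),
                    c(a = 0.012, t = 0.05, c = 0.002),
                    c(a = 0.2, t = 1.5, c = -0.001))) {
    z <- true[["a"]] * exp(-2 * d * true[["t"]]) + true[["c"]]
    f <- fit_exponential(data.frame(d_mid_cM = d, value = z))
    expect_true(f$converged)
    expect_lt(abs(f$a - true[["a"]]) / true[["a"]], 1e-6)
    expect_lt(abs(f$t - true[["t"]]) / true[["t"]], 1e-6)
    expect_lt(abs(f$c - true[["c"]]), 1e-8)
  }
})

test_that("degenerate and invalid profiles are handled", {
  d <- seq(0.15, 29.95, by = 0.1)
  flat <- fit_exponential(data.frame(d_mid_cM = d, value = rep(0.004, length(d))))
  expect_lt(flat$a, 1e-8)             # amplitude pinned at its lower bound
  expect_equal(flat$c, 0.004, tolerance = 1e-6)

  expect_error(fit_exponential(data.frame(d_mid_cM = d[1:5], value = d[1:5])),
               "bins")
  expect_error(fit_exponential(data.frame(d_mid_cM = d, value = rep(Inf, length(d)))),
               "non-finite")
})

test_that("noisy synthetic decay recovers the founder age within 5%", {
  set.seed(99)
  d <- seq(0.15, 29.95, by = 0.1)
  z <- model_expected_correlation(0.05, 40, d / 100) + rnorm(length(d), 0, 1e-4)
  f <- fit_exponential(data.frame(d_mid_cM = d, value = z))
  expect_lt(abs(f$T_f_hat - 40) / 40, 0.05)
  expect_lt(abs(f$I_f_hat - 0.05) / 0.05, 0.05)
})

test_that("estimate transforms undo the equilibrium factor and cM scaling", {
  expect_equal(transform_estimates(list(a = exp(-1), t = 0.1),
                                   distance_unit = "cM")[["I_f_hat"]], 1)
  expect_equal(transform_estimates(list(a = 0.1, t = 0.30),
                                   distance_unit = "cM")[["T_f_hat"]], 30)
  expect_equal(transform_estimates(list(a = 0.1, t = 30),
                                   distance_unit = "Morgan")[["T_f_hat"]], 30)
  expect_equal(transform_estimates(list(a = 0.00662, t = 1),
                                   distance_unit = "cM")[["I_f_hat"]],
               exp(1) * 0.00662, tolerance = 1e-12)
})

test_that("NRMSD is the range-normalised RMSD with degenerate-range error", {
  expect_equal(nrmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmsd(c(0.2, 0.0), c(0.1, 0.0)), sqrt(0.01 / 2) / 0.1,
               tolerance = 1e-12)
  expect_error(nrmsd(c(1, 2), c(1, 1)), "degenerate")
  expect_error(nrmsd(1, 1), "length")
})

# Construct a synthetic per-chromosome profile whose pooled bin values are
# exact exponential curves, with controllable per-chromosome perturbations.
synthetic_profile <- function(a_by_chrom, t = 0.3, c0 = 0, snp_counts = NULL,
                              bins = distance_bins(0.1, 20, 0.1)) {
  g <- length(a_by_chrom)
  d <- bins$mid
  w_sum <- t(vapply(a_by_chrom,
                    function(a) a * exp(-2 * d * t) + c0, numeric(bins$n)))
  w_n <- matrix(1, g, bins$n)
  ascendr:::new_sharing_profile(
    bins, "correlation", "z", "naive", paste0("c", seq_len(g)),
    snp_counts %||% rep(1000L, g), w_sum, w_n)
}

test_that("equal-weight jackknife reproduces the classical formula", {
  prof <- synthetic_profile(c(0.030, 0.034, 0.040, 0.036))
  jk <- jackknife_fit(prof)
  reps <- jk$replicates
  for (p in c("a", "t")) {
    x <- reps[[p]]
    g <- length(x)
    se_classical <- sqrt((g - 1) / g * sum((x - mean(x))^2))
    expect_equal(jk$estimates$se[jk$estimates$param == p], se_classical,
                 tolerance = 1e-8)
  }
  # point estimate is the (equal-)weighted mean of leave-one-out fits
  expect_equal(jk$estimates$estimate[jk$estimates$param == "a"],
               mean(reps$a), tolerance = 1e-8)
})

test_that("identical blocks give zero jackknife variance; order is irrelevant", {
  prof <- synthetic_profile(rep(0.03, 5))
  jk <- jackknife_fit(prof)
  expect_lt(max(jk$estimates$se), 1e-8)

  prof2 <- synthetic_profile(c(0.030, 0.034, 0.040, 0.036),
                             snp_counts = c(500L, 1500L, 800L, 1200L))
  jk2 <- jackknife_fit(prof2)
  perm <- c(3, 1, 4, 2)
  prof3 <- synthetic_profile(c(0.030, 0.034, 0.040, 0.036)[perm],
                             snp_counts = c(500L, 1500L, 800L, 1200L)[perm])
  jk3 <- jackknife_fit(prof3)
  expect_equal(sort(jk2$estimates$se), sort(jk3$estimates$se), tolerance = 1e-10)
  expect_equal(jk2$estimates$estimate, jk3$estimates$estimate, tolerance = 1e-10)

  expect_error(jackknife_fit(synthetic_profile(c(0.03, 0.04))), ">= 3 chromosomes")
})

test_that("the four significance criteria gate the founder call", {
  good <- classify_founder_event(fake_jk(30, 5, 0.02, 0.002), 0.10)
  expect_true(good$significant)
  expect_true(all(good$criteria))

  old <- classify_founder_event(fake_jk(250, 10, 0.02, 0.002), 0.10)
  expect_false(old$significant)
  expect_false(old$criteria[["recent_and_precise"]])
  expect_match(paste(old$reasons, collapse = " "), "age")

  vague <- classify_founder_event(fake_jk(30, 60, 0.02, 0.002), 0.10)
  expect_false(vague$criteria[["recent_and_precise"]])

  weak <- classify_founder_event(fake_jk(30, 5, 0.004, 0.0002), 0.10)
  expect_false(weak$significant)
  expect_false(weak$criteria[["intensity_above_threshold"]])

  noisy <- classify_founder_event(fake_jk(30, 5, 0.02, 0.002), 0.35)
  expect_false(noisy$significant)
  expect_false(noisy$criteria[["fit_quality"]])

  zero <- classify_founder_event(fake_jk(30, 20, 0.02, 0.002), 0.10)
  expect_false(zero$criteria[["ci_excludes_zero"]])

  relaxed <- classify_founder_event(fake_jk(250, 10, 0.02, 0.002), 0.10,
                                    max_age = 300)
  expect_true(relaxed$criteria[["recent_and_precise"]])
})

test_that("generation-to-year conversion handles sampling age", {
  expect_equal(generations_to_years(195, 28), 5460)
  expect_equal(generations_to_years(10, 28), 280)
  expect_equal(generations_to_years(25, 5), 125)
  expect_equal(generations_to_years(100, 28, sample_age = 9500), 12300)
  expect_error(generations_to_years(-1, 28), "non-negative")
})
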