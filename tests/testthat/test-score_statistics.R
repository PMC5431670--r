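# Distribution statistics: curves, bootstrap, KS, correlations, binary
# projection, error correction.

test_that("cumulative effect curve counts scores at or above each threshold", {
  cv <- cumulative_effect_curve(c(0, 50, 100), n_boot = 0)
  expect_equal(curve_fraction_at(cv, 50), 2 / 3)
  expect_equal(curve_fraction_at(cv, -100), 1.0)

  step <- cumulative_effect_curve(c(75, 75, 75), n_boot = 0)
  expect_equal(curve_fraction_at(step, 76), 0)
  expect_equal(curve_fraction_at(step, 75), 1)

  expect_error(cumulative_effect_curve(numeric(0)),
               class = "savshift_error_empty_input")
  expect_error(cumulative_effect_curve(150),
               class = "savshift_error_bad_input")
})

test_that("curves are monotone and agree with a linear-scan recount", {
  withr::with_seed(5, {
    for (k in 1:5) {
      scores <- runif(200, -100, 100)
      cv <- cumulative_effect_curve(scores, n_boot = 0)
      expect_true(all(diff(cv$fraction) <= 0))
      expect_equal(cv$fraction[1], 1.0)
      # second implementation: plain linear scan per threshold
      rescan <- vapply(cv$thresholds, function(t) {
        mean(scores >= t)
      }, numeric(1))
      expect_equal(cv$fraction, rescan)
    }
  })
})

test_that("bootstrap SEM is zero on constants, seeded, and near sigma/sqrt(n)", {
  expect_equal(bootstrap_sem(c(5, 5, 5, 5), seed = 1), 0)
  expect_equal(bootstrap_sem(c(5, 5, 5, 5), seed = 99), 0)

  x <- withr::with_seed(8, rnorm(10000, sd = 25))
  expect_identical(bootstrap_sem(x, 100, 7), bootstrap_sem(x, 100, 7))
  analytic <- sd(x) / sqrt(length(x))
  expect_lt(abs(bootstrap_sem(x, 100, 7) - analytic) / analytic, 0.15)

  expect_error(bootstrap_sem(x, n_boot = 1), class = "savshift_error_config")
})

test_that("curve confidence band is the threshold axis shifted by 3 SEM", {
  scores <- withr::with_seed(2, runif(500, -100, 100))
  cv <- cumulative_effect_curve(scores, n_boot = 100, seed = 3)
  expect_equal(cv$band_low, cv$thresholds - 3 * cv$sem)
  expect_equal(cv$band_high, cv$thresholds + 3 * cv$sem)
})

test_that("KS statistic matches definition and brute-force oracle", {
  same <- withr::with_seed(4, rnorm(50))
  expect_equal(ks_two_sample(same, same)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)

  withr::with_seed(19, {
    for (k in 1:60) {
      a <- sample(0:8, sample(2:12, 1), replace = TRUE)  # ties on purpose
      b <- sample(0:8, sample(2:12, 1), replace = TRUE)
      res <- ks_two_sample(a, b)
      expect_equal(res$D, oracle_ks_D(a, b))
      # cross-check against the reference library implementation
      expect_equal(res$D,
                   unname(suppressWarnings(stats::ks.test(a, b))$statistic))
    }
  })
  expect_error(ks_two_sample(numeric(0), 1),
               class = "savshift_error_empty_input")
})

test_that("KS p-values use the asymptotic Kolmogorov tail and floor at 2.2e-16", {
  a <- withr::with_seed(6, rnorm(400))
  b <- withr::with_seed(7, rnorm(400, mean = 0.3))
  res <- ks_two_sample(a, b)
  n_eff <- 400 * 400 / 800
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * (sqrt(n_eff) * res$D)^2))
  expect_equal(res$p, q, tolerance = 1e-12)
  expect_false(res$p_floored)

  far <- ks_two_sample(rep(c(-1, 0, 1), 500), rep(c(9, 10, 11), 500))
  expect_true(far$p_floored)
  expect_equal(far$p, 2.2e-16)
  expect_output(print(far), "< 2.2e-16")
})

test_that("Pearson correlation carries the analytic standard error", {
  expect_equal(signif(se_of_r(0.36, 18876), 2), 6.8e-3)
  expect_equal(se_of_r(0, 3), 1.0)

  x <- withr::with_seed(9, rnorm(100))
  y <- withr::with_seed(10, x + rnorm(100))
  res <- pearson_with_se(x, y)
  expect_equal(res$r, cor(x, y))
  expect_equal(res$se_r, sqrt((1 - res$r^2) / (res$n - 2)))

  # pairwise-complete: NAs drop pairs, n reflects it
  x[1:10] <- NA
  res2 <- pearson_with_se(x, y)
  expect_equal(res2$n, 90)

  expect_error(pearson_with_se(1:2, 2:3),
               class = "savshift_error_insufficient_data")
  expect_error(pearson_with_se(rep(1, 10), rnorm(10)),
               class = "savshift_error_undefined_correlation")
})

test_that("se_r decreases monotonically in n for fixed r", {
  ns <- c(10, 100, 1000, 10000)
  expect_true(all(diff(vapply(ns, function(n) se_of_r(0.5, n), numeric(1))) < 0))
})

test_that("effect AUC is the empirical mass strictly above zero", {
  expect_equal(effect_auc(rep(50, 5)), 1.0)
  expect_equal(effect_auc(rep(-50, 5)), 0.0)
  expect_equal(effect_auc(c(-10, -10, 10, 10)), 0.5)
  # exactly 0 is the neutral side
  expect_equal(effect_auc(c(0, 10)), 0.5)
  scores <- withr::with_seed(12, runif(301, -100, 100))
  expect_equal(effect_auc(scores) + mean(scores <= 0), 1.0)
})

test_that("accuracy curves accumulate from the extremes with NA when empty", {
  ac <- threshold_accuracy_curve(c(80, 60, -80),
                                 c("effect", "effect", "neutral"))
  at <- function(curve, t, col) curve[[col]][match(t, curve$threshold)]
  expect_equal(at(ac, 50, "effect_accuracy"), 1.0)

  ac2 <- threshold_accuracy_curve(c(80, 60, -10, -80, 70),
                                  c("effect", "effect", "effect",
                                    "neutral", "neutral"))
  expect_equal(at(ac2, 50, "effect_accuracy"), 2 / 3)
  expect_equal(at(ac2, -42, "neutral_accuracy"), 1.0)
  # TP + FP at t equals the number of scores >= t
  expect_equal(at(ac2, 50, "tp") + at(ac2, 50, "fp"), 3)
  # no score reaches +95: accuracy undefined there, not 0 or 1
  expect_true(is.na(at(ac2, 95, "effect_accuracy")))

  expect_error(threshold_accuracy_curve(c(1, 2), c("effect", "effect")),
               class = "savshift_error_degenerate_labels")
})

test_that("binary projection follows each method's convention", {
  cfg <- default_method_configs()
  expect_equal(classify_binary(c(-5, 0, 0.1), cfg$snap2),
               c("neutral", "neutral", "effect"))
  expect_equal(classify_binary(c(3.0, 3.01), cfg$cadd),
               c("neutral", "effect"))
  expect_equal(classify_binary(c("tolerated", "deleterious"), cfg$sift),
               c("neutral", "effect"))
  expect_equal(classify_binary(c("benign", "possibly_damaging",
                                 "probably_damaging"), cfg$polyphen2),
               c("neutral", "effect", "effect"))
  expect_error(classify_binary(c(1, NA), cfg$snap2),
               class = "savshift_error_missing_score")
  expect_error(method_config("x"), class = "savshift_error_config")
})

test_that("score normalisation inverts only when configured", {
  cfg <- default_method_configs()
  expect_equal(normalize_for_correlation(c(0, 1, 0.3), cfg$sift),
               c(1, 0, 0.7))
  expect_equal(normalize_for_correlation(37, cfg$snap2), 37)
  expect_error(normalize_for_correlation(NA_real_, cfg$snap2),
               class = "savshift_error_missing_score")
})

test_that("error correction moves mass by the configured rates and conserves it", {
  id <- error_correct_fractions(0.3, 0.7, fpr = 0, fnr = 0)
  expect_equal(id$neff_star, 0.3)
  expect_equal(id$nneu_star, 0.7)

  ex <- error_correct_fractions(0.5, 0.5, fpr = 0.22, fnr = 0.23)
  expect_equal(ex$neff_star, 0.505)

  withr::with_seed(13, {
    for (k in 1:50) {
      neff <- runif(1)
      res <- error_correct_fractions(neff, 1 - neff, runif(1), runif(1))
      expect_lt(abs(res$neff_star + res$nneu_star - 1), 1e-12)
    }
  })
  expect_error(error_correct_fractions(0.5, 0.6),
               class = "savshift_error_inconsistent_input")
})

test_that("grouped summaries order means correctly and compare all pairs", {
  g <- withr::with_seed(14, list(
    low = pmax(pmin(rnorm(5000, 10, 20), 100), -100),
    high = pmax(pmin(rnorm(5000, 30, 20), 100), -100)
  ))
  out <- grouped_distribution_summary(g, n_boot = 20, seed = 2)
  s <- out$summaries
  expect_lt(s$mean[s$group == "low"], s$mean[s$group == "high"])
  expect_equal(nrow(out$ks), 1L)

  same <- grouped_distribution_summary(list(a = g$low, b = g$low),
                                       n_boot = 20, seed = 2)
  expect_equal(same$ks$D, 0)

  single <- grouped_distribution_summary(list(only = g$low),
                                         n_boot = 20, seed = 2)
  expect_equal(nrow(single$ks), 0L)
  expect_error(grouped_distribution_summary(list(a = numeric(0))),
               class = "savshift_error_empty_input")
})
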