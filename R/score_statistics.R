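# Distribution-level statistics on effect scores: cumulative effect
# curves, bootstrap SEM, two-sample Kolmogorov-Smirnov comparisons,
# correlations with analytic standard errors, effect-AUC, threshold
# accuracies, binary effect/neutral projection, and error-corrected
# effect/neutral fractions.
#
# The effect-score axis is the [-100, 100] scale: -100 fully neutral,
# +100 strong effect, with 0 the default effect/neutral boundary.

SCORE_GRID <- -100:100

check_scores <- function(scores, what = "scores") {
  if (length(scores) == 0L) {
    sav_error("savshift_error_empty_input", sprintf("%s is empty", what))
  }
  if (!is.numeric(scores) || anyNA(scores)) {
    sav_error("savshift_error_bad_input",
              sprintf("%s must be numeric without NA", what))
  }
  invisible(scores)
}

#' Bootstrap standard error of the mean
#'
#' Resamples the scores with replacement `n_boot` times (resample size
#' equal to the original n), computes the mean of each resample, and
#' returns the standard deviation of those means (denominator
#' `n_boot - 1`).  Fully reproducible given the seed.
#'
#' @param scores numeric vector.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return non-negative scalar.
#' @export
bootstrap_sem <- function(scores, n_boot = 100L, seed = 1L) {
  check_scores(scores)
  if (n_boot < 2L) {
    sav_error("savshift_error_config", "n_boot must be at least 2")
  }
  n <- length(scores)
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(scores[sample.int(n, n, replace = TRUE)])
  }, numeric(1)))
  sd(means)
}

#' Cumulative effect curve
#'
#' For every integer threshold t in -100..100, the fraction of scores
#' predicted at or above t: `fraction(t) = #\{s >= t\} / n`.  The curve is
#' non-increasing with `fraction(-100) = 1`.  A single bootstrap SEM of
#' the score mean accompanies the curve; the conventional confidence band
#' is the curve shifted by +-3 SEM along the score axis, materialised here
#' as the threshold offsets `band_low`/`band_high`.
#'
#' @param scores numeric vector within \[-100, 100\].
#' @param n_boot bootstrap resamples for the SEM; 0 disables it.
#' @param seed integer seed for the bootstrap.
#' @return object of class `cumulative_curve`: a list with `thresholds`,
#'   `fraction`, `sem`, `n`, `band_low`, `band_high`.
#' @export
cumulative_effect_curve <- function(scores, n_boot = 100L, seed = 1L) {
  check_scores(scores)
  if (any(scores < -100 | scores > 100)) {
    sav_error("savshift_error_bad_input", "scores must lie within [-100, 100]")
  }
  n <- length(scores)
  # fraction >= t via one sort: #{s >= t} = n - #{s < t}
  s <- sort(scores)
  frac <- vapply(SCORE_GRID, function(t) {
    (n - findInterval(t, s, left.open = TRUE)) / n
  }, numeric(1))
  sem <- if (n_boot >= 2L) bootstrap_sem(scores, n_boot, seed) else NA_real_
  structure(list(thresholds = SCORE_GRID, fraction = frac, sem = sem, n = n,
                 band_low = SCORE_GRID - 3 * sem,
                 band_high = SCORE_GRID + 3 * sem),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("cumulative effect curve on %d scores (SEM %.3g)\n", x$n, x$sem))
  for (t in c(-42, 0, 50, 75)) {
    cat(sprintf("  fraction(score >= %+d) = %.3f\n",
                t, x$fraction[match(t, x$thresholds)]))
  }
  invisible(x)
}

#' Fraction of a curve at a threshold
#'
#' @param curve a `cumulative_curve`.
#' @param t integer threshold(s) in -100..100.
#' @return numeric fraction(s).
#' @export
curve_fraction_at <- function(curve, t) {
  idx <- match(t, curve$thresholds)
  if (anyNA(idx)) {
    sav_error("savshift_error_bad_input", "threshold outside the -100..100 grid")
  }
  curve$fraction[idx]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum over the pooled sample values of the absolute
#' difference of the two empirical distribution functions.  The p-value
#' uses the asymptotic Kolmogorov distribution at effective sample size
#' n n' / (n + n'); values below 2.2e-16 are floored and flagged, and
#' printed as "< 2.2e-16".
#'
#' @param a,b numeric samples.
#' @return object of class `ks_result` with `D`, `p`, `p_floored`, `n`,
#'   `n_prime`.
#' @export
ks_two_sample <- function(a, b) {
  check_scores(a, "sample a")
  check_scores(b, "sample b")
  n <- length(a)
  np <- length(b)
  sa <- sort(a)
  sb <- sort(b)
  pooled <- sort(unique(c(a, b)))
  Fa <- findInterval(pooled, sa) / n
  Fb <- findInterval(pooled, sb) / np
  D <- max(abs(Fa - Fb))
  n_eff <- n * np / (n + np)
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  floored <- p < 2.2e-16
  structure(list(D = D, p = max(p, 2.2e-16), p_floored = floored,
                 n = n, n_prime = np),
            class = "ks_result")
}

# Survival function of the Kolmogorov distribution,
# Q(x) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 x^2).
kolmogorov_sf <- function(x) {
  if (x <= 0) {
    return(1)
  }
  k <- 1:120
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(q, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  p_txt <- if (x$p_floored) "< 2.2e-16" else sprintf("= %.3g", x$p)
  cat(sprintf("two-sample KS: D = %.3g; n, n' = %d, %d; p-value %s\n",
              x$D, x$n, x$n_prime, p_txt))
  invisible(x)
}

#' Pearson correlation with analytic standard error
#'
#' Pairs with either value missing are dropped first (pairwise-complete,
#' as when comparing methods on the SAVs each could score).  The standard
#' error is `SE_r = sqrt((1 - r^2) / (n - 2))` with n the complete-pair
#' count.
#'
#' @param x,y numeric vectors of equal length; NAs allowed.
#' @return object of class `correlation_result` with `r`, `se_r`, `n`.
#' @export
pearson_with_se <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    sav_error("savshift_error_insufficient_data",
              sprintf("need at least 3 complete pairs, have %d", n))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    sav_error("savshift_error_undefined_correlation",
              "zero variance in x or y; correlation undefined")
  }
  r <- stats::cor(x, y)
  structure(list(r = r, se_r = se_of_r(r, n), n = n),
            class = "correlation_result")
}

#' Standard error of a Pearson coefficient
#'
#' `SE_r = sqrt((1 - r^2) / (n - 2))`.
#'
#' @param r Pearson coefficient in \[-1, 1\].
#' @param n number of pairs (>= 3).
#' @return non-negative scalar.
#' @export
se_of_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  sqrt((1 - r^2) / (n - 2))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.2f +- %.2g (n = %d)\n", x$r, x$se_r, x$n))
  invisible(x)
}

#' Effect AUC of a score distribution
#'
#' The empirical mass of the distribution on the effect side of the scale,
#' i.e. the fraction of scores strictly greater than 0.  By construction
#' `effect_auc(s) + mean(s <= 0) == 1`.
#'
#' @param scores numeric vector within \[-100, 100\].
#' @return fraction in \[0, 1\].
#' @export
effect_auc <- function(scores) {
  check_scores(scores)
  if (any(scores < -100 | scores > 100)) {
    sav_error("savshift_error_bad_input", "scores must lie within [-100, 100]")
  }
  mean(scores > 0)
}

#' Accuracy-from-the-extremes curves
#'
#' For a labeled reference set, the effect accuracy at threshold t is
#' TP / (TP + FP) among scores >= t (accumulating right-to-left from
#' +100), and the neutral accuracy is TN / (TN + FN) among scores <= t
#' (accumulating left-to-right from -100).  Thresholds whose denominator
#' is empty yield NA ("undefined"), never a silent 0 or 1.
#'
#' @param scores numeric vector.
#' @param labels character/factor vector over \{"effect", "neutral"\},
#'   aligned with `scores`; both labels must occur.
#' @return object of class `accuracy_curve`: data.frame with columns
#'   `threshold`, `effect_accuracy`, `neutral_accuracy`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
threshold_accuracy_curve <- function(scores, labels) {
  check_scores(scores)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c("effect", "neutral"))) {
    sav_error("savshift_error_bad_input",
              "labels must be 'effect' or 'neutral'")
  }
  if (length(unique(labels)) < 2L) {
    sav_error("savshift_error_degenerate_labels",
              "both effect and neutral labels are required")
  }
  eff <- labels == "effect"
  out <- data.frame(threshold = SCORE_GRID)
  out$tp <- vapply(SCORE_GRID, function(t) sum(scores >= t & eff), numeric(1))
  out$fp <- vapply(SCORE_GRID, function(t) sum(scores >= t & !eff), numeric(1))
  out$tn <- vapply(SCORE_GRID, function(t) sum(scores <= t & !eff), numeric(1))
  out$fn <- vapply(SCORE_GRID, function(t) sum(scores <= t & eff), numeric(1))
  out$effect_accuracy <- ifelse(out$tp + out$fp > 0,
                                out$tp / (out$tp + out$fp), NA_real_)
  out$neutral_accuracy <- ifelse(out$tn + out$fn > 0,
                                 out$tn / (out$tn + out$fn), NA_real_)
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Method configuration for binary projection and score normalisation
#'
#' Exactly one rule kind must be set: a numeric threshold (`effect iff
#' score > threshold`, or `>=` when `inclusive`) or a set of categorical
#' effect labels.  `invert` requests the `1 - score` transform before
#' correlation (the convention for methods whose raw score decreases with
#' effect, such as SIFT).
#'
#' @param name method identifier.
#' @param effect_threshold numeric threshold, or NULL.
#' @param inclusive does the threshold itself count as effect?
#'   Default `FALSE` (score strictly above the threshold is effect).
#' @param effect_labels character vector of categorical effect labels, or
#'   NULL.
#' @param invert apply `1 - score` in [normalize_for_correlation()]?
#' @return list of class `method_config`.
#' @export
method_config <- function(name, effect_threshold = NULL, inclusive = FALSE,
                          effect_labels = NULL, invert = FALSE) {
  if (is.null(effect_threshold) == is.null(effect_labels)) {
    sav_error("savshift_error_config",
              "set exactly one of effect_threshold and effect_labels")
  }
  structure(list(name = name, effect_threshold = effect_threshold,
                 inclusive = isTRUE(inclusive),
                 effect_labels = effect_labels, invert = isTRUE(invert)),
            class = "method_config")
}

#' Bundled method conventions
#'
#' The defaults of the four widely used predictors on their native scales:
#' effect is a SNAP2 score > 0 (a score of exactly 0 is neutral), a CADD
#' raw score > 3, a PolyPhen-2 call of probably/possibly damaging, or a
#' SIFT call of deleterious; SIFT scores are inverted (`1 - score`) before
#' correlation.
#'
#' @return named list of [method_config()] objects (`snap2`, `cadd`,
#'   `polyphen2`, `sift`).
#' @export
default_method_configs <- function() {
  list(
    snap2 = method_config("snap2", effect_threshold = 0),
    cadd = method_config("cadd", effect_threshold = 3),
    polyphen2 = method_config(
      "polyphen2",
      effect_labels = c("probably_damaging", "possibly_damaging")),
    sift = method_config("sift", effect_labels = "deleterious", invert = TRUE)
  )
}

#' Binary effect/neutral projection of raw predictions
#'
#' @param x numeric scores (threshold rule) or character labels
#'   (categorical rule).
#' @param config a [method_config()].
#' @return character vector over \{"effect", "neutral"\}.
#' @export
classify_binary <- function(x, config) {
  if (anyNA(x)) {
    sav_error("savshift_error_missing_score",
              sprintf("missing %s prediction for %d record(s)",
                      config$name, sum(is.na(x))))
  }
  if (!is.null(config$effect_threshold)) {
    if (!is.numeric(x)) {
      sav_error("savshift_error_bad_input",
                sprintf("%s uses a numeric threshold rule", config$name))
    }
    hit <- if (config$inclusive) x >= config$effect_threshold
           else x > config$effect_threshold
  } else {
    hit <- as.character(x) %in% config$effect_labels
  }
  ifelse(hit, "effect", "neutral")
}

#' Normalise a raw score for cross-method correlation
#'
#' Returns the raw score, or `1 - score` when the method's configuration
#' requests inversion.
#'
#' @param x numeric scores.
#' @param config a [method_config()].
#' @return numeric vector.
#' @export
normalize_for_correlation <- function(x, config) {
  if (anyNA(x)) {
    sav_error("savshift_error_missing_score",
              sprintf("missing %s score for %d record(s)",
                      config$name, sum(is.na(x))))
  }
  if (config$invert) 1 - x else x
}

#' Error-corrected effect/neutral fractions
#'
#' Adjusts raw binary fractions for a classifier's false-positive and
#' false-negative rates while conserving total mass:
#' `Neff* = Neff(raw) - FPR * Neff(raw) + FNR * Nneu(raw)` and
#' symmetrically for Nneu*.  The default rates 0.22/0.23 correspond to a
#' sustained positive accuracy of 78% and negative accuracy of 77% at the
#' default score threshold.
#'
#' @param neff_raw,nneu_raw raw effect/neutral fractions, summing to 1.
#' @param fpr,fnr false-positive and false-negative rates in \[0, 1\].
#' @return object of class `error_corrected_fractions` with the raw
#'   fractions, the rates, and `neff_star`, `nneu_star`.
#' @export
error_correct_fractions <- function(neff_raw, nneu_raw,
                                    fpr = 0.22, fnr = 0.23) {
  if (abs(neff_raw + nneu_raw - 1) > 1e-9) {
    sav_error("savshift_error_inconsistent_input",
              sprintf("fractions must sum to 1 (got %.12f)",
                      neff_raw + nneu_raw))
  }
  if (any(c(fpr, fnr) < 0 | c(fpr, fnr) > 1)) {
    sav_error("savshift_error_config", "rates must lie in [0, 1]")
  }
  neff_star <- neff_raw - fpr * neff_raw + fnr * nneu_raw
  nneu_star <- nneu_raw - fnr * nneu_raw + fpr * neff_raw
  structure(list(neff_raw = neff_raw, nneu_raw = nneu_raw,
                 fpr = fpr, fnr = fnr,
                 neff_star = neff_star, nneu_star = nneu_star),
            class = "error_corrected_fractions")
}

#' @export
print.error_corrected_fractions <- function(x, ...) {
  cat(sprintf("effect %.3f -> %.3f, neutral %.3f -> %.3f (FPR %.2f, FNR %.2f)\n",
              x$neff_raw, x$neff_star, x$nneu_raw, x$nneu_star,
              x$fpr, x$fnr))
  invisible(x)
}

#' Per-group distribution summaries with pairwise KS comparisons
#'
#' For every named score group: mean, bootstrap SEM, effect AUC and n;
#' plus a two-sample KS comparison for every pair of groups.
#'
#' @param scores_by_group named list of numeric score vectors.
#' @param n_boot bootstrap resamples per group.
#' @param seed integer seed; each group gets a stable sub-seed.
#' @return list with `summaries` (data.frame: group, n, mean, sem,
#'   effect_auc) and `ks` (data.frame: group_a, group_b, D, p, p_floored;
#'   zero rows for a single group).
#' @export
grouped_distribution_summary <- function(scores_by_group, n_boot = 100L,
                                         seed = 1L) {
  stopifnot(is.list(scores_by_group), !is.null(names(scores_by_group)))
  for (g in names(scores_by_group)) {
    if (length(scores_by_group[[g]]) == 0L) {
      sav_error("savshift_error_empty_input",
                sprintf("score group '%s' is empty", g))
    }
  }
  groups <- names(scores_by_group)
  summaries <- data.frame(
    group = groups,
    n = vapply(scores_by_group, length, numeric(1)),
    mean = vapply(scores_by_group, mean, numeric(1)),
    sem = vapply(groups, function(g) {
      bootstrap_sem(scores_by_group[[g]], n_boot, stable_seed(seed, g))
    }, numeric(1)),
    effect_auc = vapply(scores_by_group, effect_auc, numeric(1)),
    row.names = NULL
  )
  ks <- data.frame(group_a = character(), group_b = character(),
                   D = numeric(), p = numeric(), p_floored = logical())
  if (length(groups) > 1L) {
    pairs <- utils::combn(groups, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      res <- ks_two_sample(scores_by_group[[pairs[1, k]]],
                           scores_by_group[[pairs[2, k]]])
      data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                 D = res$D, p = res$p, p_floored = res$p_floored)
    }))
  }
  list(summaries = summaries, ks = ks)
}
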