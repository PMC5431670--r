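# Seeded synthetic-data generators: proteomes, class-specific variant
# sets, two-component effect/neutral score mixtures, diverged ortholog
# sequences, and labeled reference sets with known ground truth.
#
# Every generator is a pure function of (config, seed).  Sub-seeds are
# derived by stable hashing of a string key, so adding proteins or sets
# to a configuration does not reshuffle the streams of existing ones.

#' Synthetic study configuration
#'
#' Defaults reflect the composition of large exome variant collections,
#' scaled to desk size: unique SAVs are overwhelmingly rare (the default
#' class counts keep the roughly 7530 : 29 : 40 rare/uncommon/common
#' proportion of a 60,706-exome collection, scaled by 1/1000), allele
#' frequencies are drawn uniformly within each class band, and scores are
#' two-component effect/neutral Gaussian mixtures on the \[-100, 100\]
#' scale.  The default effect fractions (common 0.61, rare 0.48) are the
#' effect-AUC values the classes show in real predictor output; ortholog
#' divergence rates (chimp 0.01, mouse 0.10, fly 0.25) give percent
#' identities in the range where the PIDE >= 70% filter is informative.
#'
#' @param n_proteins number of synthetic proteins.
#' @param length_range integer `c(min, max)` residue lengths.
#' @param class_counts named integer vector of SAV counts per frequency
#'   class (names among rare/uncommon/common).
#' @param ldaf_ranges named list of `c(low, high)` allele-frequency bands
#'   per class; each band must lie inside the class boundaries.
#' @param score_mixtures named list of mixtures, one per set label; each
#'   a list with `effect_fraction`, `neutral_mean`, `effect_mean`, `sd`.
#' @param divergence_rates named numeric vector of per-residue
#'   substitution probabilities per species.
#' @param random_n size of the random SNV-possible background sample.
#' @param seed master integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_proteins = 40L,
    length_range = c(80L, 300L),
    class_counts = c(rare = 7530L, uncommon = 29L, common = 40L),
    ldaf_ranges = list(rare = c(0, 0.01), uncommon = c(0.01, 0.05),
                       common = c(0.05, 0.5)),
    score_mixtures = list(
      common = list(effect_fraction = 0.61, neutral_mean = -40,
                    effect_mean = 40, sd = 20),
      uncommon = list(effect_fraction = 0.50, neutral_mean = -40,
                      effect_mean = 40, sd = 20),
      rare = list(effect_fraction = 0.48, neutral_mean = -40,
                  effect_mean = 40, sd = 20),
      random = list(effect_fraction = 0.50, neutral_mean = -40,
                    effect_mean = 40, sd = 20),
      cross_species = list(effect_fraction = 0.30, neutral_mean = -40,
                           effect_mean = 40, sd = 20),
      disease = list(effect_fraction = 0.90, neutral_mean = -40,
                     effect_mean = 60, sd = 20)
    ),
    divergence_rates = c(chimp = 0.01, mouse = 0.10, fly = 0.25),
    random_n = 2000L,
    seed = 42L) {
  if (n_proteins < 1L) {
    sav_error("savshift_error_config", "n_proteins must be >= 1")
  }
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    sav_error("savshift_error_config", "invalid length_range")
  }
  if (!all(names(class_counts) %in% c("rare", "uncommon", "common"))) {
    sav_error("savshift_error_config", "unknown frequency class in class_counts")
  }
  for (cls in names(class_counts)) {
    band <- ldaf_ranges[[cls]]
    if (is.null(band) || length(band) != 2L || band[1] > band[2]) {
      sav_error("savshift_error_config",
                sprintf("missing or invalid ldaf range for class '%s'", cls))
    }
    probe <- c(band[1], band[1] + (band[2] - band[1]) * c(0.5, 0.999))
    if (!all(classify_frequency(probe) == cls)) {
      sav_error("savshift_error_config",
                sprintf("ldaf range for '%s' crosses a class boundary", cls))
    }
  }
  for (lbl in names(score_mixtures)) {
    check_mixture(score_mixtures[[lbl]], lbl)
  }
  if (any(divergence_rates < 0 | divergence_rates >= 1)) {
    sav_error("savshift_error_config", "divergence rates must lie in [0, 1)")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 class_counts = class_counts, ldaf_ranges = ldaf_ranges,
                 score_mixtures = score_mixtures,
                 divergence_rates = divergence_rates,
                 random_n = as.integer(random_n),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

check_mixture <- function(mix, lbl = "?") {
  need <- c("effect_fraction", "neutral_mean", "effect_mean", "sd")
  if (!all(need %in% names(mix))) {
    sav_error("savshift_error_config",
              sprintf("mixture '%s' lacks: %s", lbl,
                      paste(setdiff(need, names(mix)), collapse = ", ")))
  }
  if (mix$effect_fraction < 0 || mix$effect_fraction > 1) {
    sav_error("savshift_error_config",
              sprintf("mixture '%s': effect_fraction outside [0, 1]", lbl))
  }
  if (abs(mix$neutral_mean) > 100 || abs(mix$effect_mean) > 100) {
    sav_error("savshift_error_config",
              sprintf("mixture '%s': component means outside [-100, 100]", lbl))
  }
  if (mix$sd <= 0) {
    sav_error("savshift_error_config",
              sprintf("mixture '%s': sd must be positive", lbl))
  }
  invisible(mix)
}

#' Read a synthetic configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    sav_error("savshift_error_config",
              sprintf("unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  for (vec in c("class_counts", "divergence_rates")) {
    if (!is.null(raw[[vec]])) {
      raw[[vec]] <- unlist(raw[[vec]])
    }
  }
  do.call(synthetic_config, raw)
}

#' Generate a synthetic proteome
#'
#' Sequences drawn uniformly over the 20 standard residues, lengths
#' uniform on `length_range`; ids `SP0001`, `SP0002`, ...  Reproducible
#' per seed; each protein uses a stable sub-seed of its own.
#'
#' @param config a [synthetic_config()].
#' @return named character vector of sequences.
#' @export
generate_proteome <- function(config) {
  ids <- sprintf("SP%04d", seq_len(config$n_proteins))
  rng <- config$length_range
  lens <- with_seed(stable_seed(config$seed, "proteome_lengths"), {
    rng[1] - 1L + sample.int(rng[2] - rng[1] + 1L, config$n_proteins,
                             replace = TRUE)
  })
  seqs <- vapply(seq_along(ids), function(i) {
    with_seed(stable_seed(config$seed, paste0("protein_", ids[i])), {
      paste(sample(AA_STANDARD, lens[i], replace = TRUE), collapse = "")
    })
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Generate frequency-class variant sets
#'
#' SAVs are sampled without replacement across all (protein, position,
#' alternate) triples of the proteome — jointly over the classes, so no
#' SAV appears in two classes — and each SAV receives an allele frequency
#' drawn uniformly from its class band.  By construction
#' `classify_frequency(ldaf)` equals the assigned class for every record.
#'
#' @param proteome named character vector or AAStringSet.
#' @param config a [synthetic_config()].
#' @return named list of SAV tables, one per class in `class_counts`.
#' @export
generate_variant_sets <- function(proteome, config) {
  pool <- enumerate_candidate_savs(proteome, "all19")
  total <- sum(config$class_counts)
  if (total > nrow(pool)) {
    sav_error("savshift_error_insufficient_pool",
              sprintf("requested %d SAVs from a pool of %d candidates",
                      total, nrow(pool)))
  }
  idx <- with_seed(stable_seed(config$seed, "variant_sets"),
                   sample.int(nrow(pool), total))
  classes <- rep(names(config$class_counts), times = config$class_counts)
  out <- lapply(stats::setNames(nm = names(config$class_counts)), function(cls) {
    take <- sort(idx[classes == cls])
    df <- pool[take, , drop = FALSE]
    rownames(df) <- NULL
    band <- config$ldaf_ranges[[cls]]
    df$ldaf <- with_seed(stable_seed(config$seed, paste0("ldaf_", cls)),
                         runif(nrow(df), band[1], band[2]))
    # runif can in principle return its upper bound; fold such draws back
    hi <- df$ldaf >= band[2]
    df$ldaf[hi] <- band[1] + (band[2] - band[1]) / 2
    df$set_label <- cls
    df
  })
  out
}

# Normal deviates truncated to [-100, 100] by resampling (not clipping),
# so the boundaries carry no probability atoms.
rtrunc_score <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < -100 | x > 100)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < -100 | x[bad] > 100]
  }
  x
}

#' Attach mixture-model scores to a variant set
#'
#' Each SAV is independently labeled `effect` with probability
#' `effect_fraction` and its score drawn from the corresponding Gaussian
#' component, truncated to \[-100, 100\] by resampling.  The ground-truth
#' component label is retained in `true_label`.
#'
#' @param savs a SAV table.
#' @param mixture list with `effect_fraction`, `neutral_mean`,
#'   `effect_mean`, `sd`.
#' @param seed integer seed.
#' @return `savs` with `score` and `true_label` columns appended.
#' @export
generate_scores <- function(savs, mixture, seed) {
  check_mixture(mixture)
  n <- nrow(savs)
  out <- savs
  if (n == 0L) {
    out$score <- numeric(0)
    out$true_label <- character(0)
    return(out)
  }
  with_seed(seed, {
    is_effect <- runif(n) < mixture$effect_fraction
    score <- numeric(n)
    score[is_effect] <- rtrunc_score(sum(is_effect), mixture$effect_mean,
                                     mixture$sd)
    score[!is_effect] <- rtrunc_score(sum(!is_effect), mixture$neutral_mean,
                                      mixture$sd)
    out$score <- score
    out$true_label <- ifelse(is_effect, "effect", "neutral")
  })
  out
}

#' Generate a diverged ortholog sequence
#'
#' Each position is independently substituted with probability `rate` by
#' a uniformly chosen different residue; no indels, so a global alignment
#' of the pair recovers exactly the substituted positions.
#'
#' @param sequence a single amino-acid string.
#' @param rate substitution probability per residue in \[0, 1).
#' @param seed integer seed.
#' @return the diverged sequence (character scalar); attribute
#'   `n_substituted` counts changed positions.
#' @export
generate_ortholog_pair <- function(sequence, rate, seed) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            rate >= 0, rate < 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    flip <- which(runif(length(chars)) < rate)
    for (i in flip) {
      chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
    }
  })
  structure(paste(chars, collapse = ""), n_substituted = length(flip))
}

#' Generate a labeled effect/neutral reference set
#'
#' Draws `n_effect` scores from the effect component and `n_neutral` from
#' the neutral component of a mixture; feeds
#' [threshold_accuracy_curve()].
#'
#' @param n_effect,n_neutral component sample sizes (each >= 1).
#' @param mixture list with `neutral_mean`, `effect_mean`, `sd`
#'   (`effect_fraction` is ignored here: counts are explicit).
#' @param seed integer seed.
#' @return data.frame with columns `score`, `label`.
#' @export
generate_labeled_reference <- function(n_effect, n_neutral, mixture, seed) {
  if (n_effect < 1L || n_neutral < 1L) {
    sav_error("savshift_error_degenerate_labels",
              "need at least one effect and one neutral reference score")
  }
  if (is.null(mixture$effect_fraction)) {
    mixture$effect_fraction <- 0.5
  }
  check_mixture(mixture)
  with_seed(seed, {
    data.frame(
      score = c(rtrunc_score(n_effect, mixture$effect_mean, mixture$sd),
                rtrunc_score(n_neutral, mixture$neutral_mean, mixture$sd)),
      label = rep(c("effect", "neutral"), c(n_effect, n_neutral)),
      stringsAsFactors = FALSE
    )
  })
}
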