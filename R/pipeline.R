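# Orchestration of the three headline comparisons: within-human
# frequency classes, cross-species vs within-human, and observed vs
# random backgrounds.  Works from a synthetic configuration (or a YAML
# file naming one) and produces a self-contained analysis report.

#' Run the full comparison pipeline
#'
#' Stages, in order: simulate a proteome; draw frequency-class variant
#' sets and score them; sample a random SNV-possible background; build
#' diverged orthologs per species, extract cross-species SAVs through the
#' alignment/PIDE machinery and score them; then compute per-set
#' distribution summaries, cumulative effect curves, all pairwise KS
#' comparisons, error-corrected effect/neutral fractions, a cross-method
#' correlation, and the localization enrichment of proteins passing the
#' strong-effect filter.  A structured log records every filter count.
#'
#' @param config a [synthetic_config()], or the path to a YAML file of
#'   one.
#' @param n_boot bootstrap resamples per set (default 100).
#' @param params an [alignment_params()] for ortholog extraction.
#' @return object of class `analysis_report`: a list with `summaries`,
#'   `ks`, `curves`, `corrected_fractions`, `correlations`, `enrichment`,
#'   `log` and a `provenance` block.
#' @export
run_comparison <- function(config = synthetic_config(), n_boot = 100L,
                           params = alignment_params()) {
  if (is.character(config)) {
    config <- read_synthetic_config(config)
  }
  stopifnot(inherits(config, "synthetic_config"))
  log <- list()

  proteome <- generate_proteome(config)
  proteome <- filter_protein_length(proteome)
  log$proteins_dropped_by_length <- attr(proteome, "n_removed")
  log$proteins_kept <- length(proteome)

  vsets <- generate_variant_sets(proteome, config)
  scored <- lapply(stats::setNames(nm = names(vsets)), function(cls) {
    generate_scores(vsets[[cls]], config$score_mixtures[[cls]],
                    stable_seed(config$seed, paste0("scores_", cls)))
  })

  rnd <- sample_random_savs(proteome, "snv_possible", config$random_n,
                            stable_seed(config$seed, "random_background"))
  scored$random <- generate_scores(rnd, config$score_mixtures$random,
                                   stable_seed(config$seed, "scores_random"))

  xs <- cross_species_stage(proteome, config, params)
  log$ortholog_pairs_rejected_by_pide <- xs$n_rejected
  log$ortholog_pairs_aligned <- xs$n_aligned
  for (sp in names(xs$savs)) {
    set <- xs$savs[[sp]]
    if (nrow(set)) {
      scored[[sp]] <- generate_scores(
        set[setdiff(names(set), "context")],
        config$score_mixtures$cross_species,
        stable_seed(config$seed, paste0("scores_", sp)))
    }
  }

  scores_by_set <- lapply(scored, `[[`, "score")
  stats <- grouped_distribution_summary(scores_by_set, n_boot = n_boot,
                                        seed = stable_seed(config$seed,
                                                           "bootstrap"))
  curves <- lapply(stats::setNames(nm = names(scores_by_set)), function(s) {
    cumulative_effect_curve(scores_by_set[[s]], n_boot = n_boot,
                            seed = stable_seed(config$seed,
                                               paste0("curve_", s)))
  })
  snap2 <- default_method_configs()$snap2
  corrected <- lapply(stats::setNames(nm = names(scores_by_set)), function(s) {
    cls <- classify_binary(scores_by_set[[s]], snap2)
    error_correct_fractions(mean(cls == "effect"), mean(cls == "neutral"))
  })

  correlations <- method_correlation_stage(scored, config)
  enrichment <- enrichment_stage(scored, proteome, config)

  report <- structure(list(
    config = config,
    summaries = stats$summaries,
    ks = stats$ks,
    curves = curves,
    corrected_fractions = corrected,
    correlations = correlations,
    enrichment = enrichment,
    log = log,
    provenance = list(
      package = "savshift",
      version = as.character(utils::packageVersion("savshift")),
      seed = config$seed,
      config_hash = stable_seed(0L, paste(deparse(unclass(config)),
                                          collapse = "")),
      r_version = R.version.string
    )
  ), class = "analysis_report")
  report
}

# Diverged orthologs per species and their extracted SAV sets.
cross_species_stage <- function(proteome, config, params) {
  savs <- list()
  n_rejected <- 0L
  n_aligned <- 0L
  for (sp in names(config$divergence_rates)) {
    rate <- config$divergence_rates[[sp]]
    per_protein <- list()
    for (id in names(proteome)) {
      orth <- generate_ortholog_pair(
        proteome[[id]], rate,
        stable_seed(config$seed, paste0("ortholog_", sp, "_", id)))
      res <- tryCatch(
        extract_cross_species_savs(proteome[id],
                                   stats::setNames(orth, paste0(sp, "_", id)),
                                   params, set_label = sp),
        savshift_error_low_pide = function(e) NULL
      )
      if (is.null(res)) {
        n_rejected <- n_rejected + 1L
      } else {
        n_aligned <- n_aligned + 1L
        per_protein[[id]] <- res
      }
    }
    savs[[sp]] <- if (length(per_protein)) {
      out <- do.call(rbind, per_protein)
      rownames(out) <- NULL
      out
    } else {
      empty <- sav_table(character(), integer(), character(), character(),
                        numeric(), character())
      empty$context <- character(0)
      empty
    }
  }
  list(savs = savs, n_rejected = n_rejected, n_aligned = n_aligned)
}

# A second, correlated synthetic predictor on the SIFT-like [0, 1] scale
# (low = deleterious), so the cross-method correlation machinery runs on
# a method pair that needs inversion.
method_correlation_stage <- function(scored, config) {
  pooled <- do.call(rbind, lapply(names(scored), function(s) {
    scored[[s]][c("protein_id", "position", "ref_aa", "alt_aa", "score")]
  }))
  snap2_like <- pooled$score
  sift_like <- with_seed(stable_seed(config$seed, "sift_like"), {
    1 - stats::plogis((snap2_like + rnorm(length(snap2_like), 0, 35)) / 25)
  })
  cfg <- default_method_configs()
  res <- pearson_with_se(
    normalize_for_correlation(snap2_like, cfg$snap2),
    normalize_for_correlation(sift_like, cfg$sift))
  data.frame(method_a = "snap2_like", method_b = "sift_like",
             r = res$r, se_r = res$se_r, n = res$n)
}

# Strong-effect enrichment of common SAVs plus localization folds against
# synthetic per-protein localization labels.
enrichment_stage <- function(scored, proteome, config) {
  if (is.null(scored$common) || nrow(scored$common) == 0L) {
    return(NULL)
  }
  labels <- with_seed(stable_seed(config$seed, "localization"), {
    stats::setNames(
      sample(c("nuclear", "secreted", "cell_membrane", "other"),
             length(proteome), replace = TRUE,
             prob = c(0.28, 0.12, 0.11, 0.49)),
      names(proteome))
  })
  spec <- enrichment_filter_spec(frequency_class = "common")
  hits <- filter_enriched_proteins(scored$common, spec)
  background <- sort(unique(unlist(lapply(scored, `[[`, "protein_id"))))
  folds <- localization_fold(
    labels, hits, background,
    groups = list(secreted_membrane = c("secreted", "cell_membrane")))
  list(filter_spec = spec, enriched_proteins = hits,
       localization = folds, labels = labels)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("savshift analysis report (seed ", x$provenance$seed, ")\n\n", sep = "")
  print(x$summaries, digits = 3)
  cat("\npairwise KS comparisons:\n")
  ks <- x$ks
  ks$p <- ifelse(ks$p_floored, "< 2.2e-16", sprintf("%.3g", ks$p))
  print(ks[c("group_a", "group_b", "D", "p")], digits = 3)
  if (!is.null(x$enrichment)) {
    cat("\nlocalization enrichment of strong-effect proteins:\n")
    print(x$enrichment$localization, digits = 3)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (summaries, KS matrix, corrected fractions,
#' correlations, enrichment, log, provenance) plus one tab-separated
#' cumulative-curve table per set (`curve_<set>.tsv`, columns threshold,
#' fraction, band_low, band_high).
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    summaries = report$summaries,
    ks = report$ks,
    corrected_fractions = lapply(report$corrected_fractions, unclass),
    correlations = report$correlations,
    enrichment = if (!is.null(report$enrichment)) {
      list(enriched_proteins = report$enrichment$enriched_proteins,
           localization = report$enrichment$localization)
    },
    log = report$log,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in names(report$curves)) {
    cv <- report$curves[[s]]
    utils::write.table(
      data.frame(threshold = cv$thresholds, fraction = cv$fraction,
                 band_low = cv$band_low, band_high = cv$band_high),
      file.path(dir, paste0("curve_", s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
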