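# Per-protein enrichment filters for strongly predicted SAVs, optional
# residue-coverage predicates, and localization fold ratios.

#' Enrichment filter specification
#'
#' A protein passes when it carries at least `min_count` SAVs of the
#' requested frequency class and the fraction of those with a score above
#' `score_threshold` meets (or, when `fraction_strict`, strictly exceeds)
#' `min_fraction`.
#'
#' @param frequency_class `"rare"`, `"uncommon"`, `"common"` or `"any"`.
#' @param min_count minimum class-matching SAVs per protein (default 2,
#'   i.e. "more than one").
#' @param score_threshold strong-effect score cut (default 50; a SAV
#'   counts when its score is strictly above this).
#' @param min_fraction required fraction of strong-effect SAVs
#'   (default 0.5).
#' @param fraction_strict must the fraction strictly exceed
#'   `min_fraction`? Default `TRUE` ("over 50%").
#' @return list of class `enrichment_filter_spec`.
#' @export
enrichment_filter_spec <- function(frequency_class = "any", min_count = 2L,
                                   score_threshold = 50, min_fraction = 0.5,
                                   fraction_strict = TRUE) {
  frequency_class <- match.arg(frequency_class,
                               c("any", "rare", "uncommon", "common"))
  if (min_fraction < 0 || min_fraction > 1) {
    sav_error("savshift_error_config", "min_fraction must lie in [0, 1]")
  }
  if (min_count < 1L) {
    sav_error("savshift_error_config", "min_count must be >= 1")
  }
  structure(list(frequency_class = frequency_class,
                 min_count = as.integer(min_count),
                 score_threshold = score_threshold,
                 min_fraction = min_fraction,
                 fraction_strict = isTRUE(fraction_strict)),
            class = "enrichment_filter_spec")
}

#' Proteins enriched in strongly predicted SAVs
#'
#' @param scored_savs a SAV table with a numeric `score` column (and an
#'   `ldaf` column when the spec restricts the frequency class).
#' @param spec an [enrichment_filter_spec()].
#' @return character vector of passing protein ids, sorted; invariant
#'   under reordering of the input rows.
#' @export
filter_enriched_proteins <- function(scored_savs,
                                     spec = enrichment_filter_spec()) {
  if (nrow(scored_savs) == 0L) {
    return(character())
  }
  if (!"score" %in% names(scored_savs) || anyNA(scored_savs$score)) {
    sav_error("savshift_error_missing_score",
              "every SAV needs a score for the enrichment filter")
  }
  if (spec$frequency_class != "any") {
    cls <- classify_frequency(scored_savs$ldaf)
    scored_savs <- scored_savs[cls == spec$frequency_class, , drop = FALSE]
    if (nrow(scored_savs) == 0L) {
      return(character())
    }
  }
  strong <- scored_savs$score > spec$score_threshold
  counts <- tapply(strong, scored_savs$protein_id, length)
  frac <- tapply(strong, scored_savs$protein_id, mean)
  enough <- counts >= spec$min_count
  hit <- if (spec$fraction_strict) frac > spec$min_fraction
         else frac >= spec$min_fraction
  sort(names(counts)[enough & hit])
}

#' Residue coverage of a protein by a SAV set
#'
#' Number of distinct SAV positions divided by protein length; used as an
#' optional predicate (e.g. "at least 50% of residue positions observed
#' as a SAV").
#'
#' @param savs a SAV table.
#' @param proteome named character vector or AAStringSet.
#' @return named numeric vector, one coverage per protein in `savs`.
#' @export
sav_coverage <- function(savs, proteome) {
  proteome <- as_proteome(proteome)
  ids <- unique(savs$protein_id)
  unknown <- setdiff(ids, names(proteome))
  if (length(unknown)) {
    sav_error("savshift_error_bad_input",
              sprintf("no sequence for protein(s): %s",
                      paste(utils::head(unknown, 3), collapse = ", ")))
  }
  vapply(ids, function(id) {
    pos <- unique(savs$position[savs$protein_id == id])
    length(pos) / nchar(proteome[[id]])
  }, numeric(1))
}

#' @rdname sav_coverage
#' @param min_coverage required coverage fraction.
#' @return `filter_by_coverage` returns the protein ids meeting
#'   `min_coverage`.
#' @export
filter_by_coverage <- function(savs, proteome, min_coverage = 0.5) {
  cov <- sav_coverage(savs, proteome)
  sort(names(cov)[cov >= min_coverage])
}

#' Localization over/under-representation
#'
#' Per localization category: the fraction of the subset proteins in the
#' category (`observed`), the fraction of the background proteins in it
#' (`expected`), and their ratio (`fold`).  Categories present in the
#' background but absent from the subset are reported with observed 0; a
#' category present in the subset with zero background expectation gets
#' an infinite fold (flagged, not an error).  Raw labels may be grouped
#' into unions (e.g. secreted + cell membrane) via `groups`.
#'
#' @param labels named character vector mapping protein id to raw
#'   category label.
#' @param subset character vector of protein ids (e.g. the output of
#'   [filter_enriched_proteins()]).
#' @param background character vector of protein ids defining the
#'   expectation (unweighted protein fractions).
#' @param groups optional named list mapping a group name to the raw
#'   labels it unites.
#' @return data.frame with columns `category`, `observed`, `expected`,
#'   `fold`, `infinite_fold`.
#' @export
localization_fold <- function(labels, subset, background, groups = NULL) {
  if (length(background) == 0L) {
    sav_error("savshift_error_empty_input", "background is empty")
  }
  unlabeled <- setdiff(unique(c(subset, background)), names(labels))
  if (length(unlabeled)) {
    sav_error("savshift_error_bad_input",
              sprintf("no localization label for protein(s): %s",
                      paste(utils::head(unlabeled, 3), collapse = ", ")))
  }
  cat_of <- labels
  if (!is.null(groups)) {
    for (g in names(groups)) {
      cat_of[cat_of %in% groups[[g]]] <- g
    }
  }
  cats <- sort(unique(cat_of[c(subset, background)]))
  observed <- vapply(cats, function(cc) {
    if (length(subset) == 0L) 0 else mean(cat_of[subset] == cc)
  }, numeric(1))
  expected <- vapply(cats, function(cc) mean(cat_of[background] == cc),
                     numeric(1))
  fold <- ifelse(expected > 0, observed / expected,
                 ifelse(observed > 0, Inf, NA_real_))
  data.frame(category = cats, observed = observed, expected = expected,
             fold = fold, infinite_fold = is.infinite(fold),
             row.names = NULL)
}
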