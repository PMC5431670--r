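# Pairwise global alignment of human/ortholog protein pairs, identity
# filters, best-ortholog selection, and cross-species SAV extraction with
# the back-mutation convention.
#
# Scoring follows the EMBOSS needle convention: an internal gap of length
# k costs gap_open + (k - 1) * gap_extend, and end gaps are free unless
# `end_gaps = TRUE`.  The dynamic programming itself is delegated to
# Biostrings::pairwiseAlignment (type "overlap" for free end gaps,
# "global" otherwise); the wrapper converts between the two gap-cost
# parameterisations and reconstructs full-length aligned strings.

#' Alignment parameters
#'
#' @param substitution_matrix a named 20x20 scoring matrix, or the name of
#'   one shipped with Biostrings (default `"BLOSUM62"`).
#' @param gap_open penalty for the first column of a gap (default 10).
#' @param gap_extend penalty for each further gapped column (default 0.5).
#' @param min_pide minimum percent identity over gap-free columns for an
#'   alignment to be used for SAV extraction (default 0.70).
#' @param end_gaps penalise end gaps? Default `FALSE` (needle's default).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5,
                             min_pide = 0.70, end_gaps = FALSE) {
  if (is.character(substitution_matrix)) {
    name <- substitution_matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    substitution_matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    sav_error("savshift_error_config",
              "need gap_open >= gap_extend > 0")
  }
  if (min_pide < 0 || min_pide > 1) {
    sav_error("savshift_error_config", "min_pide must lie in [0,1]")
  }
  structure(list(substitution_matrix = substitution_matrix,
                 matrix_name = name, gap_open = gap_open,
                 gap_extend = gap_extend, min_pide = min_pide,
                 end_gaps = isTRUE(end_gaps)),
            class = "alignment_params")
}

check_alignable <- function(x, what) {
  bad <- masked_positions(x)
  if (length(bad)) {
    sav_error("savshift_error_alignment",
              sprintf("non-standard residue '%s' at position %d of %s",
                      substr(x, bad[1], bad[1]), bad[1], what))
  }
}

#' Optimal global alignment with affine gaps
#'
#' Returns an optimal global alignment of two protein sequences under
#' affine gap scoring (first gapped column costs `gap_open`, each further
#' one `gap_extend`; end gaps free unless `params$end_gaps`).  The aligned
#' strings always span both full sequences: stripping `-` from either row
#' recovers the corresponding input exactly.
#'
#' @param a,b amino-acid strings over the standard alphabet.
#' @param params an [alignment_params()] object.
#' @return list of class `alignment_result` with elements `aligned_a`,
#'   `aligned_b`, `score`, `pide_nogap`, `ungapped_identity`.
#' @export
global_align_affine <- function(a, b, params = alignment_params()) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    sav_error("savshift_error_alignment", "cannot align an empty sequence")
  }
  check_alignable(a, "sequence a")
  check_alignable(b, "sequence b")

  type <- if (params$end_gaps) "global" else "overlap"
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params$substitution_matrix,
    # Biostrings charges gapOpening + L * gapExtension for a gap of
    # length L; shift the opening cost so that the total matches
    # gap_open + (L - 1) * gap_extend.
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend,
    type = type
  )
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))

  if (type == "overlap") {
    # For ends-free alignments Biostrings reports only the aligned
    # region; pad the unaligned flanks back in, stacking each flank
    # against gaps (score-neutral because end gaps are free).
    rng_a <- c(Biostrings::start(Biostrings::pattern(al)),
               Biostrings::end(Biostrings::pattern(al)))
    rng_b <- c(Biostrings::start(Biostrings::subject(al)),
               Biostrings::end(Biostrings::subject(al)))
    pre_a <- substr(a, 1L, rng_a[1] - 1L)
    pre_b <- substr(b, 1L, rng_b[1] - 1L)
    suf_a <- substr(a, rng_a[2] + 1L, nchar(a))
    suf_b <- substr(b, rng_b[2] + 1L, nchar(b))
    gaps <- function(k) strrep("-", k)
    aligned_a <- paste0(pre_a, gaps(nchar(pre_b)), pat,
                        suf_a, gaps(nchar(suf_b)))
    aligned_b <- paste0(gaps(nchar(pre_a)), pre_b, sub,
                        gaps(nchar(suf_a)), suf_b)
  } else {
    aligned_a <- pat
    aligned_b <- sub
  }

  res <- structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                        score = Biostrings::score(al),
                        pide_nogap = NA_real_,
                        ungapped_identity = NA_real_,
                        params = params),
                   class = "alignment_result")
  # a fully unmatched ends-free alignment has no gap-free columns and
  # hence no defined PIDE; keep NA so downstream filters reject the pair
  ident <- tryCatch(pide_measures(res),
                    savshift_error_alignment = function(e) {
                      c(pide_nogap = NA_real_, ungapped_identity = NA_real_)
                    })
  res$pide_nogap <- ident[["pide_nogap"]]
  res$ungapped_identity <- ident[["ungapped_identity"]]
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "global alignment: score %.1f, PIDE (no gaps) %.3f, ungapped identity %.3f\n",
    x$score, x$pide_nogap, x$ungapped_identity))
  cat(x$aligned_a, x$aligned_b, sep = "\n")
  invisible(x)
}

#' Identity measures of an alignment
#'
#' `pide_nogap` is the fraction of identical columns among columns where
#' neither row carries a gap; this is the quantity the `min_pide` filter
#' tests.  `ungapped_identity` — used to pick among multiple orthologs —
#' is the number of identical columns divided by the length of the shorter
#' sequence.
#'
#' @param aln an `alignment_result`.
#' @return named numeric vector `c(pide_nogap=, ungapped_identity=)`.
#' @export
pide_measures <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  gap_free <- ca != "-" & cb != "-"
  if (!any(gap_free)) {
    sav_error("savshift_error_alignment",
              "alignment has no gap-free columns; PIDE is undefined")
  }
  ident <- sum(ca == cb & gap_free)
  c(pide_nogap = ident / sum(gap_free),
    ungapped_identity = ident / min(sum(ca != "-"), sum(cb != "-")))
}

#' Select the best ortholog among several candidates
#'
#' Aligns the human protein to every candidate, drops candidates whose
#' PIDE (excluding gaps) falls below `params$min_pide`, and among the
#' survivors returns the one with the highest ungapped sequence identity.
#' Ties go to the lexicographically smallest candidate id.
#'
#' @param human a single named sequence (named character of length 1).
#' @param candidates named character vector or AAStringSet of candidate
#'   ortholog sequences.
#' @param params an [alignment_params()] object.
#' @return list with `id`, `sequence`, `alignment`.
#' @export
select_best_ortholog <- function(human, candidates,
                                 params = alignment_params()) {
  candidates <- as_proteome(candidates)
  if (!length(candidates)) {
    sav_error("savshift_error_bad_input", "no candidate orthologs supplied")
  }
  human_seq <- unname(as_proteome(human)[1])
  # a candidate so dissimilar that the ends-free alignment is empty has
  # an undefined PIDE; treat it as failing the identity filter
  alns <- lapply(candidates, function(s) {
    tryCatch(global_align_affine(human_seq, s, params),
             savshift_error_alignment = function(e) NULL)
  })
  pide <- vapply(alns, function(x) {
    if (is.null(x)) NA_real_ else x$pide_nogap
  }, numeric(1))
  pass <- !is.na(pide) & pide >= params$min_pide
  if (!any(pass)) {
    sav_error(
      "savshift_error_no_ortholog",
      sprintf("no candidate reaches PIDE >= %.2f (%s)", params$min_pide,
              paste(sprintf("%s: %.3f", names(pide), pide), collapse = ", ")),
      pide = pide
    )
  }
  ung <- vapply(alns, function(x) {
    if (is.null(x)) -Inf else x$ungapped_identity
  }, numeric(1))
  ung[!pass] <- -Inf
  ids <- names(candidates)
  best <- ids[order(-ung, ids)][1]
  list(id = best, sequence = candidates[[best]], alignment = alns[[best]])
}

#' Extract cross-species SAVs from a human/ortholog pair
#'
#' Every gap-free alignment column where the two residues differ yields
#' one SAV in the back-mutated convention: the non-human residue `o` is
#' the reference, the human residue `h` the alternate, the position is the
#' human coordinate (counting non-gap human characters left to right), and
#' the context sequence is the human sequence with that position replaced
#' by `o` — so that applying the variant to its context reproduces the
#' human protein exactly.  Gap columns produce no SAV.
#'
#' @param human single named human sequence.
#' @param ortholog single named ortholog sequence.
#' @param params an [alignment_params()] object; the pair is rejected when
#'   PIDE (excluding gaps) is below `params$min_pide`.
#' @param set_label label stamped on the SAVs (default `"cross_species"`).
#' @return a SAV table with an extra `context` column holding the
#'   back-mutated human sequence of each SAV; attribute `alignment` keeps
#'   the underlying `alignment_result`.
#' @export
extract_cross_species_savs <- function(human, ortholog,
                                       params = alignment_params(),
                                       set_label = "cross_species") {
  human <- as_proteome(human)
  human_id <- names(human)[1]
  human_seq <- human[[1]]
  ortholog_seq <- as_proteome(ortholog)[[1]]

  aln <- global_align_affine(human_seq, ortholog_seq, params)
  if (is.na(aln$pide_nogap) || aln$pide_nogap < params$min_pide) {
    sav_error("savshift_error_low_pide",
              sprintf("pair rejected: PIDE %.3f < %.2f",
                      aln$pide_nogap, params$min_pide),
              pide = aln$pide_nogap)
  }
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  hpos <- cumsum(ca != "-")
  diff <- which(ca != "-" & cb != "-" & ca != cb)
  # each human coordinate occupies exactly one alignment column
  stopifnot(!anyDuplicated(hpos[diff]))
  empty <- sav_table(character(), integer(), character(), character(),
                     numeric(), character())
  empty$context <- character(0)
  if (!length(diff)) {
    attr(empty, "alignment") <- aln
    return(empty)
  }
  masked <- masked_positions(human_seq)
  keep <- !(hpos[diff] %in% masked)
  if (any(!keep)) {
    warning(sprintf("%d cross-species SAV(s) on masked positions skipped",
                    sum(!keep)), call. = FALSE)
    diff <- diff[keep]
  }
  if (!length(diff)) {
    attr(empty, "alignment") <- aln
    return(empty)
  }
  pos <- hpos[diff]
  out <- sav_table(human_id, pos, ref_aa = cb[diff], alt_aa = ca[diff],
                   ldaf = NA_real_, set_label = set_label)
  out$context <- vapply(seq_along(pos), function(k) {
    ctx <- human_seq
    substr(ctx, pos[k], pos[k]) <- cb[diff[k]]
    ctx
  }, character(1))
  attr(out, "alignment") <- aln
  out
}

#' Restrict per-species SAV sets to shared "house-keeping" proteins
#'
#' Keeps only SAVs on proteins that occur — with at least one SAV — in
#' every species' cross-species set and in the within-human set.
#'
#' @param per_species_savs named list of SAV tables, one per species.
#' @param within_human_savs SAV table of within-human variants.
#' @return list with `per_species` (restricted named list) and
#'   `within_human` (restricted table); attribute `shared_proteins` holds
#'   the protein ids retained.
#' @export
housekeeping_subset <- function(per_species_savs, within_human_savs) {
  stopifnot(is.list(per_species_savs), length(per_species_savs) >= 1L)
  sets <- c(per_species_savs, list(.human = within_human_savs))
  shared <- Reduce(intersect, lapply(sets, function(d) unique(d$protein_id)))
  if (!length(shared)) {
    message("housekeeping_subset: no protein shared by all sets")
  }
  restrict <- function(d) {
    out <- d[d$protein_id %in% shared, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  out <- list(per_species = lapply(per_species_savs, restrict),
              within_human = restrict(within_human_savs))
  attr(out, "shared_proteins") <- shared
  out
}
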