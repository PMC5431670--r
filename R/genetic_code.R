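# SNV reachability over amino acids and the two random SAV backgrounds.
#
# An amino-acid pair (a, b) is "SNV-reachable" when some sense codon of a
# and some sense codon of b differ at exactly one nucleotide.  The relation
# is codon-agnostic: it is existential over all codons of the reference
# residue, because no transcript/codon source is attached to the proteins
# being mutated in silico.  The codon actually present at a genomic site
# could make fewer substitutions reachable; see the methods vignette.

#' Read a codon table
#'
#' Tab-separated resource with columns `codon` and `aa` (one-letter amino
#' acid, `*` for stop).  The packaged default is the standard genetic code.
#'
#' @param path file path; defaults to the packaged standard code.
#' @return data.frame with columns `codon` and `aa`, validated to contain
#'   the 64 codons, exactly 3 stops, and all 20 amino acids.
#' @export
read_codon_table <- function(path = system.file("extdata",
                                                "standard_genetic_code.tsv",
                                                package = "savshift")) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("codon", "aa") %in% names(tbl))) {
    sav_error("savshift_error_config",
              "codon table needs columns 'codon' and 'aa'")
  }
  tbl$codon <- toupper(tbl$codon)
  tbl$aa <- toupper(tbl$aa)
  if (nrow(tbl) != 64L || anyDuplicated(tbl$codon) ||
      !all(grepl("^[ACGT]{3}$", tbl$codon))) {
    sav_error("savshift_error_config",
              "codon table must list each of the 64 ACGT codons exactly once")
  }
  sense <- tbl$aa != "*"
  if (sum(sense) != 61L || !setequal(tbl$aa[sense], AA_STANDARD)) {
    sav_error("savshift_error_config",
              "codon table must map 61 sense codons onto the 20 amino acids")
  }
  tbl
}

#' Build the SNV reachability relation
#'
#' `reachable[a, b]` is `TRUE` iff there exist sense codons for `a` and `b`
#' differing at exactly one nucleotide position.  Stop codons never
#' participate, and the diagonal is `FALSE` (a substitution requires
#' `a != b`).  The relation is symmetric by construction.
#'
#' @param codon_table a codon table as returned by [read_codon_table()].
#' @return a 20x20 logical matrix of class `snv_reachability`, rows and
#'   columns named by amino acid.
#' @export
snv_reachability <- function(codon_table = read_codon_table()) {
  sense <- codon_table[codon_table$aa != "*", ]
  reach <- matrix(FALSE, 20L, 20L, dimnames = list(AA_STANDARD, AA_STANDARD))
  codons <- strsplit(sense$codon, "", fixed = TRUE)
  aa_of <- stats::setNames(sense$aa, sense$codon)
  nucl <- c("A", "C", "G", "T")
  for (k in seq_len(nrow(sense))) {
    from <- sense$aa[k]
    cod <- codons[[k]]
    for (pos in 1:3) {
      for (nt in setdiff(nucl, cod[pos])) {
        neighbor <- cod
        neighbor[pos] <- nt
        to <- aa_of[paste(neighbor, collapse = "")]
        if (!is.na(to) && to != from) {
          reach[from, to] <- TRUE
        }
      }
    }
  }
  structure(reach, class = c("snv_reachability", "matrix", "array"))
}

#' @export
print.snv_reachability <- function(x, ...) {
  cat("SNV reachability over the 20 amino acids:",
      sum(unclass(x)), "of 380 ordered pairs reachable\n")
  invisible(x)
}

#' Enumerate candidate SAVs of a protein
#'
#' Mode `all19` yields, for every unmasked position with residue r, the 19
#' substitutions r -> x (x != r); mode `snv_possible` restricts to the
#' substitutions reachable by a single nucleotide change.  Output order is
#' deterministic: position-major, alphabetical alternate residue.
#'
#' @param proteome named character vector or AAStringSet.
#' @param mode `"all19"` or `"snv_possible"`.
#' @param reach an [snv_reachability()] relation; built from the standard
#'   code when `NULL` and `mode = "snv_possible"`.
#' @return a SAV table with `set_label` set to the mode.
#' @export
enumerate_candidate_savs <- function(proteome,
                                     mode = c("all19", "snv_possible"),
                                     reach = NULL) {
  mode <- match.arg(mode)
  proteome <- as_proteome(proteome)
  if (mode == "snv_possible" && is.null(reach)) {
    reach <- snv_reachability()
  }
  per_protein <- lapply(names(proteome), function(id) {
    chars <- strsplit(proteome[[id]], "", fixed = TRUE)[[1]]
    keep <- chars %in% AA_STANDARD
    pos <- which(keep)
    if (!length(pos)) {
      return(NULL)
    }
    ref <- chars[pos]
    # position-major, alphabetical alt (AA_STANDARD is sorted)
    df <- data.frame(
      protein_id = id,
      position = rep(pos, each = 20L),
      ref_aa = rep(ref, each = 20L),
      alt_aa = rep(AA_STANDARD, times = length(pos)),
      stringsAsFactors = FALSE
    )
    df <- df[df$ref_aa != df$alt_aa, , drop = FALSE]
    if (mode == "snv_possible") {
      df <- df[unclass(reach)[cbind(df$ref_aa, df$alt_aa)], , drop = FALSE]
    }
    df
  })
  per_protein <- per_protein[!vapply(per_protein, is.null, logical(1))]
  if (!length(per_protein)) {
    return(sav_table(character(), integer(), character(), character(),
                     numeric(), character()))
  }
  out <- do.call(rbind, per_protein)
  rownames(out) <- NULL
  sav_table(out$protein_id, out$position, out$ref_aa, out$alt_aa,
            ldaf = NA_real_, set_label = mode)
}

#' Sample a random SAV background
#'
#' Draws `n` distinct SAVs uniformly without replacement from the pooled
#' candidate set of all proteins (so long proteins contribute
#' proportionally more candidates).  Identical arguments reproduce the
#' identical set.
#'
#' @inheritParams enumerate_candidate_savs
#' @param n sample size (>= 0).
#' @param seed integer seed for the draw.
#' @return a SAV table of `n` rows with `set_label` `"random_<mode>"`.
#' @export
sample_random_savs <- function(proteome, mode = c("all19", "snv_possible"),
                               n, seed, reach = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), n >= 0)
  pool <- enumerate_candidate_savs(proteome, mode, reach)
  if (n > nrow(pool)) {
    sav_error("savshift_error_insufficient_pool",
              sprintf("requested %d SAVs from a pool of %d candidates",
                      n, nrow(pool)))
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out$set_label <- rep_len(paste0("random_", mode), nrow(out))
  out
}
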