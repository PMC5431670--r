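# Domain model: proteomes, SAV tables, allele-frequency classes, and the
# missense/SNV filter for annotated VCF input.

#' Read a proteome from FASTA
#'
#' Sequences are returned as a named character vector (id -> amino-acid
#' string).  Non-standard residues (X, B, Z, U, ...) are tolerated at load;
#' use [masked_positions()] to find them.  Positions carrying such letters
#' are excluded from SAV enumeration and validation.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_proteome(seqs)
}

#' Write a proteome to FASTA
#'
#' @param proteome named character vector or AAStringSet.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  proteome <- as_proteome(proteome)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Masked positions of a protein sequence
#'
#' Positions whose residue is not one of the 20 standard amino acids.
#' No SAV may be enumerated, extracted or validated at a masked position.
#'
#' @param sequence a single amino-acid string.
#' @return integer vector of 1-based masked positions (possibly empty).
#' @export
masked_positions <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  which(!chars %in% AA_STANDARD)
}

#' Classify allele frequencies into rare / uncommon / common
#'
#' The three classes partition \[0,1\]: rare is LDAF < 1%, uncommon is
#' 1% <= LDAF < 5%, and common is LDAF >= 5% (the 5% boundary belongs to
#' common).  Missing frequencies are an error rather than a default class,
#' because cross-species, random and disease sets legitimately carry no
#' frequency and must never be silently classified.
#'
#' @param ldaf numeric vector of allele frequencies in \[0,1\].
#' @return factor with levels `rare`, `uncommon`, `common`.
#' @export
classify_frequency <- function(ldaf) {
  if (length(ldaf) == 0L) {
    return(factor(character(), levels = c("rare", "uncommon", "common")))
  }
  if (!is.numeric(ldaf) || anyNA(ldaf)) {
    sav_error("savshift_error_missing_frequency",
              "allele frequency is missing; refusing to classify")
  }
  if (any(ldaf < 0 | ldaf > 1)) {
    sav_error("savshift_error_invalid_frequency",
              sprintf("allele frequency outside [0,1]: %s",
                      paste(ldaf[ldaf < 0 | ldaf > 1][1], collapse = ", ")))
  }
  cls <- ifelse(ldaf < 0.01, "rare", ifelse(ldaf < 0.05, "uncommon", "common"))
  factor(cls, levels = c("rare", "uncommon", "common"))
}

#' Construct a SAV table
#'
#' The canonical in-memory representation of a variant set: one row per
#' single amino acid variant, columns `protein_id`, `position` (1-based),
#' `ref_aa`, `alt_aa`, `ldaf` (NA allowed) and `set_label`.
#'
#' @param protein_id,position,ref_aa,alt_aa,ldaf,set_label column vectors,
#'   recycled to a common length.
#' @return a `data.frame` with the six canonical columns.
#' @export
sav_table <- function(protein_id, position, ref_aa, alt_aa,
                      ldaf = NA_real_, set_label = NA_character_) {
  n <- max(length(protein_id), length(position))
  df <- data.frame(
    protein_id = rep_len(as.character(protein_id), n),
    position = rep_len(as.integer(position), n),
    ref_aa = rep_len(toupper(as.character(ref_aa)), n),
    alt_aa = rep_len(toupper(as.character(alt_aa)), n),
    ldaf = rep_len(as.numeric(ldaf), n),
    set_label = rep_len(as.character(set_label), n),
    stringsAsFactors = FALSE
  )
  bad <- df$ref_aa == df$alt_aa
  if (any(bad)) {
    sav_error("savshift_error_invalid_sav",
              sprintf("ref_aa equals alt_aa for %d SAV(s), first at row %d",
                      sum(bad), which(bad)[1]))
  }
  df
}

#' SAV text notation
#'
#' `<ref><position><alt>`, e.g. `"V42L"` for a valine-to-leucine change at
#' position 42 (1-based).
#'
#' @param savs a SAV table.
#' @return character vector of notations, one per row.
#' @export
#' @examples
#' sav_notation(sav_table("P1", 42, "V", "L"))
sav_notation <- function(savs) {
  paste0(savs$ref_aa, savs$position, savs$alt_aa)
}

#' Parse SAV text notation
#'
#' @param x character vector of `<ref><position><alt>` strings.
#' @param protein_id,set_label metadata attached to the parsed rows.
#' @return a SAV table.
#' @export
parse_sav_notation <- function(x, protein_id = NA_character_,
                               set_label = NA_character_) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  ok <- lengths(m) == 4L
  if (!all(ok)) {
    sav_error("savshift_error_parse",
              sprintf("malformed SAV notation: '%s'", x[!ok][1]))
  }
  parts <- do.call(rbind, m)
  sav_table(protein_id = protein_id, position = as.integer(parts[, 3]),
            ref_aa = parts[, 2], alt_aa = parts[, 4], set_label = set_label)
}

#' Read / write a SAV table
#'
#' Tab-separated, header row, columns `protein_id`, `position`, `ref_aa`,
#' `alt_aa`, `ldaf`, `set_label`; a missing allele frequency is written as
#' `"."`.  The round trip is lossless.
#'
#' @param path file path.
#' @return `read_sav_table` returns the SAV table; `write_sav_table`
#'   returns `path` invisibly.
#' @export
read_sav_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "ldaf", "set_label")
  if (!all(need %in% names(df))) {
    sav_error("savshift_error_parse",
              sprintf("SAV table %s lacks column(s): %s", path,
                      paste(setdiff(need, names(df)), collapse = ", ")))
  }
  ldaf <- suppressWarnings(as.numeric(ifelse(df$ldaf == ".", NA, df$ldaf)))
  sav_table(df$protein_id, as.integer(df$position), df$ref_aa, df$alt_aa,
            ldaf, df$set_label)
}

#' @rdname read_sav_table
#' @param savs a SAV table.
#' @export
write_sav_table <- function(savs, path) {
  out <- savs[c("protein_id", "position", "ref_aa", "alt_aa", "ldaf",
                "set_label")]
  out$ldaf <- ifelse(is.na(out$ldaf), ".",
                     format(out$ldaf, digits = 17, trim = TRUE,
                            scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table
#'
#' Tab-separated with columns `protein_id`, `position`, `ref_aa`, `alt_aa`,
#' `method`, `score`.
#'
#' @param path file path.
#' @return data.frame of per-method scores.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "method", "score")
  if (!all(need %in% names(df))) {
    sav_error("savshift_error_parse",
              sprintf("score table %s lacks column(s): %s", path,
                      paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$score <- as.numeric(df$score)
  df
}

#' Validate a SAV table against a proteome
#'
#' Checks that every variant references a known protein, lies within its
#' length, differs from the reference residue, matches the sequence at its
#' position, and does not sit on a masked (non-standard-residue) position.
#'
#' @param savs a SAV table.
#' @param proteome named character vector or AAStringSet.
#' @return `savs`, invisibly, when everything checks out.
#' @export
validate_savs <- function(savs, proteome) {
  proteome <- as_proteome(proteome)
  unknown <- setdiff(unique(savs$protein_id), names(proteome))
  if (length(unknown)) {
    sav_error("savshift_error_invalid_sav",
              sprintf("unknown protein id(s): %s",
                      paste(utils::head(unknown, 3), collapse = ", ")))
  }
  len <- nchar(proteome)[savs$protein_id]
  bad <- savs$position < 1L | savs$position > len
  if (any(bad)) {
    i <- which(bad)[1]
    sav_error("savshift_error_invalid_sav",
              sprintf("position %d outside protein %s (length %d)",
                      savs$position[i], savs$protein_id[i], len[i]))
  }
  at <- substr(proteome[savs$protein_id], savs$position, savs$position)
  masked <- !at %in% AA_STANDARD
  if (any(masked)) {
    i <- which(masked)[1]
    sav_error("savshift_error_masked_position",
              sprintf("SAV %s on %s sits on a masked residue '%s'",
                      sav_notation(savs)[i], savs$protein_id[i], at[i]))
  }
  mismatch <- at != savs$ref_aa
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    sav_error("savshift_error_invalid_sav",
              sprintf("SAV %s on %s: sequence carries '%s' at position %d",
                      sav_notation(savs)[i], savs$protein_id[i], at[i],
                      savs$position[i]))
  }
  invisible(savs)
}

#' Collapse duplicate SAVs
#'
#' Analyses count unique SAVs, not per-person observations: duplicates of
#' the same (protein, position, ref, alt) within one set are collapsed to a
#' single record (first occurrence wins).
#'
#' @param savs a SAV table.
#' @return the de-duplicated table; attribute `n_collapsed` records how
#'   many rows were dropped.
#' @export
collapse_duplicate_savs <- function(savs) {
  key <- paste(savs$set_label, savs$protein_id, savs$position,
               savs$ref_aa, savs$alt_aa, sep = "\r")
  keep <- !duplicated(key)
  out <- savs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- sum(!keep)
  out
}

#' Drop proteins longer than a maximum length
#'
#' Some predictors cannot score very long proteins; the conventional cut is
#' 6,000 residues.  A protein of exactly `max_len` residues is retained.
#'
#' @param proteome named character vector or AAStringSet.
#' @param max_len maximum length kept (default 6000).
#' @return the filtered proteome; attribute `n_removed` reports the count
#'   of dropped proteins.
#' @export
filter_protein_length <- function(proteome, max_len = 6000L) {
  stopifnot(is.numeric(max_len), max_len >= 1)
  proteome <- as_proteome(proteome)
  keep <- nchar(proteome) <= max_len
  out <- proteome[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract missense SNVs from an annotated VCF
#'
#' Keeps exactly the records whose consequence annotation contains
#' `missense_variant` and whose variant type is a single-nucleotide
#' substitution, and converts them to SAVs using the protein coordinates
#' carried by the annotation.  Input order is preserved; all other records
#' are dropped.  Records lacking the consequence INFO field are skipped
#' with a warning and counted in the `rejects` attribute.
#'
#' The consequence field follows the VEP CSQ convention: transcript blocks
#' separated by `,`, pipe-separated fields within a block (field names from
#' the VCF header), consequence terms within a block separated by `&`.
#' When several transcript blocks are present, any block containing
#' `missense_variant` is accepted; variant type comes from a
#' `VARIANT_CLASS` field when the annotation provides one and from the
#' REF/ALT alleles otherwise.
#'
#' @param vcf path to a VCF file, or a `vcfR::vcfR` object.
#' @param csq_key name of the INFO field holding the consequence
#'   annotation (default `"CSQ"`).
#' @param protein_field,position_field,aa_field CSQ sub-field names for the
#'   protein id, 1-based protein position, and `ref/alt` amino-acid pair.
#' @param set_label label stamped on the returned SAVs.
#' @return a SAV table; attribute `rejects` counts records skipped for a
#'   missing consequence field.
#' @export
filter_missense_snv <- function(vcf, csq_key = "CSQ",
                                protein_field = c("ENSP", "Feature",
                                                  "Protein"),
                                position_field = "Protein_position",
                                aa_field = "Amino_acids",
                                set_label = "missense_snv") {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  fix <- vcfR::getFIX(vcf)
  empty <- sav_table(character(), integer(), character(),
                     character(), numeric(), character())
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    attr(empty, "rejects") <- 0L
    return(empty)
  }
  fmt <- csq_format_fields(vcf@meta, csq_key)
  csq <- vcfR::extract.info(vcf, element = csq_key)

  n_reject <- 0L
  rows <- vector("list", length(csq))
  for (i in seq_along(csq)) {
    if (is.na(csq[[i]])) {
      warning(sprintf("record %d (%s:%s) has no %s field; skipped",
                      i, fix[i, "CHROM"], fix[i, "POS"], csq_key),
              call. = FALSE)
      n_reject <- n_reject + 1L
      next
    }
    blocks <- strsplit(strsplit(csq[[i]], ",", fixed = TRUE)[[1]],
                       "|", fixed = TRUE)
    hit <- NULL
    for (b in blocks) {
      terms <- strsplit(field_of(b, fmt, "Consequence"), "&", fixed = TRUE)[[1]]
      if ("missense_variant" %in% terms) {
        hit <- b
        break
      }
    }
    if (is.null(hit)) next
    if (!is_snv_record(fix[i, "REF"], fix[i, "ALT"], blocks[[1]], fmt)) next
    pid <- NA_character_
    for (pf in protein_field) {
      if (pf %in% fmt) {
        pid <- field_of(hit, fmt, pf)
        break
      }
    }
    pos <- suppressWarnings(as.integer(field_of(hit, fmt, position_field)))
    aa <- strsplit(field_of(hit, fmt, aa_field), "/", fixed = TRUE)[[1]]
    if (is.na(pid) || is.na(pos) || length(aa) != 2L) next
    rows[[i]] <- sav_table(pid, pos, aa[1], aa[2], set_label = set_label)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "rejects") <- n_reject
  out
}

# Field names of the CSQ-style annotation, parsed from the VCF meta header
# ("... Format: Allele|Consequence|...").
csq_format_fields <- function(meta, csq_key) {
  line <- grep(sprintf("ID=%s[,>]", csq_key), meta, value = TRUE)
  if (!length(line)) {
    sav_error("savshift_error_parse",
              sprintf("VCF header does not describe INFO field '%s'", csq_key))
  }
  m <- regmatches(line[1], regexpr("Format: [^\"]+", line[1]))
  if (!length(m)) {
    sav_error("savshift_error_parse",
              sprintf("INFO field '%s' has no Format description", csq_key))
  }
  strsplit(sub("^Format: ", "", m), "|", fixed = TRUE)[[1]]
}

field_of <- function(block, fmt, name) {
  idx <- match(name, fmt)
  if (is.na(idx) || idx > length(block)) {
    return(NA_character_)
  }
  block[idx]
}

is_snv_record <- function(ref, alt, block, fmt) {
  vc <- field_of(block, fmt, "VARIANT_CLASS")
  if (!is.na(vc)) {
    return(identical(vc, "SNV"))
  }
  nucl <- c("A", "C", "G", "T")
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  nchar(ref) == 1L && ref %in% nucl && length(alts) == 1L &&
    nchar(alts) == 1L && alts %in% nucl
}
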