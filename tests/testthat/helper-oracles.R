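# Independent brute-force oracles, deliberately naive: each recomputes a
# quantity by a route that shares no code with the package.

# Two-sample KS statistic by a double loop over all pooled evaluation
# points.
oracle_ks_D <- function(a, b) {
  best <- 0
  for (t in c(a, b)) {
    d <- abs(mean(a <= t) - mean(b <= t))
    if (d > best) best <- d
  }
  best
}

# Score one explicit global alignment (columns of two equal-length
# character vectors over residues and "-") under affine gap costs
# open + (k - 1) * ext per gap run, with end runs free unless end_gaps.
oracle_score_columns <- function(ca, cb, mat, open = 10, ext = 0.5,
                                 end_gaps = FALSE) {
  stopifnot(length(ca) == length(cb))
  n <- length(ca)
  pair <- ca != "-" & cb != "-"
  s <- if (any(pair)) sum(mat[cbind(ca[pair], cb[pair])]) else 0
  gap_cost <- function(gapped) {
    cost <- 0
    r <- rle(gapped)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (!end_gaps && (starts[k] == 1 || ends[k] == n)) next
      cost <- cost + open + (r$lengths[k] - 1) * ext
    }
    cost
  }
  s - gap_cost(ca == "-") - gap_cost(cb == "-")
}

# Optimal global alignment score by exhaustive enumeration of every
# possible alignment (practical for sequence lengths <= 6).
oracle_align_score <- function(a, b, mat, open = 10, ext = 0.5,
                               end_gaps = FALSE) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca)
  nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, cols_a, cols_b) {
    if (i == na && j == nb) {
      s <- oracle_score_columns(cols_a, cols_b, mat, open, ext, end_gaps)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i < na && j < nb) rec(i + 1, j + 1, c(cols_a, ca[i + 1]),
                              c(cols_b, cb[j + 1]))
    if (i < na) rec(i + 1, j, c(cols_a, ca[i + 1]), c(cols_b, "-"))
    if (j < nb) rec(i, j + 1, c(cols_a, "-"), c(cols_b, cb[j + 1]))
  }
  rec(0L, 0L, character(), character())
  best
}

# SNV reachability by scanning all sense-codon pairs of a codon table.
oracle_snv_reachability <- function(codon_table) {
  sense <- codon_table[codon_table$aa != "*", ]
  aa <- savshift::AA_STANDARD
  reach <- matrix(FALSE, 20, 20, dimnames = list(aa, aa))
  split_codons <- strsplit(sense$codon, "", fixed = TRUE)
  for (i in seq_len(nrow(sense))) {
    for (j in seq_len(nrow(sense))) {
      if (sense$aa[i] == sense$aa[j]) next
      if (sum(split_codons[[i]] != split_codons[[j]]) == 1L) {
        reach[sense$aa[i], sense$aa[j]] <- TRUE
      }
    }
  }
  reach
}

random_aa_seq <- function(len) {
  paste(sample(savshift::AA_STANDARD, len, replace = TRUE), collapse = "")
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})
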