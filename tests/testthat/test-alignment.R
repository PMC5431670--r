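# Global affine-gap alignment, identity measures, ortholog selection and
# cross-species SAV extraction.

test_that("identical sequences align gap-free at the matrix self-score", {
  res <- global_align_affine("ACDE", "ACDE")
  expect_equal(res$score, 24)  # BLOSUM62 diagonal: A4 + C9 + D6 + E5
  expect_equal(res$pide_nogap, 1.0)
  expect_equal(res$aligned_a, "ACDE")
  expect_equal(res$aligned_b, "ACDE")

  withr::with_seed(3, {
    for (k in 1:5) {
      a <- random_aa_seq(sample(3:12, 1))
      self <- global_align_affine(a, a)
      expect_equal(self$score,
                   oracle_score_columns(strsplit(a, "")[[1]],
                                        strsplit(a, "")[[1]], blosum62))
      expect_equal(self$pide_nogap, 1.0)
    }
  })
})

test_that("a one-residue deletion costs one single-column gap", {
  res <- global_align_affine("ACDE", "ACE")
  expect_equal(res$score,
               oracle_align_score("ACDE", "ACE", blosum62))
  # exactly one gap column, in the shorter row
  expect_equal(lengths(regmatches(res$aligned_b,
                                  gregexpr("-", res$aligned_b))), 1L)
  expect_false(grepl("-", res$aligned_a))
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  withr::with_seed(17, {
    for (k in 1:40) {
      a <- random_aa_seq(sample(1:6, 1))
      b <- random_aa_seq(sample(1:6, 1))
      end_gaps <- k %% 4 == 0
      params <- alignment_params(end_gaps = end_gaps)
      res <- global_align_affine(a, b, params)
      expect_equal(res$score,
                   oracle_align_score(a, b, blosum62, end_gaps = end_gaps),
                   info = sprintf("%s vs %s (end_gaps=%s)", a, b, end_gaps))
      # the reported score is also the score of the returned alignment
      expect_equal(res$score,
                   oracle_score_columns(strsplit(res$aligned_a, "")[[1]],
                                        strsplit(res$aligned_b, "")[[1]],
                                        blosum62, end_gaps = end_gaps))
    }
  })
})

test_that("aligned strings recover the inputs and never stack two gaps", {
  withr::with_seed(23, {
    for (k in 1:20) {
      a <- random_aa_seq(sample(2:40, 1))
      b <- random_aa_seq(sample(2:40, 1))
      res <- global_align_affine(a, b)
      expect_equal(gsub("-", "", res$aligned_a), a)
      expect_equal(gsub("-", "", res$aligned_b), b)
      ca <- strsplit(res$aligned_a, "")[[1]]
      cb <- strsplit(res$aligned_b, "")[[1]]
      expect_false(any(ca == "-" & cb == "-"))
    }
  })
})

test_that("non-standard residues abort alignment with the position named", {
  expect_error(global_align_affine("ACXE", "ACDE"),
               regexp = "position 3", class = "savshift_error_alignment")
  expect_error(global_align_affine("", "ACDE"),
               class = "savshift_error_alignment")
})

as_alignment <- function(a, b) {
  structure(list(aligned_a = a, aligned_b = b), class = "alignment_result")
}

test_that("identity measures use gap-free columns and shorter-sequence length", {
  m <- pide_measures(as_alignment("AC-E", "ACDE"))
  expect_equal(m[["pide_nogap"]], 1.0)
  m <- pide_measures(as_alignment("ACDE", "ACDD"))
  expect_equal(m[["pide_nogap"]], 3 / 4)
  m <- pide_measures(as_alignment("A---", "AAAA"))
  expect_equal(m[["pide_nogap"]], 1.0)
  expect_equal(m[["ungapped_identity"]], 1.0)
  expect_error(pide_measures(as_alignment("A--", "-AA")),
               class = "savshift_error_alignment")
})

test_that("best ortholog is the highest ungapped identity, ties by id", {
  human <- c(H = "MKTAYIAKQRQISFVKSHFSRQ")
  mutate_at <- function(s, pos, aa) {
    for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- aa[k]
    s
  }
  cands <- c(b_far = mutate_at(human[[1]], c(2, 5, 9), c("W", "W", "W")),
             a_near = mutate_at(human[[1]], 2, "W"))
  best <- select_best_ortholog(human, cands)
  expect_equal(best$id, "a_near")

  # exact tie on identity: lexicographically smaller id wins
  tie <- c(zeta = cands[["a_near"]], alpha = cands[["a_near"]])
  expect_equal(select_best_ortholog(human, tie)$id, "alpha")

  # nothing passes the identity filter
  junk <- c(x = strrep("W", 22))
  err <- expect_error(select_best_ortholog(human, junk),
                      class = "savshift_error_no_ortholog")
  expect_true(is.numeric(err$pide))
})

test_that("cross-species extraction emits back-mutated SAVs in human coordinates", {
  # the worked example: human L at position 42, ortholog V there -> V42L
  human <- c(Xp = paste0(strrep("A", 41), "L", strrep("G", 8)))
  orth <- c(Xo = paste0(strrep("A", 41), "V", strrep("G", 8)))
  savs <- extract_cross_species_savs(human, orth)
  expect_equal(nrow(savs), 1L)
  expect_equal(sav_notation(savs), "V42L")
  expect_equal(savs$position, 42L)
  # context is the human sequence with V introduced at 42...
  expect_equal(substr(savs$context, 42, 42), "V")
  # ...and applying the alternate residue reproduces the human sequence
  ctx <- savs$context
  substr(ctx, savs$position, savs$position) <- savs$alt_aa
  expect_equal(ctx, unname(human))
})

test_that("identical orthologs yield no SAVs; low identity is rejected", {
  human <- c(H = "MKTAYIAKQR")
  expect_equal(nrow(extract_cross_species_savs(human, c(O = human[[1]]))), 0L)

  diverged <- c(O = paste0("MKT", strrep("W", 7)))
  err <- expect_error(extract_cross_species_savs(human, diverged),
                      class = "savshift_error_low_pide")
  expect_lt(err$pide, 0.70)
})

test_that("extraction count equals mismatching gap-free columns and round-trips", {
  withr::with_seed(31, {
    for (k in 1:10) {
      h <- random_aa_seq(60)
      o <- generate_ortholog_pair(h, 0.08, seed = k)
      savs <- extract_cross_species_savs(c(H = h), c(O = as.character(o)))
      # independent count: positionwise string comparison (no indels here)
      hs <- strsplit(h, "")[[1]]
      os <- strsplit(as.character(o), "")[[1]]
      expect_equal(nrow(savs), sum(hs != os))
      if (nrow(savs)) {
        ctx <- savs$context
        for (i in seq_len(nrow(savs))) {
          substr(ctx[i], savs$position[i], savs$position[i]) <- savs$alt_aa[i]
        }
        expect_true(all(ctx == h))
      }
    }
  })
})

test_that("extracted SAV counts increase with divergence rate", {
  withr::with_seed(41, {
    seqs <- vapply(1:6, function(i) random_aa_seq(150), character(1))
  })
  mean_count <- function(rate) {
    mean(vapply(seq_along(seqs), function(i) {
      o <- generate_ortholog_pair(seqs[i], rate, seed = 100 + i)
      nrow(extract_cross_species_savs(c(H = seqs[i]), c(O = as.character(o))))
    }, numeric(1)))
  }
  counts <- vapply(c(0.01, 0.05, 0.10), mean_count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("housekeeping subset keeps only proteins shared with SAVs everywhere", {
  mk <- function(ids) sav_table(ids, 1L, "A", "G", set_label = "x")
  per_species <- list(chimp = mk(c("P1", "P2")),
                      mouse = mk(c("P1", "P3")))
  human <- mk(c("P1", "P2", "P3"))
  out <- housekeeping_subset(per_species, human)
  expect_equal(attr(out, "shared_proteins"), "P1")
  expect_equal(unique(out$per_species$chimp$protein_id), "P1")
  expect_equal(unique(out$within_human$protein_id), "P1")
  # P2 is present in chimp and human but absent (zero SAVs) in mouse
  expect_false("P2" %in% out$per_species$chimp$protein_id)
})
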