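test_that("identity and near-identity alignments behave as expected", {
  aln <- align_global("ACDEFG", "ACDEFG")
  expect_equal(aln$gapped_a, "ACDEFG")
  expect_equal(aln$gapped_b, "ACDEFG")
  expect_equal(sum(!is.na(aln$columns$a_pos) & !is.na(aln$columns$b_pos)), 6)

  mm <- align_global("ACDEFG", "ACDKFG")
  expect_equal(mm$gapped_a, "ACDEFG")  # no gaps
  pid <- percent_identity(mm)
  expect_equal(pid$identities, 5)
  # 5/6 under every denominator
  all4 <- percent_identity(mm, c("aligned_columns", "alignment_length",
                                 "shorter_sequence", "mean_length"))
  expect_equal(all4$pid, rep(500 / 6, 4))

  # truncated partner gets terminal gaps
  tr <- align_global("ACDEFG", "ACD")
  expect_equal(tr$gapped_b, "ACD---")

  expect_error(align_global("AC1DE", "ACD"), "alphabet")
  expect_error(align_global("", "ACD"), "non-empty")
  expect_error(align_global("ACD", "ACD", gap_open = 1, gap_extend = 2),
               "gap_open")
})

test_that("alignment scores are optimal against exhaustive enumeration", {
  withr::with_seed(11, {
    for (rep in 1:15) {
      a <- random_protein(sample(2:6, 1))
      b <- random_protein(sample(2:6, 1))
      aln <- align_global(a, b)
      expect_equal(aln$score,
                   oracle_align_score(a, b, blosum62_20, 11, 1),
                   info = paste(a, b))
    }
  })
})

test_that("alignment columns reconstruct the inputs and never pair two gaps", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      a <- random_protein(sample(3:25, 1))
      b <- random_protein(sample(3:25, 1))
      aln <- align_global(a, b)
      expect_equal(gsub("-", "", aln$gapped_a), a)
      expect_equal(gsub("-", "", aln$gapped_b), b)
      expect_false(any(is.na(aln$columns$a_pos) & is.na(aln$columns$b_pos)))
      # every residue appears exactly once, in order
      expect_equal(aln$columns$a_pos[!is.na(aln$columns$a_pos)], seq_len(nchar(a)))
      expect_equal(aln$columns$b_pos[!is.na(aln$columns$b_pos)], seq_len(nchar(b)))
    }
  })
})

test_that("percent identity denominators are ordered as expected", {
  # aligned_columns >= alignment_length always; equal iff gap-free
  withr::with_seed(5, {
    for (rep in 1:10) {
      a <- random_protein(sample(4:20, 1))
      b <- random_protein(sample(4:20, 1))
      aln <- align_global(a, b)
      p <- percent_identity(aln, c("aligned_columns", "alignment_length"))
      expect_gte(p$pid[1], p$pid[2])
      gap_free <- !grepl("-", paste0(aln$gapped_a, aln$gapped_b))
      if (gap_free) {
        expect_equal(p$pid[1], p$pid[2])
      } else if (p$identities[1] > 0) {
        expect_gt(p$pid[1], p$pid[2])
      }
    }
  })

  # length-discordant pair: aligned-region PID is 100, full-length PID 50
  tr <- align_global("ACDEFG", "ACD")
  p <- percent_identity(tr, c("aligned_columns", "alignment_length"))
  expect_equal(p$pid, c(100, 50))

  ident <- align_global("MKV", "MKV")
  expect_equal(percent_identity(ident, "mean_length")$pid, 100)
})

test_that("aligned-region classification reads off the column pairing", {
  # a: ACDE aligned to b: ACE -> D sits opposite a gap
  aln <- align_global("ACDE", "ACE")
  paired <- in_aligned_region(aln, 1:4)
  expect_equal(sum(paired), 3)

  # manual alignment: a = AC-DE, b = ACXD- (human pos 4 opposite terminal gap)
  manual <- structure(
    list(
      gapped_a = "AC-DE", gapped_b = "ACHD-",
      score = 0, a = "ACDE", b = "ACHD",
      columns = tibble::tibble(a_pos = c(1L, 2L, NA, 3L, 4L),
                               b_pos = c(1L, 2L, 3L, 4L, NA))
    ),
    class = "protein_alignment"
  )
  expect_equal(in_aligned_region(manual, 1:4), c(TRUE, TRUE, TRUE, FALSE))
  # span definition counts everything between first and last paired column
  expect_equal(in_aligned_region(manual, 1:4, region = "span"),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_error(in_aligned_region(manual, 5), "Positions")

  # symmetry: swapping which protein is 'a' remaps but preserves the calls
  swapped <- structure(
    list(gapped_a = manual$gapped_b, gapped_b = manual$gapped_a,
         score = 0, a = manual$b, b = manual$a,
         columns = tibble::tibble(a_pos = manual$columns$b_pos,
                                  b_pos = manual$columns$a_pos)),
    class = "protein_alignment"
  )
  paired_cols <- !is.na(manual$columns$a_pos) & !is.na(manual$columns$b_pos)
  for (col in which(paired_cols)) {
    expect_equal(
      in_aligned_region(manual, manual$columns$a_pos[col]),
      in_aligned_region(swapped, swapped$columns$a_pos[col])
    )
  }
})

test_that("PID histograms bin by complementation class", {
  pairs <- tibble::tibble(pid = rep(10, 7), complements = rep(TRUE, 7))
  h <- pid_histogram(pairs, bin_width = 10)
  expect_equal(h$count[h$complements & h$bin_lo == 10], 7)
  expect_equal(sum(h$count), 7)

  empty <- pid_histogram(tibble::tibble(pid = numeric(), complements = logical()))
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 20)  # 10 bins x 2 classes

  # PID of exactly 100 lands in the top bin
  h100 <- pid_histogram(tibble::tibble(pid = 100, complements = FALSE))
  expect_equal(h100$count[!h100$complements & h100$bin_lo == 90], 1)

  expect_error(pid_histogram(tibble::tibble(pid = 101, complements = TRUE)),
               "\\[0, 100\\]")

  # planted shift moves the complementing histogram upward
  withr::with_seed(2, {
    shifted <- tibble::tibble(
      pid = c(rnorm(100, 25, 8), rnorm(100, 45, 8)),
      complements = rep(c(FALSE, TRUE), each = 100)
    )
    shifted$pid <- pmin(pmax(shifted$pid, 0), 100)
    h <- pid_histogram(shifted)
    mean_of <- function(cls) {
      sub <- h[h$complements == cls, ]
      sum((sub$bin_lo + 5) * sub$count) / sum(sub$count)
    }
    expect_gt(mean_of(TRUE), mean_of(FALSE))
  })

  p <- autoplot(pid_histogram(tibble::tibble(pid = c(10, 50),
                                             complements = c(TRUE, FALSE))))
  expect_s3_class(p, "ggplot")
})

test_that("pair-level PID wraps alignment per pair", {
  seqs <- c(H1 = "ACDEFGHIK", Y1 = "ACDEFGHIK", Y2 = "ACD")
  pairs <- tibble::tibble(human_gene = c("H1", "H1"),
                          yeast_gene = c("Y1", "Y2"))
  out <- pair_pid(pairs, seqs)
  expect_equal(out$pid, c(100, 100))
  out2 <- pair_pid(pairs, seqs, method = "alignment_length")
  expect_equal(out2$pid, c(100, 100 * 3 / 9))
  expect_error(pair_pid(pairs, seqs[1:2]), "Y2")
})
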