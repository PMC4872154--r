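test_that("local alignment reproduces the worked examples", {
  sc <- scoring_scheme()
  a <- smith_waterman("ACGTACGTAC", "ACGTACGTAC", sc)
  expect_equal(a$score, 20L) # 10 matches at +2
  expect_equal(a$ops, strrep("=", 10))

  b <- smith_waterman("ACGT", "ACT", sc)
  expect_equal(b$score, 5L) # match, match, deleted G in reference... 2+2-1+2
  expect_equal(sw_score_bruteforce("ACGT", "ACT"), 5)

  c0 <- smith_waterman("AAAA", "TTTT", sc)
  expect_equal(c0$score, 0L) # best local alignment is empty
  expect_equal(c0$ops, "")
  expect_equal(sw_score_bruteforce("AAAA", "TTTT"), 0)

  expect_equal(smith_waterman("", "ACGT", sc)$score, 0L)
  expect_error(smith_waterman("ACGT", "ACNT", sc), "A/C/G/T")
})

test_that("alignment score equals the independent oracle on random pairs", {
  set.seed(20)
  sc <- scoring_scheme()
  for (k in seq_len(500)) {
    read <- random_dna(sample(1:8, 1))
    ref <- random_dna(sample(1:8, 1))
    expect_identical(smith_waterman(read, ref, sc)$score,
                     as.integer(sw_score_oracle(read, ref)))
  }
  # the R dynamic program itself agrees with exhaustive substring enumeration
  for (k in seq_len(40)) {
    read <- random_dna(sample(1:6, 1))
    ref <- random_dna(sample(1:6, 1))
    expect_equal(sw_score_oracle(read, ref), sw_score_bruteforce(read, ref))
  }
})

test_that("alignment agrees with an established aligner on longer pairs", {
  set.seed(21)
  sc <- scoring_scheme()
  mat <- matrix(-2L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(mat) <- 2L
  for (k in seq_len(100)) {
    read <- random_dna(sample(5:15, 1))
    ref <- random_dna(45)
    got <- smith_waterman(read, ref, sc)$score
    want <- Biostrings::pairwiseAlignment(read, ref, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 1,
                                          scoreOnly = TRUE)
    expect_equal(got, as.integer(want))
  }
})

test_that("alignment score is symmetric under the symmetric scheme", {
  set.seed(22)
  sc <- scoring_scheme()
  for (k in seq_len(100)) {
    a <- random_dna(sample(2:10, 1))
    b <- random_dna(sample(2:10, 1))
    expect_identical(smith_waterman(a, b, sc)$score,
                     smith_waterman(b, a, sc)$score)
  }
})

test_that("alignment spans and operations are internally consistent", {
  set.seed(23)
  sc <- scoring_scheme()
  for (k in seq_len(60)) {
    read <- random_dna(sample(4:12, 1))
    ref <- random_dna(30)
    al <- smith_waterman(read, ref, sc)
    ops <- strsplit(al$ops, "")[[1]]
    expect_equal(sum(ops %in% c("=", "X", "I")), al$read_end - al$read_start)
    expect_equal(sum(ops %in% c("=", "X", "D")), al$ref_end - al$ref_start)
    # the score recomputed from the operations matches
    resc <- sum(ops == "=") * sc$match + sum(ops == "X") * sc$mismatch +
      sum(ops == "D") * sc$gap_del + sum(ops == "I") * sc$gap_ins
    expect_equal(al$score, resc)
  }
})

test_that("the three QC rules act in order on the constructed read set", {
  refs <- tiny_refs(strrep("ACGT", 5))
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10),
    seq = c("ACG", "CGT",                  # rule 1: shorter than 5
            rep("ACGTACGTAC", 4),          # alignable, multiplicity 4
            rep("AAAAAAAA", 4)),           # multiplicity 4 but unalignable
    field = 1L)
  out <- qc_filter(reads, refs)
  expect_equal(out$report$removed, c(2L, 0L, 4L))
  expect_equal(nrow(out$reads), 4L)
  expect_true(all(out$reads$seq == "ACGTACGTAC"))

  # an isolated A in "AAAAAAAA" scores 2 and chains of A's lose 3 per gap,
  # so the best possible score (2) sits far below the floor of 10
  expect_lt(smith_waterman("AAAAAAAA", strrep("ACGT", 5))$score, 10)

  # idempotence
  again <- qc_filter(out$reads, refs)
  expect_identical(again$reads, out$reads)
  expect_true(all(again$report$removed == 0L))
})

test_that("multiplicity is counted on the post-length-filter set", {
  refs <- tiny_refs(strrep("ACGT", 5))
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:7),
    seq = c(rep("ACGTACGTAC", 3), rep("ACG", 4)),
    field = 1L)
  out <- qc_filter(reads, refs, qc_params(min_multiplicity = 3))
  expect_equal(nrow(out$reads), 3L)
})

test_that("reads are assigned to their best-scoring template", {
  refs <- make_references(seed = 31)
  rd <- simulate_reads(refs, 400, errors = perfect_errors(), seed = 5)
  al <- align_reads(rd, refs)
  expect_true(all(al$template == al$true_template))
  expect_equal(attr(al, "n_ambiguous"), 0L)
  # perfect reads align end to end with no operations other than matches
  expect_true(all(grepl("^=+$", al$ops)))
  expect_true(all(al$ref_start == 0L))
})
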