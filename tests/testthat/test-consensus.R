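align_to <- function(seqs, refs, ...) {
  rd <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                       seq = seqs, field = 1L)
  align_reads(rd, refs, ...)
}

test_that("tallies conserve coverage and majority voting is exact", {
  ref <- "ACGTACGTACGTACGTACGT"
  refs <- tiny_refs(ref)
  # three error-free reads covering the first 10 positions
  al <- align_to(rep(substr(ref, 1, 10), 3), refs)
  cs <- consensus(al, ref)
  expect_equal(cs$identity, 1.0)
  expect_equal(substr(cs$consensus, 1, 10), substr(ref, 1, 10))
  # tally conservation at every position
  tal <- tidy(cs)
  expect_true(all(tal$A + tal$C + tal$G + tal$T + tal$del == tal$coverage))
  expect_equal(sum(tal$coverage > 0), 10L)
})

test_that("per-position majority, reference ties and deletion calls behave", {
  ref <- "ACGTACGTAC"
  refs <- tiny_refs(ref)
  # two reads agree with the reference, one carries A->G at position 4
  seqs <- c("ACGTACGTAC", "ACGTACGTAC", "ACGTGCGTAC")
  cs <- consensus(align_to(seqs, refs), ref)
  expect_equal(cs$call[5], "A")   # majority 2:1 keeps the reference base
  expect_equal(cs$identity, 1.0)

  # tallies {G:2, A:1} at position 4 overturn the reference
  seqs2 <- c("ACGTGCGTAC", "ACGTGCGTAC", "ACGTACGTAC")
  cs2 <- consensus(align_to(seqs2, refs), ref)
  expect_equal(cs2$call[5], "G")
  expect_lt(cs2$identity, 1.0)

  # 1-1 tie falls back to the reference base
  cs3 <- consensus(align_to(c("ACGTGCGTAC", "ACGTACGTAC"), refs), ref)
  expect_equal(cs3$call[5], "A")
  # ...unless ties are strict-lexicographic
  cs4 <- consensus(align_to(c("ACGTGCGTAC", "ACGTACGTAC"), refs), ref,
                   tie = "lexicographic")
  expect_equal(cs4$call[5], "A") # A sorts before G in the fixed symbol order

  # a deletion-majority position is called as a deletion and counts as error
  seqs5 <- c("ACGTCGTAC", "ACGTCGTAC", "ACGTCGTAC", "ACGTACGTAC")
  cs5 <- consensus(align_to(seqs5, refs), ref)
  expect_equal(cs5$call[5], "del")
  expect_lt(cs5$identity, 1.0)
  expect_equal(substr(cs5$consensus, 5, 5), "-")

  expect_error(consensus(align_to(character(), refs), ref), "no alignments")
})

test_that("error profile counts disagreements per covering read", {
  ref <- "ACGTACGTACGTACG"
  refs <- tiny_refs(ref)
  # 10 error-free reads, one with a substitution at position 3 (T->C);
  # position 3 is interior to every read, so masking leaves all 10
  seqs <- c(rep(substr(ref, 1, 12), 9), "ACGCACGTACGT")
  ep <- error_profile(align_to(seqs, refs), ref)
  pp <- tidy(ep)
  expect_equal(pp$sub_rate[4], 0.1)
  expect_equal(pp$n_sub[4], 1)
  expect_true(all(pp$sub_rate[c(3, 5)] == 0))

  # all-identical reads give zero rates
  ep0 <- error_profile(align_to(rep(substr(ref, 1, 12), 5), refs), ref)
  expect_equal(glance(ep0)$sub_rate, 0)
  expect_equal(glance(ep0)$del_rate, 0)
  expect_equal(glance(ep0)$insertion_rate, 0)
})

test_that("generative substitution and deletion rates are recovered", {
  refs <- make_references(seed = 7)
  tm <- refs$templates
  g <- purrr::map_dfr(1:4, function(i) {
    r1 <- tiny_refs(tm$wild_ref[i])
    rd <- simulate_reads(r1, 4000, seed = 300 + i)
    al <- align_reads(dplyr::filter(rd, nchar(seq) >= 5), r1)
    glance(error_profile(al, tm$wild_ref[i]))
  })
  n <- sum(g$aligned_bases)
  expect_gt(n, 1e5)
  half <- 1.96 * sqrt(0.0052 * (1 - 0.0052) / n)
  expect_lt(abs(mean(g$sub_rate) - 0.0052), half)
  # deletions dominate the error budget
  expect_gt(mean(g$del_rate), 3 * mean(g$sub_rate))
  expect_gt(mean(g$del_rate), mean(g$insertion_rate))
})

test_that("error-free subsampling is perfectly accurate at every depth", {
  refs <- make_references(seed = 8)
  rd <- simulate_reads(refs, 600, errors = perfect_errors(), seed = 2)
  al <- align_reads(rd, refs)
  a1 <- dplyr::filter(al, template == refs$templates$template[1])
  curve <- subsample_accuracy(a1, refs$templates$wild_ref[1],
                              depths = c(1, 3, 5), n_reps = 20, seed = 4)
  expect_true(all(tidy(curve)$mean_identity == 1))
})

test_that("consensus accuracy is non-decreasing along odd depths", {
  refs <- make_references(seed = 7)
  tm <- refs$templates
  acc <- purrr::map_dfr(1:4, function(i) {
    r1 <- tiny_refs(tm$wild_ref[i])
    rd <- simulate_reads(r1, 3000, seed = 400 + i)
    al <- align_reads(dplyr::filter(rd, nchar(seq) >= 5), r1)
    tidy(subsample_accuracy(al, tm$wild_ref[i], depths = c(1, 3, 5),
                            n_reps = 40, seed = 5))
  })
  m <- acc |>
    dplyr::group_by(depth) |>
    dplyr::summarise(acc = stats::weighted.mean(mean_identity, n_instances))
  expect_true(all(diff(m$acc) >= -0.002))
  # depth 1 reflects the raw per-base error; depth 5 approaches perfection
  expect_gt(m$acc[1], 0.9)
  expect_gt(m$acc[3], 0.99)
})

test_that("subsampling rejects depths beyond the available coverage", {
  refs <- make_references(seed = 8)
  rd <- simulate_reads(refs, 40, errors = perfect_errors(), seed = 2)
  al <- align_reads(rd, refs)
  a1 <- dplyr::filter(al, template == refs$templates$template[1])
  expect_error(subsample_accuracy(a1, refs$templates$wild_ref[1],
                                  depths = 1000, n_reps = 2, seed = 1),
               "depth exceeds")
})
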