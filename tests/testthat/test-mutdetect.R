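test_that("dual-reference classification applies the literal score rule", {
  refs <- make_references(seed = 13)
  tm <- refs$templates[refs$templates$kind == "point", ][1, ]
  wild <- tm$wild_ref; mut <- tm$mutant_ref
  # a wild substring spanning the variant site
  w <- classify_read(substr(wild, 1, 10), wild, mut)
  expect_equal(w$label, "wild")
  expect_gt(w$score_wild, w$score_mutant)
  # a mutant substring spanning the variant
  m <- classify_read(substr(mut, 1, 10), wild, mut)
  expect_equal(m$label, "mutant")
  # a read from a region identical in both references ties -> mutant
  shared <- substr(wild, 11, 20)
  t1 <- classify_read(shared, wild, mut)
  expect_equal(t1$score_wild, t1$score_mutant)
  expect_equal(t1$label, "mutant")
  # and is dropped under the alternative tie policy
  t2 <- classify_read(shared, wild, mut, tie = "drop")
  expect_true(is.na(t2$label))
})

test_that("mixture frequencies are binomially consistent without errors", {
  refs <- make_references(seed = 13)
  rd <- simulate_reads(refs, 8000, mixture = 0.03, n_fields = 20,
                       errors = perfect_errors(), seed = 3)
  mr <- mixture_frequencies(rd, refs)
  true_frac <- mean(rd$origin == "mutant")
  half <- 2.576 * sqrt(0.03 * 0.97 / mr$n_effective)
  expect_lt(abs(mr$pooled_frequency - true_frac), half + 0.005)
  # per-batch frequencies average back to the pooled value
  bo <- mr$batch_overall
  expect_equal(sum(bo$frequency * bo$n) / sum(bo$n), mr$pooled_frequency,
               tolerance = 1e-12)
  # pure wild with no errors: zero mutant calls on variant-spanning templates
  rd0 <- simulate_reads(refs, 2000, mixture = 0, errors = perfect_errors(),
                        seed = 4)
  mr0 <- mixture_frequencies(rd0, refs)
  pt <- refs$templates$template[refs$templates$kind == "deletion"]
  f0 <- mr0$per_template$frequency[mr0$per_template$template %in% pt]
  expect_true(all(f0 == 0))
})

test_that("sequencing errors inflate the apparent mutant frequency", {
  refs <- make_references(seed = 13)
  rd <- simulate_reads(refs, 20000, mixture = 0, n_fields = 10, seed = 5)
  rd <- qc_filter(rd, refs)$reads
  mr <- mixture_frequencies(rd, refs)
  expect_gt(mr$pooled_frequency, 0)
})

test_that("estimated frequency is monotone in the true mutant fraction", {
  refs <- make_references(seed = 13)
  freqs <- vapply(c(0, 0.03, 1 / 11, 0.5), function(f) {
    rd <- simulate_reads(refs, 12000, mixture = f, n_fields = 10,
                         seed = 700 + round(1000 * f))
    mixture_frequencies(qc_filter(rd, refs)$reads, refs)$pooled_frequency
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
  # upward bias at nonzero error rates under the literal tie rule
  expect_gt(freqs[2], 0.03)
})

test_that("the t statistic matches the closed form and its edge cases", {
  mk <- function(freqs) {
    structure(list(
      per_batch = tibble::tibble(template = "t1",
                                 batch = seq_along(freqs),
                                 n = 100, frequency = freqs),
      batch_overall = tibble::tibble(batch = seq_along(freqs), n = 100,
                                     frequency = freqs)),
      class = "mixture_result")
  }
  st <- significance_test(mk(c(0.10, 0.11, 0.09)), mk(c(0.01, 0.012, 0.008)))
  pooled <- st[st$template == "(pooled)", ]
  # closed form: sp^2 = (2e-4 + 8e-6) / 4, se = sqrt(sp^2 * 2/3)
  t_exp <- (0.1 - 0.01) / sqrt(((2e-4 + 8e-6) / 4) * (2 / 3))
  expect_equal(pooled$t, t_exp, tolerance = 1e-10)
  expect_equal(pooled$df, 4)
  expect_lt(pooled$p, 0.001)

  ident <- significance_test(mk(c(0.1, 0.2, 0.3)), mk(c(0.1, 0.2, 0.3)))
  expect_equal(ident$t[1], 0)
  expect_equal(ident$p[1], 1)

  expect_error(significance_test(mk(0.1), mk(c(0.1, 0.2))), "2 batches")
})

test_that("a generous mutant fraction is detected without errors", {
  refs <- make_references(seed = 13)
  scan <- detection_limit_scan(0.5, refs, n_reads = 4000, n_batches = 20,
                               errors = perfect_errors(), seed = 8)
  expect_true(all(tidy(scan)$significant))
  expect_equal(scan$smallest_detected, 0.5)
})

test_that("power collapses with a tiny read budget and absurd alpha", {
  refs <- make_references(seed = 13)
  scan <- detection_limit_scan(0.03, refs, n_reads = 100, n_batches = 4,
                               alpha = 1e-12, seed = 9)
  expect_true(is.na(scan$smallest_detected))
})
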