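test_that("noiseless step traces are classified exactly", {
  one <- count_steps(c(rep(1000, 50), rep(0, 50)))
  expect_equal(one$n_steps, 1L)
  expect_equal(one$label, "single")
  expect_equal(one$step_frames[[1]], 50L)
  expect_equal(one$step_sizes[[1]], 1000)

  two <- count_steps(c(rep(1000, 30), rep(500, 40), rep(0, 30)))
  expect_equal(two$n_steps, 2L)
  expect_equal(two$label, "aggregated")

  flat <- count_steps(rep(800, 60))
  expect_equal(flat$n_steps, 0L)
  expect_equal(flat$label, "unclassified")

  upward <- count_steps(c(rep(100, 40), rep(700, 40)))
  expect_equal(upward$label, "unclassified")

  expect_error(count_steps(c(1, 2, 3)), "at least 4")
})

test_that("single steps survive moderate noise", {
  set.seed(40)
  lab <- replicate(200, {
    tr <- c(rep(1000, 50), rep(0, 50)) + rnorm(100, 0, 50) # 5% of the step
    count_steps(tr)$label
  })
  expect_gte(mean(lab == "single"), 0.95)
})

test_that("rising noise pushes traces toward unclassified", {
  set.seed(41)
  frac_uncl <- vapply(c(0.05, 0.3, 0.8), function(s) {
    mean(replicate(100, {
      tr <- c(rep(1000, 40), rep(0, 60)) + rnorm(100, 0, 1000 * s)
      count_steps(tr)$label
    }) == "unclassified")
  }, numeric(1))
  expect_true(all(diff(frac_uncl) >= 0))
  expect_gt(frac_uncl[3], frac_uncl[1])
})

test_that("trace extraction follows the movie ground truth", {
  refs <- make_references(seed = 9)
  geom <- test_geometry(64)
  mols <- tibble::tibble(field = 1L, site = 1L, molecule = 1L,
                         x = 30, y = 28, occupancy = 1L,
                         template = "tmpl01", origin = "wild")
  mv <- render_bleach_movie(mols, optics_config(), geom, n_frames = 80,
                            bleach_rate = 0.02, noisefree = TRUE, seed = 50)
  b <- mv$truth$bleach_frame[1]
  tr <- extract_trace(mv, 30, 28)
  if (b <= 80) {
    expect_gt(mean(tr[seq_len(b - 1)]), 100)
    expect_lt(max(abs(tr[b:80])), 1e-6)
  }
  # constant movies give constant traces
  mv0 <- render_bleach_movie(mols, optics_config(), geom, n_frames = 10,
                             bleach_rate = 0, noisefree = TRUE, seed = 51)
  tr0 <- extract_trace(mv0, 30, 28)
  expect_equal(diff(range(tr0)), 0)
  expect_equal(count_steps(as.numeric(tr0))$label, "unclassified")

  # degenerate aperture: a single-pixel trace
  tr1 <- extract_trace(mv0, 30, 28, aperture_radius = 0)
  expect_equal(length(tr1), 10L)
  expect_error(extract_trace(mv0, -5, 10), "outside")
})

test_that("noiseless movies classify occupancy exactly when bleach frames differ", {
  refs <- make_references(seed = 9)
  geom <- test_geometry(96)
  mols <- grid_molecules(refs, nx = 3, ny = 3, spacing = 24, offset = 16)
  mols$occupancy <- rep(c(1L, 2L, 1L), 3)
  mols2 <- mols[rep(seq_len(9), mols$occupancy), ]
  mols2$molecule <- seq_len(nrow(mols2))
  mv <- render_bleach_movie(mols2, optics_config(), geom, n_frames = 300,
                            bleach_rate = 0.02, noisefree = TRUE, seed = 52)
  res <- classify_movie_spots(mv)
  sites <- mols2 |> dplyr::distinct(site, x, y, occupancy)
  idx <- vapply(seq_len(nrow(res)), function(i) {
    which.min((sites$x - res$x[i])^2 + (sites$y - res$y[i])^2)
  }, integer(1))
  truth <- sites$occupancy[idx]
  frames <- split(mv$truth$bleach_frame, mv$truth$site)
  distinct_frames <- vapply(frames, function(f) !anyDuplicated(f) &&
                              all(f <= 300), logical(1))
  ok <- distinct_frames[as.character(sites$site[idx])]
  expect_gt(sum(ok), 0)
  expect_true(all(res$label[ok & truth == 1] == "single"))
  expect_true(all(res$label[ok & truth == 2] == "aggregated"))
})

test_that("composition summaries count and normalize labels", {
  labels <- c(rep("single", 38), rep("aggregated", 36), rep("unclassified", 26))
  cmp <- summarize_composition(tibble::tibble(label = labels))
  expect_equal(cmp$fraction, c(0.38, 0.36, 0.26))
  expect_equal(sum(cmp$fraction), 1)

  all_single <- summarize_composition(tibble::tibble(label = rep("single", 5)))
  expect_equal(all_single$fraction, c(1, 0, 0))
  expect_error(summarize_composition(tibble::tibble(label = character())),
               "no step results")
})

test_that("field composition is recovered from rendered movies", {
  refs <- make_references(seed = 7)
  geom <- field_geometry(fov_um = c(27, 27), pixels = c(256, 256),
                         density = 0.15, frac_single = 0.38,
                         frac_pair = 0.36, frac_cluster = 0.26)
  res <- purrr::map_dfr(1:3, function(k) {
    mols <- place_molecules(refs, geom, seed = 500 + k)
    mv <- render_bleach_movie(mols, optics_config(), geom, n_frames = 150,
                              bleach_rate = 0.025, seed = 600 + k)
    cl <- classify_movie_spots(mv)
    occ <- mols |> dplyr::distinct(site, occupancy)
    cl$truth_single <- mean(occ$occupancy == 1)
    cl
  })
  cmp <- summarize_composition(res)
  rec <- cmp$fraction[cmp$label == "single"]
  expect_lt(abs(rec - mean(res$truth_single)), 0.07)
})
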