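test_that("phase correlation recovers circular shifts exactly", {
  set.seed(30)
  img <- matrix(runif(64 * 64), 64, 64)
  s0 <- estimate_shift_poc(img, img)
  expect_equal(c(s0$dx, s0$dy), c(0, 0))

  moved <- roll_image(img, 3, -2)
  s <- estimate_shift_poc(img, moved)
  expect_equal(c(s$dx, s$dy), c(3, -2))
  # agrees with a direct spatial-domain cross-correlation peak
  o <- xcorr_shift_oracle(img, moved)
  expect_equal(c(o$dx, o$dy), c(3, -2))

  expect_error(estimate_shift_poc(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
  expect_error(estimate_shift_poc(img, matrix(0, 8, 8)), "dimensions")
})

test_that("phase correlation tolerates noise at moderate SNR", {
  set.seed(31)
  hits <- 0L
  for (k in 1:100) {
    img <- matrix(runif(64 * 64), 64, 64)
    moved <- roll_image(img, 3, -2) + matrix(rnorm(64 * 64, 0, 0.1), 64, 64)
    s <- estimate_shift_poc(img, moved)
    hits <- hits + as.integer(s$dx == 3 && s$dy == -2)
  }
  expect_gte(hits, 99L)
})

test_that("stack registration inverts injected drift", {
  refs <- make_references(seed = 9)
  geom <- test_geometry(96)
  mols <- grid_molecules(refs, nx = 4, ny = 4, spacing = 20, offset = 12)
  ev <- simulate_events(mols, refs, flow_protocol(n_cycles = 3),
                        perfect_errors(), seed = 2)
  drift <- data.frame(dx = c(0, 3, 5), dy = c(0, -2, 1))
  stack <- render_cycle_stack(mols, ev, optics_config(), geom, drift = drift,
                              seed = 3)
  reg <- register_stack(stack)
  expect_equal(reg$shifts$dx, drift$dx)
  expect_equal(reg$shifts$dy, drift$dy)
  # after registration the template images are aligned at (0, 0)
  s12 <- estimate_shift_poc(reg$template[[1]], reg$template[[3]])
  expect_equal(c(s12$dx, s12$dy), c(0, 0))

  # single-cycle stacks and zero drift are identities
  one <- render_cycle_stack(mols, ev[ev$cycle == 1, ], optics_config(), geom,
                            drift = data.frame(dx = 0, dy = 0), seed = 4)
  reg1 <- register_stack(one)
  expect_equal(reg1$shifts$dx, 0)
  zero <- render_cycle_stack(mols, ev, optics_config(), geom,
                             drift = data.frame(dx = rep(0, 3), dy = rep(0, 3)),
                             seed = 5)
  expect_true(all(register_stack(zero)$shifts$dx == 0))
})

test_that("pure-noise images yield no spots at the default threshold", {
  set.seed(33)
  fp <- vapply(1:100, function(k) {
    img <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
    nrow(detect_spots(img))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.95)
})

test_that("bright spots are localized to sub-pixel precision", {
  set.seed(34)
  err <- vapply(1:30, function(k) {
    x0 <- runif(1, 20, 40); y0 <- runif(1, 20, 40)
    img <- matrix(rnorm(64 * 64, 0, 5), 64, 64) # noise scale 5
    img <- img + smflow:::with_seed(NULL, {
      m <- matrix(0, 64, 64)
      smflow:::add_spot(m, x0, y0, 100, 1) # amplitude 20x the noise scale
    })
    sp <- detect_spots(img)
    expect_equal(nrow(sp), 1L)
    sqrt((sp$x - x0)^2 + (sp$y - y0)^2)
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("well-separated spots are detected individually", {
  img <- matrix(rnorm(64 * 64, 0, 2), 64, 64)
  img <- smflow:::add_spot(img, 20, 30, 60, 1)
  img <- smflow:::add_spot(img, 30, 30, 60, 1) # 10 px apart
  sp <- detect_spots(img)
  expect_equal(nrow(sp), 2L)
})

test_that("detection is invariant to a constant intensity offset", {
  set.seed(35)
  img <- matrix(rnorm(96 * 96, 0, 3), 96, 96)
  for (p in list(c(20, 20), c(60, 30), c(40, 70))) {
    img <- smflow:::add_spot(img, p[1], p[2], 80, 1)
  }
  s1 <- detect_spots(img)
  s2 <- detect_spots(img + 500)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s1$x, s2$x, tolerance = 1e-6)
  expect_equal(s1$background + 500, s2$background, tolerance = 1e-3)
})

test_that("Gaussian fits recover generative parameters", {
  m <- matrix(0, 48, 48)
  m <- smflow:::add_spot(m, 10.3, 20.7, 50, 1.0) + 5
  ft <- fit_spot(m, c(10, 21))
  expect_true(ft$converged)
  expect_lt(abs(ft$x - 10.3), 0.05)
  expect_lt(abs(ft$y - 20.7), 0.05)
  expect_lt(abs(ft$sigma - 1.0), 0.05)
  expect_lt(abs(ft$background - 5), 0.1)

  # flat region: amplitude collapses toward zero or the fit fails
  flat <- matrix(5, 32, 32)
  ff <- fit_spot(flat, c(15, 15))
  expect_true(!ff$converged || ff$amplitude < 1e-6 || is.na(ff$amplitude))
})

test_that("an unresolved pair inflates the fitted width for the cluster filter", {
  m <- matrix(0, 48, 48)
  m <- smflow:::add_spot(m, 19, 24, 50, 1.0)
  m <- smflow:::add_spot(m, 21, 24, 50, 1.0) # 2 px apart: unresolved
  ft <- fit_spot(m, c(20, 24))
  expect_true(ft$converged)
  expect_gt(ft$sigma, 1.25) # measurably wider than a single emitter
  # and detect_spots drops it once sigma crosses the cluster threshold
  noisy <- m + matrix(rnorm(48 * 48, 0, 1), 48, 48)
  sp <- detect_spots(noisy, max_sigma_factor = 1.2)
  expect_equal(nrow(sp), 0L)
})

test_that("coincidence matching follows the radius and tie rules", {
  anchors <- tibble::tibble(x = c(100, 110), y = c(100, 100))
  # spot 0.5 px from anchor 1 -> matched
  inc <- tibble::tibble(x = 100.5, y = 100, cycle = 1L)
  m <- coincidence_spots(anchors, inc, radius = 1.6)
  expect_equal(nrow(m), 1L)
  expect_equal(m$anchor, 1L)

  # spot 2.0 px from the only anchor -> discarded
  m2 <- coincidence_spots(anchors[1, ], tibble::tibble(x = 102, y = 100),
                          radius = 1.6)
  expect_equal(nrow(m2), 0L)

  # equidistant spot goes to the lower-index anchor, deterministically
  m3 <- coincidence_spots(tibble::tibble(x = c(99, 101), y = c(100, 100)),
                          tibble::tibble(x = 100, y = 100), radius = 1.6)
  expect_equal(m3$anchor, 1L)

  # one anchor accepts at most one spot per cycle; the nearer wins
  m4 <- coincidence_spots(anchors[1, ],
                          tibble::tibble(x = c(100.9, 100.2), y = c(100, 100),
                                         cycle = c(1L, 1L)))
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$x, 100.2)
})
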