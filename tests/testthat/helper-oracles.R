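# Independent oracles and small fixtures used across the test files.

# Local alignment score by an independent R dynamic program (row = reference,
# column = read: transposed relative to the package implementation).
sw_score_oracle <- function(read, ref, match = 2, mismatch = -2,
                            gap_del = -1, gap_ins = -1) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(read, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + s,
                             H[i, j + 1] + gap_del,  # skip a reference base
                             H[i + 1, j] + gap_ins)  # skip a read base
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Truly exhaustive local score for tiny strings: maximum global
# Needleman-Wunsch score over every substring pair, with the global score
# computed by plain recursion (no shared state with the DP above).
sw_score_bruteforce <- function(read, ref, match = 2, mismatch = -2,
                               gap_del = -1, gap_ins = -1) {
  nw <- function(a, b) {
    if (!nchar(a) && !nchar(b)) return(0)
    if (!nchar(a)) return(gap_del * nchar(b))
    if (!nchar(b)) return(gap_ins * nchar(a))
    s <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
    max(nw(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + s,
        nw(substr(a, 2, nchar(a)), b) + gap_ins,
        nw(a, substr(b, 2, nchar(b))) + gap_del)
  }
  best <- 0
  for (i1 in seq_len(nchar(read) + 1) - 1) for (i2 in i1:nchar(read)) {
    sub_read <- substr(read, i1 + 1, i2)
    for (j1 in seq_len(nchar(ref) + 1) - 1) for (j2 in j1:nchar(ref)) {
      best <- max(best, nw(sub_read, substr(ref, j1 + 1, j2)))
    }
  }
  best
}

# Direct spatial-domain circular cross-correlation peak (shift oracle).
xcorr_shift_oracle <- function(reference, moved) {
  nr <- nrow(reference); nc <- ncol(reference)
  best <- -Inf; best_d <- c(0, 0)
  for (dy in 0:(nr - 1)) {
    for (dx in 0:(nc - 1)) {
      rolled <- reference[(seq_len(nr) - 1 - dy) %% nr + 1,
                          (seq_len(nc) - 1 - dx) %% nc + 1]
      v <- sum(rolled * moved)
      if (v > best) { best <- v; best_d <- c(dx, dy) }
    }
  }
  wrap <- function(d, n) if (d > n / 2) d - n else d
  list(dx = wrap(best_d[1], nc), dy = wrap(best_d[2], nr))
}

# circularly roll an image so that roll_image(img, dx, dy)[y + dy, x + dx]
# equals img[y, x]
roll_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  img[(seq_len(nr) - 1 - dy) %% nr + 1, (seq_len(nc) - 1 - dx) %% nc + 1]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a single-template reference set built directly from a read-space reference
tiny_refs <- function(wild_ref, mutant_ref = wild_ref, name = "t1") {
  reference_set(tibble::tibble(template = name, wild_ref = wild_ref,
                               mutant_ref = mutant_ref))
}

# molecules laid out on a regular grid (isolated, single-occupancy sites)
grid_molecules <- function(refs, nx = 6, ny = 6, spacing = 12, offset = 8,
                           seed = 1) {
  g <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  n <- nrow(g)
  smflow:::with_seed(seed, tibble::tibble(
    field = 1L, site = seq_len(n), molecule = seq_len(n),
    x = offset + g$ix * spacing + runif(n, -1, 1),
    y = offset + g$iy * spacing + runif(n, -1, 1),
    occupancy = 1L,
    template = sample(refs$templates$template, n, replace = TRUE),
    origin = "wild"))
}

# geometry for small rendered test fields
test_geometry <- function(px = 96) {
  field_geometry(fov_um = c(px, px) / 9.4, pixels = c(px, px), density = 0.1)
}
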