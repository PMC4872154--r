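#' Extract a fluorescence time trace at a spot
#'
#' Sums background-subtracted intensity over a circular aperture centred on
#' the spot in every frame. The background is the frame median (a robust
#' estimate given the sparse spot coverage).
#'
#' @param movie A `bleach_movie` (or any list of frames in `$frames`).
#' @param x,y Spot centroid (0-based pixel coordinates).
#' @param aperture_radius Aperture radius in pixels (default 2; 0 gives a
#'   single-pixel trace).
#' @param subtract_background Subtract the per-frame median (default TRUE).
#' @param frame_background Optional precomputed per-frame background values
#'   (used instead of per-frame medians when extracting many traces from the
#'   same movie).
#' @return A numeric vector of per-frame intensities, with attribute
#'   `clipped` set if the aperture touched the image border.
#' @export
extract_trace <- function(movie, x, y, aperture_radius = 2,
                          subtract_background = TRUE,
                          frame_background = NULL) {
  frames <- movie$frames
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (x < 0 || y < 0 || x > nc - 1 || y > nr - 1) {
    abort("centroid outside the frame")
  }
  rr <- which(abs(seq_len(nr) - 1 - y) <= aperture_radius)
  cc <- which(abs(seq_len(nc) - 1 - x) <= aperture_radius)
  sel <- outer((rr - 1 - y)^2, (cc - 1 - x)^2, "+") <= aperture_radius^2
  clipped <- y - aperture_radius < 0 || y + aperture_radius > nr - 1 ||
    x - aperture_radius < 0 || x + aperture_radius > nc - 1
  if (subtract_background && is.null(frame_background)) {
    frame_background <- vapply(frames, median, numeric(1))
  }
  npx <- sum(sel)
  trace <- vapply(seq_along(frames), function(f) {
    w <- frames[[f]][rr, cc, drop = FALSE]
    bg <- if (subtract_background) frame_background[f] else 0
    sum(w[sel]) - bg * npx
  }, numeric(1))
  attr(trace, "clipped") <- clipped
  trace
}

# binary segmentation into piecewise-constant means; returns change points
# (last index of each segment except the final one)
segment_trace <- function(trace, penalty) {
  n <- length(trace)
  cs <- cumsum(trace); cs2 <- cumsum(trace^2)
  sse <- function(i, j) { # inclusive 1-based
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  splits <- integer(0)
  recurse <- function(i, j) {
    if (j - i < 1L) return()
    base <- sse(i, j)
    red <- vapply((i):(j - 1L), function(k) base - (sse(i, k) + sse(k + 1L, j)),
                  numeric(1))
    k <- which.max(red)
    if (red[k] > penalty) {
      kpt <- i + k - 1L
      splits <<- c(splits, kpt)
      recurse(i, kpt)
      recurse(kpt + 1L, j)
    }
  }
  recurse(1L, n)
  sort(splits)
}

#' Count photobleaching steps in an intensity trace
#'
#' Segments the trace into piecewise-constant levels by penalised
#' change-point detection (penalty proportional to the robust noise variance
#' times `log n`) and counts significant downward level changes. One step
#' labels the spot a single molecule; two or more label it aggregated. Any
#' significant upward change, a poor piecewise-constant fit (residual sd
#' above `quality_factor` times the frame-noise estimate), or more than
#' `max_steps` steps leaves the trace unclassified.
#'
#' @param trace Numeric intensity trace (length >= 4).
#' @param penalty_scale Multiplier of `sigma^2 * log(n)` in the change-point
#'   penalty (default 10).
#' @param step_sigma Minimum significant level change, in units of the frame
#'   noise sd (default 3).
#' @param quality_factor Maximum residual sd after segmentation, in noise
#'   units (default 2.5).
#' @param max_steps Traces with more downward steps than this are
#'   unclassified (default 5).
#' @return A one-row tibble: `n_steps`, `label` (single / aggregated /
#'   unclassified), `step_frames` and `step_sizes` (list-columns),
#'   `noise_sd`, `resid_sd`.
#' @export
count_steps <- function(trace, penalty_scale = 10, step_sigma = 3,
                        quality_factor = 2.5, max_steps = 5L) {
  n <- length(trace)
  if (n < 4L) abort("trace must have at least 4 frames")
  sigma <- mad(diff(trace)) / sqrt(2)
  scale_floor <- 1e-9 * max(abs(trace), 1)
  penalty <- max(penalty_scale * sigma^2 * log(n), scale_floor^2)
  cp <- segment_trace(trace, penalty)
  bounds <- c(0L, cp, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(k) {
    mean(trace[(bounds[k] + 1L):bounds[k + 1L]])
  }, numeric(1))
  dmu <- diff(means)
  thresh <- max(step_sigma * sigma, scale_floor)
  down <- dmu < -thresh
  up <- dmu > thresh
  seg_means <- rep(means, diff(bounds))
  resid_sd <- sd(trace - seg_means)
  n_steps <- sum(down)
  irregular <- any(up) ||
    (sigma > 0 && resid_sd > quality_factor * sigma) ||
    n_steps > max_steps || n_steps == 0L
  label <- if (irregular) "unclassified" else if (n_steps == 1L) "single"
    else "aggregated"
  tibble(n_steps = n_steps, label = label,
         step_frames = list(bounds[c(FALSE, down, FALSE)]),
         step_sizes = list(-dmu[down]),
         noise_sd = sigma, resid_sd = resid_sd)
}

#' Classify all spots of a photobleaching movie
#'
#' Detects spots on the mean of the first `detect_frames` frames, extracts a
#' trace per spot and counts its bleaching steps.
#'
#' @param movie A `bleach_movie`.
#' @param detect_frames Frames averaged for spot detection (default 3).
#' @param aperture_radius Trace aperture radius (default 2).
#' @param ... Passed to [count_steps()].
#' @param threshold_k,smooth_sigma,max_sigma_factor Passed to
#'   [detect_spots()].
#' @return A tibble with one row per spot: spot coordinates plus the
#'   [count_steps()] columns.
#' @export
classify_movie_spots <- function(movie, detect_frames = 3L,
                                 aperture_radius = 2, smooth_sigma = 1,
                                 threshold_k = 5, max_sigma_factor = 3,
                                 ...) {
  first <- Reduce(`+`, movie$frames[seq_len(min(detect_frames,
                                                length(movie$frames)))]) /
    min(detect_frames, length(movie$frames))
  # aggregated sites are legitimate spots here, so the cluster filter is
  # relaxed (classification happens by step counting, not by shape)
  spots <- detect_spots(first, smooth_sigma = smooth_sigma,
                        threshold_k = threshold_k,
                        max_sigma_factor = max_sigma_factor, max_area = 200L)
  if (nrow(spots) == 0L) return(tibble())
  fbg <- vapply(movie$frames, median, numeric(1))
  res <- purrr::map(seq_len(nrow(spots)), function(i) {
    tr <- extract_trace(movie, spots$x[i], spots$y[i], aperture_radius,
                        frame_background = fbg)
    out <- count_steps(as.numeric(tr), ...)
    out$x <- spots$x[i]; out$y <- spots$y[i]
    out
  })
  dplyr::bind_rows(res)
}

#' Summarise single/aggregated/unclassified composition
#'
#' @param results Tibble of step-count results (or any tibble with a `label`
#'   column over single / aggregated / unclassified).
#' @return An object of class `composition_summary`: a tibble with `label`,
#'   `n`, `fraction` (fractions sum to 1).
#' @export
summarize_composition <- function(results) {
  if (is.data.frame(results)) {
    labels <- results$label
  } else {
    labels <- as.character(results)
  }
  if (length(labels) == 0L) abort("no step results supplied")
  lv <- c("single", "aggregated", "unclassified")
  n <- vapply(lv, function(l) sum(labels == l), integer(1))
  out <- tibble(label = lv, n = unname(n), fraction = unname(n) / sum(n))
  structure(out, class = c("composition_summary", class(out)))
}
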