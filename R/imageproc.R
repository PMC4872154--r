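#' Estimate a rigid shift by phase-only correlation
#'
#' Computes the unit-normalised cross-power spectrum of the two images and
#' takes the peak of its inverse transform: the location of the peak is the
#' translation of `moved` relative to `reference`. Exact for circular
#' integer shifts; `subpixel = TRUE` adds quadratic interpolation around the
#' peak.
#'
#' @param reference,moved Numeric matrices of identical dimensions.
#' @param subpixel Refine the peak to sub-pixel precision.
#' @return A list with `dx` (column shift) and `dy` (row shift), such that
#'   `moved` is `reference` displaced by `(dx, dy)`.
#' @export
estimate_shift_poc <- function(reference, moved, subpixel = FALSE) {
  if (!all(dim(reference) == dim(moved))) abort("images must share dimensions")
  if (sd(reference) == 0 || sd(moved) == 0) {
    abort("constant image: phase spectrum is undefined")
  }
  A <- fft(reference)
  B <- fft(moved)
  R <- B * Conj(A)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  pk <- unname(which(r == max(r), arr.ind = TRUE)[1, ])
  nr <- nrow(r); nc <- ncol(r)
  wrap <- function(i, n) if (i > n / 2) i - n else i
  dy <- wrap(pk[1] - 1L, nr)
  dx <- wrap(pk[2] - 1L, nc)
  if (subpixel) {
    para <- function(vm, v0, vp) {
      den <- vm - 2 * v0 + vp
      if (den == 0) 0 else 0.5 * (vm - vp) / den
    }
    i <- pk[1]; j <- pk[2]
    im <- (i - 2L) %% nr + 1L; ip <- i %% nr + 1L
    jm <- (j - 2L) %% nc + 1L; jp <- j %% nc + 1L
    dy <- dy + para(r[im, j], r[i, j], r[ip, j])
    dx <- dx + para(r[i, jm], r[i, j], r[i, jp])
  }
  list(dx = dx, dy = dy)
}

# integer translation by (dx, dy), vacated pixels filled with the image median
translate_image <- function(img, dx, dy) {
  dx <- round(dx); dy <- round(dy)
  out <- matrix(median(img), nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register an image stack to a reference cycle
#'
#' Estimates each cycle's drift from its template-channel image against the
#' reference cycle by phase-only correlation and translates both channels by
#' the negated (rounded) shift.
#'
#' @param stack An `image_stack`.
#' @param reference_cycle Cycle aligned to (default 1).
#' @param subpixel Estimate shifts to sub-pixel precision (application is
#'   still by integer translation).
#' @return The registered `image_stack`; estimated shifts are in its
#'   `shifts` element.
#' @export
register_stack <- function(stack, reference_cycle = 1L, subpixel = FALSE) {
  n <- length(stack$template)
  ref <- stack$template[[reference_cycle]]
  shifts <- purrr::map(seq_len(n), function(cyc) {
    if (cyc == reference_cycle) return(list(dx = 0, dy = 0))
    estimate_shift_poc(ref, stack$template[[cyc]], subpixel = subpixel)
  })
  out <- stack
  for (cyc in seq_len(n)) {
    s <- shifts[[cyc]]
    if (s$dx != 0 || s$dy != 0) {
      out$template[[cyc]] <- translate_image(stack$template[[cyc]], -s$dx, -s$dy)
      out$incorporation[[cyc]] <- translate_image(stack$incorporation[[cyc]],
                                                  -s$dx, -s$dy)
    }
  }
  out$shifts <- tibble(cycle = seq_len(n),
                       dx = vapply(shifts, `[[`, numeric(1), "dx"),
                       dy = vapply(shifts, `[[`, numeric(1), "dy"))
  out$registered <- TRUE
  out
}

#' Fit a single Gaussian spot
#'
#' Least-squares fit of an isotropic 2-D Gaussian plus constant background
#' to a square window of the image around `center`.
#'
#' @param image Numeric matrix.
#' @param center Approximate spot position `c(x, y)` (0-based, continuous).
#' @param half_width Half-width of the fit window in pixels.
#' @param sigma_start Starting value for the Gaussian sd.
#' @return A one-row tibble: `x`, `y`, `amplitude`, `sigma`, `background`,
#'   `resid_sd`, `converged`.
#' @export
fit_spot <- function(image, center, half_width = 4L, sigma_start = 1.2) {
  cx <- center[1]; cy <- center[2]
  r0 <- max(1L, round(cy + 1 - half_width)); r1 <- min(nrow(image), round(cy + 1 + half_width))
  c0 <- max(1L, round(cx + 1 - half_width)); c1 <- min(ncol(image), round(cx + 1 + half_width))
  win <- image[r0:r1, c0:c1, drop = FALSE]
  df <- expand.grid(yy = (r0:r1) - 1, xx = (c0:c1) - 1)
  df$z <- as.vector(win)
  start <- list(bg = min(df$z), A = max(df$z) - min(df$z),
                x0 = cx, y0 = cy, s = sigma_start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2)),
      data = df, start = start,
      lower = c(bg = -Inf, A = 0, x0 = c0 - 2, y0 = r0 - 2, s = 0.2),
      upper = c(bg = Inf, A = Inf, x0 = c1, y0 = r1, s = half_width),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(x = cx, y = cy, amplitude = NA_real_, sigma = NA_real_,
                  background = NA_real_, resid_sd = NA_real_,
                  converged = FALSE))
  }
  cf <- coef(fit)
  tibble(x = unname(cf["x0"]), y = unname(cf["y0"]),
         amplitude = unname(cf["A"]), sigma = abs(unname(cf["s"])),
         background = unname(cf["bg"]), resid_sd = sd(resid(fit)),
         converged = TRUE)
}

#' Detect spots in a single image
#'
#' The image is convolved with a Gaussian kernel; a threshold is set from a
#' noise measurement on the smoothed image (median plus `threshold_k` times
#' the MAD-based robust scale); contiguous above-threshold pixel groups
#' (8-connectivity) become candidate spots; each candidate is fitted with a
#' 2-D Gaussian on the raw image. Candidates whose fit fails, whose fitted
#' sigma exceeds `max_sigma_factor * psf_sigma`, or whose pixel area exceeds
#' `max_area` are filtered out as clusters of three or more molecules or
#' artefacts.
#'
#' @param image Numeric matrix.
#' @param smooth_sigma Gaussian smoothing sd in pixels (default 1).
#' @param threshold_k Threshold multiplier on the robust noise scale
#'   (default 5).
#' @param psf_sigma Expected single-emitter sd used by the cluster filter.
#' @param max_sigma_factor Cluster filter: maximum fitted sigma as a multiple
#'   of `psf_sigma` (default 1.8).
#' @param max_area Cluster filter: maximum component area in pixels.
#' @param min_area Minimum component area (default 2; suppresses single-pixel
#'   noise exceedances).
#' @return A tibble of accepted spots: `x`, `y`, `amplitude`, `sigma`,
#'   `background`, `resid_sd`, `area`. The number of rejected candidates is
#'   in the `n_rejected` attribute.
#' @export
detect_spots <- function(image, smooth_sigma = 1, threshold_k = 5,
                         psf_sigma = 1, max_sigma_factor = 1.8,
                         max_area = 40L, min_area = 2L) {
  if (length(image) == 0L) {
    return(tibble(x = numeric(), y = numeric(), amplitude = numeric(),
                  sigma = numeric(), background = numeric(),
                  resid_sd = numeric(), area = integer()))
  }
  sm <- gauss_blur_cpp(image, smooth_sigma)
  noise <- mad(sm)
  # (near-)noise-free images have a vanishing MAD relative to the signal;
  # fall back to a fixed fraction of the peak excursion there so spots
  # remain compact components
  excursion <- max(sm) - median(sm)
  thr <- if (threshold_k * noise >= 1e-3 * excursion) {
    median(sm) + threshold_k * noise
  } else {
    median(sm) + (threshold_k / 20) * excursion
  }
  mask <- sm > thr
  if (!any(mask)) {
    out <- tibble(x = numeric(), y = numeric(), amplitude = numeric(),
                  sigma = numeric(), background = numeric(),
                  resid_sd = numeric(), area = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  lab <- label_components_cpp(mask)
  comp <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  area <- tabulate(ids)
  n_rej <- 0L
  rows <- purrr::map(seq_along(area), function(k) {
    if (area[k] < min_area) return(NULL)
    px <- comp[ids == k, , drop = FALSE]
    w <- sm[px]
    cx <- sum((px[, 2] - 1) * w) / sum(w)
    cy <- sum((px[, 1] - 1) * w) / sum(w)
    ft <- fit_spot(image, c(cx, cy))
    ft$area <- area[k]
    ft
  })
  spots <- dplyr::bind_rows(rows)
  if (nrow(spots)) {
    ok <- spots$converged & !is.na(spots$amplitude) & spots$amplitude > 0 &
      spots$sigma <= max_sigma_factor * psf_sigma & spots$area <= max_area
    n_rej <- sum(!ok)
    spots <- spots[ok, ]
  }
  spots$converged <- NULL
  attr(spots, "n_rejected") <- n_rej
  spots
}

#' Match incorporation spots to template-channel anchors
#'
#' A spot appearing at the same position in both channels of a registered
#' cycle is a base incorporation event. Every incorporation spot within
#' `radius` of a template anchor is matched to the nearest such anchor;
#' unmatched spots are discarded, and each anchor accepts at most one spot
#' per cycle (nearest wins; exact ties go to the lower spot index).
#'
#' @param template_spots Anchor tibble (from [detect_spots()] on the
#'   template channel); row order defines anchor ids.
#' @param incorporation_spots Spot tibble with optional `cycle` column.
#' @param radius Matching radius in pixels (default 1.6).
#' @return A tibble of matched incorporation spots: `anchor`, `cycle`, `x`,
#'   `y`, `dist` plus any other spot columns.
#' @export
coincidence_spots <- function(template_spots, incorporation_spots,
                              radius = 1.6) {
  if (nrow(incorporation_spots) == 0L || nrow(template_spots) == 0L) {
    return(tibble(anchor = integer(), cycle = integer(),
                  x = numeric(), y = numeric(), dist = numeric()))
  }
  inc <- incorporation_spots
  if (!"cycle" %in% names(inc)) inc$cycle <- 1L
  inc$spot_index <- seq_len(nrow(inc))
  d2 <- outer(inc$x, template_spots$x, "-")^2 +
    outer(inc$y, template_spots$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(inc)), nearest)])
  cand <- inc
  cand$anchor <- nearest
  cand$dist <- dist
  cand <- dplyr::filter(cand, .data$dist <= radius)
  cand <- dplyr::arrange(cand, .data$cycle, .data$dist, .data$spot_index)
  cand <- cand |>
    group_by(.data$cycle, .data$anchor) |>
    dplyr::slice(1L) |>
    ungroup()
  dplyr::select(cand, "anchor", "cycle", "x", "y", "dist",
                dplyr::any_of(c("amplitude", "sigma")))
}
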