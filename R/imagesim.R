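# add an isotropic Gaussian spot (peak amplitude `amp`, sd `sigma`) at the
# continuous 0-based position (x, y); image[r, c] samples (x = c-1, y = r-1)
add_spot <- function(img, x, y, amp, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  h <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y + 1 - h)); r1 <- min(nr, ceiling(y + 1 + h))
  c0 <- max(1L, floor(x + 1 - h)); c1 <- min(nc, ceiling(x + 1 + h))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  gy <- exp(-((rr - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((cc - 1 - x)^2) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amp * outer(gy, gx)
  img
}

apply_camera <- function(signal, optics, noisefree = FALSE) {
  if (noisefree) return(signal + optics$background)
  n <- length(signal)
  shot <- rpois(n, lambda = as.vector(signal) + optics$background)
  matrix(shot + rnorm(n, 0, optics$read_noise), nrow = nrow(signal))
}

#' Render a per-cycle two-channel image stack
#'
#' The anchor (template) channel shows a Gaussian spot at every occupied
#' site with peak amplitude `template_amp * occupancy`; the incorporation
#' channel at cycle `c` shows a spot only at sites where at least one
#' molecule recorded an incorporation (correct or wrong) or spurious event
#' at that cycle, with amplitude proportional to the number of such events.
#' All sites in cycle `c` are displaced by that cycle's cumulative rigid
#' stage drift. Pixel values are Poisson shot noise on signal plus
#' background, plus Gaussian read noise.
#'
#' @param molecules Molecule tibble from [place_molecules()] (one field).
#' @param events Event tibble from [simulate_events()].
#' @param optics An [optics_config].
#' @param geometry A [field_geometry] providing the image dimensions.
#' @param drift Optional matrix/tibble of per-cycle drift offsets
#'   (columns dx, dy, one row per cycle, cycle 1 = 0); if NULL, cumulative
#'   Gaussian drift with per-cycle sd `drift_per_cycle_sigma` is drawn.
#' @param noisefree If TRUE, skip shot and read noise (background still
#'   added as a constant).
#' @param seed Integer seed.
#' @return An object of class `image_stack`: lists of per-cycle template and
#'   incorporation images, the true drift table, and the site table.
#' @export
render_cycle_stack <- function(molecules, events, optics = optics_config(),
                               geometry = field_geometry(), drift = NULL,
                               noisefree = FALSE, seed = 1L) {
  nx <- geometry$pixels[1]; ny <- geometry$pixels[2]
  n_cycles <- max(events$cycle)
  sites <- molecules |>
    group_by(.data$site) |>
    summarise(x = .data$x[1], y = .data$y[1], occupancy = dplyr::n(),
              .groups = "drop")
  inc <- events |>
    dplyr::filter(.data$outcome %in%
                    c("incorporated_correct", "incorporated_wrong", "spurious")) |>
    left_join(dplyr::select(molecules, "molecule", "site"), by = "molecule") |>
    dplyr::count(.data$cycle, .data$site)
  with_seed(seed, {
    if (is.null(drift)) {
      steps_x <- c(0, rnorm(n_cycles - 1L, 0, optics$drift_per_cycle_sigma))
      steps_y <- c(0, rnorm(n_cycles - 1L, 0, optics$drift_per_cycle_sigma))
      drift <- tibble(cycle = seq_len(n_cycles),
                      dx = cumsum(steps_x), dy = cumsum(steps_y))
    } else {
      drift <- as_tibble(as.data.frame(drift))
      if (!"cycle" %in% names(drift)) drift$cycle <- seq_len(nrow(drift))
    }
    tmpl_imgs <- vector("list", n_cycles)
    inc_imgs <- vector("list", n_cycles)
    for (cyc in seq_len(n_cycles)) {
      dx <- drift$dx[cyc]; dy <- drift$dy[cyc]
      tm <- matrix(0, ny, nx)
      for (i in seq_len(nrow(sites))) {
        tm <- add_spot(tm, sites$x[i] + dx, sites$y[i] + dy,
                       optics$template_amp * sites$occupancy[i],
                       optics$psf_sigma)
      }
      im <- matrix(0, ny, nx)
      ev <- inc[inc$cycle == cyc, ]
      if (nrow(ev)) {
        si <- match(ev$site, sites$site)
        for (k in seq_len(nrow(ev))) {
          im <- add_spot(im, sites$x[si[k]] + dx, sites$y[si[k]] + dy,
                         optics$incorporation_amp * ev$n[k],
                         optics$psf_sigma)
        }
      }
      tmpl_imgs[[cyc]] <- apply_camera(tm, optics, noisefree)
      inc_imgs[[cyc]] <- apply_camera(im, optics, noisefree)
    }
    structure(list(template = tmpl_imgs, incorporation = inc_imgs,
                   drift = drift, sites = sites, optics = optics,
                   geometry = geometry),
              class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d cycles, %d x %d px, %d sites\n",
              length(x$template), ncol(x$template[[1]]),
              nrow(x$template[[1]]), nrow(x$sites)))
  invisible(x)
}

#' Render a photobleaching movie of the anchor channel
#'
#' Under continuous illumination every fluorophore bleaches independently at
#' a geometric time (per-frame probability `bleach_rate`), so a site with
#' occupancy k produces an intensity trace with k downward steps (fewer if
#' two fluorophores bleach in the same frame).
#'
#' @param molecules Molecule tibble (one field).
#' @param optics An [optics_config].
#' @param geometry A [field_geometry].
#' @param n_frames Number of frames (default 200).
#' @param bleach_rate Per-frame bleaching probability (default 0.02).
#' @param noisefree If TRUE, skip camera noise.
#' @param seed Integer seed.
#' @return An object of class `bleach_movie`: frame list, site table, and a
#'   per-molecule truth table with the first dark frame.
#' @export
render_bleach_movie <- function(molecules, optics = optics_config(),
                                geometry = field_geometry(), n_frames = 200L,
                                bleach_rate = 0.02, noisefree = FALSE,
                                seed = 1L) {
  if (n_frames < 2L) abort("`n_frames` must be >= 2")
  nx <- geometry$pixels[1]; ny <- geometry$pixels[2]
  with_seed(seed, {
    # fluorophore m emits during frames 1..(bleach_frame - 1)
    bleach_frame <- if (bleach_rate > 0) {
      2L + stats::rgeom(nrow(molecules), bleach_rate)
    } else rep(.Machine$integer.max, nrow(molecules))
    truth <- tibble(molecule = molecules$molecule, site = molecules$site,
                    bleach_frame = bleach_frame)
    sites <- molecules |>
      group_by(.data$site) |>
      summarise(x = .data$x[1], y = .data$y[1], occupancy = dplyr::n(),
                .groups = "drop")
    # render the fully-lit field once, then subtract one fluorophore's spot
    # at each bleaching event
    signal <- matrix(0, ny, nx)
    for (k in seq_len(nrow(sites))) {
      signal <- add_spot(signal, sites$x[k], sites$y[k],
                         optics$template_amp * sites$occupancy[k],
                         optics$psf_sigma)
    }
    mol_site <- match(truth$site, sites$site)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      dying <- which(truth$bleach_frame == f)
      for (m in dying) {
        signal <- add_spot(signal, sites$x[mol_site[m]], sites$y[mol_site[m]],
                           -optics$template_amp, optics$psf_sigma)
      }
      frames[[f]] <- apply_camera(pmax(signal, 0), optics, noisefree)
    }
    structure(list(frames = frames, sites = sites, truth = truth,
                   optics = optics, geometry = geometry),
              class = "bleach_movie")
  })
}

#' @export
print.bleach_movie <- function(x, ...) {
  cat(sprintf("<bleach_movie> %d frames, %d sites\n",
              length(x$frames), nrow(x$sites)))
  invisible(x)
}

#' Write an image stack as multi-page TIFF files
#'
#' One multi-page TIFF per channel (pages are cycles), plus TSV sidecars for
#' the true drift and site tables.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_image_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- function(imgs) {
    mx <- max(1, max(unlist(imgs)))
    lapply(imgs, function(im) pmin(pmax(im / mx, 0), 1))
  }
  tiff::writeTIFF(norm(stack$template),
                  file.path(dir, paste0(prefix, "_template.tif")),
                  bits.per.sample = 16L)
  tiff::writeTIFF(norm(stack$incorporation),
                  file.path(dir, paste0(prefix, "_incorporation.tif")),
                  bits.per.sample = 16L)
  utils::write.table(stack$drift, file.path(dir, paste0(prefix, "_drift.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(stack$sites, file.path(dir, paste0(prefix, "_sites.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a two-channel image stack written by [write_image_stack()]
#' @param dir Directory containing the TIFF pair.
#' @param prefix File-name prefix used when writing.
#' @return An `image_stack` (drift/site sidecars attached when present).
#' @export
read_image_stack <- function(dir, prefix = "stack") {
  rd <- function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(prefix, "_", ch, ".tif")),
                            all = TRUE)
    lapply(pages, function(p) p)
  }
  drift_path <- file.path(dir, paste0(prefix, "_drift.tsv"))
  sites_path <- file.path(dir, paste0(prefix, "_sites.tsv"))
  structure(list(
    template = rd("template"), incorporation = rd("incorporation"),
    drift = if (file.exists(drift_path))
      as_tibble(utils::read.delim(drift_path)) else NULL,
    sites = if (file.exists(sites_path))
      as_tibble(utils::read.delim(sites_path)) else NULL),
    class = "image_stack")
}
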