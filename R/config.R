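#' Flow protocol
#'
#' Describes the cyclic order in which single reversible-terminator species
#' are presented to the flow cell and how many cycles are run. A positive
#' incorporation signal at cycle `c` implies that base
#' `flow_order[(c - 1) %% 4 + 1]` was added to the growing strand, which is
#' how tracks are decoded back into reads.
#'
#' @param flow_order Character vector of length 4, a permutation of A/C/G/T.
#'   The default `G, C, T, A` is the presentation order used throughout.
#' @param n_cycles Number of sequencing cycles (default 25; typical runs use
#'   19--30 cycles, enough to read roughly 10 bases).
#' @return An object of class `flow_protocol`.
#' @export
flow_protocol <- function(flow_order = c("G", "C", "T", "A"), n_cycles = 25L) {
  flow_order <- toupper(as.character(flow_order))
  if (length(flow_order) != 4L || !setequal(flow_order, BASES)) {
    abort("`flow_order` must be a permutation of A, C, G, T")
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) abort("`n_cycles` must be >= 1")
  structure(list(flow_order = flow_order, n_cycles = n_cycles),
            class = "flow_protocol")
}

# base flowed at a (1-based) cycle
flow_base <- function(protocol, cycle) {
  protocol$flow_order[(cycle - 1L) %% 4L + 1L]
}

#' Per-cycle error model for single-base incorporation
#'
#' @param p_sub Probability, per incorporated base, that a wrong base is
#'   recorded (default 0.0052, i.e. 0.52% per base).
#' @param p_del Probability, per due incorporation, that the event is missed
#'   entirely; the skipped base is never recovered, producing a deletion in
#'   the read (default 0.040). Deletions are the dominant error class.
#' @param p_ins Probability, per non-matching cycle, of a spurious
#'   incorporation signal, producing an insertion in the read (default 0.005).
#' @return An object of class `error_model`.
#' @export
error_model <- function(p_sub = 0.0052, p_del = 0.040, p_ins = 0.005) {
  p <- c(p_sub = p_sub, p_del = p_del, p_ins = p_ins)
  if (any(p < 0) || any(p > 1)) abort("error probabilities must be in [0, 1]")
  if (p_sub + p_del + p_ins >= 1) abort("p_sub + p_del + p_ins must be < 1")
  structure(as.list(p), class = "error_model")
}

#' Zero-error model (noise-free limit)
#' @return An `error_model` with all probabilities zero.
#' @export
perfect_errors <- function() error_model(0, 0, 0)

#' Field geometry and surface occupancy
#'
#' One imaged field of view. Molecules attach at random positions at a mean
#' surface density; a site may carry one molecule, a pair, or a cluster of
#' three or more, reflecting Poisson co-attachment within the diffraction
#' limit.
#'
#' @param fov_um Field edge lengths in micrometres (default 54.6 x 54.6).
#' @param pixels Camera resolution (default 512 x 512).
#' @param density Mean molecules per square micrometre (default 0.75, giving
#'   roughly 2200--2500 molecules per field).
#' @param frac_single,frac_pair,frac_cluster Fractions of occupied sites
#'   carrying 1, 2, or >= 3 molecules; must sum to 1. Defaults 0.38 / 0.36 /
#'   0.26.
#' @param margin_px Margin in pixels kept free of molecules at each edge.
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(fov_um = c(54.6, 54.6), pixels = c(512L, 512L),
                           density = 0.75, frac_single = 0.38,
                           frac_pair = 0.36, frac_cluster = 0.26,
                           margin_px = 4) {
  if (density <= 0) abort("`density` must be > 0")
  fr <- c(frac_single, frac_pair, frac_cluster)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    abort("occupancy fractions must be non-negative and sum to 1")
  }
  structure(list(fov_um = as.numeric(fov_um), pixels = as.integer(pixels),
                 density = density, frac_single = frac_single,
                 frac_pair = frac_pair, frac_cluster = frac_cluster,
                 margin_px = margin_px),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %.1f x %.1f um, %d x %d px, %.2f molecules/um^2\n",
              x$fov_um[1], x$fov_um[2], x$pixels[1], x$pixels[2], x$density))
  invisible(x)
}

#' Optical model for image rendering
#'
#' @param psf_sigma Standard deviation of the isotropic Gaussian point-spread
#'   function, in pixels (default 1.0, approximately diffraction limited for
#'   far-red emission at ~0.107 um/px).
#' @param template_amp,incorporation_amp Expected peak photons for one
#'   fluorophore in the anchor (Cy3) and incorporation (ATTO647N-like)
#'   channels.
#' @param background Mean background photons per pixel.
#' @param read_noise Gaussian camera read noise (photons, sd).
#' @param drift_per_cycle_sigma Standard deviation, in pixels, of the rigid
#'   stage translation accumulated between consecutive cycles.
#' @param exposure_frames Exposures taken per field per cycle; they are
#'   averaged into one frame per channel.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(psf_sigma = 1.0, template_amp = 200,
                          incorporation_amp = 200, background = 10,
                          read_noise = 2, drift_per_cycle_sigma = 1.0,
                          exposure_frames = 4L) {
  if (psf_sigma <= 0) abort("`psf_sigma` must be > 0")
  if (template_amp <= 0 || incorporation_amp <= 0) abort("amplitudes must be > 0")
  if (drift_per_cycle_sigma < 0) abort("`drift_per_cycle_sigma` must be >= 0")
  structure(list(psf_sigma = psf_sigma, template_amp = template_amp,
                 incorporation_amp = incorporation_amp, background = background,
                 read_noise = read_noise,
                 drift_per_cycle_sigma = drift_per_cycle_sigma,
                 exposure_frames = as.integer(exposure_frames)),
            class = "optics_config")
}

#' Alignment scoring scheme
#'
#' Linear (non-affine) local-alignment scores: +2 for a match, -2 for a
#' substitution, -1 for a deletion in a read (a reference base skipped) and
#' -1 for an insertion in a read (a read base absent from the reference).
#'
#' @param match,mismatch,gap_del,gap_ins Integer scores; `match` must be
#'   positive and penalties non-positive.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -2L, gap_del = -1L,
                           gap_ins = -1L) {
  if (match <= 0) abort("`match` must be > 0")
  if (mismatch > 0 || gap_del > 0 || gap_ins > 0) {
    abort("penalties must be <= 0")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_del = as.integer(gap_del), gap_ins = as.integer(gap_ins)),
            class = "scoring_scheme")
}

#' Read quality-control parameters
#'
#' Three sequential filters: minimum read length, minimum exact-string
#' multiplicity across the run, and an alignability floor (best local
#' alignment score against any reference below `min_score` marks a read
#' unalignable). `min_score` defaults to `2 * min_length`, the score of a
#' perfect match of `min_length` bases.
#'
#' @param min_length Minimum read length kept (default 5).
#' @param min_multiplicity Minimum number of identical copies of a read
#'   string required (default 4).
#' @param min_score Alignability floor; `NULL` for the default.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_length = 5L, min_multiplicity = 4L, min_score = NULL) {
  min_length <- as.integer(min_length)
  min_multiplicity <- as.integer(min_multiplicity)
  if (min_length < 1L || min_multiplicity < 1L) {
    abort("`min_length` and `min_multiplicity` must be >= 1")
  }
  if (is.null(min_score)) min_score <- 2L * min_length
  structure(list(min_length = min_length, min_multiplicity = min_multiplicity,
                 min_score = as.integer(min_score)),
            class = "qc_params")
}

#' Read or write a run configuration file
#'
#' The YAML configuration has sections `references`, `flow`, `errors`,
#' `geometry` and `optics`; every constructor default is a key. Sections may
#' be omitted, in which case defaults apply.
#'
#' @param path File path.
#' @return `read_run_config()` returns a named list with elements
#'   `references` (argument list for [make_references()]), `flow`
#'   ([flow_protocol]), `errors` ([error_model]), `geometry`
#'   ([field_geometry]) and `optics` ([optics_config]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  take <- function(section, fn) do.call(fn, cfg[[section]] %||% list())
  list(references = cfg$references %||% list(),
       flow = take("flow", flow_protocol),
       errors = take("errors", error_model),
       geometry = take("geometry", field_geometry),
       optics = take("optics", optics_config))
}

#' @param config A named list of sections, each a named list of keys.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
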