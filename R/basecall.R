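#' Group incorporation spots into per-anchor tracks
#'
#' Every matched incorporation spot centroid within `track_radius` of a
#' template-channel anchor, across cycles, belongs to that anchor's track.
#' Anchors closer than `2 * track_radius` to another anchor could capture
#' each other's events, so both are flagged ambiguous and excluded from base
#' calling.
#'
#' @param anchors Anchor spot tibble (row order defines anchor ids).
#' @param incorporation_spots Incorporation spot tibble with a `cycle`
#'   column (typically the per-cycle output of [detect_spots()] bound
#'   together, or [coincidence_spots()] output).
#' @param track_radius Radius in pixels (default 1.6).
#' @return A tibble with one row per anchor: `anchor`, `x`, `y`,
#'   `ambiguous`, `cycles` (list-column of event cycles).
#' @export
build_tracks <- function(anchors, incorporation_spots, track_radius = 1.6) {
  n_anchor <- nrow(anchors)
  amb <- rep(FALSE, n_anchor)
  if (n_anchor > 1L) {
    d <- as.matrix(stats::dist(cbind(anchors$x, anchors$y)))
    diag(d) <- Inf
    amb <- unname(apply(d < 2 * track_radius, 1L, any))
  }
  matched <- coincidence_spots(anchors, incorporation_spots,
                               radius = track_radius)
  cyc <- purrr::map(seq_len(n_anchor), function(a) {
    sort(unique(matched$cycle[matched$anchor == a]))
  })
  tibble(anchor = seq_len(n_anchor), x = anchors$x, y = anchors$y,
         ambiguous = amb, cycles = cyc)
}

#' Decode a track's event cycles into a read
#'
#' The read is the concatenation, over event cycles in ascending order, of
#' the base flowed at each cycle: `flow_order[(cycle - 1) %% 4 + 1]`.
#'
#' @param cycles Integer vector of event cycles (1-based).
#' @param protocol A [flow_protocol].
#' @return The read string.
#' @export
decode_track <- function(cycles, protocol = flow_protocol()) {
  if (length(cycles) == 0L) return("")
  cycles <- sort(as.integer(cycles))
  paste(flow_base(protocol, cycles), collapse = "")
}

#' Call reads from an image stack
#'
#' The composed image pipeline: register the stack to cycle 1, detect
#' template-channel anchors on the mean registered anchor image, detect
#' incorporation spots cycle by cycle, keep those coincident with an anchor,
#' group them into tracks and decode each unambiguous track with the flow
#' order.
#'
#' @param stack An `image_stack`.
#' @param protocol A [flow_protocol].
#' @param track_radius Track/coincidence radius in pixels (default 1.6).
#' @param smooth_sigma,threshold_k,psf_sigma,max_sigma_factor Passed to
#'   [detect_spots()].
#' @param register Register the stack first (default TRUE).
#' @return A read-set tibble (`read_id`, `seq`, `anchor`, `x`, `y`), with
#'   attribute `provenance = "pipeline"` and the track table in the
#'   `tracks` attribute.
#' @export
call_field <- function(stack, protocol = flow_protocol(), track_radius = 1.6,
                       smooth_sigma = 1, threshold_k = 5, psf_sigma = 1,
                       max_sigma_factor = 1.8, register = TRUE) {
  if (register) stack <- register_stack(stack)
  n_cycles <- length(stack$template)
  mean_template <- Reduce(`+`, stack$template) / n_cycles
  anchors <- detect_spots(mean_template, smooth_sigma, threshold_k,
                          psf_sigma, max_sigma_factor)
  if (nrow(anchors) == 0L) {
    out <- tibble(read_id = character(), seq = character(),
                  anchor = integer(), x = numeric(), y = numeric())
    attr(out, "provenance") <- "pipeline"
    return(out)
  }
  inc <- purrr::map(seq_len(n_cycles), function(cyc) {
    sp <- detect_spots(stack$incorporation[[cyc]], smooth_sigma, threshold_k,
                       psf_sigma, max_sigma_factor)
    if (nrow(sp)) sp$cycle <- cyc
    sp
  })
  inc <- dplyr::bind_rows(inc)
  tracks <- build_tracks(anchors, inc, track_radius)
  called <- dplyr::filter(tracks, !.data$ambiguous)
  out <- tibble(
    read_id = sprintf("a%04d_x%.1f_y%.1f", called$anchor, called$x, called$y),
    seq = vapply(called$cycles, decode_track, character(1),
                 protocol = protocol),
    anchor = called$anchor, x = called$x, y = called$y)
  attr(out, "provenance") <- "pipeline"
  attr(out, "tracks") <- tracks
  attr(out, "shifts") <- stack$shifts
  out
}
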