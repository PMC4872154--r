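#' Tidy methods for result objects
#'
#' `tidy()` returns the per-unit table of a result (per position, per batch,
#' per depth, per fraction); `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name smflow-tidiers
NULL

#' @rdname smflow-tidiers
#' @export
tidy.consensus_result <- function(x, ...) x$tally

#' @rdname smflow-tidiers
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(identity = x$identity, n_covered = x$n_covered,
         mean_coverage = mean(x$tally$coverage),
         reference_length = nchar(x$reference))
}

#' @rdname smflow-tidiers
#' @export
tidy.error_profile <- function(x, ...) x$per_position

#' @rdname smflow-tidiers
#' @export
glance.error_profile <- function(x, ...) {
  tibble(sub_rate = x$overall_sub_rate, del_rate = x$overall_del_rate,
         insertion_rate = x$insertion_rate, aligned_bases = x$aligned_bases,
         n_uncovered = x$n_uncovered, n_well_covered = x$n_well_covered)
}

#' @rdname smflow-tidiers
#' @export
tidy.accuracy_curve <- function(x, ...) as_tibble(unclass(x))

#' @rdname smflow-tidiers
#' @export
glance.accuracy_curve <- function(x, ...) {
  tibble(min_depth = min(x$depth), max_depth = max(x$depth),
         identity_at_min = x$mean_identity[which.min(x$depth)],
         identity_at_max = x$mean_identity[which.max(x$depth)])
}

#' @rdname smflow-tidiers
#' @export
tidy.mixture_result <- function(x, ...) x$per_batch

#' @rdname smflow-tidiers
#' @export
glance.mixture_result <- function(x, ...) {
  tibble(pooled_frequency = x$pooled_frequency, n_effective = x$n_effective,
         n_templates = nrow(x$per_template),
         n_batches = nrow(x$batch_overall))
}

#' @rdname smflow-tidiers
#' @export
tidy.detection_scan <- function(x, ...) x$scan

#' @rdname smflow-tidiers
#' @export
glance.detection_scan <- function(x, ...) {
  tibble(smallest_detected = x$smallest_detected, alpha = x$alpha,
         n_fractions = nrow(x$scan))
}

#' @rdname smflow-tidiers
#' @export
tidy.sw_alignment <- function(x, ...) {
  if (!nzchar(x$ops)) {
    return(tibble(op = character(), length = integer()))
  }
  r <- rle(strsplit(x$ops, "")[[1]])
  tibble(op = r$values, length = r$lengths)
}

#' @rdname smflow-tidiers
#' @export
glance.sw_alignment <- function(x, ...) {
  tibble(score = x$score, read_start = x$read_start, read_end = x$read_end,
         ref_start = x$ref_start, ref_end = x$ref_end,
         n_ops = nchar(x$ops))
}
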