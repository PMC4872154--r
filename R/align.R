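#' Smith-Waterman local alignment
#'
#' Optimal local alignment under the linear scoring of [scoring_scheme()]
#' with a deterministic traceback (diagonal preferred over a gap consuming
#' the read, preferred over a gap consuming the reference; the best cell is
#' the first maximum in read-position order). An empty alignment of score 0
#' is permitted.
#'
#' @param read,reference Sequences over A/C/G/T.
#' @param scoring A [scoring_scheme].
#' @return An object of class `sw_alignment`: score, 0-based half-open read
#'   and reference spans, and an operation string over `=` (match), `X`
#'   (substitution), `D` (deletion in the read) and `I` (insertion in the
#'   read).
#' @export
smith_waterman <- function(read, reference, scoring = scoring_scheme()) {
  read <- toupper(read); reference <- toupper(reference)
  if (nchar(read) > 0) check_dna(read, "read")
  check_dna(reference, "reference")
  al <- sw_align_cpp(read, reference, scoring$match, scoring$mismatch,
                     scoring$gap_del, scoring$gap_ins)
  structure(c(al, list(read = read, reference = reference, scoring = scoring)),
            class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %d, read [%d,%d), ref [%d,%d)\n  %s\n",
              x$score, x$read_start, x$read_end, x$ref_start, x$ref_end,
              x$ops))
  invisible(x)
}

ops_to_cigar <- function(ops) {
  if (!nzchar(ops)) return("*")
  r <- rle(strsplit(ops, "")[[1]])
  paste0(r$lengths, r$values, collapse = "")
}

# score every unique read string against a set of reference strings
score_unique <- function(seqs, refs_chr, scoring) {
  sw_score_matrix_cpp(seqs, refs_chr, scoring$match, scoring$mismatch,
                      scoring$gap_del, scoring$gap_ins)
}

#' Align reads to their best-scoring reference template
#'
#' Each read is aligned to every reference in the chosen set; the read is
#' assigned to the single best-scoring template (reads whose best score is
#' tied between templates are dropped as of ambiguous origin) and the full
#' traceback against that reference is returned. Identical read strings are
#' aligned once and the result reused.
#'
#' @param reads Read-set tibble with columns `read_id`, `seq`.
#' @param refs A [reference_set].
#' @param scoring A [scoring_scheme].
#' @param use Which references to align against: `"wild"` (default),
#'   `"mutant"`, or `"both"` (wild and mutant references of every template).
#' @return A tibble with one row per assigned read: `read_id`, `seq`,
#'   `template`, `allele`, `score`, spans, `ops` and `cigar`; dropped reads
#'   are recorded in the `n_ambiguous` attribute.
#' @export
align_reads <- function(reads, refs, scoring = scoring_scheme(),
                        use = c("wild", "mutant", "both")) {
  use <- match.arg(use)
  tmpl <- refs$templates
  ref_tbl <- switch(use,
    wild = tibble(template = tmpl$template, allele = "wild", ref = tmpl$wild_ref),
    mutant = tibble(template = tmpl$template, allele = "mutant", ref = tmpl$mutant_ref),
    both = dplyr::bind_rows(
      tibble(template = tmpl$template, allele = "wild", ref = tmpl$wild_ref),
      tibble(template = tmpl$template, allele = "mutant", ref = tmpl$mutant_ref)))
  useq <- unique(reads$seq)
  sc <- score_unique(useq, ref_tbl$ref, scoring)
  best <- max.col(sc, ties.method = "first")
  best_score <- sc[cbind(seq_along(best), best)]
  # a tie between references of different templates makes the origin ambiguous
  n_best_tmpl <- vapply(seq_along(useq), function(i) {
    length(unique(ref_tbl$template[sc[i, ] == best_score[i]]))
  }, integer(1))
  amb <- n_best_tmpl > 1L
  al <- purrr::map(seq_along(useq), function(i) {
    if (amb[i]) return(NULL)
    sw_align_cpp(useq[i], ref_tbl$ref[best[i]], scoring$match,
                 scoring$mismatch, scoring$gap_del, scoring$gap_ins)
  })
  utab <- tibble(
    seq = useq,
    template = ref_tbl$template[best],
    allele = ref_tbl$allele[best],
    score = as.integer(best_score),
    read_start = vapply(al, function(a) if (is.null(a)) NA_integer_ else a$read_start, integer(1)),
    read_end = vapply(al, function(a) if (is.null(a)) NA_integer_ else a$read_end, integer(1)),
    ref_start = vapply(al, function(a) if (is.null(a)) NA_integer_ else a$ref_start, integer(1)),
    ref_end = vapply(al, function(a) if (is.null(a)) NA_integer_ else a$ref_end, integer(1)),
    ops = vapply(al, function(a) if (is.null(a)) NA_character_ else a$ops, character(1)),
    ambiguous = amb)
  out <- left_join(reads[, intersect(c("read_id", "seq", "field", "template",
                                       "origin"), names(reads))],
                   dplyr::rename(utab, assigned = "template"), by = "seq")
  n_amb <- sum(out$ambiguous)
  out <- dplyr::filter(out, !.data$ambiguous)
  out$ambiguous <- NULL
  if ("template" %in% names(out)) out <- dplyr::rename(out, true_template = "template")
  out <- dplyr::rename(out, template = "assigned")
  out$cigar <- vapply(out$ops, ops_to_cigar, character(1), USE.NAMES = FALSE)
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Quality-control filtering of a read set
#'
#' Applies, in order: (1) removal of reads shorter than `min_length`;
#' (2) removal of reads whose exact base string occurs fewer than
#' `min_multiplicity` times in the remaining set; (3) removal of reads whose
#' best local alignment score against every reference (wild and mutant) is
#' below the alignability floor `min_score`.
#'
#' @param reads Read-set tibble.
#' @param refs A [reference_set].
#' @param params A [qc_params].
#' @param scoring A [scoring_scheme].
#' @return A list with `reads` (the surviving tibble) and `report`
#'   (a tibble of reads removed and remaining per rule).
#' @export
qc_filter <- function(reads, refs, params = qc_params(),
                      scoring = scoring_scheme()) {
  n0 <- nrow(reads)
  r1 <- dplyr::filter(reads, nchar(.data$seq) >= params$min_length)
  mult <- table(r1$seq)
  r2 <- dplyr::filter(r1, mult[.data$seq] >= params$min_multiplicity)
  ref_chr <- c(refs$templates$wild_ref, refs$templates$mutant_ref)
  useq <- unique(r2$seq)
  if (length(useq)) {
    sc <- score_unique(useq, ref_chr, scoring)
    bst <- setNames(apply(sc, 1L, max), useq)
    r3 <- dplyr::filter(r2, bst[.data$seq] >= params$min_score)
  } else {
    r3 <- r2
  }
  report <- tibble(
    rule = c("min_length", "min_multiplicity", "alignability"),
    removed = c(n0 - nrow(r1), nrow(r1) - nrow(r2), nrow(r2) - nrow(r3)),
    remaining = c(nrow(r1), nrow(r2), nrow(r3)))
  list(reads = r3, report = report)
}
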