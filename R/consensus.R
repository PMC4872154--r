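pileup_tally <- function(alignments, ref_len, edge_mask = 0L) {
  if (nrow(alignments) == 0L) {
    return(list(tally = matrix(0, ref_len, 5,
                               dimnames = list(NULL, c("A", "C", "G", "T", "del"))),
                insertions = 0, aligned_bases = 0))
  }
  # collapse identical (seq, ops, ref_start) rows and pile up with weights
  key <- paste(alignments$seq, alignments$ops, alignments$ref_start)
  u <- !duplicated(key)
  w <- as.numeric(table(key)[key[u]])
  pl <- pileup_cpp(alignments$ops[u], alignments$ref_start[u],
                   alignments$seq[u], alignments$read_start[u], w, ref_len,
                   edge_mask)
  colnames(pl$tally) <- c("A", "C", "G", "T", "del")
  pl
}

#' Majority-vote consensus from alignments
#'
#' Builds per-position tallies over A/C/G/T/deletion from the aligned columns
#' of every read, calls the most frequent symbol at each covered position
#' (ties broken toward the reference base, then in the fixed symbol order
#' A, C, G, T, deletion), and scores the consensus against the reference.
#' Identity is the fraction of reference positions with coverage at least
#' `min_coverage` whose consensus symbol equals the reference base; a
#' consensus deletion counts as an error. Insertions do not enter the
#' per-position tallies.
#'
#' @param alignments Alignment tibble from [align_reads()], already
#'   restricted to one reference.
#' @param reference The reference sequence the alignments refer to.
#' @param min_coverage Minimum coverage for a position to be called (default
#'   1).
#' @param identity_min_frac The reported `identity` is evaluated over the
#'   well-covered zone: positions whose coverage is at least this fraction
#'   of the maximum coverage (default 0.5). With a fixed cycle budget every
#'   error-free read of a template ends at the same reference position, so
#'   positions past that point are reached only by deletion-carrying reads
#'   and carry no usable consensus evidence; at full instrument scale every
#'   reported position is deeply mapped. The literal all-covered-positions
#'   identity is also returned as `identity_all_covered`.
#' @param tie Tie-break policy: `"reference"` (default) or `"lexicographic"`.
#' @return An object of class `consensus_result`.
#' @export
consensus <- function(alignments, reference, min_coverage = 1,
                      identity_min_frac = 0.5,
                      tie = c("reference", "lexicographic")) {
  tie <- match.arg(tie)
  if (nrow(alignments) == 0L) abort("no alignments supplied")
  check_dna(reference, "reference")
  L <- nchar(reference)
  pl <- pileup_tally(alignments, L)
  tally <- pl$tally
  cov <- rowSums(tally)
  ref_bases <- strsplit(reference, "")[[1]]
  symbols <- c("A", "C", "G", "T", "del")
  call <- character(L)
  for (i in seq_len(L)) {
    if (cov[i] < min_coverage || cov[i] == 0) {
      call[i] <- NA_character_
      next
    }
    mx <- max(tally[i, ])
    top <- symbols[tally[i, ] == mx]
    if (tie == "reference" && ref_bases[i] %in% top) {
      call[i] <- ref_bases[i]
    } else {
      call[i] <- top[1L]
    }
  }
  covered <- !is.na(call)
  well <- covered & cov >= identity_min_frac * max(cov)
  identity <- if (any(well)) mean(call[well] == ref_bases[well]) else NA_real_
  identity_all <- if (any(covered))
    mean(call[covered] == ref_bases[covered]) else NA_real_
  structure(list(
    tally = as_tibble(cbind(tibble(pos = seq_len(L) - 1L,
                                   ref = ref_bases, coverage = cov),
                            as_tibble(tally))),
    consensus = paste(ifelse(is.na(call), "N",
                             ifelse(call == "del", "-", call)), collapse = ""),
    call = call,
    identity = identity,
    identity_all_covered = identity_all,
    n_covered = sum(covered),
    n_well_covered = sum(well),
    reference = reference),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d/%d positions covered, identity %.4f\n",
              x$n_covered, nchar(x$reference), x$identity))
  cat(" consensus:", x$consensus, "\n")
  invisible(x)
}

#' Per-position error profile from alignments
#'
#' The error rate of a position is the number of reads disagreeing with the
#' reference there (substitution or deletion) divided by the reads covering
#' it; overall rates are means of the per-position rates over covered
#' positions. Insertions do not occupy reference positions and are reported
#' separately as events per aligned read base.
#'
#' @inheritParams consensus
#' @param edge_mask Number of reference-consuming alignment columns excluded
#'   from rate estimation at each end of every read's alignment (default 2).
#'   A local alignment keeps a terminal error only when enough matching
#'   columns follow it, so read-end columns systematically under-report
#'   errors; interior columns are unbiased.
#' @param min_coverage_frac Positions enter the overall (per-position mean)
#'   rates only when their masked coverage is at least this fraction of the
#'   maximum masked coverage (default 0.5). This restricts the overall rates
#'   to the well-covered read landing zone, the regime in which every
#'   reported position of a full-scale run is deeply covered; sparsely
#'   covered tail positions would otherwise dominate the position mean with
#'   coverage-1 noise.
#' @return An object of class `error_profile` with a per-position tibble and
#'   overall rates.
#' @export
error_profile <- function(alignments, reference, edge_mask = 2L,
                          min_coverage_frac = 0.5) {
  check_dna(reference, "reference")
  L <- nchar(reference)
  pl <- pileup_tally(alignments, L)
  plm <- pileup_tally(alignments, L, edge_mask = edge_mask)
  cov <- rowSums(pl$tally)
  mtal <- plm$tally
  mcov <- rowSums(mtal)
  ref_bases <- strsplit(reference, "")[[1]]
  ref_idx <- match(ref_bases, c("A", "C", "G", "T"))
  agree <- mtal[cbind(seq_len(L), ref_idx)]
  sub <- rowSums(mtal[, 1:4, drop = FALSE]) - agree
  del <- mtal[, 5L]
  per_pos <- tibble(pos = seq_len(L) - 1L, ref = ref_bases, coverage = cov,
                    masked_coverage = mcov, n_sub = sub, n_del = del,
                    sub_rate = ifelse(mcov > 0, sub / mcov, NA_real_),
                    del_rate = ifelse(mcov > 0, del / mcov, NA_real_))
  well <- mcov >= min_coverage_frac * max(mcov) & mcov > 0
  structure(list(
    per_position = per_pos,
    overall_sub_rate = mean(per_pos$sub_rate[well]),
    overall_del_rate = mean(per_pos$del_rate[well]),
    insertion_rate = if (pl$aligned_bases > 0) pl$insertions / pl$aligned_bases else NA_real_,
    aligned_bases = pl$aligned_bases,
    masked_aligned_bases = plm$aligned_bases,
    n_well_covered = sum(well),
    n_uncovered = sum(cov == 0),
    reference = reference),
    class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(paste0("<error_profile> substitution %.4f%%, deletion %.4f%%",
                     " per base (position means), insertion %.4f%% per aligned base\n"),
              100 * x$overall_sub_rate, 100 * x$overall_del_rate,
              100 * x$insertion_rate))
  invisible(x)
}

# smallest subsample size whose own mean coverage (aligned columns per
# covered position) reaches the requested depth, estimated by Monte Carlo
reads_for_depth <- function(ref_start, ref_end, depth, n_trials = 40L) {
  n_total <- length(ref_start)
  est <- function(n) {
    mean(vapply(seq_len(n_trials), function(t) {
      idx <- sample.int(n_total, n)
      cov <- integer(max(ref_end))
      for (i in idx) {
        if (ref_end[i] > ref_start[i]) {
          rng <- (ref_start[i] + 1L):ref_end[i]
          cov[rng] <- cov[rng] + 1L
        }
      }
      sum(cov) / max(1L, sum(cov > 0))
    }, numeric(1)))
  }
  n <- max(1L, as.integer(floor(depth)))
  while (n < n_total && est(n) < depth) n <- n + 1L
  as.integer(n)
}

#' Consensus accuracy versus coverage depth (sampling-subsampling)
#'
#' For each requested depth `d`, reads are repeatedly subsampled without
#' replacement to a subsample size whose own mean coverage is `d`, the
#' majority-vote consensus is recomputed per subsample, and accuracy is the
#' fraction of correct consensus calls among position-replicate instances
#' whose realized coverage in that subsample equals `d`. Conditioning on
#' realized per-position coverage reflects how accuracy is read off a
#' coverage-accuracy curve: reads all start at the capture probe, so a
#' subsample's coverage profile is front-loaded and its nominal mean depth
#' alone would mix very different per-position depths. Note that majority
#' voting with reference-preferring ties makes accuracy slightly
#' parity-dependent (a 1-1 split at depth 2 falls back to the reference),
#' so accuracy is monotone in depth along odd depths rather than between
#' adjacent even/odd pairs.
#'
#' @inheritParams consensus
#' @param depths Integer vector of coverage depths to report (default
#'   1, 2, 3, 5, 10).
#' @param n_reps Subsampling replicates per subsample size (default 50).
#' @param seed Integer seed.
#' @return An object of class `accuracy_curve`: a tibble with `depth`,
#'   `mean_identity`, `n_instances`, `n_reps`.
#' @export
subsample_accuracy <- function(alignments, reference,
                               depths = c(1, 2, 3, 5, 10), n_reps = 50L,
                               seed = 1L) {
  if (nrow(alignments) == 0L) abort("no alignments supplied")
  depths <- sort(unique(as.integer(depths)))
  ref_bases <- strsplit(reference, "")[[1]]
  with_seed(seed, {
    sizes <- vapply(depths, function(d) {
      reads_for_depth(alignments$ref_start, alignments$ref_end, d)
    }, integer(1))
    if (any(sizes > nrow(alignments))) {
      abort("requested depth exceeds the available coverage")
    }
    rows <- purrr::map2(depths, sizes, function(d, n_sub) {
      hits <- 0; total <- 0
      for (r in seq_len(n_reps)) {
        sub <- alignments[sample.int(nrow(alignments), n_sub), ]
        cs <- consensus(sub, reference, identity_min_frac = 0)
        cov <- cs$tally$coverage
        ok <- !is.na(cs$call) & cov == d
        hits <- hits + sum(cs$call[ok] == ref_bases[ok])
        total <- total + sum(ok)
      }
      tibble(depth = d, mean_identity = hits / total, n_instances = total,
             n_reps = n_reps)
    })
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("accuracy_curve", class(out)), seed = seed)
  })
}
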