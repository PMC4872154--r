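#' Classify a read as wild-type or mutant by dual-reference alignment
#'
#' The read is locally aligned to the wild-type and the mutant reference; if
#' the wild-type score is strictly higher the read is called wild type,
#' otherwise mutant. Under this literal rule ties go to mutant, which biases
#' the estimated mutant frequency upward (reads not reaching the variant
#' site score equally against both references); `tie = "drop"` removes tied
#' reads instead.
#'
#' @param read A read sequence.
#' @param wild_ref,mutant_ref Reference sequences.
#' @param scoring A [scoring_scheme].
#' @param tie `"mutant"` (literal rule, default) or `"drop"`.
#' @return A one-row tibble: `score_wild`, `score_mutant`, `label`.
#' @export
classify_read <- function(read, wild_ref, mutant_ref,
                          scoring = scoring_scheme(),
                          tie = c("mutant", "drop")) {
  tie <- match.arg(tie)
  sc <- score_unique(read, c(wild_ref, mutant_ref), scoring)
  label <- if (sc[1] > sc[2]) "wild" else if (sc[1] < sc[2]) "mutant" else
    if (tie == "mutant") "mutant" else NA_character_
  tibble(score_wild = sc[1], score_mutant = sc[2], label = label)
}

# vectorised classification of many reads against one template pair
classify_seqs <- function(seqs, wild_ref, mutant_ref, scoring, tie) {
  useq <- unique(seqs)
  sc <- score_unique(useq, c(wild_ref, mutant_ref), scoring)
  lab <- ifelse(sc[, 1] > sc[, 2], "wild",
                ifelse(sc[, 1] < sc[, 2], "mutant",
                       if (tie == "mutant") "mutant" else NA_character_))
  tibble(seq = seqs,
         score_wild = sc[match(seqs, useq), 1],
         score_mutant = sc[match(seqs, useq), 2],
         label = lab[match(seqs, useq)])
}

#' Mutant-read frequencies in a mixture
#'
#' Assigns every read to its best-scoring template (by the maximum of the
#' wild and mutant scores; cross-template ties dropped), classifies it as
#' wild or mutant by the dual-reference rule, and reports mutant frequencies
#' per template, per batch (field of view) and pooled.
#'
#' @param reads Read-set tibble (normally already QC-filtered).
#' @param refs A [reference_set].
#' @param scoring A [scoring_scheme].
#' @param batch_col Column of `reads` defining batches (default `"field"`).
#' @param tie Tie policy of [classify_read()].
#' @return An object of class `mixture_result` with tibbles `per_template`,
#'   `per_batch` (per template and batch), `batch_overall` (pooled over
#'   templates per batch) and the pooled frequency.
#' @export
mixture_frequencies <- function(reads, refs, scoring = scoring_scheme(),
                                batch_col = "field",
                                tie = c("mutant", "drop")) {
  tie <- match.arg(tie)
  tmpl <- refs$templates
  useq <- unique(reads$seq)
  sw <- score_unique(useq, tmpl$wild_ref, scoring)
  sm <- score_unique(useq, tmpl$mutant_ref, scoring)
  best_pair <- pmax(sw, sm)
  assigned <- max.col(best_pair, ties.method = "first")
  best <- best_pair[cbind(seq_along(useq), assigned)]
  n_top <- rowSums(best_pair == best)
  lab <- character(length(useq))
  for (i in seq_along(useq)) {
    if (n_top[i] > 1L) { lab[i] <- NA_character_; next } # ambiguous template
    w <- sw[i, assigned[i]]; m <- sm[i, assigned[i]]
    lab[i] <- if (w > m) "wild" else if (w < m) "mutant" else
      if (tie == "mutant") "mutant" else NA_character_
  }
  idx <- match(reads$seq, useq)
  calls <- tibble(read_id = reads$read_id,
                  batch = reads[[batch_col]],
                  template = tmpl$template[assigned][idx],
                  label = lab[idx])
  calls <- dplyr::filter(calls, !is.na(.data$label))
  per_template <- calls |>
    dplyr::count(.data$template, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (col in c("wild", "mutant")) {
    if (is.null(per_template[[col]])) per_template[[col]] <- 0L
  }
  per_template <- mutate(per_template,
                         n = .data$wild + .data$mutant,
                         frequency = .data$mutant / .data$n)
  per_batch <- calls |>
    group_by(.data$template, .data$batch) |>
    summarise(n = dplyr::n(), frequency = mean(.data$label == "mutant"),
              .groups = "drop")
  batch_overall <- calls |>
    group_by(.data$batch) |>
    summarise(n = dplyr::n(), frequency = mean(.data$label == "mutant"),
              .groups = "drop")
  structure(list(per_template = per_template, per_batch = per_batch,
                 batch_overall = batch_overall,
                 pooled_frequency = mean(calls$label == "mutant"),
                 n_effective = nrow(calls)),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> pooled mutant frequency %.4f over %d effective reads\n",
              x$pooled_frequency, x$n_effective))
  print(x$per_template)
  invisible(x)
}

#' Test a mixture against a pure wild-type control
#'
#' Two-sample two-tailed Student t-test (equal variances by default; Welch
#' with `var_equal = FALSE`) on per-batch mutant frequencies, per template
#' and pooled over templates.
#'
#' @param mixture,control `mixture_result` objects; the control is normally
#'   a pure wild-type run under identical conditions.
#' @param var_equal Classic equal-variance Student form (default TRUE).
#' @return A tibble with one row per template plus a `"(pooled)"` row:
#'   `template`, `mean_mixture`, `mean_control`, `t`, `df`, `p`.
#' @export
significance_test <- function(mixture, control, var_equal = TRUE) {
  one <- function(x, y, label) {
    if (length(x) < 2L || length(y) < 2L) {
      abort("need >= 2 batches per group; increase the number of fields")
    }
    tt <- tryCatch(t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL) # e.g. both groups constant
    tibble(template = label, mean_mixture = mean(x), mean_control = mean(y),
           t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
           p = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  shared <- intersect(unique(mixture$per_batch$template),
                      unique(control$per_batch$template))
  rows <- purrr::map(shared, function(tm) {
    one(mixture$per_batch$frequency[mixture$per_batch$template == tm],
        control$per_batch$frequency[control$per_batch$template == tm], tm)
  })
  pooled <- one(mixture$batch_overall$frequency,
                control$batch_overall$frequency, "(pooled)")
  dplyr::bind_rows(rows, list(pooled))
}

#' Scan mutant fractions for the detection limit
#'
#' Simulates one sequencing run per requested mutant fraction (plus the
#' mandatory pure wild-type control), applies QC, estimates per-batch mutant
#' frequencies, and tests each fraction against the control. The smallest
#' fraction with pooled p below `alpha` is reported.
#'
#' @param fractions Mutant fractions to test (0 is added as the control).
#' @param refs A [reference_set].
#' @param n_reads Molecules sequenced per group (default 2e5).
#' @param n_batches Fields of view per group (default 300).
#' @param protocol,errors,scoring,qc Run configuration.
#' @param alpha Significance level (default 0.05).
#' @param tie Tie policy of [classify_read()].
#' @param span_filter If TRUE, only reads whose best alignment covers the
#'   variant locus are classified (off by default, matching the literal
#'   procedure).
#' @param seed Integer seed.
#' @return An object of class `detection_scan`: tibble of fractions with
#'   pooled frequencies and p-values, plus the smallest significant fraction
#'   (`NA` if none).
#' @export
detection_limit_scan <- function(fractions, refs, n_reads = 2e5,
                                 n_batches = 300L,
                                 protocol = flow_protocol(),
                                 errors = error_model(),
                                 scoring = scoring_scheme(),
                                 qc = qc_params(), alpha = 0.05,
                                 tie = c("mutant", "drop"),
                                 span_filter = FALSE, seed = 1L) {
  tie <- match.arg(tie)
  fractions <- sort(unique(fractions), decreasing = TRUE)
  fr_all <- c(fractions, 0)
  results <- vector("list", length(fr_all))
  for (i in seq_along(fr_all)) {
    rd <- simulate_reads(refs, n_molecules = n_reads, mixture = fr_all[i],
                         n_fields = n_batches, protocol = protocol,
                         errors = errors, seed = seed + i)
    rd <- qc_filter(rd, refs, qc, scoring)$reads
    if (span_filter) rd <- filter_variant_spanning(rd, refs, scoring)
    results[[i]] <- mixture_frequencies(rd, refs, scoring, tie = tie)
  }
  control <- results[[length(fr_all)]]
  rows <- purrr::map2(fr_all[-length(fr_all)], results[-length(fr_all)],
                      function(f, mr) {
    st <- significance_test(mr, control)
    pooled <- st[st$template == "(pooled)", ]
    tibble(fraction = f, pooled_frequency = mr$pooled_frequency,
           control_frequency = control$pooled_frequency,
           t = pooled$t, p = pooled$p,
           significant = !is.na(pooled$p) && pooled$p < alpha)
  })
  tab <- dplyr::bind_rows(rows)
  smallest <- if (any(tab$significant)) min(tab$fraction[tab$significant]) else NA_real_
  structure(list(scan = tab, smallest_detected = smallest, alpha = alpha,
                 control = control, results = setNames(results, fr_all)),
            class = "detection_scan")
}

# keep reads whose best alignment (vs the assigned template's wild reference)
# covers the variant locus
filter_variant_spanning <- function(reads, refs, scoring) {
  al <- align_reads(reads, refs, scoring, use = "wild")
  tmpl <- refs$templates
  # variant position in read space: the wild reference offset of the variant
  ext_len <- nchar(tmpl$wild_ref)
  var_off <- ext_len - 1L - tmpl$position
  off <- var_off[match(al$template, tmpl$template)]
  keep <- al$ref_start <= off & al$ref_end > off
  reads[reads$read_id %in% al$read_id[keep], ]
}

#' @export
print.detection_scan <- function(x, ...) {
  cat(sprintf("<detection_scan> alpha = %g, smallest detected fraction: %s\n",
              x$alpha, ifelse(is.na(x$smallest_detected), "none",
                              format(x$smallest_detected))))
  print(x$scan)
  invisible(x)
}
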