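#' Write and read read sets as FASTA/FASTQ
#'
#' FASTQ qualities are a uniform placeholder (`I`): the platform emits no
#' per-base quality scores. Read ids encode molecule and field ids for
#' simulated reads.
#'
#' @param reads Read-set tibble (`read_id`, `seq`).
#' @param path Output file.
#' @return The path, invisibly (writers); a read-set tibble (readers).
#' @export
write_reads_fasta <- function(reads, path) {
  keep <- nzchar(reads$seq)
  x <- Biostrings::DNAStringSet(reads$seq[keep])
  names(x) <- reads$read_id[keep]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
write_reads_fastq <- function(reads, path) {
  keep <- nzchar(reads$seq)
  x <- Biostrings::DNAStringSet(reads$seq[keep])
  names(x) <- reads$read_id[keep]
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq[keep]),
                                     function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- tibble(read_id = names(x), seq = unname(as.character(x)))
  attr(out, "provenance") <- "file"
  out
}

#' @rdname write_reads_fasta
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- tibble(read_id = names(x), seq = unname(as.character(x)))
  attr(out, "provenance") <- "file"
  out
}

#' Write a reference set as FASTA plus a variant table
#'
#' One record per wild-type and mutant template plus `probe_`-prefixed probe
#' records; variant specifications go to a TSV sidecar named
#' `<path>.variants.tsv`.
#'
#' @param refs A [reference_set].
#' @param path FASTA output path.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  tm <- refs$templates
  seqs <- c(setNames(tm$wild, paste0(tm$template, "_wild")),
            setNames(tm$mutant, paste0(tm$template, "_mutant")))
  if (!is.null(refs$probes)) {
    seqs <- c(seqs, setNames(refs$probes$sequence, refs$probes$name))
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  utils::write.table(
    dplyr::select(tm, "template", "variant", "kind", "position", "alt_base",
                  "del_length"),
    paste0(path, ".variants.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export alignments as a minimal SAM file
#'
#' Header plus one line per aligned read; `POS` is 1-based, the CIGAR uses
#' `=`/`X`/`I`/`D` operations with soft clips for unaligned read ends.
#'
#' @param alignments Alignment tibble from [align_reads()].
#' @param refs A [reference_set] (for header lengths); wild references are
#'   used as the target sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignments_sam <- function(alignments, refs, path) {
  tm <- refs$templates
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_len(nrow(tm))) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tm$template[i],
                       nchar(tm$wild_ref[i])), con)
  }
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    lead <- a$read_start
    trail <- nchar(a$seq) - a$read_end
    cig <- paste0(if (lead > 0) paste0(lead, "S") else "",
                  ops_to_cigar(a$ops),
                  if (trail > 0) paste0(trail, "S") else "")
    writeLines(paste(a$read_id, 0L, a$template, a$ref_start + 1L, 255L, cig,
                     "*", 0L, 0L, a$seq, strrep("I", nchar(a$seq)),
                     sep = "\t"), con)
  }
  invisible(path)
}
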