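#' Describe a sequence variant carried by a mutant template
#'
#' @param name Variant identifier.
#' @param kind Either `"point"` (single-base substitution) or `"deletion"`.
#' @param position 0-based offset into the 70-nt wild-type template at which
#'   the variant starts.
#' @param alt_base Replacement base for point variants. `NA` lets
#'   [make_references()] draw a base different from the wild-type base.
#' @param del_length Deleted length in nucleotides (1--30) for deletions.
#' @return A one-row tibble.
#' @export
variant_spec <- function(name, kind = c("point", "deletion"), position,
                         alt_base = NA_character_, del_length = NA_integer_) {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (position < 0L) abort("`position` must be >= 0")
  if (kind == "deletion") {
    del_length <- as.integer(del_length)
    if (is.na(del_length) || del_length < 1L || del_length > 30L) {
      abort("`del_length` must be in 1..30 for deletion variants")
    }
  } else if (!is.na(alt_base)) {
    alt_base <- toupper(alt_base)
    if (!alt_base %in% BASES) abort("`alt_base` must be one of A/C/G/T")
  }
  tibble(name = name, kind = kind, position = position,
         alt_base = if (kind == "point") alt_base else NA_character_,
         del_length = if (kind == "deletion") del_length else NA_integer_)
}

#' Default panel of eight variants
#'
#' Six point mutations and two short deletions of 15 and 21 nt, mirroring a
#' drug-response panel of six substitutions plus two exon-19-style deletions
#' spanning five and seven codons. Positions are chosen so every variant sits
#' within the first few bases read from the capture probe.
#'
#' @return A tibble of eight variant specifications.
#' @export
default_variants <- function() {
  dplyr::bind_rows(
    variant_spec("snv_a", "point", 42L),
    variant_spec("snv_b", "point", 41L),
    variant_spec("snv_c", "point", 40L),
    variant_spec("snv_d", "point", 39L),
    variant_spec("snv_e", "point", 42L),
    variant_spec("snv_f", "point", 38L),
    variant_spec("del_15nt", "deletion", 25L, del_length = 15L),
    variant_spec("del_21nt", "deletion", 19L, del_length = 21L)
  )
}

apply_variant <- function(template, kind, position, alt_base, del_length) {
  n <- nchar(template)
  if (kind == "point") {
    if (position >= n) abort("variant position out of range")
    paste0(substr(template, 1L, position),
           alt_base,
           substr(template, position + 2L, n))
  } else {
    if (position + del_length > n) abort("variant position out of range")
    paste0(substr(template, 1L, position),
           substr(template, position + del_length + 1L, n))
  }
}

# extension reference in read space: the polymerase copies the template from
# the base 5' of the probe anchor toward the template 5' end, so the read-space
# reference is the reverse complement of the template minus its 3' anchor
extension_reference <- function(template, anchor_length) {
  n <- nchar(template)
  if (n <= anchor_length) abort("template shorter than probe anchor")
  revcomp(substr(template, 1L, n - anchor_length))
}

#' Generate a synthetic reference panel
#'
#' Builds `n_templates` wild-type 70-nt single-stranded target templates,
#' applies one variant to each to obtain the mutant version, and designs a
#' 60-nt capture probe per template (50 specific bases plus a dT10 linker).
#' The probe anchors the template's 3'-most `anchor_length` bases; its
#' remaining specific bases complement simulated gene context upstream of the
#' synthetic template, as in an assay where probes are designed against the
#' gene rather than the insert. Sequencing therefore proceeds from the anchor
#' into the template 5' region, and the read-space reference of each template
#' is the reverse complement of that region.
#'
#' Templates are drawn at random, with no two consecutive identical bases in
#' the first 12 read-space positions so that the first ~10 bases incorporate
#' without long homopolymer stalls under a 4-base flow order.
#'
#' @param n_templates Number of templates (default 8).
#' @param variants Tibble of variant specifications, one row per template
#'   (see [variant_spec()]; default [default_variants()]).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param template_length Wild-type template length (default 70).
#' @param anchor_length Template bases paired with the probe 3' end
#'   (default 25).
#' @return An object of class `reference_set`: a list with tibbles
#'   `templates` (wild/mutant template strings and read-space references) and
#'   `probes`, plus the seed.
#' @export
make_references <- function(n_templates = 8L, variants = default_variants(),
                            seed = 1L, template_length = 70L,
                            anchor_length = 25L) {
  n_templates <- as.integer(n_templates)
  if (n_templates < 1L) abort("`n_templates` must be >= 1")
  if (nrow(variants) != n_templates) {
    abort("`variants` must have exactly one row per template")
  }
  ext_len <- template_length - anchor_length
  with_seed(seed, {
    rows <- purrr::pmap(variants, function(name, kind, position, alt_base,
                                           del_length) {
      if (kind == "deletion" && position + del_length > template_length) {
        abort(sprintf("variant '%s': position out of range for a %d-nt template",
                      name, template_length))
      }
      if (kind == "point" && position >= template_length) {
        abort(sprintf("variant '%s': position out of range for a %d-nt template",
                      name, template_length))
      }
      # draw the read-space reference, then fold back into the template
      ref <- sample(BASES, ext_len, replace = TRUE)
      for (k in 2:min(12L, ext_len)) {
        while (ref[k] == ref[k - 1L]) ref[k] <- sample(BASES, 1L)
      }
      ref <- paste(ref, collapse = "")
      anchor <- rand_bases(anchor_length)
      wild <- paste0(revcomp(ref), anchor)
      if (kind == "point") {
        wt_base <- substr(wild, position + 1L, position + 1L)
        if (is.na(alt_base)) alt_base <- sample(setdiff(BASES, wt_base), 1L)
        if (alt_base == wt_base) {
          abort(sprintf("variant '%s': alt_base equals the wild-type base", name))
        }
      }
      mut <- apply_variant(wild, kind, position, alt_base, del_length)
      context <- rand_bases(anchor_length)
      gene <- paste0(wild, context)
      specific <- revcomp(substr(gene, template_length - anchor_length + 1L,
                                 template_length - anchor_length + 50L))
      probe <- paste0(strrep("T", 10L), specific)
      tibble(template = sprintf("tmpl%02d", 0L), variant = name, kind = kind,
             position = position, alt_base = alt_base, del_length = del_length,
             wild = wild, mutant = mut,
             wild_ref = extension_reference(wild, anchor_length),
             mutant_ref = extension_reference(mut, anchor_length),
             probe = probe)
    })
    templates <- dplyr::bind_rows(rows)
    templates$template <- sprintf("tmpl%02d", seq_len(n_templates))
    probes <- tibble(name = paste0("probe_", templates$template),
                     template = templates$template,
                     sequence = templates$probe)
    templates$probe <- NULL
    reference_set(templates, probes, seed = seed)
  })
}

#' Construct a reference set from tables
#'
#' Low-level constructor, mainly useful for hand-built panels and tests.
#'
#' @param templates Tibble with at least columns `template`, `wild_ref` and
#'   `mutant_ref` (read-space reference strings).
#' @param probes Optional probe tibble (`name`, `template`, `sequence`).
#' @param seed Seed recorded for provenance.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(templates, probes = NULL, seed = NA_integer_) {
  stopifnot(is.data.frame(templates),
            all(c("template", "wild_ref", "mutant_ref") %in% names(templates)))
  check_dna(templates$wild_ref, "wild_ref")
  check_dna(templates$mutant_ref, "mutant_ref")
  if (anyDuplicated(templates$template)) abort("template names must be unique")
  structure(list(templates = as_tibble(templates),
                 probes = if (is.null(probes)) NULL else as_tibble(probes),
                 seed = seed),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d templates (%d point, %d deletion variants)\n",
              nrow(x$templates), sum(x$templates$kind == "point", na.rm = TRUE),
              sum(x$templates$kind == "deletion", na.rm = TRUE)))
  print(dplyr::select(x$templates, "template", "variant", "kind", "position"))
  invisible(x)
}

# named list template -> c(wild = ..., mutant = ...) read-space references
reference_lookup <- function(refs) {
  setNames(purrr::map2(refs$templates$wild_ref, refs$templates$mutant_ref,
                       function(w, m) c(wild = w, mutant = m)),
           refs$templates$template)
}

#' Check a capture probe against design rules
#'
#' Computes the GC fraction and a basic GC-content melting temperature,
#' `Tm = 64.9 + 41 * (#GC - 16.4) / length` (degrees C), and tests the design
#' rules: GC fraction within 20--80% and Tm above 65 degrees C.
#'
#' @param probe Character vector of probe sequences over A/C/G/T.
#' @return A tibble with one row per probe: `probe`, `gc_fraction`, `tm`,
#'   `passes`.
#' @export
check_probe <- function(probe) {
  probe <- toupper(probe)
  check_dna(probe, "probe")
  n <- nchar(probe)
  if (any(n == 0L)) abort("probes must be non-empty")
  gc <- vapply(strsplit(probe, ""), function(b) sum(b %in% c("G", "C")),
               numeric(1))
  gc_fraction <- gc / n
  tm <- 64.9 + 41 * (gc - 16.4) / n
  tibble(probe = probe, gc_fraction = gc_fraction, tm = tm,
         passes = gc_fraction >= 0.20 & gc_fraction <= 0.80 & tm > 65)
}
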