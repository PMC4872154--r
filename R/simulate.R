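#' Place molecules on simulated fields of view
#'
#' The number of molecules per field is Poisson with mean
#' `density * fov area`; molecules are grouped into surface sites whose
#' occupancy (1, 2, or a cluster of 3+) is drawn from the geometry's
#' occupancy fractions, and each site receives a uniformly random position
#' inside the field. Each molecule is assigned a template uniformly and a
#' wild/mutant origin label from `mixture`.
#'
#' @param refs A [reference_set].
#' @param geometry A [field_geometry].
#' @param mixture Mutant fraction per template: a single number applied to
#'   all templates, or a named vector keyed by template name. Default 0
#'   (pure wild type).
#' @param n_fields Number of fields of view to populate.
#' @param seed Integer seed.
#' @return A tibble with one row per molecule: `field`, `site`, `molecule`,
#'   `x`, `y` (0-based pixel coordinates, continuous), `occupancy`,
#'   `template`, `origin`.
#' @export
place_molecules <- function(refs, geometry = field_geometry(), mixture = 0,
                            n_fields = 1L, seed = 1L) {
  if (geometry$density <= 0) abort("`density` must be > 0")
  area <- prod(geometry$fov_um)
  mean_n <- geometry$density * area
  mix <- mixture_fractions(refs, mixture)
  with_seed(seed, {
    fields <- purrr::map(seq_len(n_fields), function(f) {
      n_mol <- rpois(1L, mean_n)
      if (n_mol == 0L) return(NULL)
      # draw site occupancies until they hold all molecules
      occ <- integer(0)
      while (sum(occ) < n_mol) {
        k <- sample(c(1L, 2L, 3L), 64L, replace = TRUE,
                    prob = c(geometry$frac_single, geometry$frac_pair,
                             geometry$frac_cluster))
        k[k == 3L] <- 3L + rpois(sum(k == 3L), 0.3)
        occ <- c(occ, k)
      }
      cum <- cumsum(occ)
      n_sites <- which(cum >= n_mol)[1L]
      occ <- occ[seq_len(n_sites)]
      occ[n_sites] <- occ[n_sites] - (cum[n_sites] - n_mol)
      if (occ[n_sites] == 0L) {
        occ <- occ[-n_sites]
        n_sites <- n_sites - 1L
      }
      m <- geometry$margin_px
      x <- runif(n_sites, m, geometry$pixels[1] - 1 - m)
      y <- runif(n_sites, m, geometry$pixels[2] - 1 - m)
      site <- seq_len(n_sites)
      tibble(field = f,
             site = rep(site, occ),
             x = rep(x, occ), y = rep(y, occ),
             occupancy = rep(occ, occ))
    })
    mols <- dplyr::bind_rows(fields)
    mols$molecule <- seq_len(nrow(mols))
    tname <- refs$templates$template
    mols$template <- sample(tname, nrow(mols), replace = TRUE)
    mols$origin <- ifelse(runif(nrow(mols)) < mix[mols$template],
                          "mutant", "wild")
    dplyr::select(mols, "field", "site", "molecule", "x", "y", "occupancy",
                  "template", "origin")
  })
}

mixture_fractions <- function(refs, mixture) {
  tname <- refs$templates$template
  if (is.null(names(mixture))) {
    if (length(mixture) != 1L) {
      abort("`mixture` must be a single fraction or a named vector")
    }
    mix <- setNames(rep(mixture, length(tname)), tname)
  } else {
    mix <- setNames(rep(0, length(tname)), tname)
    if (!all(names(mixture) %in% tname)) {
      abort("`mixture` names must be template names")
    }
    mix[names(mixture)] <- mixture
  }
  if (any(mix < 0 | mix > 1)) abort("mutant fractions must be in [0, 1]")
  mix
}

#' Simulate per-cycle incorporation events
#'
#' For each molecule and cycle: if the flowed base equals the next due base
#' of the molecule's read-space reference, the outcome is
#' `incorporated_correct` with probability `1 - p_sub - p_del`,
#' `incorporated_wrong` (a uniformly drawn non-true base is recorded) with
#' probability `p_sub`, or `missed` with probability `p_del`; a missed base
#' is skipped permanently, producing a deletion in the read. At non-matching
#' cycles a `spurious` signal (an insertion recording the flowed base)
#' occurs with probability `p_ins`, else the outcome is `none`.
#'
#' @param molecules Molecule tibble from [place_molecules()] (or any tibble
#'   with `molecule`, `template`, `origin`).
#' @param refs A [reference_set].
#' @param protocol A [flow_protocol].
#' @param errors An [error_model].
#' @param seed Integer seed.
#' @return A tibble with one row per molecule and cycle: `molecule`, `cycle`,
#'   `flow_base`, `outcome`, `read_base` (NA when nothing is recorded).
#' @export
simulate_events <- function(molecules, refs, protocol = flow_protocol(),
                            errors = error_model(), seed = 1L) {
  tmpl <- refs$templates
  if (!all(molecules$template %in% tmpl$template)) {
    abort("molecule templates missing from the reference set")
  }
  key <- paste(molecules$template, molecules$origin)
  ref_by_key <- c(setNames(tmpl$wild_ref, paste(tmpl$template, "wild")),
                  setNames(tmpl$mutant_ref, paste(tmpl$template, "mutant")))
  ukey <- unique(key)
  seqs <- ref_by_key[ukey]
  maxlen <- max(nchar(seqs))
  base_mat <- matrix(NA_character_, nrow = length(ukey), ncol = maxlen)
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[[i]], "")[[1]]
    base_mat[i, seq_along(b)] <- b
  }
  kidx <- match(key, ukey)
  n <- nrow(molecules)
  nc <- protocol$n_cycles
  with_seed(seed, {
    ptr <- rep(0L, n) # bases already consumed from the reference
    out_outcome <- matrix("none", nrow = n, ncol = nc)
    out_base <- matrix(NA_character_, nrow = n, ncol = nc)
    for (cyc in seq_len(nc)) {
      fb <- flow_base(protocol, cyc)
      due <- base_mat[cbind(kidx, pmin(ptr + 1L, maxlen))]
      due[ptr + 1L > nchar(seqs[kidx])] <- NA_character_
      matched <- !is.na(due) & due == fb
      u <- runif(n)
      wrong <- matched & u < errors$p_sub
      missed <- matched & !wrong & u < errors$p_sub + errors$p_del
      correct <- matched & !wrong & !missed
      spur <- !matched & runif(n) < errors$p_ins
      out_outcome[correct, cyc] <- "incorporated_correct"
      out_outcome[wrong, cyc] <- "incorporated_wrong"
      out_outcome[missed, cyc] <- "missed"
      out_outcome[spur, cyc] <- "spurious"
      out_base[correct, cyc] <- fb
      if (any(wrong)) {
        others <- setdiff(BASES, fb)
        out_base[wrong, cyc] <- sample(others, sum(wrong), replace = TRUE)
      }
      out_base[spur, cyc] <- fb
      ptr <- ptr + as.integer(matched)
    }
    tibble(molecule = rep(molecules$molecule, each = nc),
           cycle = rep(seq_len(nc), times = n),
           flow_base = flow_base(protocol, rep(seq_len(nc), times = n)),
           outcome = as.vector(t(out_outcome)),
           read_base = as.vector(t(out_base)))
  })
}

#' Convert incorporation events to reads
#'
#' Each molecule's read is the concatenation, in cycle order, of the recorded
#' base of every incorporated (correct or wrong) and spurious event; missed
#' events and empty cycles contribute nothing.
#'
#' @param events Event tibble from [simulate_events()].
#' @param molecules Optional molecule tibble; when given, field/template/
#'   origin truth columns are carried onto the reads.
#' @return A read-set tibble: `read_id`, `seq`, `molecule`, plus truth
#'   columns when available, with attribute `provenance = "simulated"`.
#' @export
events_to_reads <- function(events, molecules = NULL) {
  ev <- dplyr::arrange(events, .data$molecule, .data$cycle)
  mols <- unique(ev$molecule)
  nc <- max(ev$cycle)
  m <- matrix(ifelse(is.na(ev$read_base), "", ev$read_base),
              ncol = nc, byrow = TRUE)
  seqs <- do.call(paste0, asplit(m, 2L))
  reads <- tibble(molecule = mols, seq = seqs)
  if (!is.null(molecules)) {
    keep <- intersect(c("molecule", "field", "site", "occupancy", "template",
                        "origin"), names(molecules))
    reads <- left_join(reads, molecules[, keep], by = "molecule")
  }
  if (!"field" %in% names(reads)) reads$field <- 1L
  reads$read_id <- sprintf("r%07d_f%04d", reads$molecule, reads$field)
  reads <- dplyr::select(reads, "read_id", "seq", dplyr::everything())
  attr(reads, "provenance") <- "simulated"
  reads
}

#' Simulate a read set directly (no imaging)
#'
#' Fast path that skips image rendering: draws `n_molecules` molecules (each
#' on its own site, assigned round-robin to `n_fields` fields), simulates
#' per-cycle events and decodes reads.
#'
#' @param refs A [reference_set].
#' @param n_molecules Number of molecules to sequence.
#' @param mixture Mutant fraction (scalar or named per-template vector).
#' @param n_fields Number of fields used as batch labels.
#' @param protocol A [flow_protocol].
#' @param errors An [error_model].
#' @param seed Integer seed.
#' @return A read-set tibble (see [events_to_reads()]).
#' @export
simulate_reads <- function(refs, n_molecules, mixture = 0, n_fields = 1L,
                           protocol = flow_protocol(), errors = error_model(),
                           seed = 1L) {
  mix <- mixture_fractions(refs, mixture)
  with_seed(seed, {
    tname <- refs$templates$template
    mols <- tibble(
      field = rep_len(seq_len(n_fields), n_molecules),
      site = seq_len(n_molecules),
      molecule = seq_len(n_molecules),
      occupancy = 1L,
      template = sample(tname, n_molecules, replace = TRUE))
    mols$origin <- ifelse(runif(n_molecules) < mix[mols$template],
                          "mutant", "wild")
    ev <- simulate_events(mols, refs, protocol, errors, seed = NULL)
    events_to_reads(ev, mols)
  })
}
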