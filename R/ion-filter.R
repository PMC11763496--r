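# Ion-selection rules and common/distinctive ion profiling.
#
# The biotyping workflow keeps ions above an abundance threshold (printed
# peak lists are truncated at 10% of the base peak), asks which ions recur
# across extracts, which are shared by two strains grown under the same
# (medium, period, polarity) conditions, and which are unique to one strain.

#' Filter peaks by relative abundance
#'
#' Keeps peaks with \code{rel_abundance >= min_rel}; row order is preserved.
#' An empty result is allowed.
#'
#' @param x a \code{peak_table}.
#' @param min_rel abundance threshold in percent (>= 0).
#' @return the filtered \code{peak_table}.
#' @export
filter_by_abundance <- function(x, min_rel) {
  stopifnot(inherits(x, "peak_table"))
  min_rel <- as.numeric(min_rel)
  if (is.na(min_rel) || min_rel < 0) stop("min_rel must be >= 0")
  keep <- x$rel_abundance >= min_rel
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(x), truncated = attr(x, "truncated"))
}

#' Ions recurring across a strain's extracts
#'
#' Counts, per (m/z, polarity), the number of distinct (medium, period,
#' polarity) extracts of one strain in which the ion was detected, and keeps
#' ions occurring at least \code{min_count} times. Counting is
#' polarity-specific: the same nominal m/z seen in positive and negative
#' mode is two different ions.
#'
#' @param x a \code{peak_table} holding a single strain.
#' @param min_count minimum occurrence count (>= 1).
#' @return data.frame of class \code{ion_occurrence}: one row per occurrence
#'   (columns \code{mz}, \code{polarity}, \code{medium}, \code{period_days},
#'   \code{rel_abundance}, \code{n_occurrences}), sorted by polarity, m/z,
#'   medium and period.
#' @export
recurrent_ions <- function(x, min_count = 2L) {
  stopifnot(inherits(x, "peak_table"))
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  if (length(unique(x$strain)) > 1L) {
    stop("recurrent_ions expects spectra from a single strain; got: ",
         paste(unique(x$strain), collapse = ", "))
  }
  ion <- paste(x$polarity, x$mz)
  counts <- table(ion)
  x$n_occurrences <- as.integer(counts[ion])
  out <- x[x$n_occurrences >= min_count,
           c("mz", "polarity", "medium", "period_days", "rel_abundance",
             "n_occurrences")]
  out <- out[order(factor(out$polarity, levels = POLARITIES), out$mz,
                   factor(out$medium, levels = MEDIA), out$period_days), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ion_occurrence", "data.frame")
  out
}

#' @keywords internal
split_two_strains <- function(a, b) {
  stopifnot(inherits(a, "peak_table"), inherits(b, "peak_table"))
  sa <- unique(a$strain)
  sb <- unique(b$strain)
  if (length(sa) != 1L || length(sb) != 1L) {
    stop("each input must hold exactly one strain")
  }
  if (sa == sb) stop("the two inputs hold the same strain: ", sa)
  cells_a <- unique(peak_cell_key(a, with_strain = FALSE))
  cells_b <- unique(peak_cell_key(b, with_strain = FALSE))
  miss_a <- setdiff(cells_b, cells_a)
  miss_b <- setdiff(cells_a, cells_b)
  if (length(miss_a) > 0L || length(miss_b) > 0L) {
    stop("the two strains do not cover the same extract grid; missing from ",
         sa, ": ", paste(miss_a, collapse = ", "), "; missing from ",
         sb, ": ", paste(miss_b, collapse = ", "))
  }
  list(strain_a = sa, strain_b = sb, cells = sort(cells_a))
}

#' Ions common to two strains per culture condition
#'
#' For every (medium, period, polarity) cell of the culture grid, intersects
#' the two strains' m/z sets and attaches both relative abundances. The
#' recurrence rule — a common ion must have been detected at least
#' \code{min_occurrences} times across the different extracts — is applied on
#' top of the intersection. With \code{occurrence_scope = "pooled"}
#' (default), occurrences are counted over both strains' extracts together,
#' so any same-cell co-occurrence already satisfies the default threshold of
#' 2; with \code{"per_strain"} each strain must separately reach the
#' threshold, a strictly harsher reading that prunes ions seen only once in
#' one of the strains.
#'
#' @param a,b \code{peak_table}s for the two strains, covering the same
#'   (medium, period, polarity) grid.
#' @param min_occurrences minimum detection count (>= 1).
#' @param occurrence_scope \code{"pooled"} or \code{"per_strain"}.
#' @return data.frame of class \code{common_ion_table}: columns
#'   \code{medium}, \code{period_days}, \code{polarity}, \code{mz},
#'   \code{abundance_a}, \code{abundance_b}, sorted by medium, period,
#'   polarity and m/z; attribute \code{strains} names the two strains.
#' @export
common_ions <- function(a, b, min_occurrences = 2L,
                        occurrence_scope = c("pooled", "per_strain")) {
  occurrence_scope <- match.arg(occurrence_scope)
  info <- split_two_strains(a, b)
  min_occurrences <- as.integer(min_occurrences)
  if (is.na(min_occurrences) || min_occurrences < 1L) {
    stop("min_occurrences must be >= 1")
  }
  ion_a <- paste(a$polarity, a$mz)
  ion_b <- paste(b$polarity, b$mz)
  if (occurrence_scope == "pooled") {
    pooled <- table(c(ion_a, ion_b))
    ok_a <- pooled[ion_a] >= min_occurrences
    ok_b <- pooled[ion_b] >= min_occurrences
  } else {
    ta <- table(ion_a)
    tb <- table(ion_b)
    ok_a <- ta[ion_a] >= min_occurrences & ion_a %in% names(tb)[tb >= min_occurrences]
    ok_b <- tb[ion_b] >= min_occurrences & ion_b %in% names(ta)[ta >= min_occurrences]
  }
  fa <- a[ok_a, , drop = FALSE]
  fb <- b[ok_b, , drop = FALSE]
  key_a <- paste(peak_cell_key(fa, with_strain = FALSE), fa$mz)
  key_b <- paste(peak_cell_key(fb, with_strain = FALSE), fb$mz)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  out <- data.frame(
    medium = fa$medium[ia],
    period_days = fa$period_days[ia],
    polarity = fa$polarity[ia],
    mz = fa$mz[ia],
    abundance_a = fa$rel_abundance[ia],
    abundance_b = fb$rel_abundance[ib],
    stringsAsFactors = FALSE
  )
  out <- out[order(factor(out$medium, levels = MEDIA), out$period_days,
                   factor(out$polarity, levels = POLARITIES), out$mz), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("common_ion_table", "data.frame"),
            strains = c(info$strain_a, info$strain_b))
}

#' Ions unique to each strain per culture condition
#'
#' Per (medium, period, polarity) cell, the set differences of the two
#' strains' m/z sets.
#'
#' @inheritParams common_ions
#' @return data.frame of class \code{distinctive_ion_table}: columns
#'   \code{strain}, \code{medium}, \code{period_days}, \code{polarity},
#'   \code{mz}, \code{rel_abundance}; one row per ion unique to that strain
#'   in that cell.
#' @export
distinctive_ions <- function(a, b) {
  info <- split_two_strains(a, b)
  key_a <- paste(peak_cell_key(a, with_strain = FALSE), a$mz)
  key_b <- paste(peak_cell_key(b, with_strain = FALSE), b$mz)
  only_a <- a[!key_a %in% key_b, , drop = FALSE]
  only_b <- b[!key_b %in% key_a, , drop = FALSE]
  out <- rbind(as.data.frame(only_a), as.data.frame(only_b))
  out <- out[, c("strain", "medium", "period_days", "polarity", "mz",
                 "rel_abundance")]
  out <- out[order(out$strain, factor(out$medium, levels = MEDIA),
                   out$period_days, factor(out$polarity, levels = POLARITIES),
                   out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("distinctive_ion_table", "data.frame"),
            strains = c(info$strain_a, info$strain_b))
}

#' Select precursor ions for MS/MS follow-up
#'
#' Deduplicated (m/z, polarity) pairs attaining at least \code{min_rel}
#' relative abundance in at least one extract, each reported with the
#' maximal observed abundance and the extract where it was attained (ties
#' broken by canonical strain/medium/period order).
#'
#' @param x a \code{peak_table} (one or several strains).
#' @param min_rel abundance threshold in percent, in \code{[0, 100]};
#'   default 50, the conventional cutoff for picking fragmentation targets.
#' @return data.frame of class \code{precursor_list}: columns \code{mz},
#'   \code{polarity}, \code{rel_abundance}, \code{strain}, \code{medium},
#'   \code{period_days}.
#' @export
select_precursors <- function(x, min_rel = 50) {
  stopifnot(inherits(x, "peak_table"))
  min_rel <- as.numeric(min_rel)
  if (is.na(min_rel) || min_rel < 0 || min_rel > 100) {
    stop("min_rel must lie in [0, 100]")
  }
  hits <- x[x$rel_abundance >= min_rel, , drop = FALSE]
  if (nrow(hits) > 0L) {
    hits <- hits[order(factor(hits$polarity, levels = POLARITIES), hits$mz,
                       -hits$rel_abundance, hits$strain,
                       factor(hits$medium, levels = MEDIA),
                       hits$period_days), , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$polarity, hits$mz)), , drop = FALSE]
  }
  out <- as.data.frame(hits)[, c("mz", "polarity", "rel_abundance", "strain",
                                 "medium", "period_days")]
  rownames(out) <- NULL
  structure(out, class = c("precursor_list", "data.frame"))
}

#' Compare a computed common-ion table against a reference table
#'
#' Warns about ions present in the computed table but absent from the
#' reference (and vice versa), cell by cell. Used to surface discrepancies
#' between the rule-based derivation and a manually curated reference
#' without hard-coding either.
#'
#' @param computed a [common_ions()] result.
#' @param reference data.frame with columns \code{medium},
#'   \code{period_days}, \code{polarity}, \code{mz} (extra columns ignored).
#' @param warn emit one warning per discrepancy? (default TRUE)
#' @return data.frame of discrepancies with a \code{direction} column
#'   (\code{"extra"}: computed but not in reference; \code{"missing"}:
#'   reference but not computed), invisibly empty when the tables agree.
#' @export
compare_common_ions <- function(computed, reference, warn = TRUE) {
  keyc <- paste(computed$medium, computed$period_days, computed$polarity,
                computed$mz)
  keyr <- paste(reference$medium, reference$period_days, reference$polarity,
                reference$mz)
  extra <- computed[!keyc %in% keyr, c("medium", "period_days", "polarity", "mz")]
  missing <- reference[!keyr %in% keyc, c("medium", "period_days", "polarity", "mz")]
  out <- rbind(
    if (nrow(extra) > 0L) cbind(extra, direction = "extra"),
    if (nrow(missing) > 0L) cbind(missing, direction = "missing")
  )
  if (is.null(out)) {
    out <- data.frame(medium = character(), period_days = integer(),
                      polarity = character(), mz = integer(),
                      direction = character())
  }
  rownames(out) <- NULL
  if (warn && nrow(out) > 0L) {
    for (i in seq_len(nrow(out))) {
      warning(sprintf(
        "common-ion discrepancy: m/z %d (%s/%dd/%s) %s the reference table",
        out$mz[i], out$medium[i], out$period_days[i], out$polarity[i],
        if (out$direction[i] == "extra") "satisfies the rule but is absent from"
        else "is in the reference but not selected from"), call. = FALSE)
    }
  }
  out
}
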