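# Integrated strain-differentiation analysis: profile matrix, similarity,
# compound identification, and the final biotype report.

#' Pivot a peak table into an ion-by-extract profile matrix
#'
#' Rows are ions (m/z within a polarity), columns are extracts
#' (strain/medium/period/polarity cells); values are relative abundances,
#' \code{NA} where the ion was not detected (or the column's polarity does
#' not match the row's). The pivot is lossless: [profile_to_peaks()] returns
#' the original peak list.
#'
#' @param x a \code{peak_table}.
#' @return data.frame of class \code{profile_matrix}: columns \code{mz},
#'   \code{polarity}, then one column per extract named
#'   \code{strain.medium.period.polarity}.
#' @export
profile_matrix <- function(x) {
  stopifnot(inherits(x, "peak_table"))
  x <- sort_peak_table(x)
  cell_df <- unique(as.data.frame(x)[, c("strain", "medium", "period_days", "polarity")])
  cells <- paste(cell_df$strain, cell_df$medium, cell_df$period_days,
                 cell_df$polarity, sep = ".")
  ion_df <- unique(as.data.frame(x)[, c("polarity", "mz")])
  ion_df <- ion_df[order(factor(ion_df$polarity, levels = POLARITIES), ion_df$mz), ]
  mat <- matrix(NA_real_, nrow = nrow(ion_df), ncol = length(cells),
                dimnames = list(NULL, cells))
  row_idx <- match(paste(x$polarity, x$mz),
                   paste(ion_df$polarity, ion_df$mz))
  col_idx <- match(paste(x$strain, x$medium, x$period_days, x$polarity, sep = "."),
                   cells)
  mat[cbind(row_idx, col_idx)] <- x$rel_abundance
  out <- cbind(data.frame(mz = ion_df$mz, polarity = ion_df$polarity,
                          stringsAsFactors = FALSE),
               as.data.frame(mat, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, class = c("profile_matrix", "data.frame"),
            truncated = attr(x, "truncated"))
}

#' Unpivot a profile matrix back into a peak table
#'
#' @param pm a [profile_matrix()].
#' @return a \code{peak_table}.
#' @export
profile_to_peaks <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  cells <- setdiff(names(pm), c("mz", "polarity"))
  parts <- lapply(cells, function(cell) {
    meta <- strsplit(cell, ".", fixed = TRUE)[[1]]
    vals <- pm[[cell]]
    keep <- !is.na(vals)
    if (!any(keep)) return(NULL)
    data.frame(strain = meta[1], medium = meta[2],
               period_days = as.integer(meta[3]), polarity = meta[4],
               mz = pm$mz[keep], rel_abundance = vals[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  as_peak_table(sort_peak_table(out),
                truncated = isTRUE(attr(pm, "truncated")))
}

#' Jaccard similarity of two ion sets
#'
#' @param a,b vectors interpreted as sets.
#' @return \code{|A intersect B| / |A union B|}; 1 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-cell ion-set comparison of two strains
#'
#' For every (medium, period, polarity) cell, the Jaccard similarity of the
#' two strains' m/z sets and the size of the symmetric difference.
#'
#' @inheritParams common_ions
#' @return data.frame with columns \code{medium}, \code{period_days},
#'   \code{polarity}, \code{n_a}, \code{n_b}, \code{n_common},
#'   \code{n_symmetric_diff}, \code{jaccard}.
#' @export
cell_similarity <- function(a, b) {
  info <- split_two_strains(a, b)
  cells <- do.call(rbind, strsplit(info$cells, "/", fixed = TRUE))
  out <- data.frame(medium = cells[, 1], period_days = as.integer(cells[, 2]),
                    polarity = cells[, 3], stringsAsFactors = FALSE)
  key_a <- peak_cell_key(a, with_strain = FALSE)
  key_b <- peak_cell_key(b, with_strain = FALSE)
  stats <- lapply(info$cells, function(cell) {
    sa <- a$mz[key_a == cell]
    sb <- b$mz[key_b == cell]
    data.frame(n_a = length(sa), n_b = length(sb),
               n_common = length(intersect(sa, sb)),
               n_symmetric_diff = length(union(sa, sb)) - length(intersect(sa, sb)),
               jaccard = jaccard(sa, sb))
  })
  out <- cbind(out, do.call(rbind, stats))
  out <- out[order(factor(out$medium, levels = MEDIA), out$period_days,
                   factor(out$polarity, levels = POLARITIES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify known compounds from peak tables, a library, and MS/MS spectra
#'
#' Implements the dereplication route: peaks are filtered at
#' \code{min_rel} (the reporting threshold), candidate ions are the union of
#' high-abundance precursors (>= \code{min_precursor_rel} in at least one
#' extract) and the common ions of the two strains, each candidate is
#' converted to a neutral mass and matched against the library at the given
#' tolerance, and every match with an available MS/MS spectrum is screened
#' by [consistency_check()]. Matches without an MS/MS spectrum are reported
#' as mass-match only, never identified.
#'
#' @param x a \code{peak_table} holding exactly two strains.
#' @param library a [compound_library()].
#' @param msms list of [msms_spectrum()] objects, keyed implicitly by
#'   (precursor m/z, polarity).
#' @param min_rel reporting threshold applied first (default 10).
#' @param min_precursor_rel abundance threshold for the precursor route
#'   (default 50).
#' @param tolerance mass tolerance for [match_ion()] (default 0 Da).
#' @param min_coverage consistency threshold (default 0.8).
#' @param vocab,max_depth passed to [annotate_spectrum()].
#' @param occurrence_scope passed to [common_ions()].
#' @return data.frame of class \code{identified_compounds}: one row per
#'   (compound, candidate ion) pair with the matching and consistency
#'   outcome in \code{status} (\code{"identified"},
#'   \code{"failed_consistency"}, or \code{"mass_match_only"});
#'   attribute \code{identified} lists the distinct compound names with at
#'   least one identified row.
#' @export
identify_compounds <- function(x, library, msms, min_rel = 10,
                               min_precursor_rel = 50, tolerance = 0L,
                               min_coverage = 0.8,
                               vocab = default_loss_vocabulary(),
                               max_depth = 4L,
                               occurrence_scope = "pooled") {
  stopifnot(inherits(x, "peak_table"))
  strains <- sort(unique(x$strain))
  if (length(strains) != 2L) {
    stop("identify_compounds expects a peak table holding exactly two strains")
  }
  filtered <- filter_by_abundance(x, min_rel)
  a <- filtered[filtered$strain == strains[1], , drop = FALSE]
  b <- filtered[filtered$strain == strains[2], , drop = FALSE]
  prec <- select_precursors(filtered, min_precursor_rel)
  comm <- common_ions(a, b, occurrence_scope = occurrence_scope)
  cand <- unique(rbind(
    data.frame(mz = prec$mz, polarity = prec$polarity, source = "precursor",
               stringsAsFactors = FALSE),
    data.frame(mz = comm$mz, polarity = comm$polarity, source = "common",
               stringsAsFactors = FALSE)
  ))
  both <- duplicated(paste(cand$mz, cand$polarity)) |
    duplicated(paste(cand$mz, cand$polarity), fromLast = TRUE)
  cand$source[both] <- "both"
  cand <- cand[!duplicated(paste(cand$mz, cand$polarity)), , drop = FALSE]
  spec_key <- vapply(msms, function(s) paste(s$precursor_mz, s$polarity),
                     character(1))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    hits <- match_ion(cand$mz[i], cand$polarity[i], library, tolerance = tolerance)
    if (nrow(hits) == 0L) next
    spec_idx <- which(spec_key == paste(cand$mz[i], cand$polarity[i]))
    ann <- if (length(spec_idx) > 0L) {
      annotate_spectrum(msms[[spec_idx[1]]], vocab = vocab, max_depth = max_depth)
    } else NULL
    for (j in seq_len(nrow(hits))) {
      if (is.null(ann)) {
        status <- "mass_match_only"
        coverage <- NA_real_
      } else {
        chk <- consistency_check(ann, hits[j, , drop = FALSE],
                                 min_coverage = min_coverage)
        status <- if (chk$verdict) "identified" else "failed_consistency"
        coverage <- chk$coverage
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = hits$name[j], nominal_mass = hits$nominal_mass[j],
        formula = hits$formula[j], decoy = hits$decoy[j],
        note = hits$note[j],
        ion_mz = cand$mz[i], polarity = cand$polarity[i],
        candidate_source = cand$source[i], mass_diff = hits$mass_diff[j],
        has_msms = !is.null(ann), coverage = coverage, status = status,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(name = character(), nominal_mass = integer(),
               formula = character(), decoy = logical(), note = character(),
               ion_mz = integer(), polarity = character(),
               candidate_source = character(), mass_diff = integer(),
               has_msms = logical(), coverage = numeric(), status = character())
  out <- out[order(out$name, out$polarity, out$ion_mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("identified_compounds", "data.frame"),
            identified = sort(unique(out$name[out$status == "identified"])),
            strains = strains)
}

#' Names of compounds confirmed by the identification pipeline
#'
#' @param x an [identify_compounds()] result.
#' @return sorted character vector of identified compound names.
#' @export
identified_names <- function(x) {
  stopifnot(inherits(x, "identified_compounds"))
  attr(x, "identified")
}

#' Assemble the full biotyping report for two strains
#'
#' Combines the common-ion table, the per-strain distinctive ions, per-cell
#' Jaccard similarities, and (when a library and MS/MS spectra are supplied)
#' the identified compounds. The strains are declared distinguishable when
#' every (medium, period, polarity) cell of the grid has a non-empty
#' symmetric difference between the two ion sets. If a reference common-ion
#' table is supplied, rule/reference discrepancies are attached as notes
#' (and raised as warnings).
#'
#' @param x a \code{peak_table} holding exactly two strains.
#' @param library optional [compound_library()].
#' @param msms optional list of [msms_spectrum()] objects.
#' @param reference_common optional reference common-ion table (see
#'   [compare_common_ions()]).
#' @param min_rel reporting threshold (default 10).
#' @param ... further arguments passed to [identify_compounds()].
#' @return object of class \code{biotype_report}.
#' @export
biotype_report <- function(x, library = NULL, msms = NULL,
                           reference_common = NULL, min_rel = 10, ...) {
  stopifnot(inherits(x, "peak_table"))
  strains <- sort(unique(x$strain))
  if (length(strains) != 2L) {
    stop("biotype_report expects a peak table holding exactly two strains")
  }
  filtered <- filter_by_abundance(x, min_rel)
  a <- filtered[filtered$strain == strains[1], , drop = FALSE]
  b <- filtered[filtered$strain == strains[2], , drop = FALSE]
  full_grid <- expand.grid(medium = MEDIA, period_days = PERIODS,
                           polarity = POLARITIES, stringsAsFactors = FALSE)
  observed <- unique(peak_cell_key(filtered, with_strain = FALSE))
  missing_cells <- setdiff(
    paste(full_grid$medium, full_grid$period_days, full_grid$polarity, sep = "/"),
    observed)
  warnings_out <- character(0)
  if (length(missing_cells) > 0L) {
    msg <- paste("incomplete culture grid; missing cells:",
                 paste(missing_cells, collapse = ", "))
    warning(msg, call. = FALSE)
    warnings_out <- c(warnings_out, msg)
  }
  common <- common_ions(a, b)
  distinct <- distinctive_ions(a, b)
  sim <- cell_similarity(a, b)
  distinguishable <- all(sim$n_symmetric_diff > 0L)
  discrepancies <- NULL
  if (!is.null(reference_common)) {
    discrepancies <- compare_common_ions(common, reference_common, warn = TRUE)
  }
  identification <- NULL
  if (!is.null(library) && !is.null(msms)) {
    identification <- identify_compounds(x, library, msms, min_rel = min_rel, ...)
  }
  structure(
    list(strains = strains, common_ions = common, distinctive_ions = distinct,
         cell_similarity = sim, distinguishable = distinguishable,
         identification = identification,
         identified = if (!is.null(identification)) identified_names(identification),
         discrepancies = discrepancies, missing_cells = missing_cells,
         warnings = warnings_out, min_rel = min_rel),
    class = "biotype_report"
  )
}

#' @export
print.biotype_report <- function(x, ...) {
  cat("Biotype report:", paste(x$strains, collapse = " vs "), "\n")
  cat(sprintf("  distinguishable in every cell: %s\n", x$distinguishable))
  cat(sprintf("  common ions: %d entries (%d distinct m/z)\n",
              nrow(x$common_ions), length(unique(x$common_ions$mz))))
  cat(sprintf("  distinctive ions: %d entries\n", nrow(x$distinctive_ions)))
  if (!is.null(x$identified)) {
    cat(sprintf("  identified compounds: %d\n", length(x$identified)))
  }
  if (!is.null(x$discrepancies) && nrow(x$discrepancies) > 0L) {
    cat(sprintf("  reference discrepancies: %d\n", nrow(x$discrepancies)))
  }
  invisible(x)
}

#' Write a biotype report to disk
#'
#' Writes \code{report.json}, \code{common_ions.tsv}, \code{identified.tsv}
#' and \code{profile_matrix.tsv} under \code{dir}.
#'
#' @param report a [biotype_report()].
#' @param x the \code{peak_table} the report was built from (for the profile
#'   matrix).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, x, dir) {
  stopifnot(inherits(report, "biotype_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    strains = report$strains,
    distinguishable = report$distinguishable,
    min_rel = report$min_rel,
    n_common_ions = nrow(report$common_ions),
    n_distinct_common_mz = length(unique(report$common_ions$mz)),
    n_distinctive_ions = nrow(report$distinctive_ions),
    cell_similarity = report$cell_similarity,
    common_ions = as.data.frame(report$common_ions),
    identified = if (is.null(report$identified)) list() else as.list(report$identified),
    discrepancies = if (is.null(report$discrepancies)) list() else
      as.data.frame(report$discrepancies),
    missing_cells = as.list(report$missing_cells),
    warnings = as.list(report$warnings)
  )
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, na = "null"),
             file.path(dir, "report.json"))
  utils::write.table(as.data.frame(report$common_ions),
                     file.path(dir, "common_ions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ident <- if (is.null(report$identification)) {
    data.frame(name = character(), status = character())
  } else as.data.frame(report$identification)
  utils::write.table(ident, file.path(dir, "identified.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(profile_matrix(x)),
                     file.path(dir, "profile_matrix.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(dir)
}

#' Structurally validate a biotype report JSON document
#'
#' Checks the presence and basic types of the fields promised by the shipped
#' report schema (\code{report_schema.json} in the package's
#' \code{extdata}).
#'
#' @param path path to a \code{report.json} file, or an already-parsed list.
#' @return \code{TRUE} invisibly; errors describe the first violation.
#' @export
validate_report <- function(path) {
  x <- if (is.character(path)) jsonlite::fromJSON(path) else path
  required <- c("strains", "distinguishable", "min_rel", "n_common_ions",
                "n_distinct_common_mz", "n_distinctive_ions",
                "cell_similarity", "common_ions", "identified",
                "discrepancies", "missing_cells", "warnings")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("report is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (length(x$strains) != 2L) stop("report must name exactly two strains")
  if (!is.logical(x$distinguishable)) stop("'distinguishable' must be a boolean")
  sim <- as.data.frame(x$cell_similarity)
  if (!all(c("medium", "period_days", "polarity", "jaccard") %in% names(sim))) {
    stop("'cell_similarity' lacks required columns")
  }
  if (nrow(sim) > 0 && any(sim$jaccard < 0 | sim$jaccard > 1)) {
    stop("Jaccard similarities must lie in [0, 1]")
  }
  invisible(TRUE)
}
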