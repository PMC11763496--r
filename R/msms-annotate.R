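# Combinatorial neutral-loss annotation of unit-resolution MS/MS spectra.
#
# Every product ion is explained as the precursor minus a multiset of named
# neutral losses whose nominal masses sum exactly to the observed mass
# difference. The engine enumerates all such multisets up to a depth bound
# and ranks them; isobaric losses (CO vs C2H4 at 28, CO2 vs C3H8 vs C2H4O at
# 44, ...) are all reported rather than resolved, since choosing among them
# takes chemical reasoning about the precursor structure.

#' Build a neutral-loss vocabulary
#'
#' @param label loss labels (molecular formulas, or \code{"H+"} for a single
#'   hydrogen).
#' @param mass integer nominal masses (>= 1 Da).
#' @param radical logical; odd-electron (radical) losses are permitted but
#'   flagged and deprioritised in ranking.
#' @param max_count maximum multiplicity of the entry within one loss
#'   combination (\code{Inf} = unbounded). Used to keep the mass-1 hydrogen
#'   loss from padding arbitrary mass differences.
#' @return data.frame of class \code{loss_vocabulary}. Row order defines the
#'   vocabulary precedence used to break ranking ties.
#' @export
loss_vocabulary <- function(label, mass, radical = FALSE, max_count = Inf) {
  x <- data.frame(label = as.character(label), mass = as.integer(mass),
                  radical = as.logical(radical),
                  max_count = as.numeric(max_count),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$label)) stop("loss labels must be unique")
  if (anyNA(x$mass) || any(x$mass < 1L)) stop("loss masses must be integers >= 1")
  if (any(x$max_count < 1)) stop("max_count must be >= 1")
  structure(x, class = c("loss_vocabulary", "data.frame"))
}

#' Default neutral-loss vocabulary
#'
#' Contains the small stable neutrals (H2O, CO, CO2, CH3OH, ...), the larger
#' saturated/oxygenated fragments seen in polyketide and terpenoid
#' fragmentation, and the radical losses (CH3, OCH3, C3H7, ...) that
#' unit-resolution triple-quadrupole assignments use freely. Entry order
#' doubles as the ranking precedence: small stable neutrals come first. The
#' mass-1 hydrogen loss is capped at one occurrence per combination.
#'
#' @return a [loss_vocabulary()].
#' @export
default_loss_vocabulary <- function() {
  v <- rbind(
    data.frame(label = "H2O",    mass = 18L,  radical = FALSE),
    data.frame(label = "CO",     mass = 28L,  radical = FALSE),
    data.frame(label = "CO2",    mass = 44L,  radical = FALSE),
    data.frame(label = "CH3",    mass = 15L,  radical = TRUE),
    data.frame(label = "OCH3",   mass = 31L,  radical = TRUE),
    data.frame(label = "CH3OH",  mass = 32L,  radical = FALSE),
    data.frame(label = "O",      mass = 16L,  radical = FALSE),
    data.frame(label = "H2O2",   mass = 34L,  radical = FALSE),
    data.frame(label = "C2H2",   mass = 26L,  radical = FALSE),
    data.frame(label = "C2H4O",  mass = 44L,  radical = FALSE),
    data.frame(label = "C2H6O",  mass = 46L,  radical = FALSE),
    data.frame(label = "C2H2O",  mass = 42L,  radical = FALSE),
    data.frame(label = "C2H6",   mass = 30L,  radical = FALSE),
    data.frame(label = "C3H6",   mass = 42L,  radical = FALSE),
    data.frame(label = "C3H7",   mass = 43L,  radical = TRUE),
    data.frame(label = "C3H8",   mass = 44L,  radical = FALSE),
    data.frame(label = "C3H2O",  mass = 54L,  radical = FALSE),
    data.frame(label = "C3H4O",  mass = 56L,  radical = FALSE),
    data.frame(label = "C4H6O",  mass = 70L,  radical = FALSE),
    data.frame(label = "C4H7",   mass = 55L,  radical = TRUE),
    data.frame(label = "C4H8O",  mass = 72L,  radical = FALSE),
    data.frame(label = "C4H9O",  mass = 73L,  radical = TRUE),
    data.frame(label = "C4H10",  mass = 58L,  radical = FALSE),
    data.frame(label = "C5H8",   mass = 68L,  radical = FALSE),
    data.frame(label = "C5H9",   mass = 69L,  radical = TRUE),
    data.frame(label = "C5H10",  mass = 70L,  radical = FALSE),
    data.frame(label = "C5H11",  mass = 71L,  radical = TRUE),
    data.frame(label = "C5H12",  mass = 72L,  radical = FALSE),
    data.frame(label = "C5H10O", mass = 86L,  radical = FALSE),
    data.frame(label = "C6H8O2", mass = 112L, radical = FALSE),
    data.frame(label = "C8H16",  mass = 112L, radical = FALSE),
    data.frame(label = "C9H18O", mass = 142L, radical = FALSE),
    data.frame(label = "C2H3O2", mass = 59L,  radical = TRUE),
    data.frame(label = "H+",     mass = 1L,   radical = TRUE)
  )
  loss_vocabulary(v$label, v$mass, v$radical,
                  max_count = ifelse(v$label == "H+", 1, Inf))
}

#' Read a loss vocabulary from JSON
#'
#' @param path JSON array of \code{{label, mass, radical, max_count}} objects.
#' @return a [loss_vocabulary()].
#' @export
read_loss_vocabulary <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  loss_vocabulary(
    label = vapply(raw, function(r) as.character(r$label), character(1)),
    mass = vapply(raw, function(r) as.integer(r$mass), integer(1)),
    radical = vapply(raw, function(r) isTRUE(r$radical), logical(1)),
    max_count = vapply(raw, function(r) {
      if (is.null(r$max_count)) Inf else as.numeric(r$max_count)
    }, numeric(1))
  )
}

#' Total nominal mass of a loss combination
#'
#' @param labels character vector of vocabulary labels.
#' @param vocab a [loss_vocabulary()].
#' @return integer mass sum.
#' @export
loss_mass <- function(labels, vocab = default_loss_vocabulary()) {
  idx <- match(labels, vocab$label)
  if (anyNA(idx)) stop("unknown loss label: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  sum(vocab$mass[idx])
}

#' Elemental composition of a loss combination
#' @keywords internal
loss_composition <- function(labels) {
  sum_formulas(ifelse(labels == "H+", "H", labels))
}

#' Enumerate neutral-loss explanations of a mass difference
#'
#' Finds every multiset of at most \code{max_depth} vocabulary entries whose
#' nominal masses sum exactly to \code{precursor_mz - product_mz}, ranked by
#' fewer components, then fewer radical-flagged entries, then vocabulary
#' precedence. A zero mass difference yields a single empty combination.
#'
#' @param precursor_mz,product_mz integer nominal m/z with
#'   \code{product_mz <= precursor_mz}.
#' @param vocab a [loss_vocabulary()].
#' @param max_depth maximum number of loss components (default 4; the deepest
#'   combinations seen in practice on unit-resolution data).
#' @return list of character vectors of loss labels, best-ranked first; an
#'   empty list when the difference cannot be explained.
#' @examples
#' explain_loss(193, 175)[[1]] # "H2O"
#' @export
explain_loss <- function(precursor_mz, product_mz,
                         vocab = default_loss_vocabulary(), max_depth = 4L) {
  precursor_mz <- as.integer(precursor_mz)
  product_mz <- as.integer(product_mz)
  max_depth <- as.integer(max_depth)
  if (max_depth < 1L) stop("max_depth must be >= 1")
  delta <- precursor_mz - product_mz
  if (is.na(delta) || delta < 0L) {
    stop("product m/z (", product_mz, ") exceeds precursor m/z (", precursor_mz, ")")
  }
  if (delta == 0L) return(list(character(0)))
  n <- nrow(vocab)
  masses <- vocab$mass
  caps <- vocab$max_count
  found <- list()
  # depth-first enumeration over non-decreasing vocabulary indices, so each
  # multiset is produced exactly once
  recurse <- function(start, remaining, depth_left, acc) {
    if (remaining == 0L) {
      found[[length(found) + 1L]] <<- acc
      return(invisible())
    }
    if (depth_left == 0L || start > n) return(invisible())
    for (i in start:n) {
      m <- masses[i]
      if (m > remaining) next
      k_max <- min(depth_left, remaining %/% m, caps[i])
      if (k_max < 1L) next
      for (k in seq_len(k_max)) {
        if (remaining - k * m == 0L || (depth_left - k > 0L && i < n)) {
          recurse(i + 1L, remaining - as.integer(k * m), depth_left - k,
                  c(acc, rep(i, k)))
        }
      }
    }
    invisible()
  }
  recurse(1L, delta, max_depth, integer(0))
  if (length(found) == 0L) return(list())
  len <- lengths(found)
  nrad <- vapply(found, function(ix) sum(vocab$radical[ix]), numeric(1))
  key <- vapply(found, function(ix) paste(sprintf("%03d", ix), collapse = ""),
                character(1))
  ord <- order(len, nrad, key)
  lapply(found[ord], function(ix) vocab$label[ix])
}

#' Annotate an MS/MS spectrum with neutral-loss explanations
#'
#' Runs [explain_loss()] on every product ion and summarises coverage: the
#' fraction of product ions with at least one explanation (1 for a spectrum
#' without products).
#'
#' @param spectrum an [msms_spectrum()].
#' @param vocab a [loss_vocabulary()].
#' @param max_depth maximum number of loss components per explanation.
#' @return object of class \code{msms_annotation}: list with the precursor
#'   metadata, a \code{products} data.frame (observed m/z, abundance, mass
#'   difference, chosen explanation, number of alternatives), the full
#'   \code{explanations} list, and \code{coverage}.
#' @export
annotate_spectrum <- function(spectrum, vocab = default_loss_vocabulary(),
                              max_depth = 4L) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  prods <- spectrum$products
  explanations <- lapply(prods$mz, function(mz) {
    explain_loss(spectrum$precursor_mz, mz, vocab = vocab, max_depth = max_depth)
  })
  n_expl <- lengths(explanations)
  chosen <- vapply(explanations, function(e) {
    if (length(e) == 0L) NA_character_ else paste(e[[1]], collapse = "+")
  }, character(1))
  products <- data.frame(
    mz = prods$mz,
    rel_abundance = prods$rel_abundance,
    delta = spectrum$precursor_mz - prods$mz,
    chosen = chosen,
    n_explanations = n_expl,
    stringsAsFactors = FALSE
  )
  coverage <- if (nrow(products) == 0L) 1 else mean(n_expl > 0L)
  structure(
    list(precursor_mz = spectrum$precursor_mz, polarity = spectrum$polarity,
         adduct = spectrum$adduct, compound = spectrum$compound,
         products = products, explanations = explanations,
         coverage = coverage, max_depth = max_depth),
    class = "msms_annotation"
  )
}

#' @export
print.msms_annotation <- function(x, ...) {
  cat(sprintf("Neutral-loss annotation: precursor m/z %d (%s), coverage %.2f\n",
              x$precursor_mz, x$polarity, x$coverage))
  print(x$products)
  invisible(x)
}

#' Check a candidate compound against an annotated spectrum
#'
#' A product ion is consistent with the candidate when at least one of its
#' loss explanations has an elemental composition contained in the
#' candidate's molecular formula; without a formula, any explanation counts.
#' The verdict is true when the fraction of consistent product ions reaches
#' \code{min_coverage}. The reported chosen explanation per product is the
#' best-ranked consistent one.
#'
#' @param result an [annotate_spectrum()] result.
#' @param candidate one row of a [compound_library()] (or a list with
#'   \code{name}, \code{nominal_mass} and optional \code{formula}).
#' @param min_coverage minimum consistent fraction for a positive verdict
#'   (default 0.8).
#' @return object of class \code{consistency_report}: list with
#'   \code{verdict}, \code{coverage} (consistent fraction), \code{candidate},
#'   and a per-product \code{report} data.frame.
#' @export
consistency_check <- function(result, candidate, min_coverage = 0.8) {
  stopifnot(inherits(result, "msms_annotation"))
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    candidate <- as.list(candidate)
  }
  formula <- candidate$formula
  has_formula <- !is.null(formula) && !is.na(formula) && nzchar(formula)
  comp <- if (has_formula) parse_formula(formula) else NULL
  n <- nrow(result$products)
  consistent <- logical(n)
  chosen <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    expl <- result$explanations[[i]]
    if (length(expl) == 0L) next
    if (!has_formula) {
      consistent[i] <- TRUE
      chosen[i] <- paste(expl[[1]], collapse = "+")
    } else {
      ok <- which(vapply(expl, function(e) {
        length(e) == 0L || is_subcomposition(loss_composition(e), comp)
      }, logical(1)))
      if (length(ok) > 0L) {
        consistent[i] <- TRUE
        chosen[i] <- paste(expl[[ok[1]]], collapse = "+")
      }
    }
  }
  coverage <- if (n == 0L) 1 else mean(consistent)
  report <- cbind(result$products[, c("mz", "rel_abundance", "delta")],
                  data.frame(consistent = consistent, chosen = chosen,
                             stringsAsFactors = FALSE))
  structure(
    list(verdict = coverage >= min_coverage, coverage = coverage,
         candidate = candidate$name, formula_checked = has_formula,
         min_coverage = min_coverage, report = report),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Candidate %s: %s (consistent coverage %.2f, threshold %.2f%s)\n",
              x$candidate, if (x$verdict) "CONSISTENT" else "REJECTED",
              x$coverage, x$min_coverage,
              if (x$formula_checked) ", formula-checked" else ""))
  invisible(x)
}
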