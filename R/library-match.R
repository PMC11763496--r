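# Adduct arithmetic and compound-library matching.
#
# The electrospray source registers intact protonated molecules [M+H]+ in
# positive mode and deprotonated molecules [M-H]- in negative mode; at unit
# resolution the ion m/z is therefore the neutral nominal mass plus or minus
# one. Dereplication reduces to integer mass lookup against a library of
# compounds previously reported in the genus under study.

#' Ion m/z of the default adduct for a neutral mass
#'
#' @param nominal_mass integer neutral nominal mass(es), Da; must be >= 2.
#' @param polarity \code{"positive"} ([M+H]+) or \code{"negative"} ([M-H]-).
#' @return integer ion m/z, \code{nominal_mass + 1} in positive mode and
#'   \code{nominal_mass - 1} in negative mode.
#' @examples
#' adduct_mz(210, "positive") # 211
#' adduct_mz(196, "negative") # 195
#' @export
adduct_mz <- function(nominal_mass, polarity) {
  polarity <- match.arg(polarity, POLARITIES)
  nominal_mass <- as.integer(nominal_mass)
  if (anyNA(nominal_mass) || any(nominal_mass < 2L)) {
    stop("nominal mass must be an integer >= 2 Da")
  }
  nominal_mass + adduct_shift(polarity)
}

#' @keywords internal
adduct_shift <- function(polarity) if (polarity == "positive") 1L else -1L

#' Neutral nominal mass recovered from an adduct ion m/z
#'
#' Exact inverse of [adduct_mz()].
#'
#' @param mz integer ion m/z; must be positive.
#' @param polarity ionisation mode.
#' @return integer neutral nominal mass.
#' @export
neutral_mass <- function(mz, polarity) {
  polarity <- match.arg(polarity, POLARITIES)
  mz <- as.integer(mz)
  if (anyNA(mz) || any(mz <= 0L)) stop("ion m/z must be a positive integer")
  mz - adduct_shift(polarity)
}

#' Assemble a compound library
#'
#' @param name compound names.
#' @param nominal_mass integer neutral nominal masses (>= 1 Da).
#' @param formula optional molecular formulas (NA where unknown); when given,
#'   the formula's nominal mass must equal \code{nominal_mass}.
#' @param source_taxon taxon the compound was reported from.
#' @param reference literature reference.
#' @param note free-text annotation (e.g. known mass ambiguities).
#' @param decoy logical; decoy records used to keep identification honest.
#' @return data.frame of class \code{compound_library}.
#' @export
compound_library <- function(name, nominal_mass, formula = NA_character_,
                             source_taxon = NA_character_,
                             reference = NA_character_,
                             note = NA_character_, decoy = FALSE) {
  n <- length(name)
  recycle <- function(v) if (length(v) == 1L) rep(v, n) else v
  formula <- recycle(formula)
  source_taxon <- recycle(source_taxon)
  reference <- recycle(reference)
  note <- recycle(note)
  decoy <- recycle(decoy)
  x <- data.frame(name = as.character(name),
                  nominal_mass = as.integer(nominal_mass),
                  formula = as.character(formula),
                  source_taxon = as.character(source_taxon),
                  reference = as.character(reference),
                  note = as.character(note),
                  decoy = as.logical(decoy),
                  stringsAsFactors = FALSE)
  if (anyNA(x$name) || anyDuplicated(x$name)) stop("compound names must be unique and non-missing")
  if (anyNA(x$nominal_mass) || any(x$nominal_mass < 1L)) {
    stop("nominal mass must be an integer >= 1 Da")
  }
  has_formula <- !is.na(x$formula) & nzchar(x$formula)
  for (i in which(has_formula)) {
    fm <- formula_nominal_mass(x$formula[i])
    if (fm != x$nominal_mass[i]) {
      stop(sprintf("formula %s of '%s' has nominal mass %d, record says %d",
                   x$formula[i], x$name[i], fm, x$nominal_mass[i]))
    }
  }
  structure(x, class = c("compound_library", "data.frame"))
}

#' Read a compound library from JSON
#'
#' @param path path to a JSON array of compound records.
#' @return a \code{compound_library}.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  field <- function(r, what, default = NA_character_) {
    v <- r[[what]]
    if (is.null(v)) default else as.character(v)
  }
  compound_library(
    name = vapply(raw, field, character(1), what = "name"),
    nominal_mass = as.integer(vapply(raw, function(r) as.numeric(r$nominal_mass), numeric(1))),
    formula = vapply(raw, field, character(1), what = "formula"),
    source_taxon = vapply(raw, field, character(1), what = "source_taxon"),
    reference = vapply(raw, field, character(1), what = "reference"),
    note = vapply(raw, field, character(1), what = "note"),
    decoy = vapply(raw, function(r) isTRUE(r$decoy), logical(1))
  )
}

#' Write a compound library to JSON
#'
#' @param library a \code{compound_library}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_compound_library <- function(library, path) {
  recs <- lapply(seq_len(nrow(library)), function(i) {
    r <- as.list(library[i, , drop = FALSE])
    r <- lapply(r, function(v) if (is.na(v)) NULL else v)
    Filter(Negate(is.null), r)
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE, digits = NA), path)
  invisible(path)
}

#' Match an adduct ion against a compound library
#'
#' Converts the ion to its neutral nominal mass under the polarity's adduct
#' rule and returns library records within \code{tolerance} Da, closest
#' first (ties broken by name).
#'
#' @param mz integer ion m/z.
#' @param polarity ionisation mode.
#' @param library a \code{compound_library}.
#' @param tolerance integer mass tolerance in Da (default 0: exact nominal
#'   match, appropriate for a unit-resolution instrument).
#' @return the matching library rows with columns \code{matched_mz},
#'   \code{polarity}, \code{neutral_mass} and \code{mass_diff} appended;
#'   zero rows when nothing matches.
#' @export
match_ion <- function(mz, polarity, library, tolerance = 0L) {
  polarity <- match.arg(polarity, POLARITIES)
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L) stop("tolerance must be a non-negative integer")
  target <- neutral_mass(mz, polarity)
  diff <- abs(library$nominal_mass - target)
  hit <- which(diff <= tolerance)
  out <- as.data.frame(library)[hit, , drop = FALSE]
  out$matched_mz <- rep(as.integer(mz), nrow(out))
  out$polarity <- rep(polarity, nrow(out))
  out$neutral_mass <- rep(target, nrow(out))
  out$mass_diff <- diff[hit]
  out <- out[order(out$mass_diff, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
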