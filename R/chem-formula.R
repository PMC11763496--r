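# Elemental formula arithmetic at nominal (integer) mass.

# nominal masses of the most common isotopes; enough for secondary-metabolite
# work at unit resolution
ELEMENT_MASS <- c(H = 1L, C = 12L, N = 14L, O = 16L, F = 19L, Na = 23L,
                  Si = 28L, P = 31L, S = 32L, Cl = 35L, K = 39L, Br = 79L,
                  I = 127L)

#' Parse a molecular formula into element counts
#'
#' Accepts plain Hill-style formulas such as \code{"C11H14O3"}; repeated
#' element symbols accumulate (so \code{"CH3OH"} parses to C1 H4 O1).
#'
#' @param formula a formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) stop("empty formula")
  s <- gsub("\\s", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: ", formula)
  }
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(ELEMENT_MASS)) stop("unknown element '", el, "' in ", formula)
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts[order(names(counts))]
}

#' Nominal mass of a molecular formula
#'
#' @param formula a formula string (see [parse_formula()]).
#' @return integer nominal mass in Da.
#' @export
formula_nominal_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(ELEMENT_MASS[names(counts)] * counts)
}

#' Sum the elemental composition of several formulas
#' @keywords internal
sum_formulas <- function(formulas) {
  counts <- integer(0)
  for (f in formulas) {
    fc <- parse_formula(f)
    for (el in names(fc)) {
      counts[el] <- if (el %in% names(counts)) counts[[el]] + fc[[el]] else fc[[el]]
    }
  }
  counts
}

#' Is one elemental composition contained in another?
#'
#' @param sub,sup named integer vectors of element counts (as returned by
#'   [parse_formula()]).
#' @return logical.
#' @keywords internal
is_subcomposition <- function(sub, sup) {
  all(names(sub) %in% names(sup)) &&
    all(sub <= sup[names(sub)])
}
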