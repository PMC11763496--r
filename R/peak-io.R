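# Peak-table and MS/MS spectrum I/O.
#
# A peak table is kept in long form: one row per detected ion per extract,
# where an extract is one (strain, medium, period_days, polarity) cell of the
# culture grid. m/z values are nominal (unit resolution, integer); relative
# abundances are percent of the spectrum's base peak.

#' Culture media recognised in peak tables
#' @keywords internal
MEDIA <- c("MEA", "PDA", "SDA")

#' Incubation periods (days) of the culture grid
#' @keywords internal
PERIODS <- c(7L, 15L, 22L, 30L)

#' Ionisation polarities
#' @keywords internal
POLARITIES <- c("positive", "negative")

#' Acquisition m/z range of the instrument
#' @keywords internal
MZ_RANGE <- c(125L, 2000L)

round_half_up <- function(x) floor(x + 0.5)

#' Validate and classify a long-format peak table
#'
#' Checks the invariants of a unit-resolution peak table: m/z within the
#' acquisition range \code{[125, 2000]}, integer-valued m/z (values with
#' decimals are rounded half-up with a message), relative abundances in
#' \code{(0, 100]}, unique m/z within each extract, and the base-peak
#' convention. Tables truncated at a reporting threshold (as printed peak
#' lists usually are) need not contain a 100% peak in every extract; for
#' untruncated tables exactly one base peak at 100% per extract is required.
#'
#' @param x data.frame with columns \code{strain}, \code{medium},
#'   \code{period_days}, \code{polarity}, \code{mz}, \code{rel_abundance}.
#' @param truncated logical; is the table truncated at a reporting threshold?
#' @return \code{x} with class \code{peak_table} and canonical column types.
#' @export
as_peak_table <- function(x, truncated = TRUE) {
  required <- c("strain", "medium", "period_days", "polarity", "mz", "rel_abundance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("peak table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  x$strain <- as.character(x$strain)
  x$medium <- as.character(x$medium)
  bad_medium <- setdiff(unique(x$medium), MEDIA)
  if (length(bad_medium) > 0L) {
    stop("unknown culture medium: ", paste(bad_medium, collapse = ", "))
  }
  x$period_days <- as.integer(x$period_days)
  bad_period <- setdiff(unique(x$period_days), PERIODS)
  if (length(bad_period) > 0L) {
    stop("unknown incubation period (days): ", paste(bad_period, collapse = ", "))
  }
  x$polarity <- as.character(x$polarity)
  bad_pol <- setdiff(unique(x$polarity), POLARITIES)
  if (length(bad_pol) > 0L) {
    stop("polarity must be one of ", paste(POLARITIES, collapse = "/"),
         "; got: ", paste(bad_pol, collapse = ", "))
  }
  mz_num <- as.numeric(x$mz)
  if (anyNA(mz_num)) stop("non-numeric m/z value in peak table")
  if (any(mz_num != round_half_up(mz_num))) {
    n_round <- sum(mz_num != round_half_up(mz_num))
    message("rounding ", n_round, " non-integer m/z value(s) half-up to unit resolution")
  }
  x$mz <- as.integer(round_half_up(mz_num))
  if (any(x$mz < MZ_RANGE[1] | x$mz > MZ_RANGE[2])) {
    stop("m/z outside the acquisition range [", MZ_RANGE[1], ", ", MZ_RANGE[2], "]")
  }
  x$rel_abundance <- as.numeric(x$rel_abundance)
  if (anyNA(x$rel_abundance) || any(x$rel_abundance <= 0 | x$rel_abundance > 100)) {
    stop("relative abundance must lie in (0, 100]")
  }
  key <- peak_cell_key(x)
  if (anyDuplicated(paste(key, x$mz))) {
    dup <- paste(key, x$mz)[duplicated(paste(key, x$mz))]
    stop("duplicate m/z within an extract: ", paste(unique(dup), collapse = "; "))
  }
  if (!truncated) {
    n100 <- tapply(x$rel_abundance, key, function(a) sum(a == 100))
    if (any(n100 != 1L)) {
      stop("each untruncated spectrum must contain exactly one base peak at 100%")
    }
  } else {
    n100 <- tapply(x$rel_abundance, key, function(a) sum(a == 100))
    if (any(n100 > 1L)) stop("more than one peak at 100% in a spectrum")
  }
  rownames(x) <- NULL
  structure(x, class = c("peak_table", "data.frame"), truncated = truncated)
}

#' @keywords internal
peak_cell_key <- function(x, with_strain = TRUE) {
  if (with_strain) {
    paste(x$strain, x$medium, x$period_days, x$polarity, sep = "/")
  } else {
    paste(x$medium, x$period_days, x$polarity, sep = "/")
  }
}

#' Canonical ordering of a peak table
#' @keywords internal
sort_peak_table <- function(x) {
  ord <- order(x$strain, factor(x$medium, levels = MEDIA), x$period_days,
               factor(x$polarity, levels = POLARITIES), x$mz)
  x[ord, , drop = FALSE]
}

#' Read a peak table from CSV
#'
#' The CSV dialect has header
#' \code{strain,medium,period_days,polarity,mz,rel_abundance} with polarity
#' coded \code{pos}/\code{neg}, UTF-8, LF line endings. Malformed rows are
#' reported with their line number.
#'
#' @param path path to a CSV file.
#' @param truncated passed to [as_peak_table()].
#' @return a \code{peak_table}.
#' @export
read_peak_table <- function(path, truncated = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  header <- "strain,medium,period_days,polarity,mz,rel_abundance"
  if (length(lines) == 0L || trimws(lines[1]) != header) {
    stop("peak table must start with header '", header, "'")
  }
  body <- lines[-1]
  body_lines <- which(nzchar(trimws(body))) # skip blank lines
  if (length(body_lines) == 0L) {
    empty <- data.frame(strain = character(), medium = character(),
                        period_days = integer(), polarity = character(),
                        mz = integer(), rel_abundance = numeric())
    return(as_peak_table(empty, truncated = truncated))
  }
  fields <- strsplit(body[body_lines], ",", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 6L)) {
    bad <- body_lines[which(n_fields != 6L)[1]] + 1L
    stop("malformed row (expected 6 comma-separated fields) at line ", bad)
  }
  m <- do.call(rbind, fields)
  mz <- suppressWarnings(as.numeric(m[, 5]))
  ab <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(mz) || anyNA(ab)) {
    bad <- body_lines[which(is.na(mz) | is.na(ab))[1]] + 1L
    stop("non-numeric m/z or abundance at line ", bad)
  }
  pol_code <- trimws(m[, 4])
  if (!all(pol_code %in% c("pos", "neg"))) {
    bad <- body_lines[which(!pol_code %in% c("pos", "neg"))[1]] + 1L
    stop("polarity must be 'pos' or 'neg' at line ", bad)
  }
  out <- data.frame(
    strain = trimws(m[, 1]),
    medium = trimws(m[, 2]),
    period_days = suppressWarnings(as.integer(trimws(m[, 3]))),
    polarity = ifelse(pol_code == "pos", "positive", "negative"),
    mz = mz,
    rel_abundance = ab,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$period_days)) {
    bad <- body_lines[which(is.na(out$period_days))[1]] + 1L
    stop("non-integer incubation period at line ", bad)
  }
  as_peak_table(out, truncated = truncated)
}

#' Write a peak table to CSV
#'
#' Output is bit-stable: rows are sorted by strain, medium, period, polarity
#' and m/z, with LF line endings.
#'
#' @param x a \code{peak_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peak_table <- function(x, path) {
  x <- sort_peak_table(x)
  pol <- ifelse(x$polarity == "positive", "pos", "neg")
  rows <- sprintf("%s,%s,%d,%s,%d,%s", x$strain, x$medium, x$period_days, pol,
                  x$mz, fmt_num(x$rel_abundance))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("strain,medium,period_days,polarity,mz,rel_abundance", rows),
             con, sep = "\n")
  invisible(path)
}

#' @keywords internal
fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
         character(1))
}

#' Construct an MS/MS spectrum
#'
#' @param precursor_mz nominal precursor m/z (integer at unit resolution).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @param products data.frame with columns \code{mz} and \code{rel_abundance}.
#' @param adduct adduct label; defaults to \code{"[M+H]+"} in positive and
#'   \code{"[M-H]-"} in negative mode.
#' @param compound optional compound name the spectrum is attributed to.
#' @param losses optional list (parallel to products) of character vectors of
#'   annotated neutral-loss labels.
#' @param notes optional character vector (parallel to products) of
#'   transcription notes; \code{NA} where none.
#' @return an object of class \code{msms_spectrum}.
#' @export
msms_spectrum <- function(precursor_mz, polarity, products,
                          adduct = NULL, compound = NULL,
                          losses = NULL, notes = NULL) {
  polarity <- match.arg(polarity, POLARITIES)
  if (is.null(adduct)) adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  if (!adduct %in% c("[M+H]+", "[M-H]-")) {
    stop("adduct must be '[M+H]+' or '[M-H]-'")
  }
  if ((polarity == "positive") != (adduct == "[M+H]+")) {
    stop("adduct ", adduct, " is inconsistent with ", polarity, " polarity")
  }
  precursor_mz <- as.integer(round_half_up(as.numeric(precursor_mz)))
  if (is.na(precursor_mz) || precursor_mz <= 0L) stop("invalid precursor m/z")
  products <- as.data.frame(products)
  if (nrow(products) > 0L) {
    products$mz <- as.integer(round_half_up(as.numeric(products$mz)))
    products$rel_abundance <- as.numeric(products$rel_abundance)
    if (any(products$mz >= precursor_mz)) {
      stop("product m/z must be below the precursor m/z (", precursor_mz, ")")
    }
    if (any(products$rel_abundance <= 0 | products$rel_abundance > 100)) {
      stop("product relative abundance must lie in (0, 100]")
    }
    if (anyDuplicated(products$mz)) stop("duplicate product m/z")
  } else {
    products <- data.frame(mz = integer(), rel_abundance = numeric())
  }
  if (!is.null(losses) && length(losses) != nrow(products)) {
    stop("losses must be a list parallel to the product rows")
  }
  if (!is.null(notes) && length(notes) != nrow(products)) {
    stop("notes must be parallel to the product rows")
  }
  structure(
    list(precursor_mz = precursor_mz, polarity = polarity, adduct = adduct,
         compound = compound, products = products,
         losses = losses, notes = notes),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum: precursor m/z %d %s (%s)%s\n", x$precursor_mz,
              x$adduct, x$polarity,
              if (!is.null(x$compound)) paste0(" - ", x$compound) else ""))
  print(x$products)
  invisible(x)
}

#' Read MS/MS spectra from JSON or MGF
#'
#' JSON files hold an array of objects with fields \code{precursor_mz},
#' \code{polarity}, \code{adduct}, \code{products} (array of
#' \code{{mz, rel_abundance, losses, note}}) and optionally \code{compound}.
#' MGF files are parsed per \code{BEGIN IONS} block; \code{PEPMASS} maps to
#' the precursor m/z rounded half-up to unit mass and intensities are
#' rescaled to percent of the block's base peak.
#'
#' @param path path to a \code{.json} or \code{.mgf} file.
#' @return a list of [msms_spectrum()] objects.
#' @export
read_msms <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) {
    return(read_mgf(path))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    prods <- s$products
    df <- data.frame(
      mz = vapply(prods, function(p) as.numeric(p$mz), numeric(1)),
      rel_abundance = vapply(prods, function(p) as.numeric(p$rel_abundance), numeric(1))
    )
    losses <- lapply(prods, function(p) {
      if (is.null(p$losses)) character(0) else unlist(p$losses, use.names = FALSE)
    })
    notes <- vapply(prods, function(p) {
      if (is.null(p$note)) NA_character_ else as.character(p$note)
    }, character(1))
    msms_spectrum(
      precursor_mz = s$precursor_mz,
      polarity = s$polarity,
      adduct = if (is.null(s$adduct)) NULL else s$adduct,
      compound = if (is.null(s$compound)) NULL else s$compound,
      products = df, losses = losses, notes = notes
    )
  })
}

#' @keywords internal
read_mgf <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  starts <- grep("^BEGIN IONS$", lines)
  ends <- grep("^END IONS$", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  }
  mapply(function(s, e) {
    block <- lines[(s + 1L):(e - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    pep <- vals[match("PEPMASS", keys)]
    if (is.na(pep)) stop("MGF block without PEPMASS")
    precursor <- round_half_up(as.numeric(strsplit(pep, "\\s+")[[1]][1]))
    charge <- vals[match("CHARGE", keys)]
    polarity <- if (!is.na(charge) && grepl("-", charge, fixed = TRUE)) "negative" else "positive"
    peaks <- block[!kv & nzchar(block)]
    if (length(peaks) > 0L) {
      pm <- do.call(rbind, lapply(strsplit(peaks, "\\s+"), function(f) as.numeric(f[1:2])))
      if (anyNA(pm)) stop("malformed MGF peak line")
      inten <- pm[, 2]
      df <- data.frame(mz = round_half_up(pm[, 1]),
                       rel_abundance = 100 * inten / max(inten))
      # collapse duplicate unit masses, keeping the strongest; products are
      # listed from high to low m/z as in printed MS/MS tables
      df <- df[order(-df$mz, -df$rel_abundance), , drop = FALSE]
      df <- df[!duplicated(df$mz), , drop = FALSE]
      rownames(df) <- NULL
    } else {
      df <- data.frame(mz = integer(), rel_abundance = numeric())
    }
    msms_spectrum(precursor_mz = precursor, polarity = polarity, products = df)
  }, starts, ends, SIMPLIFY = FALSE)
}

#' Write MS/MS spectra to JSON
#'
#' @param spectra a list of [msms_spectrum()] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_msms <- function(spectra, path) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectra)
  out <- lapply(spectra, function(s) {
    prods <- lapply(seq_len(nrow(s$products)), function(i) {
      p <- list(mz = s$products$mz[i], rel_abundance = s$products$rel_abundance[i])
      if (!is.null(s$losses) && length(s$losses[[i]]) > 0L) p$losses <- as.list(s$losses[[i]])
      if (!is.null(s$notes) && !is.na(s$notes[i])) p$note <- s$notes[i]
      p
    })
    x <- list(precursor_mz = s$precursor_mz, polarity = s$polarity,
              adduct = s$adduct, products = prods)
    if (!is.null(s$compound)) x <- c(list(compound = s$compound), x)
    x
  })
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA), path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's \code{extdata} directory; when
#'   missing, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
msb_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "msbiotyper")))
  }
  path <- system.file("extdata", file, package = "msbiotyper")
  if (!nzchar(path)) stop("no packaged file called ", file)
  path
}
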