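# Seeded synthetic two-strain datasets with known ground truth.
#
# The generator emulates the statistical structure of printed unit-resolution
# peak tables: a 2-strain x 3-media x 4-period x 2-polarity culture grid,
# base-peak-scaled abundances, cell-wise presence variation, sub-threshold
# noise ions, and planted library compounds observable through their default
# adduct ions. It exists so that every pipeline stage can be tested against
# a dataset whose truth is known by construction.

#' Configuration for the strain-pair simulator
#'
#' @param seed integer seed; mandatory, recorded in the output.
#' @param n_shared_ions ions planted in both strains.
#' @param n_unique_ions ions planted in exactly one strain (each strain gets
#'   this many of its own).
#' @param n_planted_compounds library compounds planted as common
#'   high-abundance adduct ions with simulated MS/MS spectra.
#' @param n_noise_ions sub-threshold (< 10%) noise ions per extract.
#' @param occurrence_prob probability that a planted ion appears in any given
#'   extract cell, in (0, 1].
#' @param abundance abundance distribution for planted ions before base-peak
#'   scaling: \code{"uniform"} on [10, 100] or \code{"log-uniform"} over the
#'   same range.
#' @param mz_range m/z sampling window, within the acquisition range.
#' @param strains labels for the two simulated strains.
#' @return a list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed, n_shared_ions = 5L, n_unique_ions = 3L,
                              n_planted_compounds = 2L, n_noise_ions = 5L,
                              occurrence_prob = 0.6,
                              abundance = c("uniform", "log-uniform"),
                              mz_range = c(125L, 2000L),
                              strains = c("SIM-A", "SIM-B")) {
  abundance <- match.arg(abundance)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("a seed is required")
  stopifnot(n_shared_ions >= 0, n_unique_ions >= 0, n_planted_compounds >= 0,
            n_noise_ions >= 0)
  if (occurrence_prob <= 0 || occurrence_prob > 1) {
    stop("occurrence_prob must lie in (0, 1]")
  }
  mz_range <- as.integer(mz_range)
  if (mz_range[1] < MZ_RANGE[1] || mz_range[2] > MZ_RANGE[2] ||
      mz_range[1] >= mz_range[2]) {
    stop("mz_range must lie within the acquisition range [",
         MZ_RANGE[1], ", ", MZ_RANGE[2], "]")
  }
  if (length(strains) != 2L || strains[1] == strains[2]) {
    stop("two distinct strain labels are required")
  }
  structure(list(seed = seed, n_shared_ions = as.integer(n_shared_ions),
                 n_unique_ions = as.integer(n_unique_ions),
                 n_planted_compounds = as.integer(n_planted_compounds),
                 n_noise_ions = as.integer(n_noise_ions),
                 occurrence_prob = occurrence_prob, abundance = abundance,
                 mz_range = mz_range, strains = as.character(strains)),
            class = "simulation_config")
}

#' Run code with a locally seeded RNG, restoring the caller's state
#' @keywords internal
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
draw_abundance <- function(n, kind, lo = 10, hi = 100) {
  if (kind == "uniform") stats::runif(n, lo, hi)
  else exp(stats::runif(n, log(lo), log(hi)))
}

#' Simulate a two-strain peak-table dataset with known ground truth
#'
#' Plants three disjoint classes of ions on the full culture grid: shared
#' ions (both strains, guaranteed in at least two cells per strain), unique
#' ions (one strain only), and the adduct ions of planted library compounds
#' (both strains, drawn at >= 50% abundance so the precursor-selection rule
#' can see them). Every extract is rescaled so its base peak is exactly
#' 100%, then sub-threshold noise ions (< 10%) are added. MS/MS spectra for
#' the planted compounds are generated with [simulate_msms()].
#'
#' @param config a [simulation_config()].
#' @param library a [compound_library()] to draw planted compounds from
#'   (non-decoy records); defaults to the packaged library.
#' @return list with \code{peaks} (a \code{peak_table}), \code{msms} (list
#'   of spectra for the planted compounds), and \code{truth} (ground-truth
#'   list: \code{shared}, \code{unique}, \code{compounds},
#'   \code{true_losses}, \code{config}).
#' @export
simulate_strain_pair <- function(config,
                                 library = read_compound_library(
                                   msb_example("compound_library.json"))) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    pool <- seq(config$mz_range[1], config$mz_range[2])
    candidates <- library[!library$decoy, , drop = FALSE]
    if (config$n_planted_compounds > nrow(candidates)) {
      stop("library holds fewer non-decoy compounds than requested")
    }
    planted_idx <- sample(nrow(candidates), config$n_planted_compounds)
    comp <- candidates[planted_idx, , drop = FALSE]
    comp$polarity <- sample(POLARITIES, nrow(comp), replace = TRUE)
    comp$adduct_mz <- vapply(seq_len(nrow(comp)), function(i) {
      adduct_mz(comp$nominal_mass[i], comp$polarity[i])
    }, integer(1))
    # keep every library adduct m/z out of the random pools so decoys can
    # never collide with planted or noise ions
    reserved <- unique(c(adduct_mz(library$nominal_mass, "positive"),
                         adduct_mz(library$nominal_mass, "negative")))
    pool <- setdiff(pool, reserved)
    n_random <- config$n_shared_ions + 2L * config$n_unique_ions
    if (n_random > length(pool)) stop("m/z pool exhausted; widen mz_range")
    drawn <- sample(pool, n_random)
    shared_mz <- drawn[seq_len(config$n_shared_ions)]
    unique_a <- drawn[config$n_shared_ions + seq_len(config$n_unique_ions)]
    unique_b <- drawn[config$n_shared_ions + config$n_unique_ions +
                        seq_len(config$n_unique_ions)]
    noise_pool <- setdiff(pool, drawn)
    grid <- expand.grid(medium = MEDIA, period_days = PERIODS,
                        polarity = POLARITIES, stringsAsFactors = FALSE)
    # each planted ion carries a fixed polarity so presence is well defined
    ion_polarity <- function(mz_set) {
      if (length(mz_set) == 0L) return(character(0))
      sample(POLARITIES, length(mz_set), replace = TRUE)
    }
    shared_pol <- ion_polarity(shared_mz)
    unique_pol_a <- ion_polarity(unique_a)
    unique_pol_b <- ion_polarity(unique_b)
    # every strain must carry at least one ion per polarity, or the empty
    # cells of that polarity would have no base peak to plant; rebalance by
    # flipping a unique ion (strain-local) or a shared ion (both strains)
    if (config$n_shared_ions + config$n_unique_ions +
          config$n_planted_compounds < 2L) {
      stop("at least two planted ions per strain are required to cover ",
           "both polarities")
    }
    for (strain_i in 1:2) {
      upol <- if (strain_i == 1L) unique_pol_a else unique_pol_b
      for (p in POLARITIES) {
        have <- c(shared_pol, upol, comp$polarity)
        if (p %in% have) next
        if (length(upol) > 0L) {
          upol[1] <- p
        } else if (length(shared_pol) > 0L) {
          shared_pol[1] <- p
        } else {
          stop("no planted ion carries ", p,
               " polarity; increase n_shared_ions or n_unique_ions")
        }
        if (strain_i == 1L) unique_pol_a <- upol else unique_pol_b <- upol
      }
    }

    rows <- list()
    add_rows <- function(strain, mz, pol, cell, ab) {
      rows[[length(rows) + 1L]] <<- data.frame(
        strain = strain, medium = cell$medium, period_days = cell$period_days,
        polarity = pol, mz = mz, rel_abundance = ab, stringsAsFactors = FALSE)
    }

    for (strain_i in 1:2) {
      strain <- config$strains[strain_i]
      uniq_mz <- if (strain_i == 1L) unique_a else unique_b
      uniq_pol <- if (strain_i == 1L) unique_pol_a else unique_pol_b
      plant <- rbind(
        if (length(shared_mz) > 0L)
          data.frame(mz = shared_mz, polarity = shared_pol, kind = "shared",
                     stringsAsFactors = FALSE),
        if (length(uniq_mz) > 0L)
          data.frame(mz = uniq_mz, polarity = uniq_pol, kind = "unique",
                     stringsAsFactors = FALSE),
        if (nrow(comp) > 0L)
          data.frame(mz = comp$adduct_mz, polarity = comp$polarity,
                     kind = "compound", stringsAsFactors = FALSE)
      )
      if (is.null(plant) || nrow(plant) == 0L) {
        stop("nothing to simulate: all ion counts are zero")
      }
      # cells matching each ion's polarity
      cell_sets <- lapply(seq_len(nrow(plant)), function(i) {
        which(grid$polarity == plant$polarity[i])
      })
      pres <- matrix(FALSE, nrow(plant), nrow(grid))
      for (i in seq_len(nrow(plant))) {
        cells <- cell_sets[[i]]
        min_cells <- if (plant$kind[i] == "shared") 2L else 1L
        on <- stats::runif(length(cells)) < config$occurrence_prob
        short <- min_cells - sum(on)
        if (short > 0L) {
          off <- which(!on)
          on[off[sample.int(length(off), short)]] <- TRUE
        }
        pres[i, cells[on]] <- TRUE
      }
      for (ci in seq_len(nrow(grid))) {
        idx <- which(pres[, ci])
        # a spectrum needs at least one signal ion to define its base peak
        if (length(idx) == 0L) {
          pool_idx <- which(vapply(cell_sets, function(cs) ci %in% cs, logical(1)))
          idx <- pool_idx[sample.int(length(pool_idx), 1L)]
        }
        ab <- numeric(length(idx))
        for (k in seq_along(idx)) {
          ab[k] <- if (plant$kind[idx[k]] == "compound") {
            stats::runif(1, 50, 100)
          } else {
            draw_abundance(1L, config$abundance)
          }
        }
        ab <- 100 * ab / max(ab)
        ab[which.max(ab)] <- 100
        cell <- grid[ci, , drop = FALSE]
        add_rows(strain, plant$mz[idx], cell$polarity, cell, ab)
        if (config$n_noise_ions > 0L) {
          taken <- plant$mz[idx]
          nz <- sample(setdiff(noise_pool, taken), config$n_noise_ions)
          add_rows(strain, nz, cell$polarity, cell,
                   stats::runif(config$n_noise_ions, 1, 9.9))
        }
      }
    }
    peaks <- as_peak_table(sort_peak_table(do.call(rbind, rows)),
                          truncated = FALSE)
    msms <- list()
    true_losses <- list()
    for (i in seq_len(nrow(comp))) {
      sim <- simulate_msms(comp[i, , drop = FALSE],
                           polarity = comp$polarity[i],
                           seed = config$seed + i)
      msms[[length(msms) + 1L]] <- sim$spectrum
      true_losses[[comp$name[i]]] <- sim$true_losses
    }
    truth <- list(
      shared = data.frame(mz = shared_mz, polarity = shared_pol,
                          stringsAsFactors = FALSE),
      unique = list(
        data.frame(mz = unique_a, polarity = unique_pol_a, stringsAsFactors = FALSE),
        data.frame(mz = unique_b, polarity = unique_pol_b, stringsAsFactors = FALSE)
      ),
      compounds = as.data.frame(comp)[, c("name", "nominal_mass", "formula",
                                          "polarity", "adduct_mz")],
      true_losses = true_losses,
      config = config
    )
    names(truth$unique) <- config$strains
    list(peaks = peaks, msms = msms, truth = truth)
  })
}

#' Simulate an MS/MS spectrum for a known compound
#'
#' Products are the precursor minus the summed masses of sampled loss
#' combinations; when the compound has a molecular formula, only
#' elementally feasible combinations are sampled, so the generated spectrum
#' is consistent with the compound by construction.
#'
#' @param compound one row of a [compound_library()].
#' @param vocab a [loss_vocabulary()].
#' @param max_depth maximal number of losses per sampled combination;
#'   \code{0} yields an empty product list.
#' @param n_products number of product ions to generate.
#' @param polarity ionisation mode of the simulated adduct.
#' @param seed integer seed.
#' @param min_product_mz smallest admissible product m/z (default 50).
#' @param max_tries rejection-sampling budget before giving up.
#' @return list with \code{spectrum} (an [msms_spectrum()]) and
#'   \code{true_losses} (list of label vectors actually used).
#' @export
simulate_msms <- function(compound, vocab = default_loss_vocabulary(),
                          max_depth = 3L, n_products = 5L,
                          polarity = "positive", seed = 1L,
                          min_product_mz = 50L, max_tries = 500L) {
  if (is.data.frame(compound)) {
    stopifnot(nrow(compound) == 1L)
    compound <- as.list(compound)
  }
  polarity <- match.arg(polarity, POLARITIES)
  max_depth <- as.integer(max_depth)
  precursor <- adduct_mz(compound$nominal_mass, polarity)
  has_formula <- !is.null(compound$formula) && !is.na(compound$formula) &&
    nzchar(compound$formula)
  comp <- if (has_formula) parse_formula(compound$formula) else NULL
  if (max_depth == 0L || n_products == 0L) {
    return(list(spectrum = msms_spectrum(precursor, polarity,
                                         data.frame(mz = integer(),
                                                    rel_abundance = numeric()),
                                         compound = compound$name),
                true_losses = list()))
  }
  with_local_seed(seed, {
    losses <- list()
    mzs <- integer(0)
    tries <- 0L
    while (length(losses) < n_products && tries < max_tries) {
      tries <- tries + 1L
      k <- sample.int(max_depth, 1L)
      idx <- sample.int(nrow(vocab), k, replace = TRUE)
      counts <- table(idx)
      if (any(counts > vocab$max_count[as.integer(names(counts))])) next
      labels <- vocab$label[sort(idx)]
      mz <- precursor - sum(vocab$mass[idx])
      if (mz < min_product_mz || mz %in% mzs || mz >= precursor) next
      if (has_formula && !is_subcomposition(loss_composition(labels), comp)) next
      losses[[length(losses) + 1L]] <- labels
      mzs <- c(mzs, mz)
    }
    if (length(losses) < n_products) {
      stop("could not sample ", n_products, " feasible loss combinations for ",
           compound$name, " within the retry budget")
    }
    ab <- stats::runif(length(mzs), 10, 100)
    ab <- 100 * ab / max(ab)
    ab[which.max(ab)] <- 100
    ord <- order(mzs, decreasing = TRUE)
    spectrum <- msms_spectrum(precursor, polarity,
                              data.frame(mz = mzs[ord], rel_abundance = ab[ord]),
                              compound = compound$name,
                              losses = losses[ord])
    list(spectrum = spectrum, true_losses = losses[ord])
  })
}
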