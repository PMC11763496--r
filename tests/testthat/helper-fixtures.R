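# Shared fixture access (memoised: the files are parsed once per test run)
# and small independent oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture_peaks <- function() {
  if (is.null(.fixture_env$peaks)) {
    .fixture_env$peaks <- read_peak_table(msb_example("diaporthe_peaks.csv"))
  }
  .fixture_env$peaks
}

fixture_strain <- function(strain) {
  pk <- fixture_peaks()
  pk[pk$strain == strain, , drop = FALSE]
}

fixture_msms <- function() {
  if (is.null(.fixture_env$msms)) {
    .fixture_env$msms <- read_msms(msb_example("diaporthe_msms.json"))
  }
  .fixture_env$msms
}

fixture_library <- function() {
  if (is.null(.fixture_env$library)) {
    .fixture_env$library <- read_compound_library(msb_example("compound_library.json"))
  }
  .fixture_env$library
}

fixture_reference_common <- function() {
  ref <- utils::read.csv(msb_example("reference_common_ions.csv"),
                         stringsAsFactors = FALSE)
  ref$polarity <- ifelse(ref$polarity == "pos", "positive", "negative")
  ref
}

# tiny peak table built in code
toy_peaks <- function(mz_a = c(130, 140, 150), mz_b = c(140, 150, 160),
                      medium = "MEA", period = 7, polarity = "positive") {
  df <- rbind(
    data.frame(strain = "A", medium = medium, period_days = period,
               polarity = polarity, mz = mz_a,
               rel_abundance = seq(100, by = -10, length.out = length(mz_a))),
    data.frame(strain = "B", medium = medium, period_days = period,
               polarity = polarity, mz = mz_b,
               rel_abundance = seq(100, by = -10, length.out = length(mz_b)))
  )
  as_peak_table(df)
}

# independent brute-force enumeration of loss multisets: generates every
# tuple of <= depth vocabulary slots via expand.grid, canonicalises to a
# sorted multiset, and keeps those whose masses sum to delta
brute_force_explanations <- function(delta, vocab, depth) {
  n <- nrow(vocab)
  slots <- expand.grid(rep(list(0:n), depth))
  seen <- character(0)
  out <- list()
  for (r in seq_len(nrow(slots))) {
    idx <- sort(as.integer(slots[r, ]))
    idx <- idx[idx > 0L]
    if (length(idx) > 0L) {
      counts <- table(idx)
      if (any(counts > vocab$max_count[as.integer(names(counts))])) next
    }
    if (sum(vocab$mass[idx]) != delta) next
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- sort(vocab$label[idx])
  }
  out
}

# canonical form for comparing sets of multisets
multiset_key <- function(expl) sort(vapply(expl, function(e) paste(sort(e), collapse = "+"), character(1)))
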