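test_that("abundance filtering keeps peaks at or above the threshold", {
  s <- fixture_strain("F0728")
  s <- s[s$medium == "MEA" & s$period_days == 7 & s$polarity == "positive", ]
  kept <- filter_by_abundance(s, 50)
  expect_setequal(kept$mz, c(163L, 177L, 215L))
  # boundary: >= is inclusive
  expect_true(215L %in% filter_by_abundance(s, 58.8)$mz)
  # degenerate thresholds
  expect_equal(as.data.frame(filter_by_abundance(s, 0)), as.data.frame(s))
  expect_equal(nrow(filter_by_abundance(s, 100.01)), 0L)
  expect_error(filter_by_abundance(s, -1), ">= 0")
})

test_that("filtering is monotone in the threshold", {
  pk <- fixture_peaks()
  sizes <- vapply(c(0, 10, 25, 50, 75, 100), function(t) {
    nrow(filter_by_abundance(pk, t))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("recurrent ions count distinct extracts per strain and polarity", {
  occ <- recurrent_ions(fixture_strain("F0728"), min_count = 2)
  ion213 <- occ[occ$mz == 213 & occ$polarity == "positive", ]
  expect_equal(unique(ion213$n_occurrences), 8L)
  expect_equal(nrow(ion213), 8L)
  # an ion seen once is excluded at min_count 2 but present at min_count 1
  occ164 <- recurrent_ions(fixture_strain("F0728"), min_count = 2)
  expect_false(any(occ164$mz == 164 & occ164$polarity == "positive"))
  occ_all <- recurrent_ions(fixture_strain("F0728"), min_count = 1)
  expect_true(any(occ_all$mz == 164 & occ_all$polarity == "positive"))
  pk728 <- fixture_strain("F0728")
  expect_setequal(paste(occ_all$polarity, occ_all$mz),
                  unique(paste(pk728$polarity, pk728$mz)))
  # raising min_count never adds ions
  n <- vapply(1:4, function(k) {
    length(unique(paste(recurrent_ions(pk728, k)$polarity,
                        recurrent_ions(pk728, k)$mz)))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
  expect_error(recurrent_ions(fixture_peaks()), "single strain")
})

test_that("common-ion derivation reproduces the curated reference cells", {
  co <- common_ions(fixture_strain("F0728"), fixture_strain("F0891"))
  # SDA/15d/positive: m/z 211 shared, base peak of F0891
  cell <- co[co$medium == "SDA" & co$period_days == 15 & co$polarity == "positive", ]
  expect_setequal(cell$mz, c(164L, 211L))
  expect_equal(cell$abundance_b[cell$mz == 211], 100)
  expect_equal(cell$abundance_a[cell$mz == 211], 23.6)
  # under the stricter per-strain recurrence reading the single-occurrence
  # ion 164 drops out and 211 is the cell's only common ion
  co_strict <- common_ions(fixture_strain("F0728"), fixture_strain("F0891"),
                           occurrence_scope = "per_strain")
  cell_strict <- co_strict[co_strict$medium == "SDA" & co_strict$period_days == 15 &
                             co_strict$polarity == "positive", ]
  expect_equal(cell_strict$mz, 211L)
  # PDA/30d/positive: m/z 213 at 96.6% in F0728
  cell <- co[co$medium == "PDA" & co$period_days == 30 & co$polarity == "positive", ]
  expect_equal(cell$mz, 213L)
  expect_equal(cell$abundance_a, 96.6)
  # MEA/30d/negative has no common ions
  expect_equal(nrow(co[co$medium == "MEA" & co$period_days == 30 &
                         co$polarity == "negative", ]), 0L)
})

test_that("common ions are symmetric and self-comparison returns everything", {
  a <- fixture_strain("F0728")
  b <- fixture_strain("F0891")
  ab <- common_ions(a, b)
  ba <- common_ions(b, a)
  expect_equal(ab$mz, ba$mz)
  expect_equal(ab$abundance_a, ba$abundance_b)
  expect_equal(ab$abundance_b, ba$abundance_a)
  # a strain against itself (relabelled): every ion is common, abundances equal
  a2 <- a
  a2$strain <- "F0728-copy"
  self <- common_ions(a, as_peak_table(as.data.frame(a2)))
  expect_equal(nrow(self), nrow(a))
  expect_equal(self$abundance_a, self$abundance_b)
})

test_that("comparison against the printed reference flags the known discrepancies", {
  co <- common_ions(fixture_strain("F0728"), fixture_strain("F0891"))
  w <- capture_warnings(diffs <- compare_common_ions(co, fixture_reference_common()))
  expect_length(w, 3L)
  expect_true(any(grepl("207", w)))
  expect_true(any(grepl("164", w)))
  expect_true(any(grepl("165", w)))
  expect_true(all(diffs$direction == "extra"))
  expect_setequal(diffs$mz, c(207L, 164L, 165L))
})

test_that("mismatched culture grids are rejected with the missing cells named", {
  a <- fixture_strain("F0728")
  b <- fixture_strain("F0891")
  b2 <- b[!(b$medium == "SDA" & b$period_days == 30 & b$polarity == "negative"), ]
  expect_error(common_ions(a, b2), "SDA/30/negative")
})

test_that("distinctive ions are the per-cell set differences", {
  a <- fixture_strain("F0728")
  b <- fixture_strain("F0891")
  di <- distinctive_ions(a, b)
  # m/z 245 positive occurs in F0891's SDA extracts and never in F0728
  d245 <- di[di$mz == 245 & di$polarity == "positive", ]
  expect_true(all(d245$strain == "F0891"))
  expect_false(any(fixture_strain("F0728")$mz == 245 &
                     fixture_strain("F0728")$polarity == "positive"))
  # identical inputs give empty differences
  a2 <- a
  a2$strain <- "copy"
  expect_equal(nrow(distinctive_ions(a, as_peak_table(as.data.frame(a2)))), 0L)
  # disjoint inputs give the full peak sets
  toy <- toy_peaks(mz_a = c(130, 140), mz_b = c(150, 160))
  dt <- distinctive_ions(toy[toy$strain == "A", ], toy[toy$strain == "B", ])
  expect_equal(nrow(dt), 4L)
})

test_that("set conservation holds per cell: |common| + |unique to A| = |A|", {
  a <- fixture_strain("F0728")
  b <- fixture_strain("F0891")
  co <- common_ions(a, b, min_occurrences = 1) # pure intersection
  di <- distinctive_ions(a, b)
  for (cell in unique(paste(a$medium, a$period_days, a$polarity))) {
    key_a <- paste(a$medium, a$period_days, a$polarity)
    key_c <- paste(co$medium, co$period_days, co$polarity)
    key_d <- paste(di$medium, di$period_days, di$polarity)
    n_a <- sum(key_a == cell)
    n_common <- sum(key_c == cell)
    n_only_a <- sum(key_d == cell & di$strain == "F0728")
    expect_equal(n_common + n_only_a, n_a, info = cell)
  }
})

test_that("set operations agree with a naive pairwise oracle on small spectra", {
  withr::local_seed(421)
  for (rep in 1:20) {
    mz_a <- sort(sample(125:200, sample(1:10, 1)))
    mz_b <- sort(sample(125:200, sample(1:10, 1)))
    toy <- toy_peaks(mz_a = mz_a, mz_b = mz_b)
    a <- toy[toy$strain == "A", ]
    b <- toy[toy$strain == "B", ]
    co <- common_ions(a, b)
    di <- distinctive_ions(a, b)
    # naive double loops
    naive_common <- mz_a[vapply(mz_a, function(m) any(mz_b == m), logical(1))]
    naive_only_a <- mz_a[vapply(mz_a, function(m) !any(mz_b == m), logical(1))]
    naive_only_b <- mz_b[vapply(mz_b, function(m) !any(mz_a == m), logical(1))]
    expect_setequal(co$mz, naive_common)
    expect_setequal(di$mz[di$strain == "A"], naive_only_a)
    expect_setequal(di$mz[di$strain == "B"], naive_only_b)
  }
})

test_that("precursor selection keeps the strongest occurrence of each ion", {
  pk <- filter_by_abundance(fixture_peaks(), 10)
  prec <- select_precursors(pk)
  r217 <- prec[prec$mz == 217 & prec$polarity == "negative", ]
  expect_equal(nrow(r217), 1L)
  expect_equal(r217$rel_abundance, 100)
  expect_equal(r217$medium, "MEA")
  expect_equal(r217$period_days, 22L)
  # 211 positive tops out at 30.4% in F0728 and is only selected via F0891
  f0728 <- fixture_strain("F0728")
  expect_equal(nrow(select_precursors(f0728, 50)[
    select_precursors(f0728, 50)$mz == 211 &
      select_precursors(f0728, 50)$polarity == "positive", ]), 0L)
  # min_rel 0 selects every distinct ion
  all_sel <- select_precursors(pk, 0)
  expect_equal(nrow(all_sel), length(unique(paste(pk$polarity, pk$mz))))
  expect_error(select_precursors(pk, 101), "\\[0, 100\\]")
})
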