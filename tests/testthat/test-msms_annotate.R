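test_that("single printed losses are recovered as top-ranked explanations", {
  # water loss from deprotonated nectriapyrone
  expect_identical(explain_loss(193, 175)[[1]], "H2O")
  # the combined water + carbon dioxide loss at delta 62
  top131 <- explain_loss(193, 131)[[1]]
  expect_identical(sort(top131), sort(c("H2O", "CO2")))
  # isobaric 112 Da losses are both reported, neither silently dropped
  single112 <- Filter(function(e) length(e) == 1L, explain_loss(343, 231))
  expect_setequal(vapply(single112, identity, character(1)),
                  c("C8H16", "C6H8O2"))
  # a zero mass difference is explained by the empty combination
  expect_identical(explain_loss(200, 200), list(character(0)))
  expect_error(explain_loss(200, 201), "exceeds")
  expect_error(explain_loss(200, 150, max_depth = 0), ">= 1")
})

test_that("every explanation balances mass exactly", {
  vocab <- default_loss_vocabulary()
  withr::local_seed(99)
  for (rep in 1:25) {
    prec <- sample(150:400, 1)
    prod <- sample(60:(prec - 1), 1)
    for (e in explain_loss(prec, prod, max_depth = 3)) {
      expect_identical(loss_mass(e, vocab), as.integer(prec - prod))
    }
  }
})

test_that("ranking prefers fewer components, then fewer radicals, and is stable", {
  vocab <- default_loss_vocabulary()
  e <- explain_loss(235, 190) # delta 45: no single non-radical entry fits
  stats <- t(vapply(e, function(x) {
    c(len = length(x), rad = sum(vocab$radical[match(x, vocab$label)]))
  }, numeric(2)))
  expect_false(is.unsorted(stats[, "len"]))
  # within equal length, radical count never decreases
  for (l in unique(stats[, "len"])) {
    expect_true(all(diff(stats[stats[, "len"] == l, "rad"]) >= 0))
  }
  # repeated runs are identical
  expect_identical(explain_loss(343, 231), explain_loss(343, 231))
  expect_identical(annotate_spectrum(fixture_msms()[[3]]),
                   annotate_spectrum(fixture_msms()[[3]]))
})

test_that("bounded enumeration equals brute force on small vocabularies", {
  vocab <- loss_vocabulary(
    label = c("H2O", "CO", "CO2", "CH3", "C2H2"),
    mass = c(18L, 28L, 44L, 15L, 26L),
    radical = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  for (delta in c(18, 44, 46, 57, 62, 88, 90, 17)) {
    got <- explain_loss(200 + delta, 200, vocab = vocab, max_depth = 3)
    want <- brute_force_explanations(delta, vocab, depth = 3)
    expect_identical(multiset_key(got), multiset_key(want),
                     info = paste("delta", delta))
  }
  # with an 8-entry vocabulary including a capped mass-1 entry
  vocab8 <- loss_vocabulary(
    label = c("H2O", "CO", "CO2", "CH3", "C2H2", "O", "CH3OH", "H+"),
    mass = c(18L, 28L, 44L, 15L, 26L, 16L, 32L, 1L),
    radical = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    max_count = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, 1))
  for (delta in c(2, 18, 33, 45, 61)) {
    got <- explain_loss(300, 300 - delta, vocab = vocab8, max_depth = 3)
    want <- brute_force_explanations(delta, vocab8, depth = 3)
    expect_identical(multiset_key(got), multiset_key(want),
                     info = paste("delta", delta))
  }
})

test_that("deepening the search never removes explanations", {
  for (delta in c(44, 62, 88, 120)) {
    prev <- character(0)
    for (depth in 1:4) {
      cur <- multiset_key(explain_loss(300, 300 - delta, max_depth = depth))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("annotation coverage behaves at the boundaries", {
  msms <- fixture_msms()
  nectria <- Filter(function(s) s$precursor_mz == 193, msms)[[1]]
  ann <- annotate_spectrum(nectria)
  expect_equal(ann$coverage, 1.0)
  expect_equal(ann$products$delta, c(18L, 44L, 46L, 62L, 86L))
  # a lone delta-1 product is explained by the flagged hydrogen loss
  s1 <- msms_spectrum(200, "positive", data.frame(mz = 199, rel_abundance = 50))
  a1 <- annotate_spectrum(s1)
  expect_equal(a1$coverage, 1.0)
  expect_identical(a1$products$chosen, "H+")
  # vacuous coverage for an empty product list
  s0 <- msms_spectrum(200, "positive", data.frame(mz = integer(),
                                                  rel_abundance = numeric()))
  expect_equal(annotate_spectrum(s0)$coverage, 1.0)
  # coverage is non-decreasing in depth and vocabulary size
  small <- loss_vocabulary("H2O", 18L)
  big <- default_loss_vocabulary()
  c_small <- annotate_spectrum(nectria, vocab = small)$coverage
  c_big <- annotate_spectrum(nectria, vocab = big)$coverage
  expect_lte(c_small, c_big)
  c_d1 <- annotate_spectrum(nectria, max_depth = 1)$coverage
  c_d4 <- annotate_spectrum(nectria, max_depth = 4)$coverage
  expect_lte(c_d1, c_d4)
})

test_that("printed loss assignments are reproduced for at least 90% of vocabulary-covered products", {
  vocab <- default_loss_vocabulary()
  matched <- 0L
  eligible <- 0L
  for (s in fixture_msms()) {
    for (i in seq_along(s$losses)) {
      labels <- s$losses[[i]]
      if (length(labels) == 0L || !all(labels %in% vocab$label)) next
      eligible <- eligible + 1L
      expl <- explain_loss(s$precursor_mz, s$products$mz[i])
      # the printed multiset must appear among the ranked explanations
      # (top-ranked or listed alternative)
      if (any(vapply(expl, function(e) identical(sort(e), sort(labels)),
                     logical(1)))) {
        matched <- matched + 1L
      }
    }
  }
  expect_gt(eligible, 50L)
  expect_gte(matched / eligible, 0.9)
})

test_that("consistency checks accept the true compound and reject an element-poor decoy", {
  msms <- fixture_msms()
  lib <- fixture_library()
  nectria_spec <- Filter(function(s) s$precursor_mz == 193, msms)[[1]]
  ann <- annotate_spectrum(nectria_spec)
  true_rec <- lib[lib$name == "nectriapyrone", ]
  chk <- consistency_check(ann, true_rec, min_coverage = 0.8)
  expect_true(chk$verdict)
  expect_equal(chk$coverage, 1.0)
  # same nominal mass, but an oxygen-free hydrocarbon cannot shed H2O or CO2
  decoy <- list(name = "hydrocarbon-decoy", nominal_mass = 194L,
                formula = "C14H26")
  chk_decoy <- consistency_check(ann, decoy, min_coverage = 0.8)
  expect_false(chk_decoy$verdict)
  expect_false(chk_decoy$report$consistent[chk_decoy$report$delta == 18L])
  # a zero threshold always passes once the precursor matched
  expect_true(consistency_check(ann, decoy, min_coverage = 0)$verdict)
})
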