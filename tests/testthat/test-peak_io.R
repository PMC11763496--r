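test_that("the packaged peak tables parse into the full culture grid", {
  pk <- fixture_peaks()
  cells <- unique(paste(pk$strain, pk$medium, pk$period_days, pk$polarity))
  expect_length(cells, 48L) # 2 strains x 3 media x 4 periods x 2 polarities
  # spot-check one printed spectrum: F0728 / MEA / 7 d / positive
  s <- pk[pk$strain == "F0728" & pk$medium == "MEA" & pk$period_days == 7 &
            pk$polarity == "positive", ]
  expect_equal(nrow(s), 7L)
  expect_equal(s$mz[s$rel_abundance == 100], 163L)
  expect_equal(s$rel_abundance[s$mz == 177], 56.8)
})

test_that("peak-table CSV round-trips exactly", {
  pk <- fixture_peaks()
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pk, path)
  expect_identical(readLines(path), readLines(msb_example("diaporthe_peaks.csv")))
  back <- read_peak_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pk))
})

test_that("an empty peak table reads and writes as a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("strain,medium,period_days,polarity,mz,rel_abundance", path)
  empty <- read_peak_table(path)
  expect_s3_class(empty, "peak_table")
  expect_equal(nrow(empty), 0L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(empty, out)
  expect_identical(readLines(out), "strain,medium,period_days,polarity,mz,rel_abundance")
})

test_that("malformed and invalid peak-table input is rejected with context", {
  header <- "strain,medium,period_days,polarity,mz,rel_abundance"
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, "A,MEA,7,pos,163,100", "A,MEA,7,pos,170"), path)
  expect_error(read_peak_table(path), "line 3")
  writeLines(c(header, "A,MEA,7,pos,163,abc"), path)
  expect_error(read_peak_table(path), "line 2")
  writeLines(c(header, "A,MEA,7,up,163,50"), path)
  expect_error(read_peak_table(path), "pos")
  # abundance outside (0, 100]
  writeLines(c(header, "A,MEA,7,pos,163,120"), path)
  expect_error(read_peak_table(path), "relative abundance")
  writeLines(c(header, "A,MEA,7,pos,163,0"), path)
  expect_error(read_peak_table(path), "relative abundance")
  # duplicate (extract, mz)
  writeLines(c(header, "A,MEA,7,pos,163,50", "A,MEA,7,pos,163,40"), path)
  expect_error(read_peak_table(path), "duplicate")
  # out of acquisition range
  writeLines(c(header, "A,MEA,7,pos,100,50"), path)
  expect_error(read_peak_table(path), "acquisition range")
})

test_that("non-integer m/z values are rounded half-up with a message", {
  df <- data.frame(strain = "A", medium = "MEA", period_days = 7,
                   polarity = "positive", mz = 163.5, rel_abundance = 50)
  expect_message(pk <- as_peak_table(df), "half-up")
  expect_identical(pk$mz, 164L)
})

test_that("base-peak invariants distinguish truncated from full spectra", {
  df <- data.frame(strain = "A", medium = "MEA", period_days = 7,
                   polarity = "positive", mz = c(150, 160),
                   rel_abundance = c(90, 40))
  expect_silent(as_peak_table(df, truncated = TRUE))
  expect_error(as_peak_table(df, truncated = FALSE), "base peak")
  df$rel_abundance <- c(100, 100)
  expect_error(as_peak_table(df, truncated = TRUE), "100%")
})

test_that("MS/MS JSON fixture parses with printed loss annotations", {
  msms <- fixture_msms()
  expect_length(msms, 13L)
  nectria <- Filter(function(s) s$precursor_mz == 193, msms)[[1]]
  expect_equal(nectria$polarity, "negative")
  expect_equal(nectria$adduct, "[M-H]-")
  expect_equal(nrow(nectria$products), 5L)
  expect_equal(nectria$products$mz[1], 175L)
  expect_equal(nectria$products$rel_abundance[1], 55)
  expect_identical(nectria$losses[[1]], "H2O")
})

test_that("MGF input maps PEPMASS to unit precursor mass and rescales intensities", {
  mgf <- c("BEGIN IONS", "TITLE=test", "PEPMASS=211.0", "CHARGE=1+",
           "193.1 500", "165.0 250", "END IONS")
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgf, path)
  spectra <- read_msms(path)
  expect_length(spectra, 1L)
  s <- spectra[[1]]
  expect_identical(s$precursor_mz, 211L)
  expect_equal(s$polarity, "positive")
  expect_equal(s$products$mz, c(193L, 165L))
  expect_equal(s$products$rel_abundance, c(100, 50))
})

test_that("a product ion at or above the precursor mass is rejected", {
  expect_error(
    msms_spectrum(150, "positive",
                  data.frame(mz = 200, rel_abundance = 50)),
    "below the precursor")
  expect_error(
    msms_spectrum(150, "positive",
                  data.frame(mz = 150, rel_abundance = 50)),
    "below the precursor")
})

test_that("MS/MS spectra round-trip through JSON", {
  msms <- fixture_msms()
  path <- withr::local_tempfile(fileext = ".json")
  write_msms(msms, path)
  back <- read_msms(path)
  expect_length(back, length(msms))
  for (i in seq_along(msms)) {
    expect_equal(back[[i]]$precursor_mz, msms[[i]]$precursor_mz)
    expect_equal(back[[i]]$products, msms[[i]]$products)
    expect_equal(back[[i]]$losses, msms[[i]]$losses)
  }
})
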