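test_that("the index dialect parses with eligibility flags and soft errors", {
  db <- make_compound_db(3, seed = 1)
  recs <- parse_compound_db(db$index)
  expect_length(recs, 3L)
  expect_true(all(vapply(recs, `[[`, logical(1), "eligible_data")))
  # empty index -> empty list
  empty <- tempfile(); writeLines(character(0), empty)
  expect_length(parse_compound_db(empty), 0L)
  # missing quantum yield or spectrum file -> retained but ineligible
  idx <- tempfile()
  writeLines(c("no_qy | dye |  | missing_abs.txt |",
               "no_abs | dye | 0.5 | nope.txt |",
               "malformed line without pipes"), idx)
  recs2 <- suppressWarnings(parse_compound_db(idx))
  expect_length(recs2, 2L)
  expect_false(any(vapply(recs2, `[[`, logical(1), "eligible_data")))
  expect_warning(parse_compound_db(idx), "malformed")
})

test_that("eligibility requires in-band absorption support and a quantum yield", {
  mk <- function(center, qy) {
    wl <- seq(round(center) - 30, round(center) + 30)
    structure(list(name = "x", class = "dye", quantum_yield = qy,
                   absorption = spectrum(wl, exp(-((wl - center) / 10)^2)),
                   emission = NULL, eligible_data = is.finite(qy)),
              class = "compound_record")
  }
  expect_true(compound_eligible(mk(600, 0.5)))
  expect_false(compound_eligible(mk(310, 0.5)))   # entirely below 350 nm
  expect_false(compound_eligible(mk(600, NA)))    # no quantum yield
  expect_true(compound_eligible(mk(340, 0.5)))    # support straddles 350 nm
})

test_that("spectrum resampling is linear, zero outside support, delta-safe", {
  sp <- spectrum(c(400, 500, 600), c(0, 10, 20))
  expect_equal(resample_to(sp, c(400, 500, 600))$value, c(0, 10, 20))
  expect_equal(resample_to(sp, c(450, 550))$value, c(5, 15))
  expect_equal(resample_to(sp, c(350, 700))$value, c(0, 0))
  # round-trip 1 nm -> 5 nm -> 1 nm within 1% over the band core of a
  # smooth (sigma 40 nm) Gaussian
  wl1 <- seq(380, 700, by = 1)
  g <- spectrum(wl1, exp(-((wl1 - 540) / 40)^2 / 2))
  back <- resample_to(resample_to(g, seq(380, 700, by = 5)), wl1)
  core <- g$value > 0.1
  expect_lt(max(abs(back$value[core] - g$value[core]) / g$value[core]), 0.01)
  # single-point spectrum lands in the nearest target bin
  d <- resample_to(spectrum(502, 3), c(495, 500, 505))
  expect_equal(d$value, c(0, 3, 0))
})

test_that("overlap scores follow the summed product times quantum yield", {
  grid <- seq(400, 499, by = 1)  # 100 points
  ich <- spectrum(grid, rep(1, 100))
  ab <- spectrum(grid, rep(0.5, 100))
  expect_equal(score_compound(ich, ab, 0.8), 40)
  expect_equal(score_compound(ich, ab, 0), 0)
  expect_error(score_compound(ich, spectrum(grid + 1, rep(1, 100)), 1),
               "grid")
  # ordering of two equal-area bands against a red-transmissive spectrum
  # matches fine quadrature
  wl <- seq(350, 850, by = 1)
  mueff <- 0.3 + 0.7 * exp(-(wl - 350) / 150)  # red-transmissive
  i_tis <- spectrum(wl, wl^-2 * exp(-mueff * 5))
  blue <- exp(-((wl - 450) / 20)^2 / 2)
  red <- exp(-((wl - 800) / 20)^2 / 2)
  s_blue <- score_compound(i_tis, spectrum(wl, blue), 1)
  s_red <- score_compound(i_tis, spectrum(wl, red), 1)
  fine <- seq(350, 850, by = 0.1)
  iref <- approx(wl, i_tis$value, xout = fine)$y
  q <- function(band_c) sum(iref * exp(-((fine - band_c) / 20)^2 / 2)) * 0.1
  expect_equal(s_blue > s_red, q(450) > q(800))
})

test_that("ranking matches the fine-quadrature oracle and its invariants", {
  db <- make_compound_db(20, seed = 4)
  recs <- parse_compound_db(db$index)
  ich <- make_analytic_cherenkov_spectrum(0, "transparent-test")
  rk <- rank_compounds(recs, ich)
  oracle <- read.csv(db$oracle)
  expect_identical(rk$name, oracle$name)
  # normalized scores in (0, 1], unique maximum
  expect_equal(rk$normalized[1], 1)
  expect_true(all(rk$normalized > 0 & rk$normalized <= 1))
  expect_equal(sum(rk$normalized == 1), 1L)
  # scale invariance of the normalized ranking
  rk2 <- rank_compounds(recs, spectrum(ich$wavelength, 17 * ich$value))
  expect_equal(rk$normalized, rk2$normalized)
  expect_identical(rk$name, rk2$name)
  # grid-resolution invariance (1 nm vs 5 nm) of the top-3 order
  ich5 <- resample_to(ich, seq(350, 900, by = 5))
  rk5 <- rank_compounds(recs, ich5)
  expect_identical(rk$name[1:3], rk5$name[1:3])
  # single compound gets normalized score 1
  one <- rank_compounds(recs[1], ich)
  expect_equal(one$normalized, 1)
  # no eligible compounds -> explicit empty-result error
  idx <- tempfile(); writeLines("x | dye |  | none.txt |", idx)
  expect_error(rank_compounds(parse_compound_db(idx), ich), "eligible")
})

test_that("a moderate long-pass filter perturbs the top ranks by at most 2", {
  # blue end suppressed by at most exp(-0.5) relative to the red end
  db <- make_compound_db(20, seed = 4)
  recs <- parse_compound_db(db$index)
  raw <- rank_compounds(recs, make_analytic_cherenkov_spectrum(0, "transparent-test"))
  wl <- seq(350, 900, by = 1)
  filt <- spectrum(wl, wl^-2 * exp(-0.5 * (900 - wl) / 550))
  shifted <- rank_compounds(recs, filt)
  shift <- abs(match(raw$name[1:3], shifted$name) - (1:3))
  expect_lte(max(shift), 2)
})

test_that("ranking output files carry scores and provenance metadata", {
  db <- make_compound_db(5, seed = 2)
  out <- tempfile("rankout")
  rep <- run_ranking(db$index, cherenkov = 0, outdir = out)
  expect_s3_class(rep$ranking, "ranking_result")
  csv <- read.csv(file.path(out, "ranking.csv"))
  expect_equal(nrow(csv), 5)
  meta <- readLines(file.path(out, "ranking.meta.json"))
  expect_match(meta, "peak_normalize")
})
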