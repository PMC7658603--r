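test_that("excitation fraction partitions absorption between fluorophore and background", {
  fl <- ptg4_like_fluorophore()
  # no fluorophore absorption -> 0 (900 nm is far outside both bands)
  expect_equal(excitation_fraction(900, fl, kappa = 0.02, background = 0.01), 0,
               tolerance = 1e-6)
  # no background -> 1 wherever the fluorophore absorbs
  expect_equal(excitation_fraction(430, fl, kappa = 0.02, background = 0), 1)
  # equal partition when kappa * ma == background
  ma630 <- fl_absorption(fl, 630)
  expect_equal(excitation_fraction(630, fl, kappa = 0.02,
                                   background = 0.02 * ma630), 0.5)
  # monotone in kappa
  ks <- seq(0.001, 0.1, length.out = 20)
  f <- vapply(ks, function(k)
    excitation_fraction(630, fl, kappa = k, background = 0.01), numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("probabilistic emission respects quantum yield and the emission density", {
  fl0 <- ptg4_like_fluorophore(quantum_yield = 0)
  set.seed(1)
  for (i in 1:20)
    expect_null(emit_luminescence(c(0, 0, 10), 430, fl0, kappa = 1, background = 0))
  # pure fluorophore with QY 1: always emits, near the 770 nm emission band
  fl1 <- ptg4_like_fluorophore(quantum_yield = 1)
  set.seed(2)
  wl <- replicate(300, emit_luminescence(c(0, 0, 10), 430, fl1, kappa = 1,
                                         background = 0)$wavelength)
  expect_length(wl, 300)
  expect_equal(mean(wl), 770, tolerance = 5 / 770)
  expect_true(all(abs(wl - 770) < 120))
  # acceptance rate tracks f(lambda) * QY across the two absorption bands
  fl <- ptg4_like_fluorophore(quantum_yield = 0.5)
  set.seed(3)
  for (pars in list(c(430, 1), c(630, 0.55))) {
    p_expect <- excitation_fraction(pars[1], fl, kappa = 0.02,
                                    background = 0.01) * 0.5
    hits <- sum(!vapply(1:800, function(i)
      is.null(emit_luminescence(c(0, 0, 10), pars[1], fl, kappa = 0.02,
                                background = 0.01)), logical(1)))
    expect_equal(hits / 800, p_expect, tolerance = 4 * sqrt(p_expect / 800) / p_expect)
  }
})

test_that("kernel emission histogram peaks at the emission band mode", {
  rep1 <- run_inclusion_experiment("6MV", 3, events = 1.5e4, seed = 4)
  tl <- rep1$runs[[1]]$tally
  expect_gt(tl$lum$generated_count, 1e4)
  mode_wl <- tl$wl_centers[which.max(tl$lum$emission_hist)]
  expect_equal(mode_wl, 765, tolerance = 10 / 765)  # 770 within one 10 nm bin
  # excitation histogram concentrates in the two absorption bands
  exc <- tl$lum$excitation_hist
  in_bands <- (tl$wl_centers > 380 & tl$wl_centers < 480) |
    (tl$wl_centers > 570 & tl$wl_centers < 690)
  expect_gt(sum(exc[in_bands]) / sum(exc), 0.9)
})

test_that("escape tallies nest and the report returns their ratios", {
  rep1 <- run_inclusion_experiment("6MV", 5, events = 2e4, seed = 5)
  tl <- rep1$runs[[1]]$tally
  lum <- tl$lum
  expect_lte(lum$surface_weight, lum$exited_weight)
  expect_lte(lum$exited_weight, lum$generated_weight)
  esc <- escape_report(tl)
  expect_equal(esc$exited_fraction, lum$exited_weight / lum$generated_weight)
  expect_true(esc$surface_fraction >= 0 && esc$surface_fraction <= 1)
  expect_error(escape_report(list(generated_weight = 0, exited_weight = 0,
                                  surface_weight = 0)), "undefined")
})

test_that("luminescence escapes an unobstructed transparent surround almost fully", {
  # transparent bulk with a scattering-free, weakly absorbing inclusion
  tab <- read.csv(make_tissue_table("transparent-test"))
  p <- tempfile(fileext = ".csv"); write.csv(tab, p, row.names = FALSE)
  fl <- ptg4_like_fluorophore(quantum_yield = 1)
  tis <- build_layered_model(p, inclusion_depth_mm = 5, fluorophore = fl,
                             background_fraction = 0, kappa = 0.05)
  set.seed(6)
  src <- sample_source_positions(beam_spec("optical", 430, field_mm = 6,
                                           divergence_deg = 0), count = 5000)
  tl <- run_transport(src, tis, transport_config(nz_fluence = 0))
  esc <- escape_report(tl)
  expect_gt(esc$exited_fraction, 0.95)
})

test_that("surface luminescence per primary decreases with inclusion depth", {
  rep3 <- run_inclusion_experiment("6MV", depths_mm = c(1, 5, 9),
                                   events = 3e4, seed = 7)
  s <- rep3$sensitivity[order(rep3$sensitivity$depth_mm), ]
  expect_true(all(diff(s$surface_per_primary) < 0))
  # and the decline is far larger than Monte Carlo noise (>2x per 4 mm)
  expect_gt(s$surface_per_primary[1], 2 * s$surface_per_primary[2])
  expect_gt(s$surface_per_primary[2], 2 * s$surface_per_primary[3])
})
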