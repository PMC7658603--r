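test_that("Cherenkov threshold energy follows the relativistic closed form", {
  expect_equal(cherenkov_threshold_energy(1.4), 219.2, tolerance = 1e-3)
  expect_equal(cherenkov_threshold_energy(1.33), 264.1, tolerance = 1e-3)
  expect_lt(cherenkov_threshold_energy(10), 5)
  expect_error(cherenkov_threshold_energy(1), "n <= 1")
})

test_that("depth-dose models are normalized with the clinical depth of maximum", {
  z <- seq(0, 50, by = 0.1)
  for (en in c("6MV", "18MV", "6MeV", "18MeV")) {
    d <- dose_at_depth(pdd_model(en), z)
    expect_true(all(d >= 0))
    expect_equal(max(d), 1, tolerance = 1e-6)
  }
  expect_equal(z[which.max(dose_at_depth(pdd_model("6MV"), z))], 15)
  expect_equal(z[which.max(dose_at_depth(pdd_model("18MV"), z))], 35)
  # photon build-up: rising at the surface, decaying beyond the maximum
  d6 <- dose_at_depth(pdd_model("6MV"), z)
  expect_true(all(diff(d6[z < 10]) > 0))
  expect_true(all(diff(d6[z > 20]) < 0))
  # electron practical range ~ E/2 cm: 6 MeV dose is negligible beyond 35 mm
  de <- dose_at_depth(pdd_model("6MeV"), z)
  expect_lt(max(de[z > 35]), 0.05)
  expect_error(dose_at_depth(pdd_model("6MV"), -1), ">= 0")
})

test_that("1/lambda^2 wavelength sampling matches the analytic law", {
  expect_equal(sample_cherenkov_wavelength(0), 350)
  expect_equal(sample_cherenkov_wavelength(1), 900)
  set.seed(42)
  wl <- sample_cherenkov_wavelength(runif(1e6))
  analytic_mean <- log(900 / 350) / (1 / 350 - 1 / 900)
  expect_equal(mean(wl), analytic_mean, tolerance = 0.5 / analytic_mean)
  # KS against the analytic CDF
  cdf <- function(l) (1 / 350 - 1 / l) / (1 / 350 - 1 / 900)
  ks <- suppressWarnings(ks.test(wl[1:1e5], cdf))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_cherenkov_wavelength(0.5, 900, 350), "lambda")
})

test_that("divergent field footprint reproduces the ~4 cm illuminated area", {
  b <- beam_spec("photon-beam", "6MV", field_mm = 10, ssd_mm = 900,
                 divergence_deg = 0.97)
  expect_equal(field_footprint(b)[1], 40.5, tolerance = 0.1 / 40.5)
  b0 <- beam_spec("photon-beam", "6MV", divergence_deg = 0)
  expect_equal(field_footprint(b0), c(10, 10))
  sheet <- beam_spec("photon-beam", "6MV", field_shape = "sheet",
                     field_mm = c(2.5, 10), ssd_mm = 200, divergence_deg = 0)
  expect_equal(field_footprint(sheet), c(2.5, 10))
})

test_that("relative Cherenkov yields encode the calibration table", {
  y <- function(mod, en) relative_yield(beam_spec(mod, en))
  expect_equal(y("electron-beam", "6MeV") / y("photon-beam", "6MV"), 100)
  expect_equal(y("photon-beam", "18MV") / y("photon-beam", "6MV"), 2.5)
  expect_equal(y("photon-beam", "6MV") / y("photon-beam", "6MV"), 1)
  expect_equal(y("electron-beam", "18MeV") / y("photon-beam", "18MV"), 100)
  expect_error(relative_yield(beam_spec("optical", 630)), "not applicable")
})

test_that("sampled source depths follow the depth-dose curve", {
  beam <- beam_spec("photon-beam", "6MV")
  pdd <- pdd_model("6MV")
  set.seed(7)
  src <- sample_source_positions(beam, pdd, count = 1e5)
  # unit directions, in-band wavelengths, unit weights
  expect_equal(max(abs(sqrt(src$ux^2 + src$uy^2 + src$uz^2) - 1)), 0,
               tolerance = 1e-9)
  expect_true(all(src$wavelength >= 350 & src$wavelength <= 900))
  # modal depth near the 15 mm maximum
  h <- hist(src$z, breaks = seq(0, 50, by = 1), plot = FALSE)
  expect_true(h$mids[which.max(h$counts)] >= 13 &&
                h$mids[which.max(h$counts)] <= 17)
  # KS distance between sampled depths and the dose density
  zg <- seq(0, 50, by = 0.01)
  dens <- dose_at_depth(pdd, zg)
  cdf_tab <- cumsum(dens) / sum(dens)
  cdf <- function(z) approx(zg, cdf_tab, xout = z, rule = 2)$y
  ks <- suppressWarnings(ks.test(src$z, cdf))
  expect_lt(unname(ks$statistic), 0.005)
  # reproducible under a fixed seed
  set.seed(11); a <- sample_source_positions(beam, pdd, count = 5)
  set.seed(11); b <- sample_source_positions(beam, pdd, count = 5)
  expect_identical(a, b)
})

test_that("optical sources fill the divergence-expanded footprint at the surface", {
  b <- beam_spec("optical", 630, field_mm = 10, ssd_mm = 900,
                 divergence_deg = 0.97)
  set.seed(3)
  src <- sample_source_positions(b, count = 2e4)
  expect_true(all(src$uz == 1))
  expect_true(all(src$wavelength == 630))
  foot <- field_footprint(b)[1]
  expect_true(all(abs(src$x) <= foot / 2))
  expect_gt(max(abs(src$x)), 0.45 * foot)  # spread over the full footprint
})
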