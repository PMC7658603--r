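test_that("FWHM of sampled and constructed profiles matches closed forms", {
  # Gaussian sigma = 2 mm: FWHM = 2 sqrt(2 ln 2) sigma = 4.71 mm
  set.seed(1)
  x <- rnorm(1e6, 0, 2)
  edges <- seq(-12, 12, by = 0.1)
  h <- hist(x, breaks = edges, plot = FALSE)
  fw <- fwhm(h$mids, h$counts)
  expect_equal(fw$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.05 / 4.71)
  expect_false(fw$boundary_truncated)
  # rectangle of width 2.5 mm on fine, edge-aligned bins
  ctr <- seq(-5 + 0.025, 5 - 0.025, by = 0.05)
  rect <- as.numeric(abs(ctr) < 1.25)
  expect_equal(fwhm(ctr, rect)$fwhm, 2.5, tolerance = 0.05 / 2.5)
  # single nonzero bin degenerates to the bin width
  one <- rep(0, 21); one[11] <- 5
  expect_equal(fwhm(seq(-1, 1, by = 0.1), one)$fwhm, 0.1)
  # invariance under count rescaling and translation
  g <- exp(-(ctr - 1)^2 / (2 * 0.8^2))
  expect_equal(fwhm(ctr, g)$fwhm, fwhm(ctr, 7 * g)$fwhm)
  expect_equal(fwhm(ctr + 3, g)$fwhm, fwhm(ctr, g)$fwhm)
  expect_error(fwhm(ctr, rep(0, length(ctr))), "no positive maximum")
  # clipped profile is flagged
  expect_true(fwhm(ctr, rep(1, length(ctr)))$boundary_truncated)
})

test_that("FWHM-by-depth recovers a constructed linear widening within 5%", {
  ev <- make_event_fixture("depth-widening", n = 4e5, seed = 2,
                           sigma0_mm = 1, slope = 0.2, depth_mm = 10)
  # light smoothing suppresses the peak-count noise bias of the half-max level
  fw <- fwhm_by_depth(ev, slab_mm = 1, bin_mm = 0.1, smooth_window = 5)
  fit <- lm(fwhm ~ depth, data = fw)
  expect_equal(unname(coef(fit)[2]), 2 * sqrt(2 * log(2)) * 0.2,
               tolerance = 0.05)
  # constant-width fixture: flat FWHM at 2.355 sigma in every slab
  ev2 <- make_event_fixture("gaussian-lateral", n = 4e5, seed = 3, sigma_mm = 2)
  fw2 <- fwhm_by_depth(ev2, slab_mm = 1, bin_mm = 0.1)
  expect_equal(fw2$fwhm, rep(2 * sqrt(2 * log(2)) * 2, nrow(fw2)),
               tolerance = 0.03)
  # empty slabs are omitted, not reported as zero
  ev3 <- ev2[ev2$z < 3 | ev2$z > 7, ]
  fw3 <- fwhm_by_depth(ev3, slab_mm = 1, z_range = c(0, 10))
  expect_false(any(fw3$depth > 3 & fw3$depth < 7))
})

test_that("depth profiles integrate events and tallies consistently", {
  ev <- data.frame(z = c(0.5, 0.5, 1.5), weight = c(1, 2, 4))
  pr <- depth_profile(ev, bin_mm = 1)
  expect_equal(pr$value[1:2], c(3, 4))
  prn <- depth_profile(ev, bin_mm = 1, normalize = TRUE)
  expect_equal(max(prn$value), 1)
})

test_that("fluence drops faster across the blood-network layers than neighbours", {
  tis <- build_layered_model(default_table())
  # 560 nm sits in the blood Q-band where the plexus layers absorb hardest
  set.seed(4)
  src <- sample_source_positions(beam_spec("optical", 560, field_mm = 10,
                                           divergence_deg = 0), count = 4e4)
  tl <- run_transport(src, tis, transport_config(nz_fluence = 5000))
  pr <- depth_profile(tl)
  # per-layer attenuation rate from the mean fluence near the layer's top
  # and bottom thirds (10 um bins; the thinner blood plexus layers still
  # hold >= 10 bins each)
  rate <- function(z1, z2) {
    sel <- pr$depth >= z1 & pr$depth < z2
    v <- pr$value[sel]; z <- pr$depth[sel]
    k <- max(2L, floor(length(v) / 3))
    top <- mean(v[seq_len(k)]); bot <- mean(v[seq(length(v) - k + 1, length(v))])
    (log(top) - log(bot)) / (mean(z[seq(length(z) - k + 1, length(z))]) -
                               mean(z[seq_len(k)]))
  }
  b <- tis$boundaries_mm
  names(b) <- c(vapply(tis$layers, `[[`, character(1), "name"), "bottom")
  ubn <- rate(b[["upper_blood_net_dermis"]], b[["reticular_dermis"]])
  ret <- rate(b[["reticular_dermis"]], b[["deep_blood_net_dermis"]])
  dbn <- rate(b[["deep_blood_net_dermis"]], b[["lower_dermis"]])
  expect_gt(ubn, ret)
  expect_gt(dbn, ret)
})

test_that("surface histograms conserve weight and size with the beam", {
  ev <- make_event_fixture("surface-cloud", n = 2e4, seed = 5, sigma_mm = 2)
  h <- surface_histogram(ev, bin_mm = 1)
  expect_equal(sum(h$counts), sum(ev$weight))
  empty <- surface_histogram(ev[0, ], bin_mm = 1, extent_mm = 5)
  expect_true(all(empty$counts == 0))
  # second-moment radius of a tighter cloud is smaller
  ev2 <- make_event_fixture("surface-cloud", n = 2e4, seed = 6, sigma_mm = 0.5)
  rad <- function(ev) sqrt(mean(ev$x^2 + ev$y^2))
  expect_lt(rad(ev2), rad(ev))
})

test_that("depth sensitivity is the thresholded relative-signal crossing", {
  d <- 0:10
  expect_equal(depth_sensitivity(d, exp(-d / 3), exp(-1))$depth_mm, 3,
               tolerance = 0.02)
  out <- depth_sensitivity(d, rep(1, 11), 0.5)
  expect_true(out$saturated)
  expect_equal(out$depth_mm, 10)
  expect_error(depth_sensitivity(d, -exp(-d), 0.5), "positive")
  expect_error(depth_sensitivity(0:1, c(1, 0.5), 0.5), "length")
})

test_that("PGM export writes a readable plain-text image", {
  h <- surface_histogram(make_event_fixture("surface-cloud", n = 1000, seed = 7),
                         bin_mm = 1)
  p <- tempfile(fileext = ".pgm")
  write_pgm(h, p)
  lines <- readLines(p)
  expect_equal(lines[1], "P2")
  expect_equal(as.integer(strsplit(lines[2], " ")[[1]]),
               c(nrow(h$counts), ncol(h$counts)))
})
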