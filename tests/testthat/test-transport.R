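test_that("free-path sampling and Fresnel reflectance follow the closed forms", {
  expect_equal(sample_step(exp(-1), 1), 1)
  expect_equal(sample_step(1, 2), 0)
  set.seed(1)
  expect_equal(mean(sample_step(runif(1e6), 2)), 0.5, tolerance = 0.004)
  expect_error(sample_step(0.5, 0), "mu_t")

  expect_equal(fresnel_reflectance(1.4, 1.4, 0.7), 0)
  expect_equal(fresnel_reflectance(1, 1.4, 1), ((1.4 - 1) / (1.4 + 1))^2,
               tolerance = 1e-12)
  expect_equal(fresnel_reflectance(1, 1.4, 1), 0.02778, tolerance = 1e-3)
  expect_equal(fresnel_reflectance(1.4, 1, 0.01), 1)  # total internal reflection
})

test_that("Henyey-Greenstein scattering has mean deflection cosine g", {
  n <- 1e6
  d0 <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  set.seed(2)
  iso <- hg_scatter(d0, 0)
  expect_equal(mean(iso[, 3]), 0, tolerance = 0.003)
  fwd <- hg_scatter(d0, 0.9)
  expect_equal(mean(fwd[, 3]), 0.9, tolerance = 0.002 / 0.9)
  # unit norm, also from oblique incident directions
  dob <- hg_scatter(matrix(rep(c(0.6, 0, 0.8), 1000), ncol = 3, byrow = TRUE), 0.5)
  expect_equal(max(abs(sqrt(rowSums(dob^2)) - 1)), 0, tolerance = 1e-9)
  # mean scattered direction preserves the incident axis for g > 0
  expect_equal(mean(fwd[, 1]), 0, tolerance = 0.003)
})

test_that("a ballistic packet in transparent tissue exits the bottom intact", {
  tis <- flat_tissue(0, 0)
  set.seed(3)
  tl <- run_transport(down_sources(10), tis, transport_config(nz_fluence = 0))
  expect_equal(unname(tl$summary["side_bottom", "excitation"]), 10)
  expect_equal(unname(tl$summary["absorbed", "excitation"]), 0)
})

test_that("fluence in a non-scattering absorber follows Beer-Lambert within 1%", {
  tis <- flat_tissue(mu_a = 0.2, mu_s = 0)
  set.seed(4)
  tl <- run_transport(down_sources(2e4), tis, transport_config(nz_fluence = 500))
  pr <- depth_profile(tl)
  sel <- pr$depth > 1 & pr$depth < 15 & pr$value > 0
  slope <- -unname(coef(lm(log(pr$value[sel]) ~ pr$depth[sel]))[2])
  expect_equal(slope, 0.2, tolerance = 0.01)
  # tally export round-trips the profile and ledger
  out <- tempfile("tally")
  paths <- write_tally(tl, out)
  fl <- read.csv(paths[["fluence"]])
  expect_equal(fl$excitation, unname(tl$fluence[, 1]))
  sm <- read.csv(paths[["summary"]])
  expect_equal(sm$excitation[sm$quantity == "launched"], 2e4)
})

test_that("launched weight is conserved to 1e-6 across absorption, exits and roulette", {
  tis <- build_layered_model(default_table(), inclusion_depth_mm = 3)
  beam <- beam_spec("photon-beam", "6MV")
  set.seed(5)
  src <- sample_source_positions(beam, count = 1e4)
  tl <- run_transport(src, tis, transport_config(nz_fluence = 0))
  expect_lt(max(weight_balance(tl)), 1e-6)
  expect_equal(tl$n_aborted, 0)
})

test_that("zero-absorption scattering medium loses weight only through boundaries", {
  tis <- flat_tissue(mu_a = 0, mu_s = 2, g = 0, depth = 10, lateral = 40)
  set.seed(6)
  tl <- run_transport(down_sources(2000), tis, transport_config(nz_fluence = 0))
  s <- tl$summary[, "excitation"]
  expect_equal(unname(s["top"] + s["side_bottom"]), unname(s["launched"]),
               tolerance = 1e-9)
  expect_equal(unname(s["absorbed"]), 0)
})

test_that("deep fluence decays at the diffusion-theory rate (three property pairs)", {
  pairs <- list(c(0.02, 1), c(0.05, 2), c(0.01, 0.5))
  for (p in pairs) {
    mua <- p[1]; musp <- p[2]; g <- 0.9
    tis <- flat_tissue(mua, musp / (1 - g), g = g, depth = 150, lateral = 400)
    set.seed(7)
    tl <- run_transport(iso_sources(4e4, z0 = 5), tis,
                        transport_config(nz_fluence = 300))
    mueff <- effective_attenuation(mua, musp)
    pr <- depth_profile(tl)
    sel <- pr$depth > 5 + 5 / mueff & pr$depth < 5 + 8 / mueff & pr$value > 0
    slope <- -unname(coef(lm(log(pr$value[sel]) ~ pr$depth[sel]))[2])
    expect_equal(slope, mueff, tolerance = 0.1)
  }
})

test_that("transport is bit-reproducible and batch merging preserves counts", {
  tis <- build_layered_model(default_table(), inclusion_depth_mm = 3)
  set.seed(8)
  src <- sample_source_positions(beam_spec("photon-beam", "6MV"), count = 1000)
  a <- run_transport(src, tis, transport_config(nz_fluence = 0), seed = 21)
  b <- run_transport(src, tis, transport_config(nz_fluence = 0), seed = 21)
  expect_identical(a$summary, b$summary)
  expect_identical(a$surface_events, b$surface_events)
  # two batches of 500 merged == one call batched 2x500 with the same seeds
  two <- run_transport(src, tis, transport_config(nz_fluence = 0),
                       batches = 2L, seed = 21)
  h1 <- run_transport(src[1:500, ], tis, transport_config(nz_fluence = 0),
                      seed = 21)
  h2 <- run_transport(src[501:1000, ], tis, transport_config(nz_fluence = 0),
                      seed = 22)
  man <- merge_tallies(h1, h2)
  expect_equal(two$summary, man$summary)
  expect_equal(two$lum, man$lum)
  # merging is order-independent for every count
  rev <- merge_tallies(h2, h1)
  expect_equal(man$summary, rev$summary)
  expect_equal(man$spec_in_tumor, rev$spec_in_tumor)
})

test_that("tissue long-pass filters the Cherenkov spectrum toward the surface", {
  rep2 <- run_inclusion_experiment("6MV", 2, events = 2e4, seed = 9)
  tl <- rep2$runs[[1]]$tally
  medw <- function(w, x) x[which(cumsum(w) / sum(w) >= 0.5)[1]]
  gen_median <- medw(tl$spec_in_tumor, tl$wl_centers)
  surf_median <- medw(tl$spec_surface_excitation, tl$wl_centers)
  expect_gt(surf_median, gen_median)
})
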