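# homogeneous single-layer tissue with flat spectral properties
flat_tissue <- function(mu_a, mu_s, g = 0.9, n = 1.4, depth = 50,
                        lateral = 100) {
  op <- optical_properties(c(350, 900), mu_a = rep(mu_a, 2),
                           mu_s = rep(mu_s, 2), g = rep(g, 2), n = rep(n, 2))
  layered_tissue(list(tissue_layer("bulk", depth, op)),
                 lateral_mm = c(lateral, lateral))
}

# n downward packets at the surface, single wavelength
down_sources <- function(n, wavelength = 600, z = 1e-6) {
  data.frame(x = 0, y = 0, z = z, ux = 0, uy = 0, uz = 1,
             wavelength = wavelength, weight = 1)[rep(1, n), ]
}

# n isotropic packets at depth z0
iso_sources <- function(n, z0, wavelength = 600) {
  d <- hg_scatter(matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE), 0)
  data.frame(x = 0, y = 0, z = z0, ux = d[, 1], uy = d[, 2], uz = d[, 3],
             wavelength = wavelength, weight = 1)
}

default_table <- function() {
  system.file("extdata", "tissue_sevenlayer_synthetic.csv", package = "celsim")
}
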