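# celsim

Monte Carlo simulation of **Cherenkov emission and Cherenkov-excited
luminescence (CEL)** in layered tissue, for researchers in biomedical
optics and radiotherapy imaging who want to reason quantitatively about
beam penumbra, depth sensitivity, and reporter-compound choice before (or
instead of) running a full GEANT4-class simulation.

During megavoltage beam delivery, secondary electrons above the Cherenkov
threshold (`511 (1/sqrt(1 - 1/n²) - 1)` keV, ≈ 220 keV at n = 1.4) emit
broadband light with Frank–Tamm spectral density ∝ 1/λ², throughout the
dose distribution. That light can excite a luminescent probe *in situ*,
while an external excitation beam decays from the surface at the effective
attenuation rate μ_eff = sqrt(3 μ_a (μ_a + μ_s′)). celsim models:

- **Cherenkov sources**: origins sampled ∝ analytic percentage depth-dose
  curves (build-up × exponential for 6/18 MV photons, peaked forms for
  6/18 MeV electrons), λ⁻² wavelengths, divergence-expanded footprints,
  calibrated relative yields (electron/photon = 100, 18 MV/6 MV = 2.5).
- **Photon transport**: weighted random walk with implicit capture,
  Henyey–Greenstein scattering, Russian roulette, Fresnel boundaries, and a
  10 µm pathlength fluence estimator, through a synthetic seven-layer skin
  + adipose + muscle stack (10 × 10 × 5 cm) with two high-absorption
  blood-network layers.
- **Luminescence**: a PtG4-like reporter (absorption bands 430/630 nm,
  emission 770 nm) inside a 1 cm spherical inclusion at 0–10 mm depth, with
  generated / exited-inclusion / reached-surface bookkeeping.
- **Analysis**: FWHM-versus-depth beam penumbra, depth profiles, surface
  histograms, spectral tallies, parameterized depth sensitivity.
- **Probe ranking**: S_j = φ_QY · Σ_i I_Ch,tissue(λ_i) · m_a,j(λ_i) over a
  compound spectra database (text dialect + deterministic synthetic
  fixtures with quadrature oracles).

## Worked example

```r
library(celsim)

report <- run_inclusion_experiment(c("6MV", "630nm"), depths_mm = c(1, 5, 7),
                                   events = 1e5, seed = 1)
report$sensitivity
#>   source depth_mm surface_per_primary generated    exited    surface packets
#> 1    6MV        1        6.310641e-05  2.235672  1.986662 0.17882098  345222
#> 2    6MV        5        2.422074e-05  2.302490  2.092490 0.06863290  438007
#> 3    6MV        7        1.483705e-05  2.665875  2.382357 0.04204288  445784
#> 4  630nm        1        2.380993e-05 17.955464 16.228738 2.38099294  869693
#> 5  630nm        5        1.864836e-06  4.770467  4.265194 0.18648360  539444
#> 6  630nm        7        6.535278e-07  2.447585  2.171189 0.06535278  403428

escape_report(report$runs[["6MV@7mm"]]$tally)[c("exited_fraction", "surface_fraction")]
#> $exited_fraction
#> [1] 0.8936489
#> $surface_fraction
#> [1] 0.01577076
```

Reading the table: `surface_per_primary` is the luminescence weight
reaching the tissue surface per beam primary (radiation beams scaled by
`cherenkov_photons_per_primary()`); `generated/exited/surface` are raw
luminescence weights in the run; `packets` counts emission packets. At 1 mm
depth the 630 nm and Cherenkov signals are the same order of magnitude; by
5 mm the Cherenkov signal leads by more than 10x. About 90 % of the
luminescence generated in the tumour exits it, while only ~2 % (1.6 % in
this seed's run) reaches the surface from 7 mm.

```r
db <- make_compound_db(20, seed = 1)
run_ranking(db$index, cherenkov = 5)   # rank against the 5 mm in-tissue spectrum
```

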