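---
title: "Modelling Cherenkov emission and Cherenkov-excited luminescence in layered tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cherenkov emission and Cherenkov-excited luminescence in layered tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celsim)
```

## The problem

During megavoltage radiotherapy, secondary electrons faster than the local
phase velocity of light emit broadband Cherenkov light throughout the
irradiated volume. Because that light is generated *in situ* — in proportion
to deposited dose — it can excite a luminescent reporter (an
oxygen-sensitive Pt-porphyrin such as PtG4) far deeper than external
epi-illumination, whose fluence decays from the surface at the effective
attenuation rate $\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$. celsim
quantifies three things about this imaging geometry:

1. the **lateral spread** (penumbra) of Cherenkov emission from a thin
   (2.5 mm, the minimum multileaf-collimator leaf width) sheet beam, as FWHM
   per millimetre of depth;
2. the **depth sensitivity** of surface-detected luminescence from a 1 cm
   spherical inclusion at 0–10 mm depth, excited by 6/18 MV x-rays or
   430/630 nm light;
3. a **spectral-overlap ranking** of candidate reporter compounds,
   $S_j = \phi_{QY}\sum_i I_{Ch,tissue}(\lambda_i)\, m_{a,j}(\lambda_i)$.

## Source model

Full coupled electron–photon transport is out of scope. Instead the package
uses the standard proxy that Cherenkov emission density follows the beam's
percentage depth-dose curve: origins are sampled with depth density
proportional to an analytic PDD (photon beams
$D(z) = (1 - e^{-\beta z})e^{-\alpha z}$ with $\beta$ solved so the maximum
falls at the clinical depth of maximum dose, 15 mm for 6 MV and 35 mm for
18 MV and $\alpha$ a typical megavoltage attenuation 0.0046–0.0035 mm⁻¹;
electron beams a Gaussian peak truncated at the practical range
$\approx E(\mathrm{MeV})/2$ cm), laterally uniform over the
divergence-expanded footprint (each side grows by $2\,\mathrm{SSD}\tan\theta$;
1 cm at 0.9 m with a 0.97° half-angle gives the observed ~4 cm side).
Wavelengths follow the Frank–Tamm $\lambda^{-2}$ law by inverse-CDF sampling
on 350–900 nm; emission directions are isotropic, a deliberate
simplification: after multiple Coulomb scattering the secondary-electron
directions — and hence the Cherenkov cones — are broadly distributed, and
deep-tissue diffuse quantities are insensitive to the residual anisotropy.
An optional Gaussian penumbra blur (default 0 for photon beams, 1 mm for
electron beams) represents the wider lateral spread of electron secondaries
that pure footprint sampling cannot produce.

Electron beams produce ~100× the Cherenkov light of the matched photon
beam, and 18 MV ~2.5× that of 6 MV; these relative yields are calibration
inputs (`relative_yield()`), not derived quantities. For cross-modality
comparisons at equal primary budgets an absolute anchor is also needed:
`cherenkov_photons_per_primary()` multiplies the Frank–Tamm photon count
per track length over 350–900 nm (~39 photons/mm at $n = 1.4$) by an
assumed 0.9 mm mean above-threshold secondary-electron track length per
6 MV primary (≈20 % interaction probability in the 5 cm volume × ≈4.5 mm
above-threshold electron path). This sets the scale once, from physics,
before any comparison is run; only the cross-modality *ratios* depend on it.

Optical sources (430/630 nm) are monochromatic downward photons spread over
the same divergence-expanded footprint as the radiation beams and attenuated
by the specular Fresnel entry loss; the <1.3° ray tilt is neglected.

## Tissue model and transport

The volume is 10 cm × 10 cm × 5 cm: a seven-sublayer skin stack (~1.5 mm,
including two highly vascular "blood network" plexus layers), 5 mm adipose,
then muscle. The published seven-layer optical properties are not
reproduced here; the shipped table is **synthetic** — analytic chromophore
shapes (blood with Soret-like 418 nm and Q-band 555 nm peaks plus a red/NIR
floor, a melanin power law, a reduced-scattering power law per layer) with
literature-typical magnitudes, constrained so the blood layers have at
least twice the $\mu_{eff}$ of the adjacent dermis at the 770 nm emission
band and so the 600–900 nm window is red-transmissive. It is a replaceable
CSV input, never hard-coded.

Transport is a weighted Monte Carlo random walk (compiled kernel):
exponential free paths $s = -\ln u/\mu_t$; implicit capture (each
interaction deposits $w\,\mu_a/\mu_t$); Henyey–Greenstein scattering;
Russian roulette below weight $10^{-4}$ with survival 1/10 (the
corresponding 10× boost keeps the expected weight ledger exact, and every
tally is checked to balance to $10^{-6}$ relative); unpolarized Fresnel
reflection/refraction wherever the refractive index changes (layer
interfaces, the inclusion surface, and the air boundary on top, where
transmitted packets become surface detections). Side and bottom boundaries
absorb: with a centred ≤4 cm field in a 10 cm volume, lateral diffuse
losses are negligible, and this matched-boundary choice avoids an
unphysical mirror. Fluence uses the pathlength estimator
(weight × pathlength per voxel volume) on a 10 µm z-grid — at that
resolution a collision estimator would be hopelessly noisy. Wavelengths are
fixed per packet; each packet caches its per-medium properties
(linearly interpolated in wavelength, clamped at 350/900 nm — the grid is
dense enough that the interpolation rule is immaterial).

Free paths are re-sampled after each boundary crossing rather than carrying
residual optical depth across; by the memorylessness of the exponential the
two schemes are statistically identical.

## Luminescence

The inclusion's absorption is $b(\lambda) + \kappa\, m_a(\lambda)$:
a background (default half the muscle absorption — tumour tissue in the NIR
window is weakly absorbing) plus the fluorophore term, so the fraction of
any absorption deposit belonging to the fluorophore is exactly
$f(\lambda) = \kappa m_a/(\kappa m_a + b)$. Because the study compound's
concentration is unknown, $\kappa$ defaults to the value at which the
fluorophore captures 50 % of inclusion absorption at its 630 nm band — all
escape *fractions* and modality *ratios* reported by the package are
insensitive to this choice, only absolute luminescence yield scales with it.
The fluorophore itself is a synthetic PtG4-like model: Gaussian absorption
bands at 430 nm (unit amplitude, σ 22 nm) and 630 nm (amplitude 0.55,
σ 28 nm), single Gaussian emission at 770 nm (σ 20 nm), quantum yield 0.07
(typical of Pt-porphyrin dendrimers). Only band positions are reported for
the real compound, so shapes and widths are package choices.

At each deposit inside the sphere the kernel spawns one emission packet of
weight $\mathrm{d}w\, f(\lambda)\, \phi_{QY}$ at the deposit position,
isotropic, with wavelength drawn from the emission density — the
expectation-equivalent weighted form of the probabilistic emission rule,
which is also implemented verbatim (`emit_luminescence()`) and
cross-checked in the tests. Luminescence is single-generation: 770 nm
emission lies outside the modelled absorption bands, so re-excitation
cascades are physically negligible and deliberately not modelled.
Phosphorescence lifetime (time gating) is likewise out of scope. The
tallies record generated weight, first outward crossing of the sphere
boundary, and surface arrivals; the nesting
$N_{surface} \le N_{exited} \le N_{generated}$ is a structural invariant.

## Analysis conventions

*FWHM* is measured between the outermost half-maximum crossings of a binned
lateral profile, linearly interpolated, invariant to count rescaling and
translation; profiles clipped by the histogram range carry a
`boundary_truncated` flag, and an optional moving-average smoother (off by
default) suppresses the upward bias of a noisy peak estimate. FWHM-by-depth
defaults to emission *origins* (final positions are also supported): the
origin spread is the beam-penumbra quantity of interest.

*Depth sensitivity* is deliberately parameterized: the source study never
defines it numerically, so `depth_sensitivity()` takes a mandatory
threshold and reports the first depth where the surface signal falls below
that fraction of its shallowest value. The scientifically robust statement —
and the one the tests assert across thresholds 0.01–0.5 — is the ordering
430 nm < 630 nm < Cherenkov.

*Ranking* resamples each compound's absorption spectrum to the Cherenkov
grid, peak-normalizes it by default (the database mixes molar absorptivity
with normalized absorbance; a switch restores raw units), multiplies by the
spectrum and quantum yield, sums inside 350–850 nm, and normalizes to the
top compound with ties broken by name. Emission spectra and detector
response are excluded by design, with a hook for an optional
detector-response spectrum. The in-tissue spectrum can come from a
transport tally (the in-tumour detector) or from the analytic stand-in
$\lambda^{-2} e^{-\int_0^d \mu_{eff}(\lambda, z)\,dz}$; note that the
stand-in filters the *whole* spectrum through the overlying stack, whereas
a real in-tumour field retains locally generated blue light, so the
stand-in is the harsher long-pass filter. "Moderate" attenuation in the
rank-stability test means a spectral optical-depth contrast ≤ 0.5 across
the band — under skin-like filtering, which suppresses blue by orders of
magnitude, large rank rearrangements are expected, not a defect.

## Synthetic fixtures and what passing tests show

Every input is generated by code under a fixed seed: tissue tables
(including transparent and homogeneous oracle presets), Gaussian-band
compound databases with sidecar scores computed by independent 0.1 nm
quadrature, analytic Cherenkov spectra, and event sets with closed-form
moments (the depth-widening fixture applies its width law per 1 mm slab
centre so the slab FWHM oracle is exact). The fixtures reproduce the
qualitative structure of real data — blood-layer absorption spikes, the
red-transmissive window, two-band reporter absorption — but not any
specific published property set; agreement of escape fractions and
modality ratios with the reference values therefore shows the *mechanism*
is right at realistic property magnitudes, not that any individual tissue
is matched.

## Numerical choices and problem sizes

Monte Carlo checks run at 2×10⁴–4×10⁵ packets with seeded RNG: large enough
that the tested contrasts (escape fractions, modality ratios, monotone depth
trends) exceed their Monte Carlo error several-fold, small enough for a
desk-scale run; the acceptance script uses 2×10⁵ packets for the 7 mm
escape-fraction run (≥10⁵ luminescence packets are generated there) and
4×10⁵ packets per source representing 10⁶ primaries for the 5 mm modality
ratio. Batching splits the source list contiguously with per-batch seeds
derived from the run seed, so a fixed (seed, batch plan) is bit-reproducible
and merged tallies are exactly the sum of their parts. Degenerate inputs
fail loudly: zero generated luminescence makes escape fractions an error,
not a zero; all-zero profiles have no FWHM; curves that never cross return
the deepest sampled depth with a `saturated` flag.

## Known limitations

- No coupled high-energy transport: beam penumbra is an input blur, not an
  emergent property, and absolute dosimetry is out of scope.
- Polarization, time-resolved transport, refractive ray bending within a
  layer, and oxygen-dependent lifetime are not modelled.
- The shipped optical properties are synthetic; absolute escape
  percentages inherit their uncertainty (the stated tolerances reflect
  this), while orderings and ratios are robust.
- The compound database dialect is a concrete reconstruction; rankings of
  the real, version-dependent database contents are not reproduced.

## A small worked run

```{r, eval = FALSE}
report <- run_inclusion_experiment(c("6MV", "630nm"), depths_mm = c(1, 5),
                                   events = 1e5, seed = 1)
report$sensitivity
escape_report(report$runs[["6MV@5mm"]]$tally)
```
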