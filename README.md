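# bilox

Quantitative analysis of how amphiphilic antioxidants — prototypically the
bile acids TUDCA and UDCA — interact with lipid membranes and reactive
oxygen species. The package bundles, as one tested R pipeline, the five
measurement analyses such a study rests on, plus a synthetic-data module
that generates every input class with known ground truth so the whole
pipeline can be exercised and validated without instrument data.

It is aimed at membrane biophysicists and photochemists who have
time-resolved phosphorescence decays, EPR spectra (oximetry or spin-label),
MD coordinate trajectories, or Raman spectra in hand and want transparent,
scriptable versions of the standard reductions.

## What it computes

**Singlet-oxygen quenching kinetics.** A ¹O₂ phosphorescence decay at
1270 nm is fit as `I(t) = A·exp(−k_obs·t) + b` (Levenberg–Marquardt, via
minpack.lm). Across quencher concentrations the pseudo-first-order rate
follows the Stern–Volmer relation

    k_obs = k₀ + k_q·[Q]

so a weighted linear regression yields the intrinsic decay constant k₀
(reciprocal of the unquenched lifetime τ = 1/k₀) and the bimolecular
quenching constant k_q (M⁻¹s⁻¹).

**EPR oximetry.** Oxygen consumption during free-radical (Fenton-driven)
lipid peroxidation is read from a spin-probe linewidth time series via a
linear calibration; the initial uptake rate dO₂/dt is the negative OLS
slope over an early window, and groups are compared by percent reduction
with a two-sided Welch t-test.

**Spin-label order and polarity.** From motionally narrowed n-PC nitroxide
spectra the outer and inner hyperfine splittings (2A∥′, 2A⊥′) give the
segmental order parameter in the Marsh ratio form

    S = (A∥′ − A⊥′) / (Azz − (Axx + Ayy)/2) · a_N / a_N′ ,  a_N′ = (A∥′ + 2A⊥′)/3

with an optional inner-splitting linewidth correction. From rigid-limit
spectra the outermost extrema separation is 2Azz, the standard depth-resolved
polarity (water-penetration) measure.

**Trajectory descriptors.** From multi-frame GRO/PDB coordinates:
the molecular order parameter per acyl-chain carbon,
`S_mol(n) = ⟨0.5·(3cos²θ_n − 1)⟩` with θ_n the angle between the
C(n−1)→C(n+1) vector and the bilayer normal, with block-averaged standard
errors; a geometric hydrogen-bond census (D···A ≤ 3.5 Å, H–D–A ≤ 30° by
default) between named atom groups; mass-density profiles along the normal;
minimum-image radial distribution functions; and solute depth traces with
water/interphase/core residency classification.

**Raman band-ratio semiquantification.** Replicate averaging, polynomial or
rubberband baseline correction, trapezoidal band integration, and the
2937/1453 cm⁻¹ CH-stretch/CH-bend ratio as a solute-abundance marker,
compared across groups with Shapiro–Wilk, one-way ANOVA and Tukey HSD.

## Worked example

```r
library(bilox)

# quenching: simulate a photon-counting titration and regress
conc <- c(0, 5.2e-3, 12e-3, 19.1e-3)                   # mol/L
traces <- gen_decay_series(k0 = 8.82e3, kq = 1.99e5, concentrations = conc,
                           noise = "poisson", seed = 1)
fits <- lapply(traces, fit_monoexponential)
stern_volmer(fits, conc)
#> Stern-Volmer: kq = (2e+05 +/- 1.1e+03) 1/(M s)
#>   k0 = (8.83e+03 +/- 12) 1/s, lifetime = 113.26 us, R^2 = 0.9999

# oximetry: three control and three treated uptake traces
ctl <- lapply(11:13, function(s) initial_uptake_rate(gen_o2_trace(9.02, sigma = 0.5, seed = s)))
tud <- lapply(14:16, function(s) initial_uptake_rate(gen_o2_trace(6.77, sigma = 0.5, seed = s)))
compare_rates(treatment = tud, control = ctl)
#> Uptake rates: control 9.01 +/- 0.02, treatment 6.79 +/- 0.01 uM/min
#>   reduction 24.6%, Welch t = -153.316 (df 2.92), p = 8.69e-07 *

# spin-label order: extract S from a synthetic 7-PC spectrum
tc <- tensor_constants()
hp <- hyperfine_for_order(0.55, tc)
sp <- gen_nitroxide_spectrum(hp$A_par, hp$A_perp, label_position = "7-PC")
order_parameter(hyperfine_extrema(sp, tc), tc)
#> [1] 0.550
```

The fitted slope (2.0×10⁵ M⁻¹s⁻¹) recovers the generating quenching
constant, the intercept's reciprocal is the unquenched ¹O₂ lifetime
(~113 µs), the uptake comparison reproduces the generating ~25% reduction
with p < 0.05, and the Marsh extraction returns the order parameter the
spectrum was built with.

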