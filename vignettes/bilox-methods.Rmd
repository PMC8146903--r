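---
title: "Methods and design of bilox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of bilox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilox)
```

bilox implements the quantitative reductions behind a membrane-antioxidant
study of hydrophilic bile acids: singlet-oxygen quenching kinetics, EPR
oximetry of radical-driven oxygen uptake, spin-label order and polarity
extraction, bilayer-trajectory descriptors, and Raman band-ratio
semiquantification. Each stage has a synthetic-data generator with known
ground truth, so every estimator in the package can be validated end to end
without instrument data. This vignette records the models, the defaults
and why they were chosen, and what the synthetic validation does and does
not demonstrate.

## Decay kinetics and Stern–Volmer analysis

A singlet-oxygen phosphorescence decay is modelled as
$I(t) = A e^{-k_{\mathrm{obs}} t} + b$ and fit by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`). The baseline $b$ is always a fitted
parameter: detector dark counts are never exactly zero, and fitting $b$
makes the recovered rate invariant to any constant offset (a property the
test suite asserts). Starting values are deterministic — $k$ from a
log-linear regression on the upper half of the background-subtracted
decay, $A$ from the maximum count, $b$ from the tail mean — so repeated
fits of the same trace are bit-identical. A `skip_initial` window (default
0 µs) can drop early points contaminated by excitation artifacts.

`stern_volmer()` regresses $k_{\mathrm{obs}} = k_0 + k_q c$ across
quencher concentrations, by default weighting each point with
$1/\mathrm{SE}(k_{\mathrm{obs}})^2$; an unweighted fit is available since
published analyses often omit weights. The intercept's reciprocal is the
unquenched lifetime, reported in µs. Units are mol/L throughout;
rescaling the concentration axis rescales the slope reciprocally, which
is tested.

The photon-count generator draws Poisson counts around the analytic mean
(photon-counting statistics); Gaussian noise is offered as a faster
alternative. Defaults — amplitude 2×10⁴ counts over a 0–500 µs grid of
251 points, five concentrations evenly spaced across 5.2–19.1 mM — mirror
a realistic titration of a weak quencher with ~10⁶ total counts per
trace; the concentration spacing is a package choice, as only the span is
typically reported.

## Oximetry

Spin-probe EPR linewidth grows linearly with dissolved oxygen, so the
calibration model is affine: $\mathrm{lw} = \mathrm{lw}_0 + s\,[\mathrm{O_2}]$.
The shipped defaults (baseline 0.014 mT, sensitivity 5×10⁻⁵ mT/µM) are
working conventions for synthetic data, not measured constants — real
analyses must supply instrument calibrations.

The "initial" uptake rate is the negative OLS slope over the first
10 minutes by default. Radical-driven uptake is steepest early, before
substrate depletion; the window is configurable because the choice is not
standardised. Group comparison reports the percent reduction of the
treatment mean and a two-sided Welch t-test (unequal variances are the
safe default for small instrument replicate groups; the flag threshold is
α = 0.05). Rates at or below 1.48 µM/min are additionally flagged as
background, the ceiling observed when the radical generator is disabled.

## Spin-label EPR: splittings, order parameter, polarity

The nitroxide generator is deliberately minimal: each $m_I = \pm 1$
hyperfine component of an axially averaged powder pattern is represented
as a Gaussian-smoothed span between the parallel and perpendicular
turning points, whose first derivative therefore peaks exactly at
$B_0 \pm A_\parallel$ and $B_0 \pm A_\perp$; the central line is a
derivative Gaussian. This is not a spin-Hamiltonian simulation — there is
no g-anisotropy, no slow-motional lineshape, no orientation-dependent
intensity — but it places every feature a splitting-based analysis reads,
which is exactly what is needed to validate the extractors. When the two
couplings coincide within a linewidth the generator degrades gracefully
to three symmetric derivative-Gaussian lines.

Extraction uses local extrema above a prominence threshold (2% of the
amplitude range by default), refined by three-point parabolic
interpolation. The outer splitting is the distance from the leftmost
prominent maximum to the rightmost prominent minimum; the inner splitting
from the leftmost prominent minimum to the rightmost prominent maximum.
We use outermost-prominent rather than global extrema because the central
line of a nitroxide spectrum is roughly an order of magnitude taller than
the outer features; a global argmax would land on it. Extrema at the grid
boundary raise an error (the sweep was too narrow) rather than returning
a truncated splitting.

The order parameter uses the Marsh ratio form
$$S = \frac{A_\parallel' - A_\perp'}{A_{zz} - (A_{xx}+A_{yy})/2}
      \cdot \frac{a_N}{a_N'},\qquad a_N' = \tfrac{1}{3}(A_\parallel' + 2A_\perp'),$$
with the optional inner-splitting correction
$A_\perp = A_\perp' + 1.4\,[1 - (A_\parallel'-A_\perp')/(A_{zz}-(A_{xx}+A_{yy})/2)]$ G.
Both corrections are individually switchable because the literature
contains several variants and published analyses rarely state which was
used; with the polarity factor on and the observed isotropic coupling
equal to the crystal $a_N$, the formula inverts exactly, which is how
`hyperfine_for_order()` designs spectra of known S. The default tensor
constants (6.3, 5.8, 33.6) G are a common doxyl-label convention and are
configurable. Rigid-limit polarity is simply the outer splitting, equal
to $2A_{zz}$.

Because published depth profiles are typically plots rather than tables,
the package's validation targets are *relative* differences: spectrum
pairs built with ground-truth S differing by 7% (7-PC, around S = 0.55)
and 15% (16-PC, around S = 0.20) must be recovered within 1–2 percentage
points. The absolute anchor values are package choices representative of
fluid phosphatidylcholine membranes at those depths.

## Trajectory descriptors

The molecular order parameter of carbon $n$ is
$S_{mol}(n) = \langle \tfrac{1}{2}(3\cos^2\theta_n - 1)\rangle$ with
$\theta_n$ the angle between the segmental vector
$\mathbf{C}_{n-1}\rightarrow\mathbf{C}_{n+1}$ and the bilayer normal.
(The cosine is squared; without the square the quantity would not be
bounded by $[-0.5, 1]$.) Errors are standard errors over non-overlapping
blocks of the frame axis, five equal blocks by default — the conventional
block-averaging protocol for correlated MD time series. The analysis
window defaults to the final 40% of frames, treating the earlier part as
equilibration. Carbons participating in a declared double bond are
tagged `sp2` in the output rather than remapped: the various sp²
correction conventions differ, so the package keeps the raw
segmental-vector estimate and leaves exclusion or remapping to the
caller.

Hydrogen bonds use the common geometric criterion, donor–acceptor
distance ≤ 3.5 Å and H–donor–acceptor angle ≤ 30°, both configurable.
Donors are O/N atoms with a covalent hydrogen (assigned once from frame-1
geometry within 1.2 Å and the same residue); acceptors are O/N atoms.
Counts are reported per frame pair-of-groups, both donor directions
included, as time mean ± SD, optionally divided by a molecule count so a
census over several solute copies reads "per molecule". The
implementation is validated against an exhaustive $O(N^2)$ enumeration
oracle.

Density profiles bin atoms by z relative to the midplane (mean lipid
phosphorus z), with bins tiling exactly one box length so that the sum of
density × bin volume equals the selected mass exactly — asserted as a
conservation test. RDFs use the orthorhombic minimum-image convention and
refuse `r_max` beyond half the smallest box length. Solute depth traces
are mass-weighted COM z minus midplane, classified into core /
interphase / water by configurable |z| thresholds (8 and 24 Å defaults,
appropriate for the toy geometry).

The toy trajectory generator builds "wobbling-rod" chains segment by
segment: the analysed vector of every segment is drawn directly with
$\cos^2\theta$ sampled uniformly on a symmetric interval whose mean is
$(2S_{target}+1)/3$, so the expected $S_{mol}$ equals the target exactly,
per segment, with nonzero sampling variance. Waters are rigid three-site
molecules uniform in the solvent slabs; solutes are small residues with
named donor/acceptor atoms at controllable depths. This emulates what the
estimators consume — geometry, periodicity, group structure — but none of
the physics that makes real bilayers hard: no excluded volume, no
inter-atomic correlations, no conformational dynamics. Passing tests
therefore demonstrate estimator correctness, not force-field realism.

## Raman semiquantification

Band areas are trapezoidal integrals over configurable windows —
2850–3000 cm⁻¹ for the 2937 cm⁻¹ CH-stretch marker and 1420–1480 cm⁻¹
for the 1453 cm⁻¹ CH-bend reference (band centres are the published
anchors; window widths are package choices). "Relative integral
intensity" is read as baseline-corrected band area. Polynomial baselines
use iterative clipped refitting (fit, clip above the fit, refit), which
removes a pure polynomial of the declared degree exactly on band-free
spectra and is not dragged up by bands; a rubberband (lower convex hull)
alternative suits convex baselines. The 2937/1453 ratio is invariant to
overall intensity scaling by construction. Group comparison follows the
conventional chain — Shapiro–Wilk per group, one-way ANOVA, Tukey HSD —
at α = 0.05. Since published fraction ratios are plot-only, validation
asserts ordering (the fraction generated with the larger marker-band area
must score the higher ratio) and detection power (a ≥ 2-pooled-SD
separation with 10 replicates per group must reach significance in ≥ 95%
of seeds), not absolute values.

## Numerical choices and degenerate inputs

- Extrema refinement is 3-point parabolic interpolation, clamped to the
  bracketing grid interval; boundary extrema raise errors.
- Fits that fail to converge raise errors rather than returning silent
  garbage; all-zero or constant signals are rejected on input.
- `with_seed()` gives every generator bit-reproducibility for identical
  (parameters, seed) without disturbing the caller's RNG stream.
- Units are fixed: µs (decays), min (oximetry), gauss (field; mT accepted
  with ×10 conversion), Å (coordinates; GRO nm converted on read/write),
  cm⁻¹ (Raman), kg/m³ (densities, 1 amu/Å³ = 1660.539 kg/m³).
- Only orthorhombic boxes are supported; triclinic input is rejected with
  a clear error rather than silently mis-imaged.
- GRO round-trips are lossless after one write (coordinates quantised to
  the format's 0.001 nm); analysis results on round-tripped coordinates
  agree to that precision.

## Problem sizes used in validation

The shipped tests and the acceptance script run at desk scale: 100-seed
Poisson decay replicates of 251 points; oxygen traces of 101 points;
spectra of a few thousand field or wavenumber points; trajectories up to
20 chains × 12 carbons × 50 frames (10⁴ segment samples, enough for
three-standard-error recovery checks); 100-seed significance sweeps with
10 Raman replicates per group. The full suite completes in well under a
minute on one core. These sizes were chosen so that statistical recovery
criteria (3 SE bands, 2% means over 100 seeds) are sharp enough to catch
estimator bias while remaining quick to rerun.

## Known limitations

- The nitroxide model cannot probe slow-motional lineshapes, g-tensor
  effects, or unresolved inner splittings typical of 5-PC spectra at low
  temperature; `inner_extrema_splitting()` errors out in that regime and
  points to the rigid-limit polarity mode.
- The hydrogen-bond census assigns covalent hydrogens from the first
  frame only, which assumes bonded topology does not change over the
  trajectory (true for classical MD).
- The sp² tagging approach defers the double-bond correction to the
  user; profiles that include tagged carbons mix conventions if compared
  against analyses that remap them.
- Welch's t-test and the ANOVA/Tukey chain assume independent replicates;
  neither corrects for within-sample autocorrelation of instrument time
  series.
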