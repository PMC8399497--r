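---
title: "Methods: FRET photophysics and ratiometric quantification in fretsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET photophysics and ratiometric quantification in fretsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretsense)
```

# Scope

`fretsense` implements the complete data analysis of a nanoparticle-donor
FRET sensing experiment: a fluorescent nanoparticle donor (the motivating
system is carbon dots, CDs) binds a light-absorbing analyte acceptor
(riboflavin, RF), donor emission is quenched in proportion to the bound
fraction and the per-complex transfer efficiency, and the sensitized
acceptor emission provides the second channel of a ratiometric readout.
This vignette documents the models, the unit conventions, the synthetic
data generator, and the numerical and design choices.

# The photophysical model

## Efficiency

Transfer efficiency is measured from integrated donor fluorescence,

$$E = 1 - \frac{F_{DA}}{F_D},$$

where $F_D$ is the integrated donor emission alone and $F_{DA}$ with the
acceptor present (`efficiency_from_fluorescence`). Because a nanoparticle
surface can bind several acceptors simultaneously, the geometric form is
the multi-acceptor point-dipole expression

$$E = \frac{n R_0^6}{n R_0^6 + r^6}$$

(`efficiency_from_distance`), with $n \ge 1$ equivalent acceptors at
distance $r$ and Förster distance $R_0$; $r = R_0$, $n = 1$ gives exactly
50% efficiency. The inversion $r = R_0\,[n(1-E)/E]^{1/6}$
(`distance_from_efficiency`) is undefined at $E \in \{0, 1\}$ and the
package refuses those inputs rather than returning infinities.

`fret_params` bundles $(J, E, R_0, r, n, \kappa^2, \eta, \phi)$ and
records a consistency flag: whether the supplied $(E, R_0, r, n)$ jointly
satisfy the geometric relation within a relative tolerance (1% by
default). Published parameter sets are not always mutually consistent —
each quantity may be derived through a different equation — so the package
reports the flag instead of silently re-deriving one value from the
others. Distance estimates are trustworthy only in the band
$0.5 R_0 < r < 1.5 R_0$ (strict bounds; `check_regime`), outside of which
the sixth-power law makes $r$ ill-conditioned in $E$.

## Overlap integral and Förster distance

The overlap integral is implemented in its area-normalized form

$$J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
d\lambda}{\int F_D(\lambda)\,d\lambda},$$

even though the unnormalized integrand is sometimes quoted: without the
normalization $J$ would depend on the arbitrary intensity units of the
fluorimeter and could not feed a dimensional constant. With $\lambda$ in
nm and $\varepsilon_A$ in M⁻¹cm⁻¹, $J$ comes out in M⁻¹cm⁻¹nm⁴ and is
also returned in M⁻¹cm³ (factor $10^{-28}$), the unit expected by

$$R_0^6\,(\mathrm{cm}^6) = 8.79\times 10^{-25}\,\kappa^2\,\eta^{-4}\,
\phi\,J.$$

Defaults are $\kappa^2 = 2/3$ (isotropic dynamic averaging — reasonable
for a freely diffusing dye against a rotating nanoparticle, wrong for
rigidly oriented systems) and $\eta = 1.336$ (aqueous buffer).
`forster_distance` cross-validates every call against the equivalent
Ångström-scale formulation
$R_0(\text{Å}) = 0.211[\kappa^2\eta^{-4}\phi J(\mathrm{M^{-1}cm^{-1}nm^4})]^{1/6}$
and aborts if the two disagree by more than 1%: the only way they can
disagree is a $J$ passed in the wrong units, which is the classic silent
failure of FRET scripts.

## Unmixing and titration analysis

Composite titration spectra are decomposed against the measured
donor-only and acceptor-emission references by nonnegative least squares
(`unmix`). Reference-based unmixing was chosen over free-form Gaussian
peak fitting because both references exist in every titration experiment
and the decomposition is then deterministic and testable. With only two
components the NNLS solution is closed-form: solve the unconstrained 2×2
normal equations; if a coefficient is negative, clamp it to zero and
refit the other by projection. References whose cosine similarity exceeds
0.999 are rejected as ill-posed. Residuals are reported as RMS fractions
of the composite RMS.

`analyze_titration` chains the modules: unmix each spectrum, convert the
donor coefficient into $F_{DA}$ over a fixed donor window (390–500 nm by
default, bracketing the 441/456 nm donor band; configurable because
instruments differ), build the quench table, and fit the modified
Stern–Volmer model. For a binding-limited titration the donor quenching
at acceptor concentration $c$ is $\theta(c)\,E$ with
$\theta = Kc/(1+Kc)$, so the Lehrer linearization

$$\frac{F_0}{F_0 - F} = \frac{1}{f_a} + \frac{1}{f_a K [Q]}$$

recovers $K$ from its slope/intercept ratio and the per-complex
efficiency $E$ as the "accessible fraction" $f_a$. The Lehrer form is the
standard "modified" Stern–Volmer equation and yields a single $K$ from a
linear plot; concentrations are converted to molar before fitting so $K$
is reported in M⁻¹. Points with $F = F_0$ (no measurable quenching) are
excluded with a warning; fewer than three usable points, or a negative
fitted $K$, abort with a model-misfit error.

## Efficiency clipping

Noise can push $F_{DA}$ slightly above $F_D$. Excesses up to 2% clip the
efficiency to 0 with a warning; anything larger aborts, because a >2%
excess indicates a units or baseline mistake, not photon noise. The same
2% guard is applied in `quench_table`.

# The sensor-application layer

The ratiometric readout `ratiometric_signal` is the ratio of window-mean
intensities around 521 nm (acceptor) and 441 nm (donor); 11 nm windows
(516–526 / 436–446 nm) are used instead of single-pixel values for
robustness to grid alignment, and are configurable. `calibrate` fits
ratio against concentration by ordinary least squares and computes the
detection limit as $DL = 3\sigma_{\text{blank}}/|S|$ with the sample
($n-1$) standard deviation of the blank replicates — the standard
analytical convention at $n = 10$ blanks. The linear range is reported
descriptively as the fitted span; no breakpoint detection is attempted.
`standard_addition` fits ratio against added concentration, estimates the
analyte as the magnitude of the x-intercept, computes a recovery per
spiked level as $100 \cdot \text{found}/\text{added}$ with
found $= (\text{ratio}_i - b_0)/b_1$, and reports the RSD as the relative
spread of the per-level base-concentration estimates
$\text{ratio}_i/b_1 - \text{added}_i$ (each level is an independent
estimate of the base concentration, so their spread is the natural
replicate dispersion of the method).

Viability is $100\,A_S/A_C$ from crystal-violet absorbances at 595 nm;
replicate wells are averaged per condition before the ratio because
treated and control wells are unpaired on a plate. The reactivity
classification uses viability bands none ≥ 90%, mild 70–90%, moderate
30–70%, severe < 30%. The five-point scale is usually quoted
qualitatively (70–90% mild, ≈55–65% moderate, ≈17% severe); these
defaults are consistent with those mappings, cover $[0, \infty)$ without
gaps, and are overridable via `reactivity_bands()`.

# The synthetic-data generator

No instrument data ship with the package; every analysis stage is
validated against simulated experiments with planted ground truth.

**What it emulates.** Donor emission is a Gaussian band per excitation
wavelength — centers 420, 440 and 456 nm for excitation at 320, 340 and
360 nm, a common width of 40 nm (FWHM ≈ 94 nm, typical of carbon-dot
emission), amplitudes increasing toward 360 nm excitation, and amplitude
linear in donor concentration. The acceptor absorptivity is a Gaussian at
445 nm with σ = 25 nm and peak 1.2×10⁴ M⁻¹cm⁻¹ (riboflavin-like); the
acceptor emission a Gaussian at 521 nm, σ = 26 nm. With equal donor band
widths, the $\lambda^4$ weighting of the overlap integral makes the
456 nm band the maximal-overlap choice, matching the physics of the
motivating system; excitation-dependent widths of a few nm would be
equally realistic but do not change any planted recovery. Titrations
follow the cumulative-aliquot protocol (ten 20 µL additions of a 1000 µM
stock into 3 mL, reaching 62.5 µM): binding follows a 1:1 Langmuir
isotherm $\theta = Kc/(1+Kc)$ — the simplest isotherm consistent with a
single association constant — and the composite spectrum is

$$(1 - \theta E)\,D(\lambda) + \theta E\, g\, A_D\, \hat{A}(\lambda)
 + d\,c\,A_{\text{em}}(\lambda),$$

where $D$ is the donor reference, $\hat{A}$ the area-normalized acceptor
emission, $A_D$ the donor area (so with transfer gain $g = 1$ the photons
removed from the donor reappear under the acceptor band), and $d$ the
direct-excitation fraction, default 0 (direct acceptor emission is
negligible at the donor excitation wavelength in the motivating system)
with a nonzero option for robustness testing. Noise is multiplicative
Gaussian on intensities, clipped at zero, because fluorescence shot and
source noise scale with signal. All randomness flows from one integer
seed through an RNG-state-preserving wrapper; identical configurations
give bit-identical data and generators never disturb the caller's RNG
stream.

**Presets.** `low_donor`/`high_donor` plant per-complex efficiencies of
0.91 and 0.84 at donor concentrations 5×10⁻³ and 4×10⁻² mg/mL (the
efficiency falls as donor concentration rises, i.e. as the acceptor:donor
ratio falls). `sv_table1` plants $K = 2.7\times 10^4$ M⁻¹. The
`calibration_dl` preset uses slope 0.12 ratio/µM over 0–11 µM and blank
σ = 10⁻³ ratio units, chosen so the planted detection limit
$3\sigma/S$ is exactly 0.025 µM; the slope value itself is arbitrary
(only the ratio is identified) and was fixed at a realistic
ratio-per-µM magnitude. The `standard_addition` preset uses a 2 µM base
concentration, additions 0–7 µM in 1 µM steps (seven spikes), and 0.4%
multiplicative ratio noise — set analytically so that per-level base
estimates scatter by about 1%, keeping the RSD comfortably below the
sub-4% regime the method is expected to operate in. The `viability`
preset plants a 0.8 treated/control fraction with 6 wells per condition
and 5% lognormal well-to-well CV.

**What it does not emulate.** Photon-level counting statistics,
instrument response functions, inner-filter effects, donor dilution
during titration, scattering baselines, and real beverage matrix effects
are all absent. Passing the planted-recovery tests therefore demonstrates
correctness of the estimators under the stated generative model, not
robustness to every artifact of real spectra; the no-extrapolation and
clipping guards are the package's defenses against the most common real
failure modes.

# Numerical choices

* **Quadrature.** Trapezoidal rule everywhere, including window
  endpoints obtained by linear interpolation. Spectra are densely
  sampled (the fixtures use 1 nm steps, a typical instrument export
  granularity), where the trapezoid is second-order accurate and robust
  to irregular grids; higher-order rules buy nothing on measured data.
* **No extrapolation.** `resample_spectrum` refuses grids outside the
  support; the overlap integral intersects the two supports. Silent
  extrapolation is the easiest way to corrupt $J$.
* **Duplicate wavelengths** in files collapse to the arithmetic mean —
  deterministic and order-independent.
* **Degenerate inputs** fail loudly: all-zero spectra cannot be
  normalized, disjoint supports cannot be overlapped or integrated,
  collinear references cannot be unmixed, constant absorbances give no
  gradient, and zero-sensitivity calibrations abort.
* **Serialization.** Written spectra and YAML configurations carry 17
  significant digits, so file round-trips preserve doubles exactly; flat
  key/value reports carry full precision plus a 6-digit display value.

# Test problem sizes

The validation suite exercises Monte-Carlo recovery at the scale the
statistics require rather than the scale an instrument would produce:
100-seed efficiency recovery at 1% spectral noise, 200-seed
detection-limit and binding-constant recovery, 500-seed
standard-addition recovery, and a 0.01 nm brute-force quadrature as the
independent oracle for the overlap integral. These sizes give sub-percent
Monte-Carlo error on every median/mean compared while keeping the whole
suite around ten seconds.

# Known limitations

* The Lehrer analysis assumes purely static, binding-limited quenching;
  mixed static/dynamic quenching or multiple binding-site classes would
  bias $K$ and need a global fit outside the package's scope.
* $\kappa^2 = 2/3$ is an assumption, not a measurement; orientation
  constraints propagate directly into $R_0$ as its sixth root.
* The efficiency returned by `analyze_titration` leans on the 1:1
  isotherm; cooperative binding would distort the Lehrer line and the
  $R^2$ of the fit is the diagnostic to watch.
* The linear range of a calibration is asserted by the experiment
  design, not detected; saturating data will show up only as a depressed
  $R^2$.
* Absorbance spectra cannot be used in the overlap integral without
  conversion to molar absorptivity (path length and concentration); the
  package deliberately refuses rather than guessing a scale.
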