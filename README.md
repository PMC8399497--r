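# fretsense

Analysis toolkit for nanoparticle-donor FRET (Förster resonance energy
transfer) sensing experiments, written for analytical-photophysics and
biosensing labs that quantify a metabolite through a ratiometric
fluorescent probe. The motivating system is a carbon-dot (CD) donor whose
blue emission is quenched by riboflavin (RF), the analyte, which in turn
lights up at 521 nm; the package covers the complete data analysis of such
a study, from raw two-column spectra to recoveries in spiked samples:

* spectral I/O, resampling, windowed trapezoidal integration,
  normalization (`read_spectrum`, `resample_spectrum`,
  `integrate_spectrum`, `normalize_spectrum`);
* overlap integral and Förster distance (`overlap_integral`,
  `forster_distance`), efficiency in both directions
  (`efficiency_from_fluorescence`, `efficiency_from_distance`,
  `distance_from_efficiency`), reference-based spectral unmixing
  (`unmix`), excitation selection (`select_excitation`) and the
  distance-regime check (`check_regime`);
* binding-constant estimation by the modified Stern–Volmer (Lehrer)
  analysis (`stern_volmer_fit`, `analyze_titration`);
* ratiometric calibration with a 3σ/S detection limit (`calibrate`),
  inverse prediction (`quantify_sample`), standard-addition
  quantification with recoveries and RSD (`standard_addition`), and
  interference scoring (`interference_score`);
* relative quantum yield by the gradient method (`relative_qy`,
  `gradient_from_series`), photostability drift, and crystal-violet
  viability scoring (`viability`, `viability_from_plate`);
* a seeded synthetic-data generator with planted ground truth
  (`synthetic_config`, `fret_preset`, `simulate_titration`,
  `simulate_calibration`, `simulate_standard_addition`,
  `simulate_viability_plate`) so the whole pipeline is testable without
  instrument data.

## The model

Transfer efficiency is measured from integrated donor fluorescence and
related to geometry through the multi-acceptor point-dipole model
(a nanoparticle donor can engage *n* proximal acceptors):

    E = 1 − F_DA / F_D = n R0⁶ / (n R0⁶ + r⁶)

with the Förster distance from the spectral overlap integral

    R0⁶ (cm⁶) = 8.79×10⁻²⁵ κ² η⁻⁴ φ J,
    J = ∫ F̂_D(λ) ε_A(λ) λ⁴ dλ   (F̂_D area-normalized)

(κ² = 2/3, η = 1.336, φ the donor quantum yield). Quenching titrations
are linearized with the Lehrer form F0/(F0 − F) = 1/f_a + 1/(f_a K [Q]),
which for a binding-limited FRET titration returns the association
constant K and, as the "accessible fraction" f_a, the per-complex
transfer efficiency. The sensor readout is the ratiometric signal
I521/I441, calibrated linearly with detection limit DL = 3σ_blank/S, and
samples are quantified by standard addition (x-intercept of the
ratio-versus-addition line).

## Worked example

```r
library(fretsense)

cfg <- fret_preset("low_donor", seed = 42, noise_sigma = 0.01)
tt  <- simulate_titration(cfg)          # ten RF additions, 0 -> 62.5 uM
fit <- analyze_titration(tt)            # unmix -> integrate -> Lehrer fit
fit
#> Titration fit: E = 0.9137, K = 2.681e+04 M^-1, R^2 = 0.99997 (10 points)

J  <- overlap_integral(normalize_spectrum(tt$donor_ref, "area"),
                       make_acceptor_absorptivity(cfg))
J
#> Overlap integral J = 2.5391e+14 M^-1 cm^-1 nm^4 (= 2.5391e-14 M^-1 cm^3)
R0 <- forster_distance(J, phi = 0.54)   # 3.69 nm
r  <- distance_from_efficiency(fit$E, R0, n = 1)
check_regime(r, R0)$ok                  # TRUE: 0.5 R0 < r < 1.5 R0

sim <- simulate_calibration(seed = 42)
calibrate(sim$table$conc_um, sim$table$ratio, sim$blanks)
#> Calibration: ratio = 0.050798 + 0.1198 * c, R^2 = 0.99999
#>   range 0-11 uM, DL = 0.02092 uM (3 sigma / S, n_blanks = 10)

sa <- simulate_standard_addition(seed = 42)
standard_addition(sa$table$addition_um, sa$table$ratio)
#> Standard addition: 2 uM found (R^2 = 0.99995); recoveries 98.8-100.6%, RSD 0.84%

viability_from_plate(simulate_viability_plate(0.8, seed = 42))
#> Viability 83.4% (A_S = 0.8476, A_C = 1.017): mild reactivity
```

The titration fit recovers the efficiency and binding constant planted by
the `low_donor` preset (0.91 and 2.7×10⁴ M⁻¹) to within the 1% spectral
noise; the calibration reproduces the planted slope and a ≈0.02 µM
detection limit; the standard addition finds the planted 2 µM base
concentration with ~100% recoveries.

## Further reading

The methods vignette (`vignettes/fret-sensing-methods.Rmd`) documents the
generative model behind the simulators, the unit conventions of the
overlap integral, the numerical choices (trapezoid quadrature, closed-form
two-component NNLS, strict no-extrapolation resampling), and the known
limitations.
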