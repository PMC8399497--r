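#' Gaussian band model
#'
#' Emission and absorption bands in the simulator are Gaussian in
#' wavelength: `amplitude * exp(-(x - center)^2 / (2 sigma^2))`.
#'
#' @param center Band center in nm (200-800).
#' @param sigma Gaussian width in nm, > 0.
#' @param amplitude Peak height in the units of the spectrum the band
#'   generates (a.u. for emission, M^-1 cm^-1 for absorptivity), >= 0.
#' @return A `band_model` object.
#' @export
band_model <- function(center, sigma, amplitude = 1) {
  stopifnot(is_scalar_number(center), is_scalar_number(sigma),
            is_scalar_number(amplitude))
  if (sigma <= 0) stop_invariant("sigma must be positive")
  if (amplitude < 0) stop_invariant("amplitude must be >= 0")
  if (center < 200 || center > 800) {
    stop_invariant("band center must lie in the instrument range 200-800 nm")
  }
  structure(list(center = center, sigma = sigma, amplitude = amplitude),
            class = "band_model")
}

eval_band <- function(band, grid) {
  band$amplitude * exp(-(grid - band$center)^2 / (2 * band$sigma^2))
}

#' Cumulative-addition titration concentrations
#'
#' Acceptor concentrations produced by adding successive aliquots of a
#' titrant stock to a starting volume (each addition dilutes the previous
#' ones): after i additions of `aliquot_ul` microliters of a
#' `titrant_um`-micromolar stock into `start_ul` microliters,
#' c_i = i * aliquot * stock / (start + i * aliquot).
#'
#' @param n_additions Number of aliquots (default 10).
#' @param aliquot_ul Aliquot volume, microliters (default 20).
#' @param titrant_um Titrant stock concentration, micromolar (default 1000).
#' @param start_ul Starting volume, microliters (default 3000).
#' @return Vector of concentrations in micromolar (length `n_additions`).
#' @export
titration_concs <- function(n_additions = 10, aliquot_ul = 20,
                            titrant_um = 1000, start_ul = 3000) {
  i <- seq_len(n_additions)
  i * aliquot_ul * titrant_um / (start_ul + i * aliquot_ul)
}

#' Synthetic FRET experiment configuration
#'
#' Full generative description of a simulated donor-acceptor titration:
#' donor emission bands per excitation wavelength, acceptor absorption and
#' emission bands, a 1:1 Langmuir binding isotherm with constant
#' `binding_K`, a planted per-complex transfer efficiency, and
#' multiplicative Gaussian noise.  Identical configurations (including
#' `seed`) generate identical data.
#'
#' @param donor_bands Named list of `band_model`s, one per excitation
#'   wavelength (names in nm).  Defaults emulate carbon-dot emission with
#'   maxima at 420, 440 and 456 nm for excitation at 320, 340 and 360 nm.
#' @param acceptor_absorption `band_model` for the acceptor molar
#'   absorptivity (default: 445 nm peak, 1.2e4 M^-1 cm^-1).
#' @param acceptor_emission `band_model` for the acceptor emission
#'   (default: 521 nm peak).
#' @param binding_K Association constant, M^-1, > 0.
#' @param planted_E Per-complex transfer efficiency in (0, 1].
#' @param donor_conc Donor concentration in mg/mL; emission amplitude
#'   scales linearly with it.
#' @param acceptor_concs Acceptor concentrations in micromolar,
#'   nonnegative increasing (default: the cumulative titration protocol of
#'   [titration_concs()], ten 20 uL additions of 1000 uM stock into 3 mL).
#' @param noise_sigma Multiplicative Gaussian noise, as a fraction of each
#'   intensity, >= 0.
#' @param seed Integer RNG seed.
#' @param acceptor_direct_excitation Fraction of the acceptor emission band
#'   excited directly (not via transfer) per micromolar acceptor; default 0.
#' @param transfer_gain Photons emitted by the acceptor per photon removed
#'   from the donor (acceptor/donor quantum-yield ratio); default 1.
#' @param excitation Donor excitation wavelength used for the titration
#'   (must have a registered band), default 360 nm.
#' @param grid Wavelength grid in nm, default `seq(350, 650, by = 1)`.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(donor_bands = NULL,
                             acceptor_absorption = band_model(445, 25, 1.2e4),
                             acceptor_emission = band_model(521, 26, 1),
                             binding_K = 2.7e4,
                             planted_E = 0.91,
                             donor_conc = 5e-3,
                             acceptor_concs = c(0, titration_concs()),
                             noise_sigma = 0,
                             seed = 1L,
                             acceptor_direct_excitation = 0,
                             transfer_gain = 1,
                             excitation = 360,
                             grid = seq(350, 650, by = 1)) {
  if (is.null(donor_bands)) {
    donor_bands <- list(
      `320` = band_model(420, 40, 0.60),
      `340` = band_model(440, 40, 0.85),
      `360` = band_model(456, 40, 1.00)
    )
  }
  stopifnot(is.list(donor_bands), length(donor_bands) > 0,
            inherits(acceptor_absorption, "band_model"),
            inherits(acceptor_emission, "band_model"))
  if (is.null(names(donor_bands)) || anyNA(as.numeric(names(donor_bands)))) {
    stop_invariant("donor_bands must be named by excitation wavelength in nm")
  }
  if (binding_K <= 0) stop_invariant("binding_K must be positive")
  if (planted_E <= 0 || planted_E > 1) stop_invariant("planted_E must lie in (0, 1]")
  if (donor_conc <= 0) stop_invariant("donor_conc must be positive")
  if (any(acceptor_concs < 0) || any(diff(acceptor_concs) <= 0)) {
    stop_invariant("acceptor_concs must be nonnegative and strictly increasing")
  }
  if (noise_sigma < 0) stop_invariant("noise_sigma must be >= 0")
  if (acceptor_direct_excitation < 0) {
    stop_invariant("acceptor_direct_excitation must be >= 0")
  }
  if (transfer_gain < 0) stop_invariant("transfer_gain must be >= 0")
  structure(list(donor_bands = donor_bands,
                 acceptor_absorption = acceptor_absorption,
                 acceptor_emission = acceptor_emission,
                 binding_K = binding_K, planted_E = planted_E,
                 donor_conc = donor_conc, acceptor_concs = acceptor_concs,
                 noise_sigma = noise_sigma, seed = seed,
                 acceptor_direct_excitation = acceptor_direct_excitation,
                 transfer_gain = transfer_gain, excitation = excitation,
                 grid = grid),
            class = "synthetic_config")
}

#' Frozen simulation presets
#'
#' Named parameter bundles reproducing the study conditions:
#' \describe{
#'   \item{low_donor}{5.0e-3 mg/mL donor, planted efficiency 0.91.}
#'   \item{high_donor}{4.0e-2 mg/mL donor, planted efficiency 0.84.}
#'   \item{sv_table1}{Titration planting the binding constant 2.7e4 M^-1.}
#'   \item{calibration_dl}{Ratiometric calibration over 0-11 uM with slope
#'     0.12 ratio/uM and blank sigma 1e-3, so the planted detection limit
#'     3 sigma / S is 0.025 uM.}
#'   \item{standard_addition}{Spiked-sample series: base 2 uM, additions
#'     0-7 uM, 0.4% multiplicative ratio noise (sub-4% RSD regime).}
#'   \item{viability}{Crystal-violet plate: treated/control absorbance
#'     fraction 0.8, 6 wells per condition, 5% well-to-well CV.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the returned configuration.
#' @param noise_sigma Spectral noise override for the titration presets.
#' @return A `synthetic_config` for the titration presets, otherwise a
#'   named parameter list.
#' @export
fret_preset <- function(name = c("low_donor", "high_donor", "sv_table1",
                                 "calibration_dl", "standard_addition",
                                 "viability"),
                        seed = 1L, noise_sigma = 0) {
  name <- match.arg(name)
  switch(name,
    low_donor = synthetic_config(donor_conc = 5e-3, planted_E = 0.91,
                                 noise_sigma = noise_sigma, seed = seed),
    high_donor = synthetic_config(donor_conc = 4e-2, planted_E = 0.84,
                                  noise_sigma = noise_sigma, seed = seed),
    sv_table1 = synthetic_config(donor_conc = 5e-3, planted_E = 0.91,
                                 binding_K = 2.7e4,
                                 noise_sigma = noise_sigma, seed = seed),
    calibration_dl = list(name = name, slope = 0.12, intercept = 0.05,
                          sigma_blank = 1e-3, conc_um = 0:11,
                          dl_planted = 3 * 1e-3 / 0.12, seed = seed),
    standard_addition = list(name = name, slope = 0.12, base_conc = 2,
                             additions = 0:7, noise_rel = 0.004, seed = seed),
    viability = list(name = name, treated_mean_fraction = 0.8, n_wells = 6,
                     cv = 0.05, seed = seed)
  )
}

#' Simulated donor emission spectrum
#'
#' Gaussian donor band for a registered excitation wavelength; amplitude
#' scales linearly with the configured donor concentration.
#'
#' @param config A `synthetic_config`.
#' @param excitation Excitation wavelength in nm; must match a registered
#'   donor band.
#' @param grid Wavelength grid (default: the config grid).
#' @return Emission `spectrum` (noise-free; noise enters only through
#'   [simulate_titration()]).
#' @export
make_donor_emission <- function(config, excitation = config$excitation,
                                grid = config$grid) {
  stopifnot(inherits(config, "synthetic_config"))
  key <- as.character(excitation)
  if (!key %in% names(config$donor_bands)) {
    stop_invariant("no donor band registered for excitation ", excitation,
                   " nm; available: ", paste(names(config$donor_bands),
                                             collapse = ", "))
  }
  band <- config$donor_bands[[key]]
  spectrum(grid, eval_band(band, grid) * config$donor_conc, "emission",
           meta = list(excitation_nm = excitation,
                       donor_conc_mg_ml = config$donor_conc))
}

#' Simulated acceptor molar absorptivity spectrum
#'
#' @param config A `synthetic_config`.
#' @param grid Wavelength grid (default: the config grid).
#' @return `spectrum` of kind `"molar_absorptivity"`.
#' @export
make_acceptor_absorptivity <- function(config, grid = config$grid) {
  stopifnot(inherits(config, "synthetic_config"))
  spectrum(grid, eval_band(config$acceptor_absorption, grid),
           "molar_absorptivity")
}

#' Simulate a FRET titration series
#'
#' For each acceptor concentration c the bound fraction follows the 1:1
#' Langmuir isotherm theta = K c / (1 + K c) (c in molar).  The composite
#' spectrum is
#' `(1 - theta E) * donor + theta E g A_D * acceptor_hat + d c * acceptor_em`
#' where `E` is the planted per-complex efficiency, `g` the transfer gain,
#' `A_D` the donor emission area (so with g = 1 the photons removed from
#' the donor reappear under the acceptor band), `acceptor_hat` the
#' area-normalized acceptor emission band, and `d` the direct-excitation
#' fraction per micromolar.  Multiplicative Gaussian noise
#' (`noise_sigma`, clipped at zero) is applied to every measured spectrum,
#' including the c = 0 donor reference.
#'
#' @param config A `synthetic_config`.
#' @return List of class `titration_series`: `conc_um`, `spectra` (one per
#'   concentration, c = 0 first), `donor_ref` (the measured c = 0
#'   spectrum), `acceptor_ref` (area-normalized acceptor emission band),
#'   and `truth` (theta vector, planted_E, K) for validation.
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  concs <- config$acceptor_concs
  if (concs[1] != 0) concs <- c(0, concs)
  grid <- config$grid
  donor_clean <- make_donor_emission(config)
  acc_unit <- normalize_spectrum(
    spectrum(grid, eval_band(config$acceptor_emission, grid), "emission"),
    "area")
  donor_area <- integrate_spectrum(donor_clean)
  theta <- config$binding_K * concs * 1e-6 / (1 + config$binding_K * concs * 1e-6)

  with_seed(config$seed, {
    spectra <- vector("list", length(concs))
    for (i in seq_along(concs)) {
      v <- (1 - theta[i] * config$planted_E) * donor_clean$value +
        theta[i] * config$planted_E * config$transfer_gain * donor_area *
          acc_unit$value +
        config$acceptor_direct_excitation * concs[i] *
          eval_band(config$acceptor_emission, grid)
      if (config$noise_sigma > 0) {
        v <- pmax(0, v * (1 + stats::rnorm(length(v), 0, config$noise_sigma)))
      }
      spectra[[i]] <- spectrum(grid, v, "emission",
                               meta = list(acceptor_conc_um = concs[i]))
    }
    structure(list(conc_um = concs, spectra = spectra,
                   donor_ref = spectra[[1]], acceptor_ref = acc_unit,
                   truth = list(theta = theta, planted_E = config$planted_E,
                                K = config$binding_K)),
              class = "titration_series")
  })
}

#' Simulate a ratiometric calibration experiment
#'
#' Generates blank replicates and a concentration/ratio table with a
#' planted slope and blank noise chosen (in the `calibration_dl` preset)
#' so that 3 sigma / S equals the planted detection limit of 0.025 uM.
#' Gaussian noise of the blank sigma is applied to every ratio.
#'
#' @param preset Parameter list from `fret_preset("calibration_dl")`, or a
#'   list with `slope`, `intercept`, `sigma_blank`, `conc_um`.
#' @param n_blanks Number of blank replicates, >= 2 (default 10).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return List: `blanks`, `table` (data.frame conc_um, ratio), `truth`
#'   (slope, intercept, sigma_blank, dl).
#' @export
simulate_calibration <- function(preset = fret_preset("calibration_dl"),
                                 n_blanks = 10, seed = preset$seed) {
  stopifnot(is.list(preset), !is.null(preset$slope),
            !is.null(preset$sigma_blank))
  if (n_blanks < 2) stop_invariant("need at least 2 blank replicates")
  conc <- preset$conc_um
  with_seed(seed, {
    blanks <- preset$intercept + stats::rnorm(n_blanks, 0, preset$sigma_blank)
    ratio <- preset$intercept + preset$slope * conc +
      stats::rnorm(length(conc), 0, preset$sigma_blank)
    list(blanks = blanks,
         table = data.frame(conc_um = conc, ratio = ratio),
         truth = list(slope = preset$slope, intercept = preset$intercept,
                      sigma_blank = preset$sigma_blank,
                      dl = 3 * preset$sigma_blank / preset$slope))
  })
}

#' Simulate a standard-addition series
#'
#' Ratiometric responses linear in (base concentration + addition) with
#' multiplicative Gaussian noise at the preset relative level.
#'
#' @param preset Parameter list from `fret_preset("standard_addition")`.
#' @param base_conc Unknown analyte concentration in the sample, uM.
#' @param additions Spiked concentrations, uM, strictly increasing,
#'   starting at 0.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return List: `table` (data.frame addition_um, ratio), `truth`
#'   (base_conc, slope, noise_rel).
#' @export
simulate_standard_addition <- function(preset = fret_preset("standard_addition"),
                                       base_conc = preset$base_conc,
                                       additions = preset$additions,
                                       seed = preset$seed) {
  stopifnot(is.list(preset), !is.null(preset$slope))
  if (base_conc < 0) stop_invariant("base_conc must be >= 0")
  if (any(diff(additions) <= 0)) {
    stop_invariant("additions must be strictly increasing")
  }
  with_seed(seed, {
    clean <- preset$slope * (base_conc + additions)
    ratio <- clean * (1 + stats::rnorm(length(additions), 0, preset$noise_rel))
    list(table = data.frame(addition_um = additions, ratio = ratio),
         truth = list(base_conc = base_conc, slope = preset$slope,
                      noise_rel = preset$noise_rel))
  })
}

#' Simulate a crystal-violet viability plate
#'
#' Control and treated well absorbances with lognormal well-to-well
#' variation: each well is `mean * exp(N(-s^2/2, s))` with
#' `s = sqrt(log(1 + cv^2))`, so the expected well value equals the
#' condition mean and `cv = 0` gives exact values.
#'
#' @param treated_mean_fraction Mean treated/control absorbance fraction,
#'   >= 0 (i.e. planted viability / 100).
#' @param n_wells Wells per condition (default 6).
#' @param cv Well-to-well coefficient of variation, >= 0 (default 0.05).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @param control_mean Mean control absorbance, a.u. (default 1).
#' @return Data frame with columns `well`, `condition`
#'   (control/treated), `absorbance_595nm`.
#' @export
simulate_viability_plate <- function(treated_mean_fraction, n_wells = 6,
                                     cv = 0.05, seed = 1L,
                                     control_mean = 1.0) {
  if (treated_mean_fraction < 0) {
    stop_invariant("treated_mean_fraction must be >= 0")
  }
  if (n_wells < 1) stop_invariant("need at least 1 well per condition")
  if (cv < 0) stop_invariant("cv must be >= 0")
  s <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    draw <- function(mean, n) {
      if (s == 0) rep(mean, n) else mean * exp(stats::rnorm(n, -s^2 / 2, s))
    }
    data.frame(
      well = seq_len(2 * n_wells),
      condition = rep(c("control", "treated"), each = n_wells),
      absorbance_595nm = c(draw(control_mean, n_wells),
                           draw(control_mean * treated_mean_fraction, n_wells))
    )
  })
}
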