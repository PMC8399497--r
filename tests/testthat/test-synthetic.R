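test_that("band and config constructors validate their parameters", {
  expect_error(band_model(450, -1), "sigma")
  expect_error(band_model(450, 10, -2), "amplitude")
  expect_error(band_model(900, 10), "instrument range")
  expect_error(synthetic_config(binding_K = -1), "binding_K")
  expect_error(synthetic_config(planted_E = 1.2), "planted_E")
  expect_error(synthetic_config(noise_sigma = -0.1), "noise_sigma")
  expect_error(synthetic_config(acceptor_concs = c(5, 3)), "increasing")
})

test_that("titration concentrations follow the cumulative-aliquot protocol", {
  concs <- titration_concs()
  # ten 20 uL additions of 1000 uM stock into 3 mL: last step 62.5 uM
  expect_length(concs, 10)
  expect_equal(concs[1], 20 * 1000 / 3020)
  expect_equal(concs[10], 62.5)
  expect_true(all(diff(concs) > 0))
})

test_that("donor emission peaks where the excitation dictates and scales with concentration", {
  cfg <- fret_preset("low_donor")
  em360 <- make_donor_emission(cfg, 360)
  expect_equal(peak_wavelength(em360), 456)
  expect_equal(peak_wavelength(make_donor_emission(cfg, 320)), 420)
  expect_equal(peak_wavelength(make_donor_emission(cfg, 340)), 440)

  cfg2 <- synthetic_config(donor_conc = 1e-2)
  expect_equal(make_donor_emission(cfg2, 360)$value, 2 * em360$value)

  expect_error(make_donor_emission(cfg, 500), "available: 320, 340, 360")
})

test_that("simulated titration follows the planted generative model", {
  cfg <- fret_preset("low_donor")
  tt <- simulate_titration(cfg)
  expect_equal(tt$conc_um[1], 0)
  # noise-free c = 0 composite is exactly the donor reference
  expect_identical(tt$spectra[[1]]$value, tt$donor_ref$value)
  # donor-band depletion matches theta * E pointwise through unmixing
  i <- 6
  u <- unmix(tt$spectra[[i]], tt$donor_ref, tt$acceptor_ref)
  expect_equal(u$donor_coeff, 1 - tt$truth$theta[i] * cfg$planted_E,
               tolerance = 1e-9)
})

test_that("saturated binding quenches the donor band by exactly the planted efficiency", {
  cfg <- synthetic_config(binding_K = 1e12, planted_E = 0.91,
                          acceptor_concs = c(0, 1e3))
  tt <- simulate_titration(cfg)
  f_d <- integrate_spectrum(tt$donor_ref, c(390, 500))
  u <- unmix(tt$spectra[[2]], tt$donor_ref, tt$acceptor_ref)
  expect_equal(u$donor_coeff * f_d, (1 - 0.91) * f_d, tolerance = 1e-6)
})

test_that("titration composites are nonnegative and seed-deterministic", {
  cfg <- fret_preset("low_donor", seed = 99, noise_sigma = 0.05)
  t1 <- simulate_titration(cfg)
  t2 <- simulate_titration(cfg)
  for (i in seq_along(t1$spectra)) {
    expect_identical(t1$spectra[[i]]$value, t2$spectra[[i]]$value)
    expect_true(all(t1$spectra[[i]]$value >= 0))
  }
  t3 <- simulate_titration(fret_preset("low_donor", seed = 100,
                                       noise_sigma = 0.05))
  expect_false(identical(t1$spectra[[2]]$value, t3$spectra[[2]]$value))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_titration(fret_preset("low_donor", seed = 7,
                                           noise_sigma = 0.01)))
  invisible(simulate_calibration(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("direct acceptor excitation adds signal outside the transfer pathway", {
  cfg0 <- synthetic_config(acceptor_direct_excitation = 0)
  cfg1 <- synthetic_config(acceptor_direct_excitation = 0.002)
  t0 <- simulate_titration(cfg0)
  t1 <- simulate_titration(cfg1)
  n <- length(t0$conc_um)
  extra <- t1$spectra[[n]]$value - t0$spectra[[n]]$value
  expect_gt(max(extra), 0)
  expect_equal(t1$spectra[[n]]$wavelength[which.max(extra)], 521)
})

test_that("calibration generator plants slope, blank noise, and the 0.025 uM detection limit", {
  pre <- fret_preset("calibration_dl")
  expect_equal(pre$dl_planted, 0.025)
  sim <- simulate_calibration(pre, n_blanks = 10, seed = 4)
  expect_length(sim$blanks, 10)
  expect_equal(sim$truth$dl, 0.025)
  expect_error(simulate_calibration(pre, n_blanks = 1), "at least 2")

  # zero-noise variant: perfectly linear, DL exactly 0
  pre0 <- pre; pre0$sigma_blank <- 0
  sim0 <- simulate_calibration(pre0, n_blanks = 10, seed = 4)
  cal0 <- calibrate(sim0$table$conc_um, sim0$table$ratio, sim0$blanks)
  expect_equal(cal0$r_squared, 1)
  expect_equal(cal0$detection_limit, 0)
  expect_equal(cal0$slope, pre$slope)
})

test_that("recovered detection limit is unbiased to within 10% at n = 10 blanks", {
  dls <- vapply(1:200, function(i) {
    sim <- simulate_calibration(seed = i)
    calibrate(sim$table$conc_um, sim$table$ratio, sim$blanks)$detection_limit
  }, numeric(1))
  expect_lt(abs(mean(dls) - 0.025) / 0.025, 0.10)
})

test_that("standard-addition generator is exact at zero noise", {
  pre <- fret_preset("standard_addition")
  pre$noise_rel <- 0
  sim <- simulate_standard_addition(pre, base_conc = 3, seed = 1)
  res <- standard_addition(sim$table$addition_um, sim$table$ratio)
  expect_equal(res$estimated_conc, 3, tolerance = 1e-9)
  expect_equal(res$recoveries, rep(100, 7), tolerance = 1e-9)
  expect_equal(res$rsd, 0, tolerance = 1e-7)

  sim0 <- simulate_standard_addition(pre, base_conc = 0, seed = 1)
  res0 <- standard_addition(sim0$table$addition_um, sim0$table$ratio)
  expect_equal(res0$estimated_conc, 0, tolerance = 1e-9)

  expect_error(simulate_standard_addition(pre, additions = c(0, 2, 1)),
               "increasing")
})

test_that("viability plate generator plants the treated fraction", {
  p <- simulate_viability_plate(1.0, cv = 0, seed = 1)
  expect_equal(viability_from_plate(p)$viability, 100)
  p17 <- simulate_viability_plate(0.17, cv = 0, seed = 1)
  expect_equal(viability_from_plate(p17)$viability, 17)
  expect_identical(simulate_viability_plate(0.5, seed = 8),
                   simulate_viability_plate(0.5, seed = 8))
  expect_error(simulate_viability_plate(-0.1), ">= 0")
})

test_that("a synthetic_config round-trips through the YAML run config", {
  cfg <- fret_preset("high_donor", seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_s3_class(cfg2, "synthetic_config")
  expect_equal(cfg2$planted_E, cfg$planted_E)
  expect_equal(cfg2$donor_conc, cfg$donor_conc)
  # identical data from the reloaded config
  t1 <- simulate_titration(cfg)
  t2 <- simulate_titration(cfg2)
  expect_identical(t1$spectra[[3]]$value, t2$spectra[[3]]$value)
})
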