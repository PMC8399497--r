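test_that("overlap integral requires the right spectrum kinds and overlapping support", {
  d <- gauss_spectrum(456, 25)
  a <- gauss_spectrum(445, 20, 1.2e4, kind = "molar_absorptivity")
  expect_error(overlap_integral(a, a), "emission")
  expect_error(overlap_integral(d, gauss_spectrum(445, 20, kind = "absorbance")),
               "molar absorptivity")
  d_blue <- gauss_spectrum(300, 5, grid = seq(280, 320, 1))
  a_red <- gauss_spectrum(600, 5, 1e4, grid = seq(580, 620, 1),
                          kind = "molar_absorptivity")
  expect_error(overlap_integral(d_blue, a_red), "disjoint")
})

test_that("spectrally disjoint bands give a vanishing overlap integral", {
  d <- gauss_spectrum(300, 3, grid = seq(250, 800, 1))
  a <- gauss_spectrum(700, 3, 1e4, grid = seq(250, 800, 1),
                      kind = "molar_absorptivity")
  j <- overlap_integral(d, a)
  # bands 400 nm apart: the product underflows to numerically nothing
  expect_lt(j$J_nm4 / (1e4 * 700^4), 1e-100)
})

test_that("overlap integral matches a fine-grid brute-force quadrature", {
  skip_if_not_installed("pracma")
  d <- gauss_spectrum(456, 25, grid = seq(350, 650, 1))
  a <- gauss_spectrum(445, 20, 1.2e4, grid = seq(350, 650, 1),
                      kind = "molar_absorptivity")
  j <- overlap_integral(d, a)

  # independent oracle: closed-form band shapes on a 0.01 nm grid
  lam <- seq(350, 650, 0.01)
  fd <- exp(-(lam - 456)^2 / (2 * 25^2))
  ea <- 1.2e4 * exp(-(lam - 445)^2 / (2 * 20^2))
  j_ref <- pracma::trapz(lam, fd * ea * lam^4) / pracma::trapz(lam, fd)
  expect_equal(j$J_nm4, j_ref, tolerance = 1e-3)
  expect_equal(j$J_cm3, j$J_nm4 * 1e-28)
})

test_that("narrow coincident bands approach the delta-function limit eps0 * lambda0^4", {
  lam0 <- 480; eps0 <- 5e3
  grid <- seq(470, 490, 0.005)
  d <- gauss_spectrum(lam0, 0.05, grid = grid)
  a <- gauss_spectrum(lam0, 20, eps0, grid = grid, kind = "molar_absorptivity")
  j <- overlap_integral(d, a)
  expect_equal(j$J_nm4, eps0 * lam0^4, tolerance = 1e-4)
})

test_that("overlap integral is donor-amplitude invariant and acceptor-linear", {
  d <- gauss_spectrum(456, 25)
  a <- gauss_spectrum(445, 20, 1.2e4, kind = "molar_absorptivity")
  j1 <- overlap_integral(d, a)$J_nm4
  d10 <- gauss_spectrum(456, 25, amplitude = 10)
  expect_equal(overlap_integral(d10, a)$J_nm4, j1, tolerance = 1e-12)
  a3 <- gauss_spectrum(445, 20, 3.6e4, kind = "molar_absorptivity")
  expect_equal(overlap_integral(d, a3)$J_nm4, 3 * j1, tolerance = 1e-12)
})

test_that("Forster distance reproduces the hand-evaluated benchmark", {
  # kappa2 = 2/3, eta = 1.336, phi = 0.54, J = 1.30e14 M^-1 cm^-1 nm^4
  r0 <- forster_distance(1.30e14 * 1e-28, phi = 0.54)
  expect_equal(r0, 3.30, tolerance = 0.005)
  # accepts an overlap_integral object directly
  j <- overlap_integral(gauss_spectrum(456, 25),
                        gauss_spectrum(445, 20, 1.2e4,
                                       kind = "molar_absorptivity"))
  expect_equal(forster_distance(j, phi = 0.54),
               forster_distance(j$J_cm3, phi = 0.54))
})

test_that("Forster distance scales as the sixth root and validates inputs", {
  r0 <- forster_distance(1e-14, phi = 0.4)
  expect_equal(forster_distance(1e-14, phi = 0.8) / r0, 2^(1 / 6))
  # phi -> 0 drives R0 -> 0
  expect_lt(forster_distance(1e-14, phi = 1e-12), 0.05)
  expect_error(forster_distance(-1e-14, phi = 0.5), "positive")
  expect_error(forster_distance(1e-14, phi = 1.2), "<= 1")
})

test_that("cm-scale and Angstrom-scale formulations agree over four decades of J", {
  for (j_nm4 in 10^seq(12, 16, 0.5)) {
    r0_cm <- (8.79e-25 * (2 / 3) * 1.336^-4 * 0.54 * j_nm4 * 1e-28)^(1 / 6) * 1e7
    r0_A <- 0.211 * ((2 / 3) * 1.336^-4 * 0.54 * j_nm4)^(1 / 6) / 10
    expect_equal(r0_cm, r0_A, tolerance = 0.01)
    expect_equal(forster_distance(j_nm4 * 1e-28, phi = 0.54), r0_cm)
  }
})

test_that("efficiency from fluorescence reproduces the study ratios and clips noise", {
  expect_equal(efficiency_from_fluorescence(100, 100), 0)
  expect_equal(efficiency_from_fluorescence(0.09 * 250, 250), 0.91)
  expect_equal(efficiency_from_fluorescence(0.16 * 250, 250), 0.84)
  expect_warning(e <- efficiency_from_fluorescence(101, 100), "clipping")
  expect_equal(e, 0)
  expect_error(efficiency_from_fluorescence(103, 100), "more than 2%")
  expect_error(efficiency_from_fluorescence(10, 0), "positive")
})

test_that("geometric efficiency obeys the multi-acceptor relation", {
  expect_equal(efficiency_from_distance(3.3, 3.3, 1), 0.5)
  expect_equal(efficiency_from_distance(1.8, 3.3, 1),
               3.3^6 / (3.3^6 + 1.8^6))  # 0.9743 by hand
  expect_equal(efficiency_from_distance(1.8, 3.3, 1), 0.9743, tolerance = 1e-4)
  expect_gt(efficiency_from_distance(2, 3, 1e9), 1 - 1e-6)  # n -> inf limit
  expect_error(efficiency_from_distance(2, 3, 0.5), ">= 1")
})

test_that("efficiency is monotone in r, n and R0", {
  r <- seq(0.5, 8, 0.25)
  e_r <- vapply(r, efficiency_from_distance, numeric(1), R0 = 3.3, n = 2)
  expect_true(all(diff(e_r) < 0))
  n <- 1:12
  e_n <- vapply(n, function(k) efficiency_from_distance(3, 3.3, k), numeric(1))
  expect_true(all(diff(e_n) > 0))
  R0 <- seq(1, 6, 0.25)
  e_R <- vapply(R0, function(x) efficiency_from_distance(3, x, 1), numeric(1))
  expect_true(all(diff(e_R) > 0))
})

test_that("distance inversion round-trips efficiency to machine precision", {
  expect_equal(distance_from_efficiency(0.5, 3.3, 1), 3.3)
  expect_equal(distance_from_efficiency(0.91, 3.3, 1), 2.243, tolerance = 1e-3)
  for (E in c(0.05, 0.3, 0.5, 0.84, 0.91, 0.99)) {
    for (n in c(1, 2, 5, 17)) {
      r <- distance_from_efficiency(E, 3.3, n)
      expect_equal(efficiency_from_distance(r, 3.3, n), E, tolerance = 1e-12)
    }
  }
  expect_error(distance_from_efficiency(1, 3.3, 1), "strictly inside")
  expect_error(distance_from_efficiency(0, 3.3, 1), "strictly inside")
})

test_that("distance-regime check uses strict bounds around R0", {
  res <- check_regime(1.8, 3.3)
  expect_true(res$ok)
  expect_equal(res$ratio, 1.8 / 3.3)  # ~0.545
  expect_false(check_regime(1, 2)$ok)  # boundaries excluded (strict)
  expect_false(check_regime(3, 2)$ok)
  expect_true(check_regime(3.3, 3.3)$ok)
})

test_that("unmixing recovers exact mixture coefficients", {
  d <- gauss_spectrum(456, 40, grid = seq(350, 650, 1))
  a <- gauss_spectrum(521, 26, grid = seq(350, 650, 1))
  mix <- spectrum(d$wavelength, 0.3 * d$value + 0.7 * a$value, "emission")
  u <- unmix(mix, d, a)
  expect_equal(u$donor_coeff, 0.3, tolerance = 1e-9)
  expect_equal(u$acceptor_coeff, 0.7, tolerance = 1e-9)
  expect_lt(u$residual_rms, 1e-12)

  u2 <- unmix(d, d, a)  # donor only
  expect_equal(u2$donor_coeff, 1, tolerance = 1e-12)
  expect_equal(u2$acceptor_coeff, 0)
})

test_that("unmixing is nonnegative and rejects collinear references", {
  d <- gauss_spectrum(456, 40)
  a <- gauss_spectrum(521, 26)
  # composite = donor minus a bit of acceptor shape: NNLS must clamp at 0
  mix <- spectrum(d$wavelength, pmax(0, d$value - 0.2 * a$value), "emission")
  u <- unmix(mix, d, a)
  expect_gte(u$acceptor_coeff, 0)
  near <- gauss_spectrum(456.05, 40)
  expect_error(unmix(mix, d, near), "collinear")
})

test_that("unmixing tracks random mixtures under 1% noise to 3% RMS", {
  set.seed(11)
  d <- gauss_spectrum(456, 40, grid = seq(350, 650, 1))
  a <- gauss_spectrum(521, 26, grid = seq(350, 650, 1))
  err <- replicate(100, {
    co <- runif(2, 0.1, 1)
    v <- co[1] * d$value + co[2] * a$value
    v <- pmax(0, v * (1 + rnorm(length(v), 0, 0.01)))
    u <- unmix(spectrum(d$wavelength, v, "emission"), d, a)
    c(u$donor_coeff - co[1], u$acceptor_coeff - co[2]) / co
  })
  expect_lt(sqrt(mean(err^2)), 0.03)
})

test_that("excitation selection maximizes overlap with tie-break to the bluest", {
  cfg <- fret_preset("low_donor")
  cands <- sapply(c("320", "340", "360"), function(e) {
    make_donor_emission(cfg, as.numeric(e))
  }, simplify = FALSE)
  acc <- make_acceptor_absorptivity(cfg)
  sel <- select_excitation(cands, acc)
  expect_equal(sel$excitation, 360)

  single <- select_excitation(cands["340"], acc)
  expect_equal(single$excitation, 340)

  twin <- list(`340` = cands[["320"]], `320` = cands[["320"]])
  expect_equal(select_excitation(twin, acc)$excitation, 320)
  expect_error(select_excitation(list(), acc), "at least one")
})

test_that("fret_params flags geometric inconsistency of a parameter triple", {
  ok <- fret_params(E = 0.5, R0 = 3.3, r = 3.3, n = 1)
  expect_true(ok$consistent)
  # a triple that no n >= 1 can reconcile
  bad <- fret_params(E = 0.91, R0 = 3.3, r = 1.8, n = 1)
  expect_false(bad$consistent)
  expect_true(is.na(fret_params(E = 0.91)$consistent))
})
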