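test_that("diffraction satisfies Parseval, Friedel symmetry and closed forms", {
  ph <- make_phantom(seed = 3, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  expect_true(all(pat$valid))
  expect_equal(sum(pat$intensity),
               length(ph$density) * sum(ph$density^2))
  # Friedel: I(f) = I(-f) for a real object
  expect_equal(pat$intensity, specklekit:::point_invert(pat$intensity),
               tolerance = 1e-12)

  # point object: flat intensity q^2 everywhere
  n <- 64
  supp <- matrix(FALSE, n, n)
  supp[20, 25] <- TRUE
  dens <- matrix(0, n, n)
  dens[20, 25] <- 3
  pt <- diffract(phantom(dens, 20, supp))
  expect_equal(pt$intensity, matrix(9, n, n), tolerance = 1e-12)

  # uniform square object: separable sinc^2 ridge along the axes
  supp <- matrix(FALSE, n, n)
  supp[29:36, 29:36] <- TRUE
  dens <- matrix(0, n, n)
  dens[supp] <- 1
  sq <- diffract(phantom(dens, 20, supp))
  c0 <- 33
  axis_cut <- sq$intensity[c0, ]
  u <- (seq_len(n) - c0)
  dirichlet <- function(u, w, n) {
    v <- sin(pi * u * w / n) / sin(pi * u / n)
    v[u == 0] <- w
    v^2
  }
  # along the axis the perpendicular factor is the full width (8), squared
  expect_equal(axis_cut, 64 * dirichlet(u, 8, n), tolerance = 1e-9)
})

test_that("Poisson noise is budgeted, seeded and zero-preserving", {
  ph <- make_phantom(seed = 3, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  budget <- 1e6
  n1 <- add_poisson_noise(pat, budget, seed = 7)
  n2 <- add_poisson_noise(pat, budget, seed = 7)
  expect_identical(n1$intensity, n2$intensity)
  # total within 5 standard deviations of the budget
  expect_lt(abs(sum(n1$intensity) - budget), 5 * sqrt(budget))
  # zero-intensity pixels stay zero
  zero_px <- pat$intensity == 0
  if (any(zero_px)) expect_true(all(n1$intensity[zero_px] == 0))
  # an explicit common scale preserves relative totals between patterns
  half <- pat
  half$intensity <- pat$intensity / 2
  s <- attr(n1, "scale")
  nh <- add_poisson_noise(half, seed = 8, scale = s)
  expect_lt(abs(sum(nh$intensity) - budget / 2), 5 * sqrt(budget / 2))
})

test_that("beamstop masking and Friedel refill behave as contracted", {
  ph <- make_phantom(seed = 4, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)

  # centred symmetric stop: nothing recoverable
  st <- apply_beamstop_and_symmetrize(pat, stop_halfwidth = 3)
  expect_equal(sum(!st$valid), 7 * 7)
  # the missing set is centrosymmetric
  expect_identical(st$valid, specklekit:::point_invert(st$valid))

  # fully off-centre stop: everything recovered from the Friedel partner
  off <- apply_beamstop_and_symmetrize(pat, stop_halfwidth = 2,
                                       stop_offset = c(12, 15))
  expect_true(all(off$valid))
  expect_equal(off$intensity, pat$intensity, tolerance = 1e-12)

  # partially off-centre stop: recovered pixels equal their pre-stop values
  part <- apply_beamstop_and_symmetrize(pat, stop_halfwidth = 4,
                                        stop_offset = c(2, 0))
  rec <- part$valid
  expect_equal(part$intensity[rec], pat$intensity[rec], tolerance = 1e-12)
  expect_identical(part$valid, specklekit:::point_invert(part$valid))
})

test_that("binning conserves counts and deconvolution inverts on retained bands", {
  ph <- make_phantom(seed = 6, grid_size = 66 * 3, object_fraction = 0.05)
  pat <- diffract(ph)

  # b = 1 is the identity
  expect_identical(bin_and_deconvolve(pat, 1), pat)

  # constant image, b = 3: 9x the value
  const <- diffraction_pattern(matrix(2, 66, 66))
  cb <- bin_and_deconvolve(const, 3)
  expect_equal(cb$intensity, matrix(18, 22, 22), tolerance = 1e-10)
  expect_equal(cb$freq_per_pixel, 3)

  # binning-step conservation on a masked pattern
  masked <- apply_beamstop_and_symmetrize(pat, stop_halfwidth = 4)
  b <- 3
  binned <- bin_and_deconvolve(masked, b, reg_threshold = 1 + 1e-9)
  # reg_threshold > max|H| disables deconvolution: pure binning
  ri <- rep(seq_len(66), each = b)
  ci <- rep(seq_len(66), each = b)
  blocks_ok <- t(rowsum(t(rowsum(masked$valid + 0, ri)), ci)) == 9
  sums <- t(rowsum(t(rowsum(masked$intensity, ri)), ci))
  dimnames(sums) <- NULL
  expect_equal(binned$intensity[binned$valid], sums[blocks_ok])
  expect_identical(unname(which(binned$valid)), which(blocks_ok))

  # deconvolution then re-convolution recovers the binned spectrum on
  # frequencies where the transfer function was applied; checked on a
  # smooth positive pattern so the non-negativity clip stays inactive
  r <- specklekit:::freq_radius(c(198, 198))
  smooth_pat <- diffraction_pattern(1e4 * exp(-r^2 / 800) + 10)
  dec <- bin_and_deconvolve(smooth_pat, b)
  h <- box_transfer(66, b)
  pure <- bin_and_deconvolve(smooth_pat, b, reg_threshold = 1 + 1e-9)
  usable <- abs(h) >= 0.1
  back <- specklekit:::fft2(dec$intensity) * h
  ref <- specklekit:::fft2(pure$intensity)
  expect_lt(max(Mod(back[usable] - ref[usable])) / max(Mod(ref)), 1e-10)

  expect_error(bin_and_deconvolve(pat, 7), "divisible")
  expect_error(bin_and_deconvolve(crop_pattern(pat, 4), 5), "larger")
})

test_that("central crop preserves the zero-frequency pixel", {
  ph <- make_phantom(seed = 3, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  cr <- crop_pattern(pat, 40)
  c_old <- specklekit:::centre_index(64)
  c_new <- specklekit:::centre_index(40)
  expect_equal(cr$intensity[c_new, c_new], pat$intensity[c_old, c_old])
  expect_equal(dim(cr$intensity), c(40L, 40L))
})

test_that("exposure arithmetic and absorbed dose follow their definitions", {
  expect_equal(total_exposure(exposure_schedule(c(0.08, 12), c(1000, 80))),
               1040)
  expect_equal(total_exposure(exposure_schedule(1, 1)), 1)
  expect_equal(total_exposure(list(c(0.5, 4), c(2, 3))), 8)
  expect_error(exposure_schedule(c(0.08, -1), c(10, 10)), "positive")

  # D = fluence x E x mu/rho; hand value: 1e12 ph/um^2 at 5.5 keV with
  # mu/rho = 30 cm^2/g:
  #   1e12 * 1e12 ph/m^2 x 5.5 * 1.602176634e-16 J x 3 m^2/kg
  #   = 2.6435914461e9 Gy
  p <- dose_params(photon_energy_keV = 5.5, mass_attenuation_cm2_g = 30,
                   fluence_per_um2 = 1e12)
  expect_equal(absorbed_dose(p), 2.6435914461e9, tolerance = 1e-9)

  # zero exposure and linearity
  expect_equal(absorbed_dose(p, exposure_seconds = 0, flux_density = 1e9), 0)
  d1 <- absorbed_dose(p, exposure_seconds = 10, flux_density = 1e9)
  d2 <- absorbed_dose(p, exposure_seconds = 20, flux_density = 1e9)
  expect_equal(d2, 2 * d1)
})
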