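test_that("shell maps partition the Nyquist disc with the stated centres", {
  sm <- build_shells(c(64, 64), freq_per_pixel = 0.5)
  # ~N/2 one-pixel shells
  expect_equal(length(sm$f), 32)
  # every pixel within the Nyquist radius is in exactly one shell
  r <- specklekit:::freq_radius(c(64, 64))
  expect_equal(sum(sm$counts), sum(r < 32))
  expect_true(all(is.na(sm$index[r >= 32])))
  # centre frequency of shell j is (j - 1/2) * width * freq_per_pixel
  expect_equal(sm$f, (seq_len(32) - 0.5) * 0.5)
  sm4 <- build_shells(c(64, 64), 0.5, shell_width = 4)
  expect_equal(sm4$f, (seq_len(8) - 0.5) * 2)
  expect_error(build_shells(c(64, 64), 0.5, shell_width = 0.5), "at least 1")
})

test_that("PRTF is 1 for a self-consistent average and floored for random phases", {
  ph <- make_phantom(seed = 12, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  shells <- build_shells(c(64, 64), pat$freq_per_pixel)
  pr <- prtf(ph$density, pat, shells)
  expect_equal(attr(pr, "kind"), "PRTF")
  expect_equal(pr$y, rep(1, nrow(pr)), tolerance = 1e-9)

  # single reconstruction with exact magnitudes: also 1
  set.seed(4)
  scrambled <- Re(project_magnitudes(matrix(rnorm(64^2), 64, 64), pat))
  expect_equal(prtf(scrambled, pat, shells)$y[-1], rep(1, nrow(pr) - 1),
               tolerance = 1e-6)

  # averaging members with independent uniform phases collapses the PRTF
  # to the 1/sqrt(n) floor (RMS accumulation), here over thick shells so
  # every shell carries thousands of pixels
  n <- 256
  flat <- diffraction_pattern(matrix(1, n, n), freq_per_pixel = 0.1)
  thick <- build_shells(c(n, n), 0.1, shell_width = 16)
  n_members <- 24
  set.seed(5)
  zbar <- matrix(0 + 0i, n, n)
  for (m in seq_len(n_members)) {
    zbar <- zbar + exp(2i * pi * matrix(runif(n^2), n, n))
  }
  avg <- specklekit:::ifft2(specklekit:::ifftshift2(zbar / n_members))
  floor_curve <- prtf(avg, flat, thick, statistic = "rms")
  expect_true(all(abs(floor_curve$y - 1 / sqrt(n_members)) < 0.015))
})

test_that("noise floor estimation recovers planted floors", {
  n <- 64
  shells <- build_shells(c(n, n), 1)
  flat <- diffraction_pattern(matrix(7, n, n))
  expect_equal(estimate_noise_floor(flat, shells), 7)

  # decaying signal on a flat Poisson-like floor
  r <- specklekit:::freq_radius(c(n, n))
  set.seed(6)
  planted <- 50
  sig <- 4000 * exp(-r / 4)
  noisy <- diffraction_pattern(matrix(
    rpois(n^2, as.numeric(sig + planted)), n, n))
  est <- estimate_noise_floor(noisy, shells, tail_fraction = 0.1)
  expect_lt(abs(est - planted) / planted, 0.2)
  expect_gte(est, 0)
  expect_error(estimate_noise_floor(flat, shells, tail_fraction = 0.7),
               "between 0 and 0.5")
})

test_that("Wiener weights and the wPRTF obey their algebra", {
  n <- 64
  shells <- build_shells(c(n, n), 1)
  # PSD = 3N exactly: W = 2/3 everywhere
  pat3 <- diffraction_pattern(matrix(30, n, n))
  w3 <- wiener_weight(pat3, shells, noise_floor = 10)
  expect_equal(w3$y, rep(2 / 3, nrow(w3)))
  # N = 0: W = 1 wherever there is signal
  w0 <- wiener_weight(pat3, shells, noise_floor = 0)
  expect_equal(w0$y, rep(1, nrow(w0)))
  # PSD = N exactly: W = 0
  wn <- wiener_weight(pat3, shells, noise_floor = 30)
  expect_equal(wn$y, rep(0, nrow(wn)))
  expect_true(all(w3$y >= 0 & w3$y <= 1))

  # wPRTF is the pointwise product and bounded by both factors
  ph <- make_phantom(seed = 13, grid_size = n, object_fraction = 0.08)
  pat <- add_poisson_noise(diffract(ph), 1e6, seed = 2)
  shells2 <- build_shells(c(n, n), pat$freq_per_pixel)
  pr <- prtf(ph$density, pat, shells2)
  w <- wiener_weight(pat, shells2)
  wp <- wprtf(pr, w)
  expect_equal(wp$y, pr$y * w$y)
  ok <- is.finite(wp$y) & pr$y <= 1
  expect_true(all(wp$y[ok] <= pmin(pr$y[ok], w$y[ok]) + 1e-12))
  expect_error(wprtf(pr, w3), "shells")
})

test_that("resolution read-off interpolates, flags limits, and is monotone", {
  # step from 1 to 0 between shells at 9.5 and 10.5: crossing at
  # f* = 9.5 + (1 - 1/e), d = 1000 / f*
  curve <- specklekit:::new_curve(c(9.5, 10.5), c(1, 0), "wPRTF")
  res <- resolution_from_curve(curve, threshold = exp(-1))
  f_star <- 9.5 + (1 - exp(-1))
  expect_equal(res$f_um_inv, f_star)
  expect_equal(res$d_nm, 1000 / f_star)
  expect_false(res$limit_reached)

  # curve above threshold everywhere: Nyquist-limited
  flat <- specklekit:::new_curve(1:10, rep(1, 10), "wPRTF")
  resf <- resolution_from_curve(flat)
  expect_true(resf$limit_reached)
  expect_equal(resf$d_nm, 100)

  # starting below threshold is a contract violation
  low <- specklekit:::new_curve(1:10, rep(0.1, 10), "wPRTF")
  expect_error(resolution_from_curve(low), "threshold")

  # monotone: pointwise-larger curves never give worse resolution
  set.seed(7)
  f <- seq(0.5, 20, by = 0.5)
  for (i in 1:20) {
    y1 <- pmax(cumprod(runif(length(f), 0.8, 1.0)), 0)
    y2 <- pmin(y1 + runif(length(f), 0, 0.2), 1.5)
    c1 <- specklekit:::new_curve(f, y1, "wPRTF")
    c2 <- specklekit:::new_curve(f, y2, "wPRTF")
    if (y1[1] <= exp(-1)) next
    r1 <- resolution_from_curve(c1)
    r2 <- resolution_from_curve(c2)
    expect_lte(r2$d_nm, r1$d_nm + 1e-9)
  }
})

test_that("amplitude variance localizes member disagreement", {
  ph <- make_phantom(seed = 14, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  shells <- build_shells(c(64, 64), pat$freq_per_pixel)
  mk <- function(img, s) specklekit:::new_reconstruction(
    img, ph$support, 0.1, s, rfactor = 0.1)

  # identical members: zero variance everywhere (log flagged as -Inf)
  same <- specklekit:::new_reconstruction_set(
    lapply(1:3, function(i) mk(ph$density, i)), pat, registered = TRUE)
  v0 <- amplitude_variance(same, shells)
  expect_true(all(attr(v0, "raw") < 1e-18))
  expect_gt(attr(v0, "n_zero") + sum(is.infinite(v0$y)), 0)

  # two members differing in one Fourier pixel: variance only in its shell
  c0 <- specklekit:::centre_index(64)
  delta <- matrix(0 + 0i, 64, 64)
  delta[c0 + 10, c0] <- 50       # a single frequency, 10 shells out
  img_b <- ph$density +
    Re(specklekit:::ifft2(specklekit:::ifftshift2(delta)))
  pair <- specklekit:::new_reconstruction_set(
    list(mk(ph$density, 1), mk(img_b, 2)), pat, registered = TRUE)
  vp <- amplitude_variance(pair, shells)
  raw <- attr(vp, "raw")
  expect_gt(raw[11], 0)
  expect_lt(max(raw[-11]) , raw[11] * 1e-6)
  expect_error(amplitude_variance(same, build_shells(c(64, 64), 1)),
               NA)
})

test_that("shell and global cross-correlations behave as Pearson statistics", {
  ph <- make_phantom(seed = 15, grid_size = 64, object_fraction = 0.08)
  pat <- add_poisson_noise(diffract(ph), 1e6, seed = 3)
  shells <- build_shells(c(64, 64), pat$freq_per_pixel, shell_width = 8)

  # self-correlation is 1 in every defined shell
  self <- shell_cc(pat, pat, shells)
  expect_equal(self$y[!is.na(self$y)],
               rep(1, sum(!is.na(self$y))), tolerance = 1e-12)

  # against independent noise the correlation is within the null bound
  set.seed(8)
  noise <- diffraction_pattern(matrix(rpois(64^2, 100), 64, 64),
                               freq_per_pixel = pat$freq_per_pixel)
  null_cc <- shell_cc(pat, noise, shells)
  npx <- tabulate(shells$index[!is.na(shells$index)], length(shells$f))
  ok <- !is.na(null_cc$y)
  expect_true(all(abs(null_cc$y[ok]) < 3 / sqrt(npx[ok])))

  # affine rescaling of both patterns leaves the curves unchanged
  resc <- pat
  resc$intensity <- 5 * pat$intensity + 2
  expect_equal(shell_cc(resc, noise, shells)$y, null_cc$y, tolerance = 1e-9)

  # global matrix: symmetric, unit diagonal, [P, P] fully correlated
  m <- global_cc(list(pat, pat))
  expect_equal(m, matrix(1, 2, 2))
  m3 <- global_cc(list(pat, noise, resc))
  expect_equal(m3, t(m3))
  expect_equal(diag(m3), rep(1, 3))
  expect_error(global_cc(list(pat)), "at least two")
})

test_that("band-to-scale conversion inverts the band-centre frequency", {
  expect_equal(band_scale(5, 15), 100)        # 1 / (10 um^-1) = 100 nm
  expect_equal(band_scale(16.5, 18.9), 1000 / 17.7)
  expect_equal(band_scale(1, 1 + 1e-9), 1000, tolerance = 1e-6)
  expect_error(band_scale(0, 5), "f_lo")
  expect_error(band_scale(5, 3), "f_lo")
})
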