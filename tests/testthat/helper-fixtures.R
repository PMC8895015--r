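# Fixtures and independent oracles used across the suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# tiny hand-built phantom (any grid size), bypassing make_phantom's
# 64-pixel minimum; egg-shaped asymmetric envelope with smooth interior
tiny_phantom <- function(n = 32, seed = 1, pixel_nm = 20) {
  c0 <- floor(n / 2) + 1
  x <- matrix(rep(seq_len(n) - c0, n), n, n)
  y <- t(x)
  a <- n * 0.18
  b <- n * 0.11
  set.seed(seed)
  th <- runif(1, 0, pi)
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  supp <- (u / a)^2 + (v / (b * (1 + 0.25 * u / a)))^2 <= 1
  dens <- matrix(0, n, n)
  dens[supp] <- 1 + 0.5 * sin(u[supp] / 2.5) * cos(v[supp] / 2)
  phantom(dens, pixel_nm, supp)
}

# independently coded plain HIO (Fienup), for the OSS degenerate-limit
# check: same seeding contract (uniform random phases on the measured
# magnitudes), magnitude projection on valid pixels, feedback g - beta*g'
# on pixels outside the support or negative inside it. Records the
# per-iteration R-factor of the constrained estimate and returns the best
# estimate, mirroring what the reconstruction engine reports.
hio_oracle <- function(pattern, support, n_iter, beta, seed) {
  shift_back <- function(m) {
    # undo the centre-origin storage: zero frequency to element [1,1]
    d <- dim(m)
    src <- function(n, k) ((seq_len(n) - 1 + k) %% n) + 1
    m[src(d[1], floor(d[1] / 2)), src(d[2], floor(d[2] / 2))]
  }
  amp <- sqrt(shift_back(pattern$intensity))
  valid <- shift_back(pattern$valid)
  npix <- length(amp)
  set.seed(seed)
  phi <- matrix(runif(npix, 0, 2 * pi), nrow(amp), ncol(amp))
  g <- Re(fft(amp * exp(1i * phi), inverse = TRUE) / npix)
  amp_sum <- sum(amp[valid])
  errs <- numeric(n_iter)
  best <- Inf
  best_est <- NULL
  for (k in seq_len(n_iter)) {
    G <- fft(g)
    Gv <- G[valid]
    mv <- Mod(Gv)
    Gp <- G
    Gp[valid] <- amp[valid] * ifelse(mv > 0, Gv / mv, 1 + 0i)
    gp <- Re(fft(Gp, inverse = TRUE) / npix)
    est <- gp
    est[!support] <- 0
    est[est < 0] <- 0
    errs[k] <- sum(abs(Mod(fft(est))[valid] - amp[valid])) / amp_sum
    viol <- (!support) | (gp < 0)
    gnew <- gp
    gnew[viol] <- g[viol] - beta * gp[viol]
    g <- gnew
    if (errs[k] < best) {
      best <- errs[k]
      best_est <- est
    }
  }
  list(image = best_est, errors = errs, rfactor = best)
}

# synthetic ensemble with planted failure members: `n_good` copies of the
# phantom plus small noise, `n_bad` stagnated blob images; R-factors are
# computed against the supplied pattern
planted_ensemble <- function(ph, pattern, n_good, n_bad, noise_sd = 0.02,
                             seed = 1) {
  set.seed(seed)
  d <- dim(ph$density)
  mk <- function(img, s) {
    img <- pmax(img, 0)
    r <- fourier_rfactor(img, pattern)
    specklekit:::new_reconstruction(img, ph$support, r, s, rfactor = r)
  }
  good <- lapply(seq_len(n_good), function(i) {
    mk(ph$density + matrix(rnorm(prod(d), 0, noise_sd), d[1], d[2]) *
         ph$support, i)
  })
  # stagnated runs: partial object/twin superpositions (the classic
  # failure mode when the support cannot break the Friedel ambiguity)
  # carrying the smooth amplitude distortion and residual noise of an
  # unconverged iterate
  twin <- specklekit:::point_invert(ph$density)
  rr <- specklekit:::ifftshift2(specklekit:::freq_radius(d))
  bad <- lapply(seq_len(n_bad), function(i) {
    a <- runif(1, 0.35, 0.65)
    ripple <- Re(specklekit:::ifft2(specklekit:::fft2(
      matrix(rnorm(prod(d)), d[1], d[2])) * exp(-rr^2 / 50)))
    ripple <- ripple / stats::sd(ripple)
    img <- (a * ph$density + (1 - a) * twin) * (1 + 0.3 * ripple) *
      ph$support +
      matrix(rnorm(prod(d), 0, 8 * noise_sd), d[1], d[2]) * ph$support
    mk(img, 100 + i)
  })
  specklekit:::new_reconstruction_set(c(good, bad), pattern)
}

# correlation between a reconstruction image and the ground truth after
# shift/twin registration, computed over the whole grid
truth_correlation <- function(image, ph) {
  reg <- specklekit:::register_to(Re(image), ph$density)
  stats::cor(as.numeric(reg), as.numeric(ph$density))
}
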