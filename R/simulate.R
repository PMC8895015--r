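#' Generate a synthetic organelle-like phantom
#'
#' Builds a compact elongated envelope (an ellipse of random orientation,
#' mimicking a mitochondrion in projection) containing smooth internal
#' Gaussian blobs, so the object has distinct high- and low-density areas.
#' The envelope area is `object_fraction` of the grid, which keeps the
#' oversampling ratio above two per axis as required for phase retrieval.
#'
#' With `n_blobs = 0` the density is constant (the midpoint of
#' `density_range`) inside the support. Otherwise the internal blob field is
#' rescaled linearly so the density inside the support spans exactly
#' `density_range`.
#'
#' @param seed integer seed; the phantom is bit-reproducible for a fixed seed.
#' @param grid_size grid edge length in pixels (at least 64).
#' @param object_fraction fraction of grid area covered by the support, in
#'   (0, 0.25]. Fractions whose envelope would violate the oversampling
#'   condition are rejected.
#' @param n_blobs number of internal Gaussian blobs.
#' @param density_range range (electrons per pixel) spanned by the internal
#'   density.
#' @param pixel_nm real-space sampling in nm per pixel.
#' @param aspect envelope axis ratio (major/minor).
#' @return A [phantom()].
#' @examples
#' ph <- make_phantom(seed = 1, grid_size = 128)
#' mean(ph$support)
#' @export
make_phantom <- function(seed, grid_size = 128L, object_fraction = 0.1,
                         n_blobs = 6L, density_range = c(0.5, 1.5),
                         pixel_nm = 20, aspect = 1.8) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 64L) stop_sk("`grid_size` must be at least 64")
  if (object_fraction <= 0 || object_fraction > 0.25)
    stop_sk("`object_fraction` must be in (0, 0.25]")
  if (length(density_range) != 2L || any(density_range < 0) ||
      diff(density_range) < 0)
    stop_sk("`density_range` must be a non-decreasing non-negative pair")
  n <- grid_size
  area <- object_fraction * n^2
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  if (2 * a > n / 2)
    stop_sk("`object_fraction` too large to satisfy oversampling ",
            "(envelope extent would exceed half the grid); reduce the ",
            "fraction or the aspect ratio")
  with_seed(seed, {
    theta <- stats::runif(1, 0, pi)
    c0 <- centre_index(n)
    x <- matrix(rep(seq_len(n) - c0, n), n, n)        # row offsets
    y <- t(x)                                          # column offsets
    u <- cos(theta) * x + sin(theta) * y
    v <- -sin(theta) * x + cos(theta) * y
    support <- (u / a)^2 + (v / b)^2 <= 1
    density <- matrix(0, n, n)
    if (n_blobs > 0L) {
      field <- matrix(0, n, n)
      placed <- 0L
      while (placed < n_blobs) {
        cu <- stats::runif(1, -0.8 * a, 0.8 * a)
        cv <- stats::runif(1, -0.8 * b, 0.8 * b)
        if ((cu / a)^2 + (cv / b)^2 > 0.75) next
        sg <- stats::runif(1, b / 4, b / 2)
        amp <- ifelse(placed %% 2L == 0L, 1, -1) * stats::runif(1, 0.5, 1)
        field <- field + amp * exp(-((u - cu)^2 + (v - cv)^2) / (2 * sg^2))
        placed <- placed + 1L
      }
      inside <- field[support]
      rng <- range(inside)
      if (diff(rng) > 0) {
        scaled <- density_range[1] +
          diff(density_range) * (inside - rng[1]) / diff(rng)
      } else {
        scaled <- rep(mean(density_range), length(inside))
      }
      density[support] <- scaled
    } else {
      density[support] <- mean(density_range)
    }
    phantom(density, pixel_nm, support)
  })
}

#' Simulate progressive radiation damage of a phantom
#'
#' Emulates the structural response of soft biological matter to an
#' increasing cumulative X-ray dose: pixels in the high-density region (above
#' the 75th density percentile of the support) lose density by multiplicative
#' exponential decay, while pixels in the low-density region (below the 25th
#' percentile) first gain density -- a smooth localized swelling consistent
#' with radiation-induced aggregation of macromolecules -- up to
#' `swell_peak_step`, after which the gain collapses. Step 0 is the
#' undamaged input; the support never changes.
#'
#' @param phantom_obj a [phantom()].
#' @param n_steps number of dose steps including the undamaged step 0.
#' @param high_decay per-step fractional density loss of the high-density
#'   region, in `[0, 1)`.
#' @param low_swell peak fractional density gain of the low-density region,
#'   in `[0, 1)`.
#' @param swell_peak_step step index (0-based) at which the low-density gain
#'   peaks.
#' @param seed seed for the swelling field.
#' @return A list of `n_steps` phantoms; element 1 is the input.
#' @export
simulate_damage_series <- function(phantom_obj, n_steps = 4L,
                                   high_decay = 0.05, low_swell = 0.05,
                                   swell_peak_step = 2L, seed = 1L) {
  stopifnot(inherits(phantom_obj, "phantom"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop_sk("`n_steps` must be at least 2")
  if (high_decay < 0 || high_decay >= 1 || low_swell < 0 || low_swell >= 1)
    stop_sk("`high_decay` and `low_swell` must lie in [0, 1)")
  if (swell_peak_step < 1L || swell_peak_step > n_steps - 1L)
    stop_sk("`swell_peak_step` must be a step index in 1..n_steps-1")
  d0 <- phantom_obj$density
  supp <- phantom_obj$support
  q <- stats::quantile(d0[supp], c(0.25, 0.75))
  low <- supp & d0 <= q[1]
  high <- supp & d0 >= q[2]
  # smooth, strictly positive swelling field on the low region, normalized so
  # its mean over that region equals the region's undamaged mean density
  gain <- with_seed(seed, {
    n <- nrow(d0)
    idx <- which(low, arr.ind = TRUE)
    g <- matrix(0, n, n)
    n_bumps <- max(1L, min(3L, nrow(idx) %/% 8L))
    for (i in seq_len(n_bumps)) {
      ctr <- idx[sample.int(nrow(idx), 1L), ]
      sg <- max(2, sqrt(nrow(idx)) / 3)
      dr <- matrix(rep(seq_len(n) - ctr[1], n), n, n)
      dc <- t(matrix(rep(seq_len(n) - ctr[2], n), n, n))
      g <- g + exp(-(dr^2 + dc^2) / (2 * sg^2))
    }
    g <- g + 0.2                      # keep the field positive everywhere
    g * mean(d0[low]) / mean(g[low])
  })
  steps <- vector("list", n_steps)
  steps[[1L]] <- phantom_obj
  for (t in seq_len(n_steps - 1L)) {
    s_t <- if (t <= swell_peak_step) t / swell_peak_step else
      0.5^(t - swell_peak_step)
    d <- d0
    d[high] <- d0[high] * (1 - high_decay)^t
    # past the peak the transient gain collapses and the region starts
    # losing density outright, like the rest of the damaged object
    post <- max(0L, t - swell_peak_step)
    d[low] <- (d0[low] + s_t * low_swell * gain[low]) *
      (1 - high_decay)^post
    steps[[t + 1L]] <- phantom(d, phantom_obj$pixel_nm, supp)
  }
  steps
}

#' Noiseless far-field diffraction of a phantom
#'
#' Computes the oversampled speckle pattern: the squared magnitude of the
#' discrete Fourier transform of the electron density, with the
#' zero-frequency pixel at the grid centre. All pixels are valid. Parseval's
#' identity holds exactly: the intensity total equals the pixel count times
#' the sum of squared density. For a real phantom the pattern is
#' centrosymmetric (Friedel symmetry).
#'
#' The frequency calibration follows the full-period convention: the
#' increment per pattern pixel is `1e3 / (N * pixel_nm)` inverse
#' micrometres, so a feature at frequency `f` has full-period scale
#' `d = 1/f`.
#'
#' @param phantom_obj a [phantom()].
#' @param meta optional instrument metadata merged into the pattern.
#' @return A [diffraction_pattern()].
#' @export
diffract <- function(phantom_obj, meta = list()) {
  stopifnot(inherits(phantom_obj, "phantom"))
  ext <- support_extent(phantom_obj$support)
  if (any(ext * 2 > dim(phantom_obj$density)))
    stop_sk("phantom violates the oversampling condition")
  intensity <- fftshift2(Mod(fft2(phantom_obj$density))^2)
  n <- nrow(intensity)
  fpp <- 1e3 / (n * phantom_obj$pixel_nm)       # um^-1 per pixel
  diffraction_pattern(intensity, freq_per_pixel = fpp, meta = meta)
}

#' Add Poisson photon noise to a pattern
#'
#' Rescales the intensity so its total over valid pixels equals
#' `photon_budget`, then replaces every valid pixel by a Poisson draw with
#' that mean. Deterministic for a fixed seed; the expected total equals the
#' budget.
#'
#' For a dose series measured with equal exposures, pass the `scale` of the
#' first pattern (attribute `"scale"` of its noisy result) to the later
#' ones, so the absolute intensity differences between steps -- and hence
#' the electron change of the object -- survive the noise step instead of
#' being normalized away.
#'
#' @param pattern a [diffraction_pattern()].
#' @param photon_budget total expected photon count, positive.
#' @param seed integer seed.
#' @param scale optional explicit photons-per-intensity-unit factor,
#'   overriding the budget normalization.
#' @return A [diffraction_pattern()] of integer photon counts, with the
#'   applied factor attached as attribute `"scale"`.
#' @export
add_poisson_noise <- function(pattern, photon_budget, seed = 1L,
                              scale = NULL) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  if (is.null(scale)) {
    if (!is_square_number(photon_budget) || photon_budget <= 0)
      stop_sk("`photon_budget` must be a positive scalar")
    tot <- sum(pattern$intensity[pattern$valid])
    if (tot <= 0) stop_sk("pattern carries no intensity to scale")
    scale <- photon_budget / tot
  } else if (!is_square_number(scale) || scale <= 0) {
    stop_sk("`scale` must be a positive scalar")
  }
  lam <- pattern$intensity * scale
  counts <- pattern$intensity
  counts[pattern$valid] <- with_seed(seed, {
    stats::rpois(sum(pattern$valid), lam[pattern$valid])
  })
  out <- pattern
  out$intensity <- counts
  attr(out, "scale") <- scale
  out
}

#' Mask a beamstop and refill by Friedel symmetry
#'
#' Invalidates a rectangular beamstop region (optionally off-centre), then
#' refills every invalidated pixel whose Friedel partner `-f` is still valid
#' with the partner's value, revalidating it. Because a real object's
#' pattern is centrosymmetric, the refilled values are exact for noiseless
#' data. The pixels that remain missing form a centrosymmetric set -- the
#' residual gap that no symmetry operation can recover.
#'
#' @param pattern a [diffraction_pattern()].
#' @param stop_halfwidth half-extent of the stop in pixels, scalar or
#'   `(rows, cols)` pair.
#' @param stop_offset offset of the stop centre from the zero-frequency
#'   pixel, `(rows, cols)`.
#' @return A [diffraction_pattern()] with an updated validity mask.
#' @export
apply_beamstop_and_symmetrize <- function(pattern, stop_halfwidth,
                                          stop_offset = c(0L, 0L)) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  hw <- rep_len(as.integer(stop_halfwidth), 2L)
  off <- rep_len(as.integer(stop_offset), 2L)
  d <- dim(pattern$intensity)
  if (any(hw < 0) || any(2L * hw + 1L >= d))
    stop_sk("beamstop must be smaller than the grid")
  ctr <- c(centre_index(d[1L]), centre_index(d[2L])) + off
  rows <- max(1L, ctr[1L] - hw[1L]):min(d[1L], ctr[1L] + hw[1L])
  cols <- max(1L, ctr[2L] - hw[2L]):min(d[2L], ctr[2L] + hw[2L])
  valid <- pattern$valid
  valid[rows, cols] <- FALSE
  symmetrize_pattern(pattern, valid)
}

# refill invalid pixels from their Friedel partners where those are valid
symmetrize_pattern <- function(pattern, valid = pattern$valid) {
  partner_valid <- point_invert(valid)
  partner_value <- point_invert(pattern$intensity)
  fillable <- !valid & partner_valid
  intensity <- pattern$intensity
  intensity[fillable] <- partner_value[fillable]
  valid[fillable] <- TRUE
  out <- pattern
  out$intensity <- intensity
  out$valid <- valid
  out
}

#' Crop a pattern symmetrically about the zero-frequency pixel
#'
#' Keeps the central `size` pixels per axis while preserving the convention
#' that zero frequency sits at index `floor(N/2)+1`. Useful before binning
#' when the detector grid is not divisible by the binning factor.
#'
#' @param pattern a [diffraction_pattern()].
#' @param size new edge length(s), scalar or `(rows, cols)`.
#' @return A cropped [diffraction_pattern()].
#' @export
crop_pattern <- function(pattern, size) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  sz <- rep_len(as.integer(size), 2L)
  d <- dim(pattern$intensity)
  if (any(sz < 2L) || any(sz > d)) stop_sk("crop size out of range")
  take <- function(n, m) {
    c0 <- centre_index(n)
    (c0 - floor(m / 2L)):(c0 + ceiling(m / 2L) - 1L)
  }
  rows <- take(d[1L], sz[1L])
  cols <- take(d[2L], sz[2L])
  out <- pattern
  out$intensity <- pattern$intensity[rows, cols, drop = FALSE]
  out$valid <- pattern$valid[rows, cols, drop = FALSE]
  out
}

# amplitude transfer function of a length-b detector-pixel box on an M-point
# binned axis (unshifted index order); H(0) = 1
box_transfer_axis <- function(m, b) {
  u <- seq_len(m) - 1L
  u[u > m / 2] <- u[u > m / 2] - m
  n <- m * b
  h <- rep(1, m)
  nz <- u != 0L
  h[nz] <- sin(pi * u[nz] / m) / (b * sin(pi * u[nz] / n))
  h
}

#' Transfer function of b x b detector binning
#'
#' Separable amplitude transfer function of summing `b x b` detector pixels,
#' evaluated on the binned `m x m` grid in unshifted (DFT) index order and
#' normalized to 1 at zero frequency. Exposed so that the deconvolution in
#' [bin_and_deconvolve()] can be verified externally.
#'
#' @param m binned grid edge length.
#' @param b binning factor.
#' @return An `m x m` numeric matrix.
#' @export
box_transfer <- function(m, b) {
  h <- box_transfer_axis(m, b)
  outer(h, h)
}

#' Bin detector pixels and deconvolve the binning contrast loss
#'
#' Sums `b x b` pixel blocks (a block is valid only when every member is
#' valid; photon totals over valid blocks are conserved), then corrects the
#' contrast reduction caused by the binning box: the Fourier transform of
#' the binned pattern is divided by the box transfer function wherever its
#' magnitude exceeds `reg_threshold`, and left unchanged elsewhere to avoid
#' noise blow-up near the transfer-function zeros. Small negative excursions
#' introduced by the deconvolution are clipped at zero. The frequency
#' increment is multiplied by `b`.
#'
#' @param pattern a [diffraction_pattern()] whose grid is divisible by `b`
#'   (use [crop_pattern()] first otherwise).
#' @param b binning factor, at least 1 (`b = 1` returns the input).
#' @param reg_threshold regularization threshold on the transfer magnitude.
#' @return A binned, deconvolved [diffraction_pattern()].
#' @export
bin_and_deconvolve <- function(pattern, b, reg_threshold = 0.1) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  b <- as.integer(b)
  if (b < 1L) stop_sk("`b` must be at least 1")
  if (b == 1L) return(pattern)
  d <- dim(pattern$intensity)
  if (any(b >= d)) stop_sk("binning factor larger than the grid")
  if (any(d %% b != 0L))
    stop_sk("grid not divisible by `b`; crop first with crop_pattern()")
  m <- d %/% b
  ri <- rep(seq_len(m[1L]), each = b)
  ci <- rep(seq_len(m[2L]), each = b)
  binned <- t(rowsum(t(rowsum(pattern$intensity, ri)), ci))
  dimnames(binned) <- NULL
  nvalid <- t(rowsum(t(rowsum(pattern$valid + 0, ri)), ci))
  valid <- nvalid == b * b
  binned[!valid] <- 0
  # contrast deconvolution, regularized at transfer-function zeros
  h <- outer(box_transfer_axis(m[1L], b), box_transfer_axis(m[2L], b))
  g <- fft2(binned)
  usable <- abs(h) >= reg_threshold
  g[usable] <- g[usable] / h[usable]
  dec <- pmax(Re(ifft2(g)), 0)
  dec[!valid] <- 0
  out <- pattern
  out$intensity <- dec
  out$valid <- valid
  out$freq_per_pixel <- pattern$freq_per_pixel * b
  out$meta$binning <- pattern$meta$binning * b
  out
}

#' Total exposure time of a schedule
#'
#' @param schedule an [exposure_schedule()], or anything coercible to one
#'   (a 2-column matrix/data frame or a list of `(seconds, count)` pairs).
#' @return Total exposure time in seconds.
#' @examples
#' total_exposure(exposure_schedule(c(0.08, 12), c(1000, 80)))  # 1040
#' @export
total_exposure <- function(schedule) {
  if (!inherits(schedule, "exposure_schedule")) {
    if (is.list(schedule) && !is.data.frame(schedule))
      schedule <- do.call(rbind, lapply(schedule, unlist))
    schedule <- as.matrix(schedule)
    if (ncol(schedule) != 2L)
      stop_sk("schedule must have (seconds, counts) entries")
    schedule <- exposure_schedule(schedule[, 1L], schedule[, 2L])
  }
  sum(schedule$seconds * schedule$counts)
}

#' Absorbed dose of an exposure
#'
#' Standard mass-attenuation estimate of the absorbed dose:
#' `D = fluence x E_photon x (mu/rho)` in grays (J/kg). The fluence is taken
#' from `params$fluence_per_um2` or computed as `flux_density *
#' exposure_seconds`; dose is therefore additive over consecutive exposures.
#'
#' @param params a [dose_params()].
#' @param exposure_seconds exposure time in seconds (with `flux_density`).
#' @param flux_density incident flux density in photons per square
#'   micrometre per second.
#' @return Absorbed dose in Gy.
#' @export
absorbed_dose <- function(params, exposure_seconds = NULL,
                          flux_density = NULL) {
  stopifnot(inherits(params, "dose_params"))
  if (!is.null(exposure_seconds) && !is.null(flux_density)) {
    if (exposure_seconds < 0 || flux_density < 0)
      stop_sk("exposure and flux must be non-negative")
    fluence <- flux_density * exposure_seconds
  } else if (!is.null(params$fluence_per_um2)) {
    fluence <- params$fluence_per_um2
  } else {
    stop_sk("supply either `fluence_per_um2` in params or flux and time")
  }
  kev_to_joule <- 1.602176634e-16
  # photons/um^2 -> photons/m^2 is 1e12; cm^2/g -> m^2/kg is 0.1
  fluence * 1e12 * params$photon_energy_keV * kev_to_joule *
    params$mass_attenuation_cm2_g * 0.1
}
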