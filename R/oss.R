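#' Phase a diffraction pattern with the oversampling-smoothness algorithm
#'
#' Iterative phase retrieval alternating between a Fourier-magnitude
#' projection and a real-space update. The magnitude projection replaces the
#' modulus of the iterate's Fourier transform by the measured amplitude
#' `sqrt(I)` on valid pixels only; pixels under the beamstop (never valid)
#' keep the iterate's own modelled value, the standard treatment for missing
#' central data. The real-space update applies hybrid input-output (HIO)
#' feedback `g - beta * g'` on every pixel violating the object constraint
#' (outside the support, or negative inside it in `"real_nonneg"` mode), and
#' then -- the OSS step -- replaces the region outside the support by its
#' Gaussian-low-pass-filtered version, with the filter width taken from the
#' current stage of the schedule. Wide early filters suppress the noise-driven
#' high-frequency content outside the support; the width shrinks stage by
#' stage. Each stage restarts from the lowest-error iterate seen in the
#' previous stage, and the lowest-error iterate overall is returned.
#'
#' With all filter widths infinite the OSS step is skipped entirely and the
#' iteration is exactly plain HIO.
#'
#' @param pattern a [diffraction_pattern()] (shifted order, centre pixel =
#'   zero frequency).
#' @param support logical matrix; `NULL` derives one with [make_support()].
#' @param schedule an [oss_schedule()].
#' @param constraint_mode `"real_nonneg"` (electron density; the default) or
#'   `"complex"`.
#' @param seed seed for the random starting phases.
#' @return A `reconstruction`: the best iterate, its support, the per-
#'   iteration Fourier R-factor history, and the seed.
#' @references Fienup, J. R. (1982). Appl. Opt. 21, 2758. Rodriguez et al.
#'   (2013). J. Appl. Cryst. 46, 312.
#' @export
oss_reconstruct <- function(pattern, support = NULL,
                            schedule = oss_schedule(),
                            constraint_mode = c("real_nonneg", "complex"),
                            seed = 1L) {
  stopifnot(inherits(pattern, "diffraction_pattern"),
            inherits(schedule, "oss_schedule"))
  constraint_mode <- match.arg(constraint_mode)
  if (!any(pattern$valid)) stop_sk("pattern has no valid pixels")
  if (is.null(support)) support <- make_support(pattern)
  if (!any(support)) stop_sk("support is empty")
  d <- dim(pattern$intensity)
  if (!identical(dim(support), d))
    stop_sk("support shape must match the pattern")
  npix <- prod(d)
  amp <- sqrt(pmax(ifftshift2(pattern$intensity), 0))
  valid <- ifftshift2(pattern$valid)
  amp_sum <- sum(amp[valid])
  if (amp_sum <= 0) stop_sk("measured amplitudes are all zero")

  sigmas <- schedule$filter_sigmas
  if (is.null(sigmas)) {
    n <- max(d)
    sigmas <- if (schedule$n_stages == 1L) n else
      seq(n, n / 10, length.out = schedule$n_stages)
  }
  per_stage <- schedule$n_iterations %/% schedule$n_stages
  radius_u <- ifftshift2(freq_radius(d))   # unshifted distance from f = 0
  real_mode <- constraint_mode == "real_nonneg"

  g <- with_seed(seed, {
    phi <- matrix(stats::runif(npix, 0, 2 * pi), d[1L], d[2L])
    g0 <- ifft2(amp * exp(1i * phi))
    if (real_mode) Re(g0) else g0
  })

  outside <- !support
  errs <- numeric(schedule$n_iterations)
  best_err <- Inf
  best_img <- NULL
  it <- 0L
  for (stage in seq_len(schedule$n_stages)) {
    sg <- sigmas[stage]
    w <- if (is.finite(sg)) exp(-radius_u^2 / (2 * sg^2)) else NULL
    stage_best_err <- Inf
    stage_best_g <- g
    for (k in seq_len(per_stage)) {
      it <- it + 1L
      G <- fft2(g)
      Gv <- G[valid]
      mv <- Mod(Gv)
      ph <- ifelse(mv > 0, Gv / mv, 1 + 0i)
      Gp <- G
      Gp[valid] <- amp[valid] * ph
      gp <- ifft2(Gp)
      if (real_mode) gp <- Re(gp)
      # object estimate: magnitude-projected iterate with the real-space
      # constraints enforced; this is what the error ranks and what the
      # caller receives (the HIO driver keeps feedback residue outside the
      # support by construction, so its own R-factor never vanishes)
      est <- gp
      est[outside] <- 0
      if (real_mode) est[est < 0] <- 0
      errs[it] <- sum(abs(Mod(fft2(est))[valid] - amp[valid])) / amp_sum
      viol <- if (real_mode) outside | (gp < 0) else outside
      gh <- gp
      gh[viol] <- g[viol] - schedule$beta * gp[viol]
      if (!is.null(w)) {
        gf <- ifft2(fft2(gh) * w)
        if (real_mode) gf <- Re(gf)
        gh[outside] <- gf[outside]
      }
      g <- gh
      if (errs[it] < stage_best_err) {
        stage_best_err <- errs[it]
        stage_best_g <- g
      }
      if (errs[it] < best_err) {
        best_err <- errs[it]
        best_img <- est
      }
    }
    g <- stage_best_g     # hand the best iterate of this stage to the next
  }
  new_reconstruction(best_img, support, errs, seed, rfactor = best_err,
                     mode = constraint_mode)
}

#' Project an image onto the measured Fourier magnitudes
#'
#' Replaces the modulus of the image's Fourier transform by `sqrt(I)` on
#' the pattern's valid pixels, keeping the image's phases; invalid pixels
#' keep the image's own Fourier value. This is the Fourier-domain half of
#' every phase-retrieval iteration; it is idempotent on the valid set.
#'
#' @param image numeric or complex matrix.
#' @param pattern a [diffraction_pattern()] of matching shape.
#' @return The projected image (complex matrix).
#' @export
project_magnitudes <- function(image, pattern) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  if (!identical(dim(image), dim(pattern$intensity)))
    stop_sk("image and pattern shapes differ")
  amp <- sqrt(pmax(ifftshift2(pattern$intensity), 0))
  valid <- ifftshift2(pattern$valid)
  G <- fft2(image)
  Gv <- G[valid]
  mv <- Mod(Gv)
  G[valid] <- amp[valid] * ifelse(mv > 0, Gv / mv, 1 + 0i)
  ifft2(G)
}

#' Fourier R-factor of a reconstruction against a pattern
#'
#' The standard convergence metric of iterative phase retrieval:
#' `R = sum_valid | |F(image)| - sqrt(I) | / sum_valid sqrt(I)`,
#' the normalized absolute deviation of the reconstructed Fourier amplitudes
#' from the measured ones, over valid pixels only. Invariant to real-space
#' translation of the image.
#'
#' @param reconstruction a `reconstruction`, or a bare image matrix.
#' @param pattern a [diffraction_pattern()] of matching shape.
#' @return Non-negative scalar.
#' @export
fourier_rfactor <- function(reconstruction, pattern) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  img <- if (inherits(reconstruction, "reconstruction"))
    reconstruction$image else reconstruction
  if (!identical(dim(img), dim(pattern$intensity)))
    stop_sk("image and pattern shapes differ")
  amp <- sqrt(pmax(ifftshift2(pattern$intensity), 0))
  valid <- ifftshift2(pattern$valid)
  denom <- sum(amp[valid])
  if (denom <= 0) stop_sk("measured amplitudes sum to zero on valid pixels")
  modF <- Mod(fft2(img))
  sum(abs(modF[valid] - amp[valid])) / denom
}

#' Run an ensemble of independent OSS reconstructions
#'
#' Performs `n_runs` independent reconstructions from seeds `base_seed`,
#' `base_seed + 1`, ..., so the ensemble is reproducible from one integer.
#' Independent restarts explore different phase-retrieval solutions (shifts,
#' Friedel twins, stagnated local minima); downstream clustering selects the
#' mutually consistent subset.
#'
#' @inheritParams oss_reconstruct
#' @param n_runs number of independent runs, at least 2.
#' @param base_seed seed of the first run.
#' @return A `reconstruction_set`.
#' @export
run_ensemble <- function(pattern, support = NULL, schedule = oss_schedule(),
                         n_runs = 24L, base_seed = 1L,
                         constraint_mode = "real_nonneg") {
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop_sk("`n_runs` must be at least 2")
  if (is.null(support)) support <- make_support(pattern)
  members <- lapply(seq_len(n_runs) - 1L, function(i) {
    oss_reconstruct(pattern, support, schedule,
                    constraint_mode = constraint_mode,
                    seed = base_seed + i)
  })
  new_reconstruction_set(members, pattern)
}

#' Derive a support mask from a pattern's autocorrelation
#'
#' The inverse Fourier transform of the measured intensity is the object's
#' autocorrelation, whose extent is twice the object extent in every
#' direction. Thresholding it at `threshold` times its maximum and closing
#' small gaps morphologically yields a loose but valid support for phase
#' retrieval. Missing pixels are treated as zero intensity, so symmetrize
#' and fill the centre first where possible.
#'
#' @param pattern a [diffraction_pattern()].
#' @param method only `"autocorrelation"` is implemented.
#' @param threshold fraction of the autocorrelation maximum, in (0, 1).
#' @param closing_radius radius (pixels) of the morphological closing disc;
#'   0 disables closing.
#' @return A logical support matrix covering less than half the grid.
#' @export
make_support <- function(pattern, method = "autocorrelation",
                         threshold = 0.04, closing_radius = 2L) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  method <- match.arg(method, "autocorrelation")
  if (threshold <= 0 || threshold >= 1)
    stop_sk("`threshold` must lie strictly between 0 and 1")
  intens <- pattern$intensity
  intens[!pattern$valid] <- 0
  ac <- Re(fftshift2(ifft2(ifftshift2(intens))))
  ac <- ac / max(ac)
  supp <- ac > threshold
  if (closing_radius > 0L && any(supp)) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    supp <- EBImage::closing(supp + 0, brush) > 0.5
  }
  if (mean(supp) >= 0.5)
    stop_sk("derived support covers half the grid or more; ",
            "raise `threshold`")
  supp
}
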