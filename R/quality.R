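# Resolution and consistency metrics: radial shells, PRTF, Wiener
# weighting, wPRTF resolution at the 1/e criterion, shell amplitude
# variance, and shell / global cross-correlation between patterns.

#' Build concentric resolution shells
#'
#' Partitions every pixel within the Nyquist disc (radius `min(shape)/2`
#' pixels from the zero-frequency pixel) into annuli of `shell_width`
#' pixels. Shell `j` has centre frequency `(j - 1/2) * shell_width *
#' freq_per_pixel`.
#'
#' @param shape grid dimensions `(rows, cols)`.
#' @param freq_per_pixel spatial-frequency increment (inverse micrometres).
#' @param shell_width shell width in pixels, at least 1.
#' @return An object of class `"shell_map"` with the per-pixel shell index
#'   (`NA` beyond Nyquist), shell centre frequencies `f`, and pixel counts.
#' @export
build_shells <- function(shape, freq_per_pixel, shell_width = 1) {
  if (shell_width < 1) stop_sk("`shell_width` must be at least 1 pixel")
  r <- freq_radius(shape)
  nyq <- min(shape) / 2
  idx <- ifelse(r < nyq, floor(r / shell_width) + 1L, NA_integer_)
  n_shells <- max(idx, na.rm = TRUE)
  counts <- tabulate(idx[!is.na(idx)], n_shells)
  f <- (seq_len(n_shells) - 0.5) * shell_width * freq_per_pixel
  structure(list(index = idx, f = f, counts = counts,
                 freq_per_pixel = freq_per_pixel,
                 shell_width = shell_width, shape = shape),
            class = "shell_map")
}

#' @export
print.shell_map <- function(x, ...) {
  cat(sprintf("<shell_map> %d shells of %g px on a %d x %d grid\n",
              length(x$f), x$shell_width, x$shape[1], x$shape[2]))
  invisible(x)
}

# shell-wise statistic of per-pixel values; empty shells give NA
shell_stat <- function(values, index, n_shells, fun = mean) {
  keep <- !is.na(index) & is.finite(values)
  out <- rep(NA_real_, n_shells)
  if (!any(keep)) return(out)
  agg <- tapply(values[keep], index[keep], fun)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Phase retrieval transfer function
#'
#' The PRTF compares the Fourier amplitude of the *average* of independent
#' reconstructions with the measured amplitude `sqrt(I)`: where the
#' retrieved phases are reproducible the average retains full amplitude
#' (PRTF = 1); where they are random the phasors cancel and the PRTF falls
#' towards the `1/sqrt(N)` floor (0.2 for N = 24). Accumulation is the
#' shell-wise mean (default) or root-mean-square of the per-pixel ratios
#' `|F(average)| / sqrt(I)`; measured pixels whose amplitude falls below
#' `amp_floor_frac` times the maximum are excluded, since dividing by a
#' near-zero measured amplitude makes naive PRTF values blow up at high
#' frequency. Shells with no contributing pixel are returned as `NA`.
#'
#' @param average_image registered mean of independent reconstructions
#'   (matrix or `"speckle_average"`).
#' @param pattern the measured [diffraction_pattern()].
#' @param shells a [build_shells()] map.
#' @param statistic `"mean"` (default) or `"rms"` shell accumulation.
#' @param amp_floor_frac exclusion floor as a fraction of the maximum
#'   measured amplitude.
#' @return A `speckle_curve` of kind `"PRTF"`; attribute `"n_excluded"`
#'   records how many valid pixels were excluded by the amplitude floor.
#' @export
prtf <- function(average_image, pattern, shells, statistic = c("mean", "rms"),
                 amp_floor_frac = 1e-6) {
  stopifnot(inherits(pattern, "diffraction_pattern"),
            inherits(shells, "shell_map"))
  statistic <- match.arg(statistic)
  img <- if (inherits(average_image, "speckle_average"))
    average_image$image else average_image
  if (!identical(dim(img), dim(pattern$intensity)))
    stop_sk("image and pattern shapes differ")
  amp_rec <- Mod(fftshift2(fft2(img)))
  amp_meas <- sqrt(pmax(pattern$intensity, 0))
  floor_amp <- amp_floor_frac * max(amp_meas[pattern$valid])
  use <- pattern$valid & amp_meas > floor_amp
  ratio <- matrix(NA_real_, nrow(img), ncol(img))
  ratio[use] <- amp_rec[use] / amp_meas[use]
  fun <- if (statistic == "mean") mean else function(v) sqrt(mean(v^2))
  y <- shell_stat(ratio, shells$index, length(shells$f), fun)
  new_curve(shells$f, y, "PRTF",
            extra = list(statistic = statistic,
                         n_excluded = sum(pattern$valid) - sum(use)))
}

#' Monte-Carlo PRTF floor for averaged random phases
#'
#' The expected PRTF of an average of `n_members` reconstructions whose
#' Fourier phases are independent and uniformly random: per frequency bin,
#' `n_members` unit phasors are averaged, and the root-mean-square magnitude
#' of the per-bin averages over `n_bins` bins is returned. Its expectation
#' is exactly `1/sqrt(n_members)` (0.204 for 24 members), the floor below
#' which a measured PRTF carries no phase information.
#'
#' @param n_members number of averaged reconstructions.
#' @param n_bins number of independent frequency bins simulated.
#' @param seed integer seed.
#' @return The RMS magnitude of the averaged phasors (scalar).
#' @export
prtf_random_floor <- function(n_members = 24L, n_bins = 10000L, seed = 1L) {
  if (n_members < 1L || n_bins < 1L)
    stop_sk("`n_members` and `n_bins` must be positive")
  with_seed(seed, {
    phi <- matrix(stats::runif(n_members * n_bins, 0, 2 * pi),
                  n_members, n_bins)
    z <- colMeans(exp(1i * phi))
    sqrt(mean(Mod(z)^2))
  })
}

#' Estimate the constant noise floor of a pattern
#'
#' The noise power is modelled as a single constant, read off where the
#' power spectral density fluctuates steadily at high frequency: the median
#' of the shell-averaged intensity over the outermost `tail_fraction` of
#' shells.
#'
#' @param pattern a [diffraction_pattern()].
#' @param shells a [build_shells()] map.
#' @param tail_fraction fraction of outermost shells used, in (0, 0.5).
#' @return Non-negative scalar noise level (photons).
#' @export
estimate_noise_floor <- function(pattern, shells, tail_fraction = 0.1) {
  stopifnot(inherits(pattern, "diffraction_pattern"),
            inherits(shells, "shell_map"))
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop_sk("`tail_fraction` must lie strictly between 0 and 0.5")
  psd <- shell_psd(pattern, shells)
  m <- length(psd)
  tail <- max(1L, ceiling(tail_fraction * m))
  stats::median(psd[(m - tail + 1L):m], na.rm = TRUE)
}

# shell-averaged intensity over valid pixels
shell_psd <- function(pattern, shells) {
  intens <- pattern$intensity
  intens[!pattern$valid] <- NA_real_
  shell_stat(intens, shells$index, length(shells$f))
}

#' Wiener weight of each resolution shell
#'
#' From the shell-averaged power spectral density `PSD(f)` and the constant
#' noise level `N`, the pure signal is `S = max(PSD - N, 0)` and the Wiener
#' weight is `W = S / (S + N)` (0 where both vanish). `W` lies in `[0, 1]`:
#' 1 where the signal dominates, 0 where the shell is pure noise.
#'
#' @param pattern a [diffraction_pattern()].
#' @param shells a [build_shells()] map.
#' @param noise_floor constant noise level; `NULL` calls
#'   [estimate_noise_floor()].
#' @return A `speckle_curve` of kind `"wiener"`.
#' @export
wiener_weight <- function(pattern, shells, noise_floor = NULL) {
  stopifnot(inherits(pattern, "diffraction_pattern"),
            inherits(shells, "shell_map"))
  if (is.null(noise_floor)) noise_floor <- estimate_noise_floor(pattern, shells)
  if (noise_floor < 0) stop_sk("`noise_floor` must be non-negative")
  psd <- shell_psd(pattern, shells)
  s <- pmax(psd - noise_floor, 0)
  w <- ifelse(s + noise_floor > 0, s / (s + noise_floor), 0)
  new_curve(shells$f, w, "wiener", extra = list(noise_floor = noise_floor))
}

#' Wiener-weighted PRTF
#'
#' Pointwise product of a PRTF curve and a Wiener weight curve on matching
#' shells. Damping the PRTF by the Wiener weight suppresses the spurious
#' high-frequency PRTF values caused by noise, giving a more conservative
#' resolution estimate.
#'
#' @param prtf_curve a `speckle_curve` of kind `"PRTF"`.
#' @param wiener_curve a `speckle_curve` of kind `"wiener"` on the same
#'   shells.
#' @return A `speckle_curve` of kind `"wPRTF"`.
#' @export
wprtf <- function(prtf_curve, wiener_curve) {
  if (nrow(prtf_curve) != nrow(wiener_curve) ||
      !isTRUE(all.equal(prtf_curve$f, wiener_curve$f)))
    stop_sk("PRTF and Wiener curves must share the same shells")
  new_curve(prtf_curve$f, prtf_curve$y * wiener_curve$y, "wPRTF")
}

#' Resolution from a transfer curve at a threshold
#'
#' Finds the first frequency at which the curve drops below `threshold`
#' (the 1/e criterion by default), linearly interpolating between the
#' bracketing shells, and returns the full-period scale `d = 1/f` in
#' nanometres. If the curve never crosses the threshold, the Nyquist-limit
#' scale is returned with `limit_reached = TRUE`.
#'
#' @param curve a `speckle_curve` (frequencies in inverse micrometres).
#' @param threshold crossing level; defaults to `1/e`.
#' @return A list with `d_nm`, the crossing frequency `f_um_inv`, and
#'   `limit_reached`.
#' @export
resolution_from_curve <- function(curve, threshold = exp(-1)) {
  f <- curve$f
  y <- curve$y
  keep <- is.finite(y)
  f <- f[keep]
  y <- y[keep]
  if (length(y) == 0L) stop_sk("curve has no finite values")
  if (y[1L] <= threshold)
    stop_sk("curve starts at or below the threshold; no resolution defined")
  below <- which(y < threshold)
  if (length(below) == 0L) {
    return(list(d_nm = 1e3 / f[length(f)], f_um_inv = f[length(f)],
                limit_reached = TRUE))
  }
  i <- below[1L]
  f_star <- f[i - 1L] + (y[i - 1L] - threshold) / (y[i - 1L] - y[i]) *
    (f[i] - f[i - 1L])
  list(d_nm = 1e3 / f_star, f_um_inv = f_star, limit_reached = FALSE)
}

#' Shell variance of reconstructed Fourier amplitudes
#'
#' For each pixel, the variance of the Fourier amplitude `|F(member)|`
#' across the (registered) ensemble members; for each shell, the mean of
#' those pixel variances, reported on the natural-log scale. A low variance
#' means the independent runs agree at that length scale. Shells of exactly
#' zero variance map to `-Inf` (counted in attribute `"n_zero"`); the raw
#' variances are attached as attribute `"raw"`.
#'
#' @param set a registered `reconstruction_set` with at least 2 members.
#' @param shells a [build_shells()] map.
#' @return A `speckle_curve` of kind `"variance"`.
#' @export
amplitude_variance <- function(set, shells) {
  stopifnot(inherits(set, "reconstruction_set"),
            inherits(shells, "shell_map"))
  n <- length(set$members)
  if (n < 2L) stop_sk("variance needs at least two members")
  amps <- vapply(set$members,
                 function(m) as.numeric(Mod(fftshift2(fft2(m$image)))),
                 numeric(length(set$members[[1L]]$image)))
  mu <- rowMeans(amps)
  pixvar <- rowSums((amps - mu)^2) / (n - 1L)
  v <- shell_stat(matrix(pixvar, shells$shape[1L], shells$shape[2L]),
                  shells$index, length(shells$f))
  new_curve(shells$f, log(v), "variance",
            extra = list(raw = v, n_zero = sum(v == 0, na.rm = TRUE)))
}

#' Shell-wise cross-correlation between two patterns
#'
#' Pearson correlation of the two intensity arrays over the mutually valid
#' pixels of each resolution shell. High shells decorrelate first when fine
#' structure changes between exposures (or when noise dominates), so the
#' curve localizes structural change in length scale. Shells with fewer
#' than 3 shared pixels or with constant values are returned as `NA`.
#'
#' @param pattern_a,pattern_b two [diffraction_pattern()]s of identical
#'   geometry.
#' @param shells a [build_shells()] map.
#' @return A `speckle_curve` of kind `"shell_cc"` with values in `[-1, 1]`.
#' @export
shell_cc <- function(pattern_a, pattern_b, shells) {
  stopifnot(inherits(pattern_a, "diffraction_pattern"),
            inherits(pattern_b, "diffraction_pattern"),
            inherits(shells, "shell_map"))
  if (!identical(dim(pattern_a$intensity), dim(pattern_b$intensity)))
    stop_sk("patterns must share the same geometry")
  both <- pattern_a$valid & pattern_b$valid
  n_shells <- length(shells$f)
  y <- rep(NA_real_, n_shells)
  for (j in seq_len(n_shells)) {
    px <- which(both & !is.na(shells$index) & shells$index == j)
    if (length(px) < 3L) next
    a <- pattern_a$intensity[px]
    b <- pattern_b$intensity[px]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    y[j] <- stats::cor(a, b)
  }
  new_curve(shells$f, y, "shell_cc", extra = list(method = "pearson"))
}

#' Global cross-correlation matrix of a pattern series
#'
#' Symmetric matrix of Pearson correlations between every pair of patterns,
#' computed over the pixels valid in both; unit diagonal. Across a dose
#' series the first-to-later correlations decay as cumulative damage
#' accumulates.
#'
#' @param patterns list of [diffraction_pattern()]s of identical geometry.
#' @return Numeric correlation matrix.
#' @export
global_cc <- function(patterns) {
  n <- length(patterns)
  if (n < 2L) stop_sk("need at least two patterns")
  d <- dim(patterns[[1L]]$intensity)
  for (p in patterns) {
    if (!inherits(p, "diffraction_pattern") || !identical(dim(p$intensity), d))
      stop_sk("all patterns must share the same geometry")
  }
  cc <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- patterns[[i]]$valid & patterns[[j]]$valid
      cc[i, j] <- cc[j, i] <-
        stats::cor(patterns[[i]]$intensity[both],
                   patterns[[j]]$intensity[both])
    }
  }
  cc
}

#' Length scale probed by a frequency band
#'
#' Converts a band of full-period spatial frequencies (inverse micrometres)
#' to its representative full-period length scale in nanometres:
#' `d = 1 / ((f_lo + f_hi)/2)`.
#'
#' @param f_lo,f_hi band edges, `0 < f_lo < f_hi`, in inverse micrometres.
#' @return Scale in nanometres.
#' @examples
#' band_scale(16.5, 18.9)  # ~56 nm
#' @export
band_scale <- function(f_lo, f_hi) {
  if (!is_square_number(f_lo) || !is_square_number(f_hi) ||
      f_lo <= 0 || f_hi <= f_lo)
    stop_sk("need 0 < f_lo < f_hi")
  1e3 / ((f_lo + f_hi) / 2)
}
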