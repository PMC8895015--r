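#' Construct a phantom (ground-truth electron-density map)
#'
#' A phantom is a 2-D non-negative electron-density grid (electrons per
#' pixel) together with a boolean support marking the object's extent and
#' the real-space sampling in nanometres. The support must occupy a minority
#' of the grid so that the far-field speckle pattern is oversampled by more
#' than a factor of two per axis, the condition under which iterative phase
#' retrieval is feasible.
#'
#' @param density numeric matrix, non-negative, zero outside `support`.
#' @param pixel_nm real-space sampling in nm per pixel.
#' @param support logical matrix of the same shape as `density`.
#' @return An object of class `"phantom"`.
#' @seealso [make_phantom()] for the generative constructor.
#' @export
phantom <- function(density, pixel_nm, support) {
  if (!is.matrix(density) || !is.numeric(density))
    stop_sk("`density` must be a numeric matrix")
  if (!is.matrix(support) || !is.logical(support) ||
      !identical(dim(support), dim(density)))
    stop_sk("`support` must be a logical matrix matching `density`")
  if (anyNA(density) || any(density < 0))
    stop_sk("`density` must be finite and non-negative")
  if (any(density[!support] != 0))
    stop_sk("`density` must be zero outside the support")
  if (!is_square_number(pixel_nm) || pixel_nm <= 0)
    stop_sk("`pixel_nm` must be a positive scalar")
  ext <- support_extent(support)
  if (any(ext * 2 > dim(density)))
    stop_sk("support too large: oversampling ratio must exceed 2 per axis")
  structure(list(density = density, pixel_nm = pixel_nm, support = support),
            class = "phantom")
}

# per-axis bounding-box extent of a logical mask
support_extent <- function(support) {
  if (!any(support)) return(c(0L, 0L))
  rows <- range(which(rowSums(support) > 0))
  cols <- range(which(colSums(support) > 0))
  c(diff(rows) + 1L, diff(cols) + 1L)
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom> %d x %d grid, %.3g nm/pixel\n", d[1], d[2], x$pixel_nm))
  cat(sprintf("  support: %d px (%.1f%% of grid), density in [%.3g, %.3g] e-/px\n",
              sum(x$support), 100 * mean(x$support),
              min(x$density[x$support]), max(x$density[x$support])))
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  graphics::image(x$density, asp = 1, axes = FALSE, useRaster = TRUE,
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

#' Construct a diffraction pattern
#'
#' Holds a measured or simulated far-field intensity grid (photons) together
#' with a validity mask (`FALSE` under the beamstop or any unsymmetrized
#' gap), the spatial-frequency increment per pixel, and instrument metadata.
#' The zero-frequency pixel sits at 1-based index `floor(N/2)+1` on each
#' axis.
#'
#' @param intensity numeric matrix of photon counts; must be non-negative on
#'   valid pixels.
#' @param valid logical matrix; `FALSE` marks missing data.
#' @param freq_per_pixel spatial-frequency increment, inverse micrometres per
#'   pixel (full-period convention: resolution `d = 1/f`).
#' @param meta list of instrument metadata (photon energy keV, detector
#'   distance m, detector pixel micrometres, binning factor).
#' @return An object of class `"diffraction_pattern"`.
#' @export
diffraction_pattern <- function(intensity, valid = NULL, freq_per_pixel = 1,
                                meta = list()) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop_sk("`intensity` must be a numeric matrix")
  if (is.null(valid)) valid <- array(TRUE, dim(intensity))
  if (!is.logical(valid) || !identical(dim(valid), dim(intensity)))
    stop_sk("`valid` must be a logical matrix matching `intensity`")
  if (anyNA(intensity[valid]) || any(intensity[valid] < 0))
    stop_sk("`intensity` must be finite and non-negative on valid pixels")
  if (!is_square_number(freq_per_pixel) || freq_per_pixel <= 0)
    stop_sk("`freq_per_pixel` must be a positive scalar")
  meta <- utils::modifyList(list(photon_energy_keV = NA_real_,
                                 detector_distance_m = NA_real_,
                                 detector_pixel_um = NA_real_,
                                 binning = 1L), meta)
  structure(list(intensity = intensity, valid = valid,
                 freq_per_pixel = freq_per_pixel, meta = meta),
            class = "diffraction_pattern")
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<diffraction_pattern> %d x %d, %.4g um^-1/pixel, binning %dx\n",
              d[1], d[2], x$freq_per_pixel, x$meta$binning))
  cat(sprintf("  %d invalid px (%.2f%%), total %.4g photons on valid px\n",
              sum(!x$valid), 100 * mean(!x$valid), sum(x$intensity[x$valid])))
  invisible(x)
}

#' @export
plot.diffraction_pattern <- function(x, log = TRUE, ...) {
  z <- x$intensity
  z[!x$valid] <- NA
  if (log) z <- log1p(z)
  graphics::image(z, asp = 1, axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(256, "viridis"), ...)
  invisible(x)
}

#' Exposure schedule
#'
#' A list of (exposure seconds, number of exposures) entries, as used when a
#' pattern is accumulated from repeated short and long exposures to extend
#' detector dynamic range.
#'
#' @param seconds numeric vector of per-exposure times (s), strictly positive.
#' @param counts integer vector of exposure counts, strictly positive.
#' @return An object of class `"exposure_schedule"`.
#' @examples
#' sched <- exposure_schedule(c(0.08, 12), c(1000, 80))
#' total_exposure(sched)  # 1040 s
#' @export
exposure_schedule <- function(seconds, counts) {
  if (length(seconds) == 0L || length(seconds) != length(counts))
    stop_sk("`seconds` and `counts` must be non-empty and of equal length")
  if (anyNA(seconds) || anyNA(counts) || any(seconds <= 0) || any(counts <= 0))
    stop_sk("all exposure times and counts must be strictly positive")
  structure(data.frame(seconds = as.numeric(seconds),
                       counts = as.numeric(counts)),
            class = c("exposure_schedule", "data.frame"))
}

#' OSS iteration schedule
#'
#' Controls the oversampling-smoothness (OSS) engine: the total iteration
#' count, the number of Gaussian filter stages, the HIO feedback parameter
#' beta, and the per-stage filter widths (sigma, in frequency pixels). The
#' widths must decrease strictly across stages: early stages smooth the
#' region outside the support heavily, late stages barely at all. Widths of
#' `Inf` disable filtering, reducing OSS to plain HIO.
#'
#' @param n_iterations total number of iterations.
#' @param n_stages number of filter stages; must divide `n_iterations`.
#' @param beta HIO feedback parameter, conventionally 0.5-1.
#' @param filter_sigmas per-stage Gaussian sigma in frequency pixels,
#'   strictly decreasing. Default `NULL` resolves at reconstruction time to a
#'   linear progression from the grid extent N down to N/10.
#' @return An object of class `"oss_schedule"`.
#' @export
oss_schedule <- function(n_iterations = 2000L, n_stages = 10L, beta = 0.9,
                         filter_sigmas = NULL) {
  n_iterations <- as.integer(n_iterations)
  n_stages <- as.integer(n_stages)
  if (n_iterations < 1L || n_stages < 1L || n_iterations %% n_stages != 0L)
    stop_sk("`n_stages` must be positive and divide `n_iterations`")
  if (!is_square_number(beta) || beta <= 0)
    stop_sk("`beta` must be a positive scalar")
  if (!is.null(filter_sigmas)) {
    if (length(filter_sigmas) != n_stages)
      stop_sk("`filter_sigmas` must have one width per stage")
    if (any(diff(filter_sigmas) >= 0) && n_stages > 1L)
      stop_sk("`filter_sigmas` must be strictly decreasing")
    if (any(filter_sigmas <= 0)) stop_sk("`filter_sigmas` must be positive")
  }
  structure(list(n_iterations = n_iterations, n_stages = n_stages,
                 beta = beta, filter_sigmas = filter_sigmas),
            class = "oss_schedule")
}

#' @export
print.oss_schedule <- function(x, ...) {
  sig <- if (is.null(x$filter_sigmas)) "auto (N .. N/10)" else
    paste(signif(x$filter_sigmas, 3), collapse = ", ")
  cat(sprintf("<oss_schedule> %d iterations, %d stages, beta = %g\n",
              x$n_iterations, x$n_stages, x$beta))
  cat("  filter sigmas (freq px):", sig, "\n")
  invisible(x)
}

# internal constructor for a single phase-retrieval result
new_reconstruction <- function(image, support, error_history, seed,
                               rfactor = NULL, mode = "real_nonneg") {
  if (is.null(rfactor)) rfactor <- error_history[length(error_history)]
  structure(list(image = image, support = support,
                 error_history = as.numeric(error_history),
                 seed = as.integer(seed), rfactor = as.numeric(rfactor),
                 mode = mode),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d x %d (%s), seed %d\n",
              nrow(x$image), ncol(x$image), x$mode, x$seed))
  cat(sprintf("  Fourier R-factor %.4g after %d iterations\n",
              x$rfactor, length(x$error_history)))
  invisible(x)
}

#' @export
plot.reconstruction <- function(x, ...) {
  graphics::image(Re(x$image), asp = 1, axes = FALSE, useRaster = TRUE,
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

# internal constructor for an ensemble of independent runs
new_reconstruction_set <- function(members, pattern, registered = FALSE) {
  shapes <- vapply(members, function(m) dim(m$image), integer(2))
  if (length(unique(shapes[1, ])) != 1L || length(unique(shapes[2, ])) != 1L)
    stop_sk("all ensemble members must share the grid shape")
  structure(list(members = members, pattern = pattern,
                 registered = registered),
            class = "reconstruction_set")
}

#' @export
print.reconstruction_set <- function(x, ...) {
  r <- member_rfactors(x)
  cat(sprintf("<reconstruction_set> %d members%s, R-factor %.4g .. %.4g\n",
              length(x$members), if (x$registered) " (registered)" else "",
              min(r), max(r)))
  invisible(x)
}

#' Fourier R-factors of all ensemble members
#'
#' @param set a `reconstruction_set`.
#' @return Numeric vector, one R-factor per member.
#' @export
member_rfactors <- function(set) {
  vapply(set$members, function(m) m$rfactor, numeric(1))
}

# radially binned curve container
new_curve <- function(f, y, kind, extra = NULL) {
  out <- data.frame(f = as.numeric(f), y = as.numeric(y))
  class(out) <- c("speckle_curve", "data.frame")
  attr(out, "kind") <- kind
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.speckle_curve <- function(x, ...) {
  cat(sprintf("<speckle_curve> kind '%s', %d shells, f in [%.4g, %.4g] um^-1\n",
              attr(x, "kind"), nrow(x), min(x$f), max(x$f)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.speckle_curve <- function(x, ...) {
  graphics::plot(x$f, x$y, type = "l", xlab = expression(f ~ (mu * m^-1)),
                 ylab = attr(x, "kind"), ...)
  invisible(x)
}

#' Rectangular analysis region of a reconstruction
#'
#' @param row0,col0 1-based top-left corner, in reconstruction pixels.
#' @param height,width positive extent in pixels.
#' @param label optional region name.
#' @return An object of class `"region_spec"`.
#' @export
region_spec <- function(row0, col0, height, width, label = "") {
  v <- c(row0, col0, height, width)
  if (anyNA(v) || any(v < 1) || any(v != round(v)))
    stop_sk("region coordinates and extents must be positive integers")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 label = label),
            class = "region_spec")
}

region_indices <- function(region, dim) {
  r <- region$row0:(region$row0 + region$height - 1L)
  c <- region$col0:(region$col0 + region$width - 1L)
  if (max(r) > dim[1L] || max(c) > dim[2L])
    stop_sk("region exceeds image bounds")
  list(rows = r, cols = c)
}

#' Dose series of registered reconstructions
#'
#' Bundles reconstructions of the same object measured at strictly
#' increasing cumulative doses, with the calibration constant converting
#' image intensity units to electrons.
#'
#' @param reconstructions list of `reconstruction` objects (or bare numeric
#'   matrices) sharing one grid shape.
#' @param doses numeric vector of cumulative doses (Gy), strictly increasing.
#' @param calibration electrons per image-intensity unit, positive.
#' @return An object of class `"dose_series"`.
#' @export
dose_series <- function(reconstructions, doses, calibration = 1) {
  if (length(reconstructions) < 2L)
    stop_sk("a dose series needs at least two members")
  if (length(doses) != length(reconstructions))
    stop_sk("`doses` must have one entry per reconstruction")
  if (anyNA(doses) || any(diff(doses) <= 0))
    stop_sk("`doses` must be strictly increasing")
  if (!is_square_number(calibration) || calibration <= 0)
    stop_sk("`calibration` must be a positive scalar")
  reconstructions <- lapply(reconstructions, function(m) {
    if (is.matrix(m)) new_reconstruction(m, array(TRUE, dim(m)), 0, 0L) else m
  })
  shapes <- vapply(reconstructions, function(m) dim(m$image), integer(2))
  if (length(unique(shapes[1, ])) != 1L || length(unique(shapes[2, ])) != 1L)
    stop_sk("all series members must share the grid shape")
  structure(list(reconstructions = reconstructions,
                 doses = as.numeric(doses),
                 calibration = as.numeric(calibration)),
            class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %d members, doses %s Gy, calibration %g e-/unit\n",
              length(x$reconstructions),
              paste(signif(x$doses, 3), collapse = ", "), x$calibration))
  invisible(x)
}

# clustering outcome container
new_cluster_result <- function(labels, selected, chosen_members,
                               rfactors = NULL, method = "convre") {
  structure(list(labels = as.integer(labels), selected = as.integer(selected),
                 chosen_members = as.integer(chosen_members),
                 rfactors = rfactors, method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> method '%s': %d members in %d clusters\n",
              x$method, length(x$labels), length(unique(x$labels))))
  cat(sprintf("  selected cluster %d with %d members\n",
              x$selected, length(x$chosen_members)))
  invisible(x)
}

#' Parameters of the absorbed-dose calculation
#'
#' Standard absorbed-dose bookkeeping for an X-ray imaging exposure: dose is
#' energy deposited per unit mass, `D = fluence x photon energy x (mu/rho)`,
#' with the mass attenuation coefficient `mu/rho` taken at the working
#' photon energy.
#'
#' @param photon_energy_keV photon energy in keV.
#' @param mass_attenuation_cm2_g mass attenuation coefficient in cm^2/g.
#' @param sample_density_g_cm3 sample mass density in g/cm^3 (recorded for
#'   provenance; the mass-attenuation form of the dose does not use it).
#' @param fluence_per_um2 optional pre-computed photon fluence (photons per
#'   square micrometre); alternatively supply flux and time to
#'   [absorbed_dose()].
#' @return An object of class `"dose_params"`.
#' @export
dose_params <- function(photon_energy_keV, mass_attenuation_cm2_g,
                        sample_density_g_cm3 = 1, fluence_per_um2 = NULL) {
  v <- c(photon_energy_keV, mass_attenuation_cm2_g, sample_density_g_cm3)
  if (anyNA(v) || any(v <= 0))
    stop_sk("all dose parameters must be strictly positive")
  if (!is.null(fluence_per_um2) && fluence_per_um2 <= 0)
    stop_sk("`fluence_per_um2` must be strictly positive")
  structure(list(photon_energy_keV = photon_energy_keV,
                 mass_attenuation_cm2_g = mass_attenuation_cm2_g,
                 sample_density_g_cm3 = sample_density_g_cm3,
                 fluence_per_um2 = fluence_per_um2),
            class = "dose_params")
}
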