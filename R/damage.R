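# Quantification of radiation-induced structural change across a dose
# series of registered reconstructions: electron totals, region density
# trajectories, lateral profiles.

#' Total electron count of a reconstruction
#'
#' Integrates the real-space image over the support and converts to
#' electrons with the calibration constant (electrons per image-intensity
#' unit). Negative pixel values produced by phase retrieval are kept, not
#' clipped, to avoid biasing the total.
#'
#' @param reconstruction a `reconstruction` or bare image matrix.
#' @param support logical mask delimiting the object; defaults to the
#'   reconstruction's own support.
#' @param calibration electrons per image-intensity unit, positive.
#' @return Electron count (scalar).
#' @export
total_electrons <- function(reconstruction, support = NULL, calibration = 1) {
  if (!is_square_number(calibration) || calibration <= 0)
    stop_sk("`calibration` must be a positive scalar")
  img <- if (inherits(reconstruction, "reconstruction"))
    reconstruction$image else reconstruction
  if (is.null(support)) {
    support <- if (inherits(reconstruction, "reconstruction"))
      reconstruction$support else array(TRUE, dim(img))
  }
  calibration * sum(Re(img)[support])
}

#' Fractional electron change along a dose series
#'
#' Per step `t`, `(E_t - E_0) / E_0` where `E_t` is the electron total of
#' member `t` over the common support (member 1's). Step 0 is 0 by
#' construction, and the fractions are invariant to the calibration
#' constant.
#'
#' @param series a [dose_series()], ideally registered
#'   ([register_series()]).
#' @param support common support; defaults to member 1's.
#' @return Numeric vector of fractional changes, one per step.
#' @export
electron_loss_series <- function(series, support = NULL) {
  stopifnot(inherits(series, "dose_series"))
  if (is.null(support)) support <- series$reconstructions[[1L]]$support
  e <- vapply(series$reconstructions,
              function(m) total_electrons(m, support, series$calibration),
              numeric(1))
  if (e[1L] == 0) stop_sk("baseline electron count is zero")
  (e - e[1L]) / e[1L]
}

#' Mean density of a region along a dose series
#'
#' Per step, the mean image value over a fixed pixel rectangle in the
#' common registered frame, times the calibration. Tracking fixed
#' rectangles across doses exposes the opposite responses of high-density
#' regions (monotone loss) and low-density regions (transient gain).
#'
#' @param series a registered [dose_series()].
#' @param region a [region_spec()].
#' @return Numeric vector of mean densities (electrons per pixel), one per
#'   step.
#' @export
region_density_series <- function(series, region) {
  stopifnot(inherits(series, "dose_series"), inherits(region, "region_spec"))
  idx <- region_indices(region, dim(series$reconstructions[[1L]]$image))
  vapply(series$reconstructions, function(m) {
    series$calibration * mean(Re(m$image)[idx$rows, idx$cols])
  }, numeric(1))
}

#' Lateral density profile of a region
#'
#' Column-wise mean of the region (averaging vertically over its rows),
#' i.e. the 1-D lateral electron-density profile. Its mean equals the
#' region's mean density.
#'
#' @param reconstruction a `reconstruction` or image matrix.
#' @param region a [region_spec()].
#' @param calibration electrons per image-intensity unit.
#' @return Numeric vector of length `region$width`.
#' @export
lateral_profile <- function(reconstruction, region, calibration = 1) {
  stopifnot(inherits(region, "region_spec"))
  img <- if (inherits(reconstruction, "reconstruction"))
    reconstruction$image else reconstruction
  idx <- region_indices(region, dim(img))
  calibration * colMeans(Re(img)[idx$rows, idx$cols, drop = FALSE])
}

#' Register a dose series to a common frame
#'
#' Aligns every member to member 1 by the same integer-shift / Friedel-twin
#' registration used for ensembles, so that fixed pixel rectangles refer to
#' the same part of the object at every dose. Idempotent.
#'
#' @param series a [dose_series()].
#' @return The registered [dose_series()].
#' @export
register_series <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  ref <- registration_image(series$reconstructions[[1L]])
  out <- series
  for (i in seq_along(series$reconstructions)[-1L]) {
    out$reconstructions[[i]] <- register_to(series$reconstructions[[i]], ref)
  }
  out
}
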