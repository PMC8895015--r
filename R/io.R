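# File I/O. The interchange container is a multi-page 32-bit float TIFF
# (page 1: intensity normalized to [0, 1]; page 2: validity mask) with a
# JSON sidecar `<path>.json` carrying the intensity scale, frequency
# calibration and instrument metadata. `.rds` is supported for exact
# round-trip serialization of any package object. Coordinate convention in
# all files: row-major, zero frequency at the centre pixel.

SCHEMA_VERSION <- "1.0"

#' Write a diffraction pattern to disk
#'
#' `.tif`/`.tiff` paths write a two-page 32-bit float TIFF (intensity
#' scaled to `[0, 1]`, then the validity mask) plus a JSON sidecar
#' `<path>.json` with the scale factor, frequency calibration and metadata.
#' `.rds` paths serialize the object exactly.
#'
#' @param pattern a [diffraction_pattern()].
#' @param path output file path ending in `.tif`, `.tiff` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(pattern, path)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff"))
    stop_sk("unsupported pattern format '", ext, "' (use tif/tiff or rds)")
  scale <- max(pattern$intensity[pattern$valid], 1e-300)
  intens <- pmin(pmax(pattern$intensity / scale, 0), 1)
  intens[!pattern$valid] <- 0
  tiff::writeTIFF(list(intens, pattern$valid + 0), path,
                  bits.per.sample = 32L, compression = "none")
  sidecar <- list(schema_version = SCHEMA_VERSION,
                  kind = "diffraction_pattern",
                  intensity_scale = scale,
                  freq_per_pixel = pattern$freq_per_pixel,
                  meta = pattern$meta,
                  convention = "row-major, zero frequency at centre pixel")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a diffraction pattern from disk
#'
#' Reads the TIFF + JSON-sidecar layout written by [write_pattern()], or an
#' `.rds` file. A TIFF without sidecar or mask page is accepted with a
#' warning: the scale defaults to 1 and the mask to all-valid.
#'
#' @param path path to a `.tif`/`.tiff` or `.rds` file.
#' @return A [diffraction_pattern()].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop_sk("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (!inherits(obj, "diffraction_pattern"))
      stop_sk("rds file does not contain a diffraction_pattern")
    return(obj)
  }
  if (!ext %in% c("tif", "tiff"))
    stop_sk("unsupported pattern format '", ext, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  intens <- pages[[1L]]
  if (length(dim(intens)) == 3L) intens <- intens[, , 1L]
  valid <- if (length(pages) >= 2L) {
    v <- pages[[2L]]
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    v > 0.5
  } else {
    warning("no mask page found; assuming all pixels valid", call. = FALSE)
    array(TRUE, dim(intens))
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    for (key in c("intensity_scale", "freq_per_pixel")) {
      if (is.null(side[[key]]))
        stop_sk("malformed sidecar: missing field '", key, "' in ",
                sidecar_path)
    }
    scale <- side$intensity_scale
    fpp <- side$freq_per_pixel
    meta <- as.list(side$meta)
  } else {
    warning("no sidecar ", basename(sidecar_path),
            "; assuming unit scale and calibration", call. = FALSE)
    scale <- 1
    fpp <- 1
    meta <- list()
  }
  diffraction_pattern(intens * scale, valid, freq_per_pixel = fpp,
                      meta = meta)
}

#' Export a curve (or curves) as tidy CSV
#'
#' Columns `f_um_inv`, `value`, `kind` -- one row per shell, curves stacked.
#'
#' @param curves a `speckle_curve` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "speckle_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(f_um_inv = cv$f, value = cv$y, kind = attr(cv, "kind"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes `report.json` (schema-versioned; resolutions, cluster membership,
#' CC matrices, electron fractions -- whichever sections are present in
#' `results`), any curves as tidy CSV under `curves.csv`, and optional PNG
#' previews of images. Numeric fields are serialized at full precision, so
#' a read-back reproduces them exactly.
#'
#' @param results named list; elements of class `speckle_curve` (or lists
#'   of them) go to CSV, matrices named in `previews` go to PNG, everything
#'   else goes into the JSON report.
#' @param dir output directory (created if needed).
#' @param previews named list of image matrices to render as PNG.
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(results, dir, previews = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  is_curve <- vapply(results, inherits, logical(1), "speckle_curve")
  curves <- results[is_curve]
  rest <- results[!is_curve]
  rest <- lapply(rest, function(x) if (is.matrix(x)) unclass(x) else x)
  report <- c(list(schema_version = SCHEMA_VERSION), rest)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  if (length(curves) > 0L)
    write_curves(unname(curves), file.path(dir, "curves.csv"))
  for (nm in names(previews)) {
    img <- Re(previews[[nm]])
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1L]) / diff(rng)
    grDevices::png(file.path(dir, paste0(nm, ".png")),
                   width = ncol(img), height = nrow(img))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(img, asp = 1, axes = FALSE, useRaster = TRUE,
                    col = grDevices::gray.colors(256, 0, 1))
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(json_path)
}

#' Read back a JSON report
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_sk("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
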