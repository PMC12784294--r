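#' @title Core spectral data structures
#' @description Lightweight S3 containers shared by every stage of the
#'   pipeline: a wavenumber axis, a single spectrum, a hyperspectral cube,
#'   and the integer compartment label map with its derived cell mask.
#' @name spectra-types
NULL

#' Validate a wavenumber axis
#'
#' A wavenumber axis is a plain numeric vector of band positions in cm^-1,
#' one per spectral channel. It must be finite and strictly increasing.
#'
#' @param values numeric vector of wavenumbers (cm^-1).
#' @return the validated numeric vector, invisibly classed as
#'   `"wavenumber_axis"`.
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("wavenumber axis must contain at least one channel")
  }
  if (any(!is.finite(values))) {
    stop("non-finite wavenumber at channel ",
         which(!is.finite(values))[1L])
  }
  d <- diff(values)
  if (any(d <= 0)) {
    idx <- which(d <= 0)[1L]
    if (values[idx + 1L] == values[idx]) {
      stop("duplicated wavenumber ", values[idx],
           " at channel ", idx + 1L)
    }
    stop("wavenumber axis not strictly increasing at channel ", idx + 1L)
  }
  structure(values, class = "wavenumber_axis")
}

#' Construct a single Raman spectrum
#'
#' @param axis wavenumber axis (cm^-1), strictly increasing.
#' @param intensity intensity values (detector counts, arbitrary units);
#'   negatives are allowed (they arise after background correction).
#' @return an object of class `"raman_spectrum"` with fields `axis` and
#'   `intensity`.
#' @export
raman_spectrum <- function(axis, intensity) {
  axis <- wavenumber_axis(axis)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(axis)) {
    stop("axis (", length(axis), ") and intensity (", length(intensity),
         ") lengths differ")
  }
  if (any(!is.finite(intensity))) {
    stop("non-finite intensity at channel ",
         which(!is.finite(intensity))[1L])
  }
  structure(list(axis = as.numeric(axis), intensity = intensity),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d channels, %.1f-%.1f cm^-1\n",
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' The central object of the pipeline: an image whose every pixel holds a
#' full Raman spectrum. Pixels are indexed `[row, col]`, 1-based, row-major
#' with the origin at the top-left, and share one wavenumber axis.
#'
#' @param intensities numeric array `rows x cols x channels` (counts).
#' @param axis wavenumber axis of length `channels` (cm^-1).
#' @param pixel_size edge length of one pixel in micrometres (default 0.5).
#' @return an object of class `"hyper_cube"`.
#' @export
hyper_cube <- function(intensities, axis, pixel_size = 0.5) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("intensities must be a rows x cols x channels array")
  }
  axis <- wavenumber_axis(axis)
  if (dim(intensities)[3L] != length(axis)) {
    stop("cube has ", dim(intensities)[3L], " channels but axis has ",
         length(axis))
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (micrometres)")
  }
  structure(list(intensities = intensities,
                 axis = as.numeric(axis),
                 pixel_size = pixel_size),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "Hyperspectral cube: %d x %d px (%.2f um/px), %d channels %.1f-%.1f cm^-1\n",
    d[1L], d[2L], x$pixel_size, d[3L], min(x$axis), max(x$axis)))
  invisible(x)
}

#' Dimensions of a hyperspectral cube
#' @param cube a `"hyper_cube"`.
#' @return integer vector `c(rows, cols, channels)`.
#' @export
cube_dim <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  dim(cube$intensities)
}

#' Flatten a cube to a pixels-by-channels matrix
#'
#' Row-major flattening: pixel index `p` corresponds to
#' `row = (p - 1) %/% cols + 1`, `col = (p - 1) %% cols + 1`.
#'
#' @param cube a `"hyper_cube"`.
#' @return numeric matrix `(rows*cols) x channels`.
#' @keywords internal
cube_matrix <- function(cube) {
  d <- dim(cube$intensities)
  # aperm so that pixels enumerate row-major (col fastest within a row)
  m <- matrix(aperm(cube$intensities, c(2L, 1L, 3L)),
              nrow = d[1L] * d[2L], ncol = d[3L])
  m
}

#' Rebuild a cube from a pixels-by-channels matrix
#' @keywords internal
matrix_cube <- function(m, rows, cols, axis, pixel_size = 0.5) {
  arr <- aperm(array(m, dim = c(cols, rows, ncol(m))), c(2L, 1L, 3L))
  hyper_cube(arr, axis, pixel_size)
}

#' Extract one pixel's spectrum from a cube
#' @param cube a `"hyper_cube"`.
#' @param row,col 1-based pixel coordinates (origin top-left).
#' @return a `"raman_spectrum"`.
#' @export
cube_spectrum <- function(cube, row, col) {
  raman_spectrum(cube$axis, cube$intensities[row, col, ])
}

#' Mean spectrum over a pixel subset
#'
#' @param cube a `"hyper_cube"`.
#' @param mask logical matrix `rows x cols` selecting the pixels to average
#'   (e.g. the lipid-droplet class of a segmentation).
#' @return a `"raman_spectrum"` averaging the selected pixels.
#' @export
mean_spectrum <- function(cube, mask) {
  d <- dim(cube$intensities)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("mask must be a logical rows x cols matrix matching the cube")
  }
  if (!any(mask)) stop("mask selects no pixels")
  m <- matrix(cube$intensities, nrow = d[1L] * d[2L], ncol = d[3L])
  raman_spectrum(cube$axis, colMeans(m[as.vector(mask), , drop = FALSE]))
}

# Compartment label codes shared across the package.
CLASS_CODES <- c(background = 1L, matrix = 2L, nucleus = 3L, droplet = 4L)

#' Construct a compartment class map
#'
#' Integer labels per pixel: 1 background, 2 cellular matrix, 3 nucleus,
#' 4 lipid droplet.
#'
#' @param labels integer matrix `rows x cols` with values in `{1,2,3,4}`.
#' @return an integer matrix of class `"class_map"`.
#' @export
class_map <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% 1:4)
  if (any(bad)) {
    stop("class map contains label(s) outside {1,2,3,4}: ",
         paste(unique(labels[bad]), collapse = ", "))
  }
  structure(labels, class = c("class_map", "matrix", "array"))
}

#' Construct a cell mask
#' @param mask logical matrix `rows x cols`; TRUE marks cellular pixels.
#' @return a logical matrix of class `"cell_mask"`.
#' @export
cell_mask_matrix <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  structure(mask, class = c("cell_mask", "matrix", "array"))
}
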