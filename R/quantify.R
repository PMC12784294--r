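#' @title Band-area quantitation and nuclear-reference normalization
#' @description Chord-corrected trapezoidal band areas per pixel, the
#'   per-cell normalization of the tag signal to the mean nuclear DNA band
#'   area near 789 cm^-1, the arsinh display transform, and per-compartment
#'   value summaries.
#' @name quantify
NULL

#' Define an integration window
#'
#' @param center band center (cm^-1).
#' @param half_width half-width of the window (cm^-1, default 15).
#' @return a list of class `"band_window"`.
#' @export
band_window <- function(center, half_width = 15) {
  if (half_width <= 0) stop("half_width must be > 0")
  structure(list(center = center, half_width = half_width),
            class = "band_window")
}

window_channels <- function(axis, window) {
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  if (lo < min(axis) || hi > max(axis)) {
    stop("window ", window$center, " +/- ", window$half_width,
         " cm^-1 outside axis range ", min(axis), "-", max(axis))
  }
  # bounds snap to the nearest on-grid channels
  i0 <- which.min(abs(axis - lo))
  i1 <- which.min(abs(axis - hi))
  if (i1 - i0 + 1L < 3L) {
    stop("window ", window$center, " +/- ", window$half_width,
         " cm^-1 covers fewer than 3 channels")
  }
  i0:i1
}

band_area_matrix <- function(m, axis, window) {
  ch <- window_channels(axis, window)
  x <- axis[ch]
  y <- m[, ch, drop = FALSE]
  n <- length(ch)
  # chord between the spectrum values at the snapped window bounds
  frac <- (x - x[1L]) / (x[n] - x[1L])
  chord <- y[, 1L] %o% (1 - frac) + y[, n] %o% frac
  r <- y - chord
  # trapezoidal weights for a possibly non-uniform grid
  dx <- diff(x)
  w <- c(dx / 2, 0) + c(0, dx / 2)
  drop(r %*% w)
}

#' Background-corrected band area of a spectrum
#'
#' Trapezoidal integral, over the window, of the spectrum minus the chord
#' (the straight line joining the spectrum values at the two window
#' bounds). The chord subtraction removes any locally linear background --
#' in particular the broad water combination band under the silent region --
#' so the area is zero for affine spectra and may be negative when only
#' noise is present.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param window a `"band_window"` inside the axis range.
#' @return the band area (counts * cm^-1).
#' @export
band_area <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(window, "band_window"))
  band_area_matrix(matrix(spectrum$intensity, nrow = 1),
                   spectrum$axis, window)
}

#' Per-pixel band-area map of a cube
#'
#' @param cube a `"hyper_cube"`.
#' @param window a `"band_window"`.
#' @return an object of class `"area_map"`: a numeric `rows x cols` matrix
#'   with attributes `window`, `normalized` (FALSE) and `reference_value`
#'   (NA until [normalize_map()] is applied).
#' @export
area_map <- function(cube, window) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$intensities)
  a <- band_area_matrix(cube_matrix(cube), cube$axis, window)
  vals <- matrix(a, d[1L], d[2L], byrow = TRUE)
  structure(vals, window = window, normalized = FALSE,
            reference_value = NA_real_,
            class = c("area_map", "matrix", "array"))
}

#' Mean nuclear DNA reference area
#'
#' The mean of the 789 +/- 15 cm^-1 band area over the pixels labeled
#' nucleus (class 3), used to normalize tag band areas per cell so that
#' results are comparable between cells and measurement sessions.
#'
#' @param area_map_789 an `"area_map"` computed with the DNA window.
#' @param class_map integer compartment labels (`"class_map"` or plain
#'   matrix).
#' @return the reference value (counts * cm^-1), strictly positive.
#' @export
nuclear_reference <- function(area_map_789, class_map) {
  nuc <- unclass(class_map) == CLASS_CODES[["nucleus"]]
  if (!any(nuc)) stop("class map contains no nucleus pixels (label 3)")
  ref <- mean(unclass(area_map_789)[nuc])
  if (!is.finite(ref) || ref <= 0) {
    stop("nuclear reference area is not positive (", format(ref),
         "); the DNA band is unusable as normalization reference")
  }
  ref
}

#' Normalize an area map by the nuclear reference
#'
#' Divides every pixel by `reference`; negative areas keep their sign.
#'
#' @param map an `"area_map"`.
#' @param reference positive reference value (see [nuclear_reference()]).
#' @return the normalized `"area_map"` with `normalized = TRUE` and the
#'   reference recorded in `reference_value`.
#' @export
normalize_map <- function(map, reference) {
  stopifnot(inherits(map, "area_map"))
  if (!is.finite(reference) || reference <= 0) {
    stop("normalization reference must be > 0, got ", format(reference))
  }
  structure(unclass(map) / reference,
            window = attr(map, "window"), normalized = TRUE,
            reference_value = reference,
            class = class(map))
}

#' Inverse hyperbolic sine display transform
#'
#' `arsinh(x) = log(x + sqrt(x^2 + 1))`: compresses a wide dynamic range
#' like a logarithm but remains defined (and odd) for the negative band
#' ratios that pure-noise pixels produce.
#'
#' @param values numeric vector, matrix or `"area_map"`.
#' @return transformed values of the same shape.
#' @export
arsinh_transform <- function(values) {
  if (any(!is.finite(values))) stop("arsinh_transform requires finite input")
  asinh(values)
}

#' Per-compartment distributions of a normalized map
#'
#' Partitions the pixels of `map` by compartment class within the cell
#' mask and returns the raw values plus per-class summaries.
#'
#' @param map an `"area_map"` (normalized or not) or numeric matrix.
#' @param class_map integer compartment labels.
#' @param cell_mask logical cell mask (default: everything except
#'   background label 1).
#' @return list with `values` (named list of numeric vectors per class:
#'   `matrix`, `nucleus`, `droplet`) and `summary` (data frame with class,
#'   n, mean, sd, se). Empty classes yield empty vectors, not errors.
#' @export
compartment_distributions <- function(map, class_map,
                                      cell_mask = NULL) {
  vals <- unclass(map)
  cm <- unclass(class_map)
  if (!all(dim(vals) == dim(cm))) stop("map and class map shapes differ")
  if (is.null(cell_mask)) {
    cell_mask <- cm != CLASS_CODES[["background"]]
  }
  if (!all(dim(cell_mask) == dim(cm))) {
    stop("cell mask shape differs from class map")
  }
  classes <- c("matrix", "nucleus", "droplet")
  values <- lapply(classes, function(nm) {
    vals[cell_mask & cm == CLASS_CODES[[nm]]]
  })
  names(values) <- classes
  summ <- data.frame(
    class = classes,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(values, function(v) if (length(v) > 1) stats::sd(v)
                else NA_real_, numeric(1)))
  summ$se <- summ$sd / sqrt(summ$n)
  rownames(summ) <- NULL
  list(values = values, summary = summ)
}
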