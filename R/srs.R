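#' @title Stimulated Raman scattering stack corrections
#' @description Per-frame laser-power compensation (stimulated Raman loss
#'   is bilinear in pump and Stokes power), off-resonance background
#'   subtraction, min-max normalization of silent-region spectra, and
#'   z-projection of volumetric scans.
#' @name srs
NULL

#' Construct an SRS image stack
#'
#' @param frames numeric array `rows x cols x n_frames`.
#' @param meta data frame with one row per frame: `wavenumber` (cm^-1),
#'   `pump` and `stokes` powers (any consistent unit, > 0), optional `z`
#'   plane index.
#' @return a list of class `"srs_stack"`.
#' @export
srs_stack <- function(frames, meta) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a rows x cols x n array")
  }
  need <- c("wavenumber", "pump", "stokes")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(meta) != dim(frames)[3L]) {
    stop("metadata rows (", nrow(meta), ") != frames (", dim(frames)[3L], ")")
  }
  if (any(meta$pump <= 0) || any(meta$stokes <= 0)) {
    stop("pump and Stokes powers must be positive")
  }
  structure(list(frames = frames, meta = meta), class = "srs_stack")
}

#' Compensate per-frame laser-power fluctuations
#'
#' Multiplies each frame by
#' `(P_pump,ref * P_stokes,ref) / (P_pump * P_stokes)`, with the first
#' frame as reference. With `model = "pump"` only the pump power enters.
#'
#' @param stack an `"srs_stack"`.
#' @param model `"bilinear"` (default) or `"pump"`.
#' @return the corrected `"srs_stack"`; the applied factors are stored in
#'   the metadata column `power_factor`.
#' @export
power_correct <- function(stack, model = c("bilinear", "pump")) {
  stopifnot(inherits(stack, "srs_stack"))
  model <- match.arg(model)
  m <- stack$meta
  f <- if (model == "bilinear") {
    (m$pump[1L] * m$stokes[1L]) / (m$pump * m$stokes)
  } else {
    m$pump[1L] / m$pump
  }
  frames <- stack$frames
  for (i in seq_along(f)) frames[, , i] <- frames[, , i] * f[i]
  m$power_factor <- f
  srs_stack(frames, m)
}

#' Subtract an off-resonance frame
#'
#' Pixelwise difference removing non-Raman background (the off-resonance
#' frame is typically recorded at 2500 cm^-1, where no band exists);
#' negative results are preserved.
#'
#' @param frame,off_frame numeric matrices of equal shape.
#' @return the background-subtracted matrix.
#' @export
off_resonance_subtract <- function(frame, off_frame) {
  if (!all(dim(frame) == dim(off_frame))) {
    stop("frame and off-resonance frame shapes differ")
  }
  frame - off_frame
}

#' Min-max normalize a spectrum over the silent-region window
#'
#' Computes the affine map sending the minimum of the 2050-2300 cm^-1
#' window to 0 and its maximum to 1, and applies it to the whole spectrum.
#' Idempotent.
#'
#' @param spectrum a `"raman_spectrum"` whose axis covers the window.
#' @param lo,hi window bounds (cm^-1).
#' @return the normalized `"raman_spectrum"`.
#' @export
normalize_silent <- function(spectrum, lo = 2050, hi = 2300) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  ch <- which(spectrum$axis >= lo & spectrum$axis <= hi)
  if (length(ch) < 2L) {
    stop("axis must cover ", lo, "-", hi, " cm^-1 with >= 2 samples")
  }
  w <- spectrum$intensity[ch]
  rng <- range(w)
  if (rng[2L] == rng[1L]) {
    stop("spectrum is constant within ", lo, "-", hi,
         " cm^-1; normalization range is zero")
  }
  raman_spectrum(spectrum$axis,
                 (spectrum$intensity - rng[1L]) / (rng[2L] - rng[1L]))
}

#' Retrieve the SRS spectrum of a pixel region
#'
#' Mean intensity of each frame over `mask`, against the frames'
#' wavenumbers -- a lambda-scan spectrum.
#'
#' @param stack an `"srs_stack"` ordered by increasing wavenumber.
#' @param mask logical matrix selecting the region.
#' @return a `"raman_spectrum"`.
#' @export
srs_spectrum <- function(stack, mask) {
  stopifnot(inherits(stack, "srs_stack"))
  d <- dim(stack$frames)
  if (!all(dim(mask) == d[1:2])) stop("mask shape differs from frames")
  vals <- vapply(seq_len(d[3L]),
                 function(i) mean(stack$frames[, , i][mask]), numeric(1))
  ord <- order(stack$meta$wavenumber)
  raman_spectrum(stack$meta$wavenumber[ord], vals[ord])
}

#' Project a volumetric stack along z
#'
#' @param stack an `"srs_stack"` with a `z` metadata column (all frames
#'   are treated as one plane if absent).
#' @param type `"max"` (default) or `"mean"`.
#' @return a single projected frame (numeric matrix).
#' @export
z_project <- function(stack, type = c("max", "mean")) {
  stopifnot(inherits(stack, "srs_stack"))
  type <- match.arg(type)
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1L] * d[2L], ncol = d[3L])
  v <- if (type == "max") apply(m, 1L, max) else rowMeans(m)
  matrix(v, d[1L], d[2L])
}
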