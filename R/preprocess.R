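#' @title Spectral pre-processing chain
#' @description Despiking by modified z-scores of the first-difference
#'   series, sectioned SNIP background estimation with cross-faded merging,
#'   wavenumber-axis calibration against a reference compound, and linear
#'   resampling onto a uniform grid. All stages operate per spectrum and are
#'   vectorized over the pixels of a cube.
#' @name preprocess
NULL

# ---- despiking ------------------------------------------------------------

#' Modified z-scores of the first-difference series
#'
#' `z_i = 0.6745 (d_i - median(d)) / MAD(d)` with `d_i = x_i - x_{i-1}`
#' and MAD the raw (unscaled) median absolute deviation. Channel 1 owns no
#' difference and always scores 0. When `MAD = 0` (majority-constant data)
#' the convention is `0/0 = 0` and `x/0 = Inf`: a constant spectrum scores
#' 0 everywhere, while an isolated spike on a constant floor scores
#' infinite and is always flagged.
#'
#' @param intensity numeric vector (>= 3 channels).
#' @return numeric vector of |z| per channel (same length as input).
#' @export
despike_scores <- function(intensity) {
  drop(despike_scores_matrix(matrix(intensity, nrow = 1)))
}

despike_scores_matrix <- function(m) {
  n <- ncol(m)
  if (n < 3L) stop("despiking needs at least 3 channels")
  d <- m[, -1L, drop = FALSE] - m[, -n, drop = FALSE]
  med <- apply(d, 1L, stats::median)
  madr <- apply(abs(d - med), 1L, stats::median)
  z <- 0.6745 * (d - med) / madr  # MAD = 0: +/-Inf where d != median
  z[is.nan(z)] <- 0               # 0/0: constant data, nothing flagged
  cbind(0, abs(z))
}

replace_flagged <- function(x, flagged, window = 3L) {
  n <- length(x)
  out <- x
  for (i in which(flagged)) {
    w <- window
    repeat {
      nb <- setdiff(max(1L, i - w):min(n, i + w), which(flagged))
      if (length(nb) > 0L || w >= n) break
      w <- w + window  # widen until an unflagged neighbor exists
    }
    if (length(nb) > 0L) out[i] <- mean(x[nb])
  }
  out
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Flags channels whose first-difference modified z-score exceeds
#' `threshold` (default 37) and replaces each flagged channel by the mean of
#' the unflagged channels within a +/- `window` channel neighborhood
#' (widened if every neighbor is flagged). Unflagged channels pass through
#' unchanged, so the operation is idempotent.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param threshold modified z-score cutoff (default 37).
#' @param window half-width, in channels, of the replacement neighborhood.
#' @return list with the despiked `spectrum` and `flagged`, the integer
#'   indices of replaced channels.
#' @export
despike <- function(spectrum, threshold = 37, window = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  z <- despike_scores(spectrum$intensity)
  flagged <- z > threshold
  out <- replace_flagged(spectrum$intensity, flagged, window)
  list(spectrum = raman_spectrum(spectrum$axis, out),
       flagged = which(flagged))
}

# ---- SNIP background ------------------------------------------------------

#' Define a SNIP section
#'
#' @param lo,hi wavenumber bounds (cm^-1), `lo < hi`.
#' @param iterations number of clipping passes (the window grows from 1 to
#'   `iterations` samples).
#' @return a list of class `"snip_section"`.
#' @export
snip_section <- function(lo, hi, iterations) {
  if (lo >= hi) stop("snip section requires lo < hi")
  if (iterations < 1) stop("snip section requires iterations >= 1")
  structure(list(lo = lo, hi = hi, iterations = as.integer(iterations)),
            class = "snip_section")
}

#' The default sectioned-SNIP scheme
#'
#' Three sections: 2600-3150 cm^-1 with 100 iterations, 1800-2800 cm^-1
#' with 7 iterations (gentle, so the narrow silent-region tag bands
#' survive while the broad water combination band is removed with the
#' baseline), 550-1900 cm^-1 with 100 iterations. Neighboring sections
#' overlap; corrections are cross-faded across the overlaps.
#'
#' @return list of `"snip_section"` objects, ascending in `lo`.
#' @export
default_snip_sections <- function() {
  list(snip_section(550, 1900, 100),
       snip_section(1800, 2800, 7),
       snip_section(2600, 3150, 100))
}

snip_clip_matrix <- function(m, iterations) {
  n <- ncol(m)
  idx <- seq_len(n)
  for (p in seq_len(iterations)) {
    il <- pmax(idx - p, 1L)
    ir <- pmin(idx + p, n)
    m <- pmin(m, (m[, il, drop = FALSE] + m[, ir, drop = FALSE]) / 2)
  }
  m
}

#' SNIP baseline on one section
#'
#' Plain SNIP (no log-log-sqrt transform): iterative clipping
#' `y_i <- min(y_i, (y_{i-p} + y_{i+p}) / 2)` with the half-window `p`
#' increasing from 1 to `iterations` samples and edge indices clamped.
#' The estimate never exceeds the input at any channel.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param section a `"snip_section"` whose bounds lie within the axis.
#' @return list with `channels` (indices of the section within the axis)
#'   and `baseline` (the SNIP estimate on those channels).
#' @export
snip_baseline <- function(spectrum, section) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(section, "snip_section"))
  ch <- which(spectrum$axis >= section$lo & spectrum$axis <= section$hi)
  if (length(ch) == 0L) {
    stop("snip section ", section$lo, "-", section$hi,
         " cm^-1 lies outside the axis")
  }
  if (length(ch) <= 2L * section$iterations) {
    stop("snip section ", section$lo, "-", section$hi, " holds ",
         length(ch), " samples but needs more than ",
         2L * section$iterations, " for ", section$iterations,
         " iterations")
  }
  bl <- snip_clip_matrix(matrix(spectrum$intensity[ch], nrow = 1),
                         section$iterations)
  list(channels = ch, baseline = drop(bl))
}

sectioned_correct_matrix <- function(m, axis, sections) {
  n <- ncol(m)
  num <- matrix(0, nrow(m), n)
  wsum <- numeric(n)
  covered <- integer(n)
  single <- matrix(NA_real_, nrow(m), n)
  for (s in sections) {
    ch <- which(axis >= s$lo & axis <= s$hi)
    if (length(ch) == 0L) {
      stop("snip section ", s$lo, "-", s$hi, " cm^-1 lies outside the axis")
    }
    if (length(ch) <= 2L * s$iterations) {
      stop("snip section ", s$lo, "-", s$hi, " holds ", length(ch),
           " samples but needs more than ", 2L * s$iterations)
    }
    corr <- m[, ch, drop = FALSE] -
      snip_clip_matrix(m[, ch, drop = FALSE], s$iterations)
    # trapezoidal weight: distance to the nearer section edge, so that two
    # overlapping sections cross-fade linearly across their overlap
    w <- pmin(axis[ch] - s$lo, s$hi - axis[ch])
    num[, ch] <- num[, ch] + sweep(corr, 2L, w, `*`)
    wsum[ch] <- wsum[ch] + w
    covered[ch] <- covered[ch] + 1L
    single[, ch] <- corr
  }
  out <- m  # uncovered channels pass through unchanged
  multi <- covered > 0L & wsum > 0
  out[, multi] <- sweep(num[, multi, drop = FALSE], 2L, wsum[multi], `/`)
  lone <- covered == 1L
  out[, lone] <- single[, lone, drop = FALSE]
  zerow <- covered > 1L & wsum == 0
  if (any(zerow)) out[, zerow] <- single[, zerow, drop = FALSE]
  out
}

#' Sectioned SNIP background correction
#'
#' Subtracts the per-section SNIP baseline and merges the sections into one
#' corrected spectrum. Inside an overlap of two sections the corrections
#' are cross-faded linearly; channels outside every section pass through
#' unchanged.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param sections list of `"snip_section"`, default
#'   [default_snip_sections()].
#' @return the corrected `"raman_spectrum"`.
#' @export
sectioned_correct <- function(spectrum, sections = default_snip_sections()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  m <- sectioned_correct_matrix(matrix(spectrum$intensity, nrow = 1),
                                spectrum$axis, sections)
  raman_spectrum(spectrum$axis, drop(m))
}

# ---- calibration and resampling ------------------------------------------

#' Build a wavenumber calibration table
#'
#' Pairs of known reference band positions and their measured positions for
#' a calibration compound. The packaged default table for 4-acetaminophen
#' (paracetamol) band positions from the ASTM E1840 Raman-shift standard is
#' available via [acetaminophen_reference()].
#'
#' @param reference known band positions (cm^-1), strictly increasing.
#' @param measured measured positions of the same bands (cm^-1).
#' @return a `data.frame` of class `"calibration_table"`.
#' @export
calibration_table <- function(reference, measured) {
  if (length(reference) < 1L) stop("calibration needs at least one pair")
  if (length(reference) != length(measured)) {
    stop("reference and measured lengths differ")
  }
  if (any(diff(reference) <= 0)) {
    stop("reference positions must be strictly increasing")
  }
  structure(data.frame(reference = reference, measured = measured),
            class = c("calibration_table", "data.frame"))
}

#' ASTM E1840 4-acetaminophen reference band positions
#'
#' Editable reference data shipped with the package
#' (`extdata/acetaminophen_astm_e1840.tsv`): the Raman shift standard's
#' band positions for 4-acetaminophen (paracetamol).
#'
#' @return numeric vector of reference band positions (cm^-1).
#' @export
acetaminophen_reference <- function() {
  path <- system.file("extdata", "acetaminophen_astm_e1840.tsv",
                      package = "ramantag")
  tab <- utils::read.delim(path)
  tab$wavenumber
}

#' Calibrate a wavenumber axis
#'
#' Applies one global shift equal to the mean of
#' `reference - measured` over all calibration pairs.
#'
#' @param axis wavenumber axis (cm^-1).
#' @param table a `"calibration_table"`.
#' @return list with the shifted `axis` and the applied `shift` (cm^-1).
#' @export
calibrate <- function(axis, table) {
  stopifnot(inherits(table, "calibration_table"))
  shift <- mean(table$reference - table$measured)
  list(axis = as.numeric(axis) + shift, shift = shift)
}

interp_weights <- function(x, xout) {
  if (min(xout) < min(x) || max(xout) > max(x)) {
    stop("target grid ", min(xout), "-", max(xout),
         " cm^-1 extends beyond the input axis (",
         min(x), "-", max(x), "); no extrapolation")
  }
  j <- findInterval(xout, x, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(x) - 1L)
  w <- (xout - x[j]) / (x[j + 1L] - x[j])
  list(j = j, w = w)
}

interp_matrix <- function(m, x, xout) {
  iw <- interp_weights(x, xout)
  m[, iw$j, drop = FALSE] * rep(1 - iw$w, each = nrow(m)) +
    m[, iw$j + 1L, drop = FALSE] * rep(iw$w, each = nrow(m))
}

#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `seq(start, stop, by = step)`; the input axis
#' must cover the full target range (no extrapolation). The default grid,
#' 600-3050 cm^-1 in 2 cm^-1 steps, has 1226 channels.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param start,stop,step target grid parameters (cm^-1).
#' @return the resampled `"raman_spectrum"`.
#' @export
resample <- function(spectrum, start = 600, stop = 3050, step = 2) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  grid <- seq(start, stop, by = step)
  m <- interp_matrix(matrix(spectrum$intensity, nrow = 1),
                     spectrum$axis, grid)
  raman_spectrum(grid, drop(m))
}

# ---- whole-cube chain -----------------------------------------------------

#' Pre-processing configuration
#'
#' @param spike_threshold modified z-score cutoff for despiking.
#' @param spike_window replacement neighborhood half-width (channels).
#' @param sections sectioned-SNIP scheme.
#' @param calibration a `"calibration_table"` or `NULL` to skip the axis
#'   shift.
#' @param start,stop,step target resampling grid (cm^-1).
#' @return a list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(spike_threshold = 37, spike_window = 3L,
                              sections = default_snip_sections(),
                              calibration = NULL,
                              start = 600, stop = 3050, step = 2) {
  structure(list(spike_threshold = spike_threshold,
                 spike_window = spike_window, sections = sections,
                 calibration = calibration,
                 start = start, stop = stop, step = step),
            class = "preprocess_config")
}

#' Pre-process a hyperspectral cube
#'
#' Applies, per pixel and in this order: despiking, sectioned SNIP
#' background correction, wavenumber calibration, and resampling onto the
#' uniform target grid.
#'
#' @param cube a `"hyper_cube"`.
#' @param config a `"preprocess_config"`.
#' @return list with the processed `cube` and `log`, containing `flagged`
#'   (data frame of despiked `row`, `col`, `channel`), `n_flagged`, and the
#'   calibration `shift` (cm^-1, 0 when no table was given).
#' @export
preprocess_cube <- function(cube, config = preprocess_config()) {
  stopifnot(inherits(cube, "hyper_cube"),
            inherits(config, "preprocess_config"))
  d <- dim(cube$intensities)
  m <- cube_matrix(cube)

  z <- despike_scores_matrix(m)
  fl <- z > config$spike_threshold
  hit <- which(rowSums(fl) > 0L)
  for (p in hit) {
    m[p, ] <- replace_flagged(m[p, ], fl[p, ], config$spike_window)
  }
  idx <- which(fl, arr.ind = TRUE)
  flagged <- data.frame(
    row = (idx[, 1L] - 1L) %/% d[2L] + 1L,
    col = (idx[, 1L] - 1L) %% d[2L] + 1L,
    channel = idx[, 2L])
  flagged <- flagged[order(flagged$row, flagged$col, flagged$channel), ,
                     drop = FALSE]
  rownames(flagged) <- NULL

  m <- sectioned_correct_matrix(m, cube$axis, config$sections)

  axis <- cube$axis
  shift <- 0
  if (!is.null(config$calibration)) {
    cal <- calibrate(axis, config$calibration)
    axis <- cal$axis
    shift <- cal$shift
  }

  grid <- seq(config$start, config$stop, by = config$step)
  m <- interp_matrix(m, axis, grid)

  out <- matrix_cube(m, d[1L], d[2L], grid, cube$pixel_size)
  list(cube = out,
       log = list(flagged = flagged, n_flagged = nrow(flagged),
                  shift = shift))
}
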