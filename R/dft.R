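#' @title Raman activity to intensity conversion and broadening
#' @description Converts quantum-chemistry Raman activities (A^4 amu^-1)
#'   into relative Raman intensities using the fourth-power scattering
#'   factor with the Boltzmann occupation bracket, after empirical
#'   frequency scaling, and broadens the stick spectrum with Lorentzian
#'   profiles onto a wavenumber axis for comparison with measured spectra.
#' @name dft-convert
NULL

# 2018 CODATA values
PLANCK_H <- 6.62607015e-34      # J s
SPEED_C <- 2.99792458e10        # cm / s
BOLTZMANN_K <- 1.380649e-23     # J / K

#' Convert a laser wavelength to its wavenumber
#' @param lambda_nm wavelength in nm.
#' @return wavenumber in cm^-1 (`1e7 / lambda_nm`).
#' @export
wavelength_to_wavenumber <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  1e7 / lambda_nm
}

#' Convert Celsius to Kelvin
#' @param celsius temperature in degrees Celsius.
#' @return temperature in K.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Spectral resolution in wavenumbers
#'
#' Converts a wavelength resolution `delta_lambda` at spectral center
#' `lambda` into the corresponding wavenumber interval via
#' `d(nu) = d(lambda) / lambda^2`.
#'
#' @param delta_lambda_nm wavelength resolution (nm).
#' @param lambda_nm spectral center (nm).
#' @return resolution in cm^-1.
#' @export
spectral_resolution_cm1 <- function(delta_lambda_nm, lambda_nm) {
  1e7 * delta_lambda_nm / lambda_nm^2
}

#' Conversion settings for activity-to-intensity
#'
#' @param excitation_cm1 excitation wavenumber (default 19455.3 cm^-1, a
#'   514 nm laser).
#' @param temperature_K temperature (default 298.15 K, i.e. 25 degrees C).
#' @param scale_factor empirical frequency scale factor applied to the
#'   computed mode frequencies (default 0.9626).
#' @param fwhm Lorentzian broadening FWHM (default 15 cm^-1).
#' @param prefactor `"shifted"` (default) uses the standard
#'   `(nu0 - nu_j)^4` scattered-wavenumber factor; `"incident"` uses
#'   `nu0^4` for the alternative convention.
#' @return a list of class `"conversion_spec"`.
#' @export
conversion_spec <- function(excitation_cm1 = 19455.3,
                            temperature_K = 298.15,
                            scale_factor = 0.9626,
                            fwhm = 15,
                            prefactor = c("shifted", "incident")) {
  prefactor <- match.arg(prefactor)
  if (temperature_K <= 0) stop("temperature must be > 0 K")
  if (scale_factor <= 0 || scale_factor > 1.2) {
    stop("frequency scale factor must be in (0, 1.2]")
  }
  if (fwhm <= 0) stop("broadening FWHM must be > 0")
  structure(list(excitation_cm1 = excitation_cm1,
                 temperature_K = temperature_K,
                 scale_factor = scale_factor, fwhm = fwhm,
                 prefactor = prefactor,
                 h = PLANCK_H, c = SPEED_C, kB = BOLTZMANN_K),
            class = "conversion_spec")
}

#' Scale mode frequencies
#'
#' Multiplies every mode frequency by `factor` (harmonic frequencies from
#' electronic-structure calculations systematically overestimate measured
#' positions); activities are untouched and ordering is preserved.
#'
#' @param table a `"raman_mode_table"`.
#' @param factor positive scale factor.
#' @return the scaled `"raman_mode_table"`.
#' @export
scale_frequencies <- function(table, factor) {
  stopifnot(inherits(table, "raman_mode_table"))
  if (factor <= 0) stop("scale factor must be positive")
  raman_mode_table(table$frequency * factor, table$activity,
                   intensity = table$intensity)
}

#' Convert Raman activities to relative intensities
#'
#' For each mode j with (scaled) frequency `nu_j` and activity `S_j`:
#' \deqn{I_j \propto \frac{(\nu_0 - \nu_j)^4 \, S_j}
#'   {\nu_j \, [1 - \exp(-h c \nu_j / (k_B T))]}}
#' normalized so that the largest intensity is 1. Apply after
#' [scale_frequencies()].
#'
#' @param table a `"raman_mode_table"`.
#' @param spec a `"conversion_spec"`.
#' @return the table with an `intensity` column (max 1).
#' @export
activity_to_intensity <- function(table, spec = conversion_spec()) {
  stopifnot(inherits(table, "raman_mode_table"),
            inherits(spec, "conversion_spec"))
  nu <- table$frequency
  if (any(nu >= spec$excitation_cm1)) {
    stop("mode frequency ", max(nu), " cm^-1 is not below the excitation ",
         "wavenumber ", spec$excitation_cm1, " cm^-1")
  }
  bracket <- 1 - exp(-spec$h * spec$c * nu / (spec$kB * spec$temperature_K))
  pre <- if (spec$prefactor == "shifted") {
    (spec$excitation_cm1 - nu)^4
  } else {
    spec$excitation_cm1^4
  }
  intensity <- pre * table$activity / (nu * bracket)
  if (max(intensity) > 0) intensity <- intensity / max(intensity)
  raman_mode_table(table$frequency, table$activity, intensity = intensity)
}

#' Broaden a mode table into a spectrum
#'
#' Sums one Lorentzian per mode -- unit peak height scaled by the mode's
#' intensity (so the FWHM sets the width and the intensity the height), or
#' unit area when `height_convention = "area"` -- and rescales the result
#' to maximum 1 over the axis.
#'
#' @param table a `"raman_mode_table"` with intensities (see
#'   [activity_to_intensity()]); if absent, activities are used as heights.
#' @param spec a `"conversion_spec"` (provides the FWHM).
#' @param axis output wavenumber axis (default 600-3050 cm^-1, 2 cm^-1
#'   steps).
#' @param height_convention `"peak"` (default) or `"area"`.
#' @return a `"raman_spectrum"` with maximum 1.
#' @export
broaden <- function(table, spec = conversion_spec(),
                    axis = seq(600, 3050, by = 2),
                    height_convention = c("peak", "area")) {
  stopifnot(inherits(table, "raman_mode_table"),
            inherits(spec, "conversion_spec"))
  height_convention <- match.arg(height_convention)
  weights <- if (!is.null(table$intensity)) table$intensity
             else table$activity
  y <- numeric(length(axis))
  for (j in seq_len(nrow(table))) {
    lj <- lorentzian(axis, table$frequency[j], spec$fwhm)
    if (height_convention == "area") {
      lj <- lj * 2 / (pi * spec$fwhm)
    }
    y <- y + weights[j] * lj
  }
  if (max(y) > 0) y <- y / max(y)
  raman_spectrum(axis, y)
}

#' Full activity-to-spectrum pipeline
#'
#' Frequency scaling, activity-to-intensity conversion, and Lorentzian
#' broadening in one call.
#'
#' @inheritParams broaden
#' @return a `"raman_spectrum"` with maximum 1.
#' @export
dft_spectrum <- function(table, spec = conversion_spec(),
                         axis = seq(600, 3050, by = 2)) {
  table <- scale_frequencies(table, spec$scale_factor)
  table <- activity_to_intensity(table, spec)
  broaden(table, spec, axis)
}
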