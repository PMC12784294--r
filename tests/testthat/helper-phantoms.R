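# Small, fast phantom specs used across the suite. The geometry scales
# with the grid; 32 x 32 keeps preprocessing of a full cube around a few
# seconds while retaining all four compartments.

small_spec <- function(rows = 32, cols = 32, seed = 1, ...) {
  phantom_spec(rows = rows, cols = cols, droplet_count = 4,
               droplet_radius_px = 2, seed = seed, ...)
}

# a spec whose cube is exactly its baseline polynomial: every amplitude off
silent_spec <- function(baseline_poly = c(5, 2), noise_sd = 0,
                        drug_loading = c(background = 0, matrix = 0,
                                         nucleus = 0, droplet = 0),
                        odya_loading = c(background = 0, matrix = 0,
                                         nucleus = 0, droplet = 0),
                        ...) {
  dict <- default_band_dictionary()
  dict <- lapply(dict, function(b) { b$amplitude <- 0 * b$amplitude; b })
  small_spec(band_dictionary = dict,
             drug_loading = drug_loading,
             odya_loading = odya_loading,
             water_band = c(center = 2150, fwhm = 400, amplitude = 0),
             baseline_poly = baseline_poly,
             noise_sd = noise_sd, spike_rate = 0, ...)
}

nearest_channel <- function(axis, wn) which.min(abs(axis - wn))

class_means_at <- function(cube, cmap, wn) {
  ch <- nearest_channel(cube$axis, wn)
  plane <- cube$intensities[, , ch]
  vapply(1:4, function(k) mean(plane[unclass(cmap) == k]), numeric(1))
}
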