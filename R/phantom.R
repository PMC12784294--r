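#' @title Synthetic cell phantoms with ground truth
#' @description Generates hyperspectral cubes with the statistical structure
#'   the analysis assumes -- compartmentalized cells (background, cellular
#'   matrix, nucleus, lipid droplets) with compartment-specific Raman band
#'   dictionaries, a drug nitrile band set and an alkyne tag band, a broad
#'   water combination band under the silent region, a smooth baseline,
#'   additive Gaussian noise and optional cosmic-ray spikes -- together with
#'   the ground-truth compartment map and per-pixel tag loadings.
#' @name phantom
NULL

#' Unit-height Lorentzian profile
#' @param x evaluation positions (cm^-1).
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @param height peak height (default 1).
#' @return numeric vector of the same length as `x`.
#' @export
lorentzian <- function(x, center, fwhm, height = 1) {
  height / (1 + ((x - center) / (fwhm / 2))^2)
}

band_profile <- function(axis, bands) {
  y <- numeric(length(axis))
  if (is.null(bands) || nrow(bands) == 0L) return(y)
  for (i in seq_len(nrow(bands))) {
    y <- y + lorentzian(axis, bands$center[i], bands$fwhm[i],
                        bands$amplitude[i])
  }
  y
}

#' Default per-compartment Raman band dictionary
#'
#' Peak heights are in detector counts; centers follow common cellular
#' assignments (789 cm^-1 DNA backbone in the nucleus, 2850 cm^-1 CH2
#' stretch dominating lipid droplets, protein/lipid fingerprint bands in the
#' matrix). Each entry is a data frame with columns `center`, `fwhm`,
#' `amplitude`.
#'
#' @return named list with elements `background`, `matrix`, `nucleus`,
#'   `droplet`.
#' @export
default_band_dictionary <- function() {
  bd <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], fwhm = m[, 2], amplitude = m[, 3])
  }
  list(
    background = data.frame(center = numeric(0), fwhm = numeric(0),
                            amplitude = numeric(0)),
    matrix = bd(1004, 12, 30,
                1267, 18, 25,
                1342, 18, 25,
                1447, 18, 30,
                1661, 20, 40,
                2850, 20, 15,
                2940, 30, 60),
    nucleus = bd(789, 15, 50,
                 1100, 18, 35,
                 1342, 18, 30,
                 1447, 18, 25,
                 1661, 20, 35,
                 2940, 30, 50),
    droplet = bd(789, 15, 5,
                 1267, 18, 20,
                 1447, 18, 80,
                 1661, 20, 50,
                 2850, 20, 120,
                 2940, 30, 70)
  )
}

#' Default drug (nitrile-tagged antagonist) band set
#'
#' Band centers at 2223, 1618, 1510 and 1255 cm^-1 with relative heights
#' 1 : 0.35 : 0.3 : 0.15 and an absolute scale of 20 counts per loading
#' unit for the nitrile band.
#' @return data frame with columns `center`, `fwhm`, `amplitude`.
#' @export
default_drug_bands <- function() {
  data.frame(center = c(1255, 1510, 1618, 2223),
             fwhm = c(15, 15, 15, 15),
             amplitude = 20 * c(0.15, 0.3, 0.35, 1.0))
}

#' Default alkyne (17-ODYA-like) band set
#' @return data frame with columns `center`, `fwhm`, `amplitude`.
#' @export
default_odya_bands <- function() {
  data.frame(center = 2115, fwhm = 15, amplitude = 20)
}

#' Specify a synthetic cell phantom
#'
#' All geometry is in pixels (1-based pixel centers, row/column order,
#' origin top-left); all band amplitudes are peak heights in counts; the
#' baseline polynomial is evaluated in the scaled coordinate
#' `u = (wavenumber - min) / (max - min)` so its coefficients are counts.
#'
#' @param rows,cols image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param axis wavenumber axis (cm^-1); must cover at least 550-3150 cm^-1
#'   so every processing window of the pipeline exists.
#' @param cell_ellipse,nucleus_ellipse lists with `center = c(row, col)` and
#'   `semi = c(row_semiaxis, col_semiaxis)`; the nucleus must lie strictly
#'   inside the cell.
#' @param droplet_count,droplet_radius_px lipid-droplet geometry; droplets
#'   are placed by seeded rejection sampling inside the cell and outside the
#'   nucleus.
#' @param band_dictionary per-compartment band list, see
#'   [default_band_dictionary()].
#' @param drug_bands,odya_bands tag band sets (counts at loading 1).
#' @param drug_loading,odya_loading named per-compartment loading
#'   multipliers (`background`, `matrix`, `nucleus`, `droplet`).
#' @param ring_width_px,ring_drug_loading,ring_odya_loading optional
#'   perinuclear ring: matrix pixels within `ring_width_px` of the nucleus
#'   boundary get these loadings added (0 disables the ring).
#' @param water_band `c(center, fwhm, amplitude)` of the broad water
#'   combination band underlying the silent region.
#' @param baseline_poly polynomial coefficients (constant first) in counts.
#' @param noise_sd additive i.i.d. Gaussian noise SD in counts.
#' @param spike_rate fraction of (pixel, channel) entries hit by a spike.
#' @param spike_amplitude spike height in counts.
#' @param seed RNG seed; identical (spec, seed) pairs give bit-identical
#'   phantoms.
#' @return a list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 64, cols = 64, pixel_size = 0.5,
                         axis = seq(550, 3150, by = 2),
                         cell_ellipse = list(center = c((rows + 1) / 2,
                                                        (cols + 1) / 2),
                                             semi = c(0.42 * rows,
                                                      0.45 * cols)),
                         nucleus_ellipse = list(center = c((rows + 1) / 2,
                                                           0.40 * cols),
                                                semi = c(0.14 * rows,
                                                         0.12 * cols)),
                         droplet_count = 6, droplet_radius_px = 3,
                         band_dictionary = default_band_dictionary(),
                         drug_bands = default_drug_bands(),
                         odya_bands = default_odya_bands(),
                         drug_loading = c(background = 0, matrix = 1,
                                          nucleus = 0.5, droplet = 10),
                         odya_loading = c(background = 0, matrix = 0,
                                          nucleus = 0, droplet = 0),
                         ring_width_px = 0, ring_drug_loading = 0,
                         ring_odya_loading = 0,
                         water_band = c(center = 2150, fwhm = 400,
                                        amplitude = 30),
                         baseline_poly = c(30, 20),
                         noise_sd = 2, spike_rate = 0,
                         spike_amplitude = 100, seed = 1) {
  compartments <- c("background", "matrix", "nucleus", "droplet")
  if (!is.null(names(drug_loading))) drug_loading <- drug_loading[compartments]
  if (!is.null(names(odya_loading))) odya_loading <- odya_loading[compartments]
  names(drug_loading) <- names(odya_loading) <- compartments
  if (is.null(names(water_band))) {
    names(water_band) <- c("center", "fwhm", "amplitude")
  }
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               pixel_size = pixel_size, axis = as.numeric(axis),
               cell_ellipse = cell_ellipse,
               nucleus_ellipse = nucleus_ellipse,
               droplet_count = as.integer(droplet_count),
               droplet_radius_px = droplet_radius_px,
               band_dictionary = band_dictionary,
               drug_bands = drug_bands, odya_bands = odya_bands,
               drug_loading = drug_loading, odya_loading = odya_loading,
               ring_width_px = ring_width_px,
               ring_drug_loading = ring_drug_loading,
               ring_odya_loading = ring_odya_loading,
               water_band = water_band, baseline_poly = baseline_poly,
               noise_sd = noise_sd, spike_rate = spike_rate,
               spike_amplitude = spike_amplitude, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

ellipse_inside <- function(points_rc, ellipse, inflate = 0) {
  ((points_rc[, 1] - ellipse$center[1]) / (ellipse$semi[1] + inflate))^2 +
    ((points_rc[, 2] - ellipse$center[2]) / (ellipse$semi[2] + inflate))^2 <= 1
}

#' Validate a phantom specification
#'
#' Checks geometry containment (nucleus strictly inside the cell), positive
#' band widths, droplet radius >= 1 and a spike rate in `[0, 1]`.
#'
#' @param spec a `"phantom_spec"`.
#' @return `spec`, invisibly; errors name the offending shape or field.
#' @export
validate_phantom_spec <- function(spec) {
  with(spec, {
    if (rows < 4 || cols < 4) stop("phantom grid too small")
    if (droplet_radius_px < 1) stop("droplet_radius_px must be >= 1")
    if (spike_rate < 0 || spike_rate > 1) {
      stop("spike_rate must be in [0, 1]")
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    for (nm in names(band_dictionary)) {
      b <- band_dictionary[[nm]]
      if (nrow(b) > 0 && any(b$fwhm <= 0)) {
        stop("band dictionary '", nm, "' contains FWHM <= 0")
      }
    }
    if (any(drug_bands$fwhm <= 0) || any(odya_bands$fwhm <= 0)) {
      stop("tag band sets must have FWHM > 0")
    }
    if (water_band[["fwhm"]] <= 0) stop("water band FWHM must be > 0")
    if (any(drug_loading < 0) || any(odya_loading < 0)) {
      stop("tag loadings must be nonnegative")
    }
  })
  wavenumber_axis(spec$axis)
  # nucleus boundary sampled and required strictly inside the cell ellipse
  t <- seq(0, 2 * pi, length.out = 256)
  bnd <- cbind(spec$nucleus_ellipse$center[1] +
                 spec$nucleus_ellipse$semi[1] * sin(t),
               spec$nucleus_ellipse$center[2] +
                 spec$nucleus_ellipse$semi[2] * cos(t))
  inside <- ((bnd[, 1] - spec$cell_ellipse$center[1]) /
               spec$cell_ellipse$semi[1])^2 +
    ((bnd[, 2] - spec$cell_ellipse$center[2]) / spec$cell_ellipse$semi[2])^2
  if (any(inside >= 1)) {
    stop("configuration error: nucleus ellipse not strictly inside ",
         "cell ellipse")
  }
  invisible(spec)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(list = ".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

place_droplets <- function(spec) {
  n <- spec$droplet_count
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  rad <- spec$droplet_radius_px
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  tries <- 0L
  ce <- spec$cell_ellipse
  ne <- spec$nucleus_ellipse
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      stop("configuration error: could not place droplet ", placed + 1L,
           " of radius ", rad, " inside cell and outside nucleus")
    }
    p <- c(stats::runif(1, ce$center[1] - ce$semi[1],
                        ce$center[1] + ce$semi[1]),
           stats::runif(1, ce$center[2] - ce$semi[2],
                        ce$center[2] + ce$semi[2]))
    ok_cell <- ellipse_inside(matrix(p, ncol = 2), ce, inflate = -rad - 1)
    out_nuc <- !ellipse_inside(matrix(p, ncol = 2), ne, inflate = rad + 1)
    sep <- placed == 0L ||
      all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          matrix(p, placed, 2, byrow = TRUE))^2)) >
            2 * rad + 1)
    if (isTRUE(ok_cell) && isTRUE(out_nuc) && isTRUE(sep)) {
      placed <- placed + 1L
      centers[placed, ] <- p
    }
  }
  centers
}

phantom_geometry <- function(spec) {
  grid <- cbind(rep(seq_len(spec$rows), each = spec$cols),
                rep(seq_len(spec$cols), times = spec$rows))
  labels <- rep(CLASS_CODES[["background"]], nrow(grid))
  in_cell <- ellipse_inside(grid, spec$cell_ellipse)
  labels[in_cell] <- CLASS_CODES[["matrix"]]
  in_nuc <- ellipse_inside(grid, spec$nucleus_ellipse)
  labels[in_cell & in_nuc] <- CLASS_CODES[["nucleus"]]
  centers <- place_droplets(spec)
  for (i in seq_len(nrow(centers))) {
    d2 <- (grid[, 1] - centers[i, 1])^2 + (grid[, 2] - centers[i, 2])^2
    labels[d2 <= spec$droplet_radius_px^2] <- CLASS_CODES[["droplet"]]
  }
  lm <- matrix(labels, nrow = spec$rows, ncol = spec$cols, byrow = TRUE)
  ring <- matrix(FALSE, spec$rows, spec$cols)
  if (spec$ring_width_px > 0) {
    near_nuc <- ellipse_inside(grid, spec$nucleus_ellipse,
                               inflate = spec$ring_width_px)
    ring_v <- near_nuc & labels == CLASS_CODES[["matrix"]]
    ring <- matrix(ring_v, spec$rows, spec$cols, byrow = TRUE)
  }
  list(class_map = class_map(lm), ring_mask = ring,
       droplet_centers = centers)
}

#' Generate a synthetic hyperspectral phantom
#'
#' Builds the cube as the sum of per-compartment band profiles, the drug and
#' alkyne tag band sets scaled by per-pixel loadings, the broad water band,
#' the baseline polynomial, Gaussian noise, and (optionally) seeded spikes.
#' Deterministic: the same spec yields a bit-identical cube and truth.
#'
#' @param spec a `"phantom_spec"`.
#' @return list with elements `cube` (a `"hyper_cube"`) and `truth` (class
#'   `"phantom_truth"`: `class_map`, per-pixel `drug_map` / `odya_map`
#'   loadings, `ring_mask`, `droplet_centers`, and `spikes` -- a data frame
#'   of seeded spike positions, empty when `spike_rate = 0`).
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    geom <- phantom_geometry(spec)
    lm <- unclass(geom$class_map)
    axis <- spec$axis
    k <- length(axis)
    npx <- spec$rows * spec$cols

    class_profiles <- vapply(
      c("background", "matrix", "nucleus", "droplet"),
      function(nm) band_profile(axis, spec$band_dictionary[[nm]]),
      numeric(k))
    drug_profile <- band_profile(axis, spec$drug_bands)
    odya_profile <- band_profile(axis, spec$odya_bands)
    u <- (axis - min(axis)) / (max(axis) - min(axis))
    common <- lorentzian(axis, spec$water_band[["center"]],
                         spec$water_band[["fwhm"]],
                         spec$water_band[["amplitude"]]) +
      drop(outer(u, seq_along(spec$baseline_poly) - 1, `^`) %*%
             spec$baseline_poly)

    drug_map <- matrix(spec$drug_loading[lm], spec$rows, spec$cols)
    odya_map <- matrix(spec$odya_loading[lm], spec$rows, spec$cols)
    if (any(geom$ring_mask)) {
      drug_map[geom$ring_mask] <- drug_map[geom$ring_mask] +
        spec$ring_drug_loading
      odya_map[geom$ring_mask] <- odya_map[geom$ring_mask] +
        spec$ring_odya_loading
    }

    # pixels x channels, column-major pixel order to match matrix()
    m <- t(class_profiles[, lm]) +
      as.vector(drug_map) %o% drug_profile +
      as.vector(odya_map) %o% odya_profile +
      matrix(common, npx, k, byrow = TRUE)
    if (spec$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(npx * k, sd = spec$noise_sd), npx, k)
    }
    cube <- hyper_cube(array(m, dim = c(spec$rows, spec$cols, k)),
                       axis, spec$pixel_size)

    spikes <- data.frame(row = integer(0), col = integer(0),
                         channel = integer(0))
    if (spec$spike_rate > 0) {
      sp <- inject_spikes(cube, spec$spike_rate, spec$spike_amplitude,
                          seed = spec$seed + 1L)
      cube <- sp$cube
      spikes <- sp$positions
    }

    truth <- structure(list(class_map = geom$class_map,
                            drug_map = drug_map, odya_map = odya_map,
                            ring_mask = geom$ring_mask,
                            droplet_centers = geom$droplet_centers,
                            spikes = spikes),
                       class = "phantom_truth")
    list(cube = cube, truth = truth)
  })
}

#' Inject single-channel spikes into a cube
#'
#' Adds `+amplitude` to exactly `round(rate * rows * cols * channels)`
#' distinct (pixel, channel) entries chosen by the seeded RNG, emulating
#' cosmic-ray artifacts for despiking tests.
#'
#' @param cube a `"hyper_cube"`.
#' @param rate fraction of (pixel, channel) entries to hit, in `[0, 1]`.
#' @param amplitude spike height (counts).
#' @param seed RNG seed.
#' @return list with the spiked `cube` and `positions`, a data frame with
#'   columns `row`, `col`, `channel` (one row per spike).
#' @export
inject_spikes <- function(cube, rate, amplitude, seed = 1L) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (rate < 0 || rate > 1) stop("spike rate must be in [0, 1]")
  d <- dim(cube$intensities)
  total <- prod(d)
  n <- round(rate * total)
  if (n == 0L) {
    return(list(cube = cube,
                positions = data.frame(row = integer(0), col = integer(0),
                                       channel = integer(0))))
  }
  with_seed(seed, {
    idx <- sample.int(total, n)
    arr <- cube$intensities
    arr[idx] <- arr[idx] + amplitude
    idx0 <- idx - 1L
    pos <- data.frame(
      row = idx0 %% d[1L] + 1L,
      col = (idx0 %/% d[1L]) %% d[2L] + 1L,
      channel = idx0 %/% (d[1L] * d[2L]) + 1L)
    pos <- pos[order(pos$row, pos$col, pos$channel), , drop = FALSE]
    rownames(pos) <- NULL
    list(cube = hyper_cube(arr, cube$axis, cube$pixel_size),
         positions = pos)
  })
}

#' Serialize / load a phantom spec as a YAML config
#'
#' Band tables are stored as lists of columns; the spec is reconstructed
#' through [phantom_spec()] so it is re-validated on load.
#'
#' @param spec a `"phantom_spec"`.
#' @param path YAML file path.
#' @return `read_phantom_spec` returns a `"phantom_spec"`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  ser <- unclass(spec)
  ser$band_dictionary <- lapply(ser$band_dictionary, as.list)
  ser$drug_bands <- as.list(ser$drug_bands)
  ser$odya_bands <- as.list(ser$odya_bands)
  ser$drug_loading <- as.list(ser$drug_loading)
  ser$odya_loading <- as.list(ser$odya_loading)
  ser$water_band <- as.list(ser$water_band)
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$band_dictionary <- lapply(raw$band_dictionary, function(b) {
    if (length(b$center) == 0L) default_band_dictionary()$background
    else as.data.frame(b)
  })
  raw$drug_bands <- as.data.frame(raw$drug_bands)
  raw$odya_bands <- as.data.frame(raw$odya_bands)
  raw$drug_loading <- unlist(raw$drug_loading)
  raw$odya_loading <- unlist(raw$odya_loading)
  raw$water_band <- unlist(raw$water_band)
  do.call(phantom_spec, raw)
}
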