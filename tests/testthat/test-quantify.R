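ax <- seq(600, 3050, by = 2)

strip_map <- function(m) matrix(as.vector(unclass(m)), nrow(m), ncol(m))

test_that("band area is the chord-corrected trapezoid integral", {
  # constant and affine spectra integrate to exactly zero
  for (y in list(rep(4, length(ax)), 0.01 * ax - 3)) {
    sp <- raman_spectrum(ax, y)
    expect_equal(band_area(sp, band_window(2223)), 0, tolerance = 1e-10)
  }

  # triangular peak of height 1 spanning exactly a 30 cm^-1 window with
  # on-grid base (984, 1014) and apex (1000): piecewise-linear with knots
  # on the grid, so the trapezoid rule is exact and the area is 15
  y <- approx(c(600, 984, 1000, 1014, 3050), c(0, 0, 1, 0, 0),
              xout = ax)$y
  sp <- raman_spectrum(ax, y)
  expect_equal(band_area(sp, band_window(999, 15)), 15, tolerance = 1e-12)

  # oracle equivalence on an arbitrary piecewise-linear fixture
  set.seed(8)
  knots <- sort(sample(seq_along(ax), 40))
  yk <- approx(ax[knots], runif(40, -5, 20), xout = ax, rule = 2)$y
  spk <- raman_spectrum(ax, yk)
  w <- band_window(1500, 25)
  i0 <- which.min(abs(ax - 1475)); i1 <- which.min(abs(ax - 1525))
  expect_equal(band_area(spk, w),
               trapz_chord_reference(ax, yk, i0, i1), tolerance = 1e-12)

  expect_error(band_area(sp, band_window(3500)), "outside axis")
})

test_that("band area is linear and affine-invariant", {
  set.seed(12)
  y1 <- rnorm(length(ax)); y2 <- lorentzian(ax, 2223, 15, 10)
  w <- band_window(2223)
  a1 <- band_area(raman_spectrum(ax, y1), w)
  a2 <- band_area(raman_spectrum(ax, y2), w)
  mix <- band_area(raman_spectrum(ax, 3 * y1 - 2 * y2), w)
  expect_equal(mix, 3 * a1 - 2 * a2, tolerance = 1e-10)
  # adding any affine function of wavenumber changes nothing
  shifted <- band_area(raman_spectrum(ax, y2 + 0.05 * ax - 11), w)
  expect_equal(shifted, a2, tolerance = 1e-9)
})

test_that("area maps localize the tag to its true support", {
  flat <- hyper_cube(array(7, dim = c(3, 3, length(ax))), ax)
  m <- area_map(flat, band_window(2223))
  expect_equal(strip_map(m), matrix(0, 3, 3), tolerance = 1e-10)

  spec <- silent_spec(noise_sd = 0.2,
                      drug_loading = c(background = 0, matrix = 0,
                                       nucleus = 0, droplet = 5))
  ph <- make_phantom(spec)
  am <- area_map(ph$cube, band_window(2223))
  drop_px <- unclass(ph$truth$class_map) == 4L
  expect_gt(min(unclass(am)[drop_px]), 500)     # strong positive in droplets
  expect_lt(max(abs(unclass(am)[!drop_px])), 25)  # noise-scale elsewhere

  # doubling the loading doubles the mean droplet area
  spec2 <- silent_spec(noise_sd = 0.2,
                       drug_loading = c(background = 0, matrix = 0,
                                        nucleus = 0, droplet = 10))
  am2 <- area_map(make_phantom(spec2)$cube, band_window(2223))
  expect_equal(mean(unclass(am2)[drop_px]) / mean(unclass(am)[drop_px]),
               2, tolerance = 0.02)
})

test_that("nuclear reference averages the DNA band over nucleus pixels", {
  cm <- class_map(matrix(c(1L, 3L, 3L, 2L), 2, 2))
  am <- structure(matrix(c(9, 1, 3, 9), 2, 2),
                  window = band_window(789), normalized = FALSE,
                  reference_value = NA_real_,
                  class = c("area_map", "matrix", "array"))
  expect_equal(nuclear_reference(am, cm), 2)

  am_const <- am; am_const[] <- 2
  expect_equal(nuclear_reference(am_const, cm), 2)

  no_nuc <- class_map(matrix(c(1L, 2L, 2L, 4L), 2, 2))
  expect_error(nuclear_reference(am, no_nuc), "no nucleus")

  am_neg <- am; am_neg[] <- -1
  expect_error(nuclear_reference(am_neg, cm), "not positive")
})

test_that("normalization divides by the reference and keeps signs", {
  am <- structure(matrix(c(3, -0.3, 0, 1.5), 2, 2),
                  window = band_window(2223), normalized = FALSE,
                  reference_value = NA_real_,
                  class = c("area_map", "matrix", "array"))
  nm <- normalize_map(am, 1.5)
  expect_equal(strip_map(nm), matrix(c(2, -0.2, 0, 1), 2, 2))
  expect_true(attr(nm, "normalized"))
  expect_equal(attr(nm, "reference_value"), 1.5)
  expect_error(normalize_map(am, 0), "> 0")
})

test_that("arsinh transform is the odd log-like compression", {
  expect_equal(arsinh_transform(0), 0)
  expect_equal(arsinh_transform(1), log(1 + sqrt(2)))
  expect_equal(round(arsinh_transform(1), 4), 0.8814)
  x <- c(0.1, 0.5, 2, 10, 250)
  expect_equal(arsinh_transform(-x), -arsinh_transform(x))
  expect_true(all(diff(arsinh_transform(seq(-5, 5, by = 0.1))) > 0))
  expect_error(arsinh_transform(c(1, NA)), "finite")
})

test_that("normalization cancels global intensity rescaling", {
  spec <- small_spec(seed = 17)
  ph <- make_phantom(spec)
  ratio_of <- function(cube) {
    pre <- preprocess_cube(cube)$cube
    cn <- area_map(pre, band_window(2223))
    dna <- area_map(pre, band_window(789))
    nm <- normalize_map(cn, nuclear_reference(dna, ph$truth$class_map))
    d <- compartment_distributions(nm, ph$truth$class_map)
    d$summary$mean[d$summary$class == "droplet"] /
      d$summary$mean[d$summary$class == "nucleus"]
  }
  r1 <- ratio_of(ph$cube)
  scaled <- hyper_cube(ph$cube$intensities * 3.7, ph$cube$axis,
                       ph$cube$pixel_size)
  expect_equal(ratio_of(scaled), r1, tolerance = 1e-9)
})

test_that("compartment distributions partition by class within the mask", {
  cm <- class_map(matrix(c(1L, 2L, 2L, 3L, 4L, 4L), 2, 3))
  vals <- matrix(c(99, 1, 2, 5, 7, 9), 2, 3)
  d <- compartment_distributions(vals, cm)
  expect_equal(sort(d$values$matrix), c(1, 2))
  expect_equal(d$values$nucleus, 5)
  expect_equal(sort(d$values$droplet), c(7, 9))
  expect_equal(d$summary$mean[d$summary$class == "droplet"], 8)

  # constant map gives identical class means; empty class is not an error
  ones <- matrix(1, 2, 3)
  cm2 <- class_map(matrix(c(1L, 2L, 2L, 3L, 2L, 3L), 2, 3))
  d2 <- compartment_distributions(ones, cm2)
  expect_equal(d2$summary$mean[1:2], c(1, 1))
  expect_length(d2$values$droplet, 0)

  # heterogeneous matrix-only placement spreads matrix beyond nucleus
  spec <- small_spec(seed = 23, ring_width_px = 3, ring_drug_loading = 6,
                     drug_loading = c(background = 0, matrix = 0,
                                      nucleus = 0, droplet = 0))
  ph <- make_phantom(spec)
  am <- area_map(ph$cube, band_window(2223))
  d3 <- compartment_distributions(unclass(am), ph$truth$class_map)
  expect_gt(d3$summary$sd[d3$summary$class == "matrix"],
            d3$summary$sd[d3$summary$class == "nucleus"])
})
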