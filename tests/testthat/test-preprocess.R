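axis1226 <- seq(600, 3050, by = 2)

test_that("despiking flags spikes, spares constants and smooth bands", {
  # constant spectrum: all differences zero, nothing flagged
  const <- raman_spectrum(axis1226, rep(100, length(axis1226)))
  r <- despike(const)
  expect_length(r$flagged, 0)
  expect_equal(r$spectrum$intensity, const$intensity)

  # flat floor with one huge spike: flagged, replaced close to the floor
  y <- rep(100, length(axis1226)); y[400] <- 1e4
  r <- despike(raman_spectrum(axis1226, y))
  expect_true(400 %in% r$flagged)
  expect_equal(r$spectrum$intensity[400], 100, tolerance = 0.01)

  # smooth band over a realistic noise floor: zero flags at threshold 37
  set.seed(42)
  smooth <- lorentzian(axis1226, 1450, 15, 500) +
    rnorm(length(axis1226), sd = 2)
  r <- despike(raman_spectrum(axis1226, smooth))
  expect_length(r$flagged, 0)
  # oracle: the brute-force statistic itself stays below threshold
  expect_lt(max(despike_scores(smooth)), 37)
})

test_that("despiking is idempotent", {
  set.seed(7)
  y <- lorentzian(axis1226, 1450, 15, 300) + rnorm(length(axis1226), sd = 2)
  y[c(200, 600, 900)] <- y[c(200, 600, 900)] + 5000
  first <- despike(raman_spectrum(axis1226, y))
  expect_gt(length(first$flagged), 0)
  second <- despike(first$spectrum)
  expect_length(second$flagged, 0)
  expect_equal(second$spectrum$intensity, first$spectrum$intensity)
})

test_that("SNIP baseline matches the reference implementation exactly", {
  set.seed(3)
  n <- 1000
  ax <- seq(550, 550 + 2 * (n - 1), by = 2)
  y <- lorentzian(ax, 1200, 30, 80) + lorentzian(ax, 1900, 400, 40) +
    0.01 * ax + rnorm(n, sd = 1.5)
  sp <- raman_spectrum(ax, y)
  for (iters in c(7, 100)) {
    sec <- snip_section(min(ax), max(ax), iters)
    got <- snip_baseline(sp, sec)
    expect_equal(got$baseline, snip_reference(y, iters), tolerance = 1e-12)
    # min-operation invariant: baseline never exceeds the input
    expect_true(all(got$baseline <= y + 1e-12))
  }
})

test_that("SNIP keeps narrow peaks and removes broad structure", {
  ax <- seq(1000, 2600, by = 2)
  flat <- raman_spectrum(ax, rep(10, length(ax)))
  got <- snip_baseline(flat, snip_section(1000, 2600, 7))
  expect_equal(got$baseline, rep(10, length(ax)))

  narrow <- raman_spectrum(ax, lorentzian(ax, 1800, 8, 100))
  bl <- snip_baseline(narrow, snip_section(1000, 2600, 7))$baseline
  resid <- narrow$intensity - bl
  expect_gte(max(resid), 70)  # >= 70% of the 100-count peak survives

  broad <- raman_spectrum(ax, 100 * exp(-((ax - 1800) / (400 / 2.3548))^2 / 2))
  blb <- snip_baseline(broad, snip_section(1000, 2600, 7))$baseline
  expect_lte(max(broad$intensity - blb), 10)  # broad band goes with baseline

  expect_error(snip_baseline(flat, snip_section(1000, 1020, 100)),
               "needs more than")
})

test_that("sectioned correction merges continuously and keeps tag bands", {
  ax <- seq(550, 3150, by = 2)
  flat <- raman_spectrum(ax, rep(25, length(ax)))
  corr <- sectioned_correct(flat)
  expect_equal(corr$intensity, rep(0, length(ax)), tolerance = 1e-12)

  # drug band on the broad water background: band survives, water removed
  y <- lorentzian(ax, 2223, 15, 200) + lorentzian(ax, 2150, 400, 30)
  corr <- sectioned_correct(raman_spectrum(ax, y))
  ch <- nearest_channel(ax, 2223)
  expect_gt(corr$intensity[ch], 0.5 * 200)
  silent_floor <- corr$intensity[abs(ax - 2010) < 40 | abs(ax - 2450) < 40]
  expect_lt(max(abs(silent_floor)), 5)

  # continuity: the cross-faded merge introduces no step beyond those the
  # signal itself carries
  expect_lte(max(abs(diff(corr$intensity))),
             max(abs(diff(y))) + 1)
  # inside an overlap the merge stays between the two sections' corrections
  sections <- default_snip_sections()
  corrA <- sectioned_correct(raman_spectrum(ax, y), sections[2])
  corrB <- sectioned_correct(raman_spectrum(ax, y), sections[3])
  ov <- ax >= 2600 & ax <= 2800
  lo_env <- pmin(corrA$intensity[ov], corrB$intensity[ov])
  hi_env <- pmax(corrA$intensity[ov], corrB$intensity[ov])
  expect_true(all(corr$intensity[ov] >= lo_env - 1e-9))
  expect_true(all(corr$intensity[ov] <= hi_env + 1e-9))

  expect_error(
    sectioned_correct(raman_spectrum(ax, y),
                      sections = list(snip_section(4000, 5000, 10))),
    "outside the axis")
})

test_that("calibration shifts by the mean reference-measured offset", {
  ax <- seq(600, 700, by = 2)
  tab <- calibration_table(c(620, 680), c(618, 676))
  got <- calibrate(ax, tab)
  expect_equal(got$shift, 3)
  expect_equal(got$axis, ax + 3)

  same <- calibrate(ax, calibration_table(c(620, 680), c(620, 680)))
  expect_equal(same$shift, 0)
  expect_equal(same$axis, ax)

  one <- calibrate(ax, calibration_table(1000, 998))
  expect_equal(one$shift, 2)
  expect_error(calibration_table(c(700, 620), c(700, 620)),
               "strictly increasing")
})

test_that("resampling hits the printed grid and is exact on affine data", {
  ax <- seq(550, 3150, by = 2)
  ramp <- raman_spectrum(ax, 0.3 * ax + 7)
  out <- resample(ramp)
  expect_length(out$axis, 1226)
  expect_equal(out$axis[1], 600)
  expect_equal(out$axis[1226], 3050)
  expect_equal(out$intensity, 0.3 * out$axis + 7, tolerance = 1e-12)

  # input already on the target grid passes through unchanged
  sp <- raman_spectrum(axis1226, sin(axis1226 / 100))
  expect_equal(resample(sp)$intensity, sp$intensity, tolerance = 1e-12)

  short <- raman_spectrum(seq(700, 2000, by = 2), rep(1, 651))
  expect_error(resample(short), "extends beyond")
})

test_that("acetaminophen reference table loads from package data", {
  ref <- acetaminophen_reference()
  expect_true(all(diff(ref) > 0))
  expect_true(all(ref > 300 & ref < 3100))
  expect_gte(length(ref), 10)
})

test_that("cube preprocessing runs the stages in order and is deterministic", {
  # zero-noise flat cube comes out as all zeros on the 1226-channel grid
  ax <- seq(550, 3150, by = 2)
  flat <- hyper_cube(array(50, dim = c(4, 4, length(ax))), ax)
  out <- preprocess_cube(flat)
  expect_equal(cube_dim(out$cube), c(4L, 4L, 1226L))
  expect_equal(max(abs(out$cube$intensities)), 0, tolerance = 1e-10)
  expect_equal(out$log$n_flagged, 0)

  spec <- small_spec(seed = 31, spike_rate = 2e-4, spike_amplitude = 5000)
  ph <- make_phantom(spec)
  a <- preprocess_cube(ph$cube)
  b <- preprocess_cube(ph$cube)
  expect_identical(a$cube$intensities, b$cube$intensities)

  # seeded strong spikes recovered
  key <- function(df) paste(df$row, df$col, df$channel)
  recall <- mean(key(ph$truth$spikes) %in% key(a$log$flagged))
  expect_gte(recall, 0.95)

  # calibration shift propagates into the resampled cube
  cfg <- preprocess_config(calibration = calibration_table(1000, 998))
  shifted <- preprocess_cube(ph$cube, cfg)
  expect_equal(shifted$log$shift, 2)
})

test_that("calibration and resampling commute with constant offsets", {
  ax <- seq(550, 3150, by = 2)
  set.seed(5)
  y <- lorentzian(ax, 1450, 20, 50) + rnorm(length(ax), sd = 0.5)
  tab <- calibration_table(c(800, 1600), c(799, 1598.5))
  pipe <- function(v) {
    cal <- calibrate(ax, tab)
    resample(raman_spectrum(cal$axis, v))$intensity
  }
  expect_equal(pipe(y + 12), pipe(y) + 12, tolerance = 1e-10)
})
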