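fake_map <- function(vals, window = band_window(2223)) {
  structure(vals, window = window, normalized = TRUE, reference_value = 1,
            class = c("area_map", "matrix", "array"))
}

test_that("point assembly excludes negatives and keeps provenance", {
  cn <- fake_map(matrix(c(1, -0.1, 2, 3), 2, 2))
  cc <- fake_map(matrix(c(1, 1, -2, 0.5), 2, 2), band_window(2115))
  mask <- cell_mask_matrix(matrix(TRUE, 2, 2))
  pts <- coloc_points(cn, cc, mask)
  expect_equal(nrow(pts$points) + nrow(pts$excluded), 4)
  expect_equal(nrow(pts$excluded), 2)
  expect_true(all(pts$points$x >= 0 & pts$points$y >= 0))
  # the x = -0.1 pixel is listed among exclusions
  expect_true(any(pts$excluded$x == -0.1))

  # all-positive maps yield zero exclusions
  pos <- coloc_points(fake_map(matrix(1, 2, 2)),
                      fake_map(matrix(2, 2, 2)), mask)
  expect_equal(nrow(pos$excluded), 0)

  none <- cell_mask_matrix(matrix(FALSE, 2, 2))
  expect_error(coloc_points(cn, cc, none), "no pixels")
})

test_that("density mode matches a fine-histogram oracle", {
  set.seed(33)
  n <- 500
  x <- rnorm(n, 2, 0.1); y <- rnorm(n, 1, 0.1)
  pts <- structure(list(points = data.frame(row = 1, col = seq_len(n),
                                            x = x, y = y),
                        excluded = data.frame(), shape = c(1L, n)),
                   class = "coloc_points")
  mode <- density_mode(pts)
  bw <- max(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  expect_lt(abs(mode["x"] - 2), 3 * bw)
  expect_lt(abs(mode["y"] - 1), 3 * bw)
  expect_identical(mode, density_mode(pts))  # deterministic

  # 90/10 mixture: the mode sits at the heavy cluster
  x2 <- c(rnorm(900, 1, 0.05), rnorm(100, 3, 0.05))
  y2 <- c(rnorm(900, 1, 0.05), rnorm(100, 3, 0.05))
  pts2 <- structure(list(points = data.frame(row = 1, col = 1:1000,
                                             x = x2, y = y2),
                         excluded = data.frame(), shape = c(1L, 1000L)),
                    class = "coloc_points")
  mode2 <- density_mode(pts2)
  oracle <- hist2d_mode(x2, y2)
  expect_lt(abs(mode2["x"] - oracle[1]), 0.3)
  expect_lt(abs(mode2["y"] - oracle[2]), 0.3)
  expect_lt(abs(mode2["x"] - 1), 0.3)

  few <- structure(list(points = data.frame(row = 1, col = 1:5,
                                            x = 1:5, y = 1:5),
                        excluded = data.frame(), shape = c(1L, 5L)),
                   class = "coloc_points")
  expect_error(density_mode(few), ">= 10")
})

test_that("partition labels split ratio and intensity with low tie-breaks", {
  # geometry fixed by hand: slope 1, mode at (1, 1)
  pts <- structure(
    list(points = data.frame(row = 1, col = 1:5,
                             x = c(0.5, 3, 0.2, 1, 1.4),
                             y = c(0.5, 3, 1.0, 0.2, 1.5)),
         excluded = data.frame(row = integer(0), col = integer(0),
                               x = numeric(0), y = numeric(0)),
         shape = c(1L, 5L)),
    class = "coloc_points")
  geom <- coloc_partition(pts, t0_factor = 1.05, mode = c(x = 1, y = 1))
  expect_equal(geom$slope, 1)
  expect_equal(geom$t0, 1.05 * sqrt(2), tolerance = 1e-12)

  lab <- partition_labels(pts, geom)
  # point on the central line below t0: low ratio, low intensity
  expect_equal(lab[1], 1L)
  # point at twice the mode projection on the line: high intensity (2)
  expect_equal(lab[2], 2L)
  # above the line, low intensity
  expect_equal(lab[3], 3L)
  # below the line, low intensity
  expect_equal(lab[4], 1L)
  # above line and above t0
  expect_equal(lab[5], 4L)
  # partition property: every retained point gets exactly one label
  expect_equal(length(lab), nrow(pts$points))
  expect_true(all(lab %in% 1:4))
})

test_that("labels are invariant to a common positive rescaling", {
  set.seed(44)
  n <- 400
  x <- abs(rnorm(n, 2, 0.5)); y <- abs(rnorm(n, 1.6, 0.5))
  mk <- function(f) structure(
    list(points = data.frame(row = 1, col = 1:n, x = f * x, y = f * y),
         excluded = data.frame(), shape = c(1L, n)),
    class = "coloc_points")
  p1 <- mk(1); p2 <- mk(7.3)
  l1 <- partition_labels(p1, coloc_partition(p1))
  l2 <- partition_labels(p2, coloc_partition(p2))
  expect_equal(l1, l2)
})

test_that("back-projection round-trips labels and marks exclusions", {
  cn <- fake_map(matrix(c(1, -0.1, 2, 3, 0.5, 1), 2, 3))
  cc <- fake_map(matrix(c(1, 1, 1, 0.5, 2, 0.1), 2, 3), band_window(2115))
  mask <- cell_mask_matrix(matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                                  2, 3))
  pts <- coloc_points(cn, cc, mask)
  lab <- rep(c(1L, 4L), length.out = nrow(pts$points))
  img <- back_project(pts, lab)
  expect_equal(dim(img), c(2L, 3L))
  expect_equal(img[2, 3], 0L)                      # outside the mask
  expect_equal(img[cbind(pts$excluded$row, pts$excluded$col)],
               rep(5L, nrow(pts$excluded)))        # excluded marked
  expect_identical(labels_from_image(img, pts), lab)
  expect_error(back_project(pts, lab[-1]), "one label per")
})

test_that("ring phantom back-projects drug enrichment next to droplets", {
  spec <- phantom_spec(
    seed = 21,
    drug_loading = c(background = 0, matrix = 1, nucleus = 0.5,
                     droplet = 8),
    odya_loading = c(background = 0, matrix = 1, nucleus = 0.5,
                     droplet = 12),
    ring_width_px = 3, ring_drug_loading = 5)
  ph <- make_phantom(spec)
  pre <- preprocess_cube(ph$cube)$cube
  dna <- area_map(pre, band_window(789))
  ref <- nuclear_reference(dna, ph$truth$class_map)
  cn <- normalize_map(area_map(pre, band_window(2223)), ref)
  cc <- normalize_map(area_map(pre, band_window(2115)), ref)
  mask <- cell_mask(ph$truth$class_map)
  pts <- coloc_points(cn, cc, mask)
  geom <- coloc_partition(pts)
  lab <- partition_labels(pts, geom)
  img <- back_project(pts, lab)

  drop_lab <- img[unclass(ph$truth$class_map) == 4L & unclass(mask)]
  ring_lab <- img[ph$truth$ring_mask & unclass(mask)]
  maj <- as.integer(names(which.max(table(drop_lab))))
  # droplets carry the alkyne-rich high CC/CN ratio; the ring must sit on the
  # higher-CN (lower CC/CN ratio) side relative to the droplet majority
  expect_true(maj %in% c(3L, 4L))
  expect_gte(mean(ring_lab %in% c(1L, 2L)), 0.8)
})
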