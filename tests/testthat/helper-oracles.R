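# Independent reference implementations used as oracles. These are written
# as plain elementwise loops, deliberately distinct from the vectorized
# code paths inside the package.

# straightforward SNIP: increasing half-window, explicit index clamping
snip_reference <- function(y, iterations) {
  n <- length(y)
  for (p in seq_len(iterations)) {
    new_y <- y
    for (i in seq_len(n)) {
      left <- y[max(1, i - p)]
      right <- y[min(n, i + p)]
      m <- (left + right) / 2
      if (m < y[i]) new_y[i] <- m
    }
    y <- new_y
  }
  y
}

# hand-summed trapezoid-minus-chord band area over channels i0..i1
trapz_chord_reference <- function(x, y, i0, i1) {
  xb <- x[i0:i1]
  yb <- y[i0:i1]
  nb <- length(xb)
  chord <- yb[1] + (yb[nb] - yb[1]) * (xb - xb[1]) / (xb[nb] - xb[1])
  r <- yb - chord
  a <- 0
  for (i in seq_len(nb - 1)) {
    a <- a + (r[i] + r[i + 1]) / 2 * (xb[i + 1] - xb[i])
  }
  a
}

# peak-position oracle: interpolate the sampled spectrum onto a 10x finer
# grid and take the argmax in a window around the expected position
fine_argmax <- function(axis, intensity, center, halfwidth = 60) {
  fine <- seq(min(axis), max(axis),
              length.out = 10 * (length(axis) - 1) + 1)
  yi <- stats::spline(axis, intensity, xout = fine)$y
  win <- abs(fine - center) <= halfwidth
  fine[win][which.max(yi[win])]
}

# 2d histogram argmax as a density-mode oracle
hist2d_mode <- function(x, y, bins = 80) {
  bx <- seq(min(x), max(x), length.out = bins + 1)
  by <- seq(min(y), max(y), length.out = bins + 1)
  ix <- pmin(findInterval(x, bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, by, rightmost.closed = TRUE), bins)
  counts <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  top <- which(counts == max(counts), arr.ind = TRUE)[1, ]
  c((bx[top[1]] + bx[top[1] + 1]) / 2, (by[top[2]] + by[top[2] + 1]) / 2)
}
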