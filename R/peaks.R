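#' @title Smoothing-spline second-derivative peak detection
#' @description Detects band maxima as negative extrema of the second
#'   derivative of a smoothing spline fitted to the max-normalized
#'   spectrum, with a relative height threshold and a vertical-prominence
#'   (delta) hysteresis to reject noise, and reports treated-vs-control
#'   differential bands.
#' @name peaks
NULL

#' Peak-finder configuration
#'
#' @param smoothing `"gcv"` (default) selects the spline smoothness by
#'   generalized cross-validation, which is scale-free and keeps detection
#'   invariant under rescaling of the spectrum; alternatively a numeric
#'   FITPACK-style residual budget (sum of squared residuals on the
#'   max-1-normalized spectrum) for explicit control.
#' @param height_fraction a candidate counts only if its second-derivative
#'   magnitude reaches this fraction of the largest second-derivative
#'   magnitude over the spectrum (default 0.02).
#' @param delta vertical distance on the max-1-normalized spectrum that the
#'   signal must recede on both sides of a maximum for it to count
#'   (default 0.01).
#' @param refine evaluation-grid refinement factor for reporting positions
#'   (default 10).
#' @return a list of class `"peak_config"`.
#' @export
peak_config <- function(smoothing = "gcv", height_fraction = 0.02,
                        delta = 0.01, refine = 10L) {
  if (height_fraction <= 0 || height_fraction >= 1) {
    stop("height_fraction must be in (0, 1)")
  }
  if (delta <= 0) stop("delta must be > 0")
  structure(list(smoothing = smoothing,
                 height_fraction = height_fraction,
                 delta = delta, refine = as.integer(refine)),
            class = "peak_config")
}

fit_detection_spline <- function(x, y, smoothing) {
  if (identical(smoothing, "gcv")) {
    return(stats::smooth.spline(x, y, all.knots = TRUE, cv = FALSE))
  }
  target <- as.numeric(smoothing)
  rss_at <- function(spar) {
    fit <- stats::smooth.spline(x, y, spar = spar, all.knots = TRUE)
    sum((stats::predict(fit, x)$y - y)^2)
  }
  lo <- -1.5; hi <- 2.5
  if (rss_at(lo) >= target) {
    return(stats::smooth.spline(x, y, spar = lo, all.knots = TRUE))
  }
  if (rss_at(hi) <= target) {
    return(stats::smooth.spline(x, y, spar = hi, all.knots = TRUE))
  }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (rss_at(mid) < target) lo <- mid else hi <- mid
  }
  stats::smooth.spline(x, y, spar = (lo + hi) / 2, all.knots = TRUE)
}

prominence_ok <- function(yv, i, delta, max_climb = Inf) {
  n <- length(yv)
  # climb to the local spectrum maximum the curvature extremum belongs to
  # (the second-derivative minimum can sit a grid step off the crest); a
  # candidate without a crest within max_climb steps sits on a flank and
  # is rejected by the receding-walk below
  steps <- 0L
  repeat {
    if (steps >= max_climb) break
    if (i > 1L && yv[i - 1L] > yv[i]) i <- i - 1L
    else if (i < n && yv[i + 1L] > yv[i]) i <- i + 1L
    else break
    steps <- steps + 1L
  }
  # walk left/right until the curve rises back above the candidate; the
  # candidate counts only if it recedes by >= delta on both sides first
  for (dir in c(-1L, 1L)) {
    j <- i
    drop <- 0
    repeat {
      j <- j + dir
      if (j < 1L || j > n) break
      if (yv[j] > yv[i]) break
      drop <- max(drop, yv[i] - yv[j])
      if (drop >= delta) break
    }
    if (drop < delta) return(FALSE)
  }
  TRUE
}

#' Detect band positions in a spectrum
#'
#' The spectrum is scaled to maximum 1, fitted with a smoothing spline, and
#' band maxima are located where the spline's second derivative has a local
#' minimum below zero. Candidates must pass a height rule (second-
#' derivative magnitude at least `height_fraction` of the global maximum
#' magnitude) and a delta-hysteresis rule (the normalized spectrum recedes
#' by at least `delta` on both sides). Positions are reported on a
#' `refine`-times finer evaluation grid.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param config a `"peak_config"`.
#' @return a `data.frame` of class `"peak_list"` with columns `position`
#'   (cm^-1, strictly increasing), `curvature` (spline second derivative,
#'   negative) and `height` (normalized spline value at the peak).
#' @export
find_peaks <- function(spectrum, config = peak_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(config, "peak_config"))
  x <- spectrum$axis
  y <- spectrum$intensity
  if (length(x) < 8L) stop("too few channels for spline peak detection")
  empty <- data.frame(position = numeric(0), curvature = numeric(0),
                      height = numeric(0))
  class(empty) <- c("peak_list", "data.frame")
  if (max(y) <= min(y)) return(empty)  # flat spectrum
  yn <- y / max(y)

  fit <- fit_detection_spline(x, yn, config$smoothing)
  xf <- seq(min(x), max(x), length.out = config$refine * (length(x) - 1L) + 1L)
  yf <- stats::predict(fit, xf)$y
  d2 <- stats::predict(fit, xf, deriv = 2L)$y

  n <- length(xf)
  cand <- which(d2[2:(n - 1L)] < d2[1:(n - 2L)] &
                  d2[2:(n - 1L)] <= d2[3:n] &
                  d2[2:(n - 1L)] < 0) + 1L
  if (length(cand) == 0L) return(empty)
  keep <- abs(d2[cand]) >= config$height_fraction * max(abs(d2))
  cand <- cand[keep]
  ynf <- yf / max(yf)
  cand <- cand[vapply(cand,
                      function(i) prominence_ok(ynf, i, config$delta,
                                                max_climb = config$refine),
                      logical(1))]
  if (length(cand) == 0L) return(empty)
  out <- data.frame(position = xf[cand], curvature = d2[cand],
                    height = ynf[cand])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Bands present in a treated spectrum but not in a control
#'
#' Runs [find_peaks()] on both spectra (which must share one axis) and
#' returns the treated peaks that have no control peak within
#' `tolerance` cm^-1. The nonzero default tolerance absorbs the small
#' position jitter between independent detections of the same band.
#'
#' @param treated,control `"raman_spectrum"` objects on a common axis.
#' @param config a `"peak_config"`.
#' @param tolerance match tolerance in cm^-1 (default 10).
#' @return a `"peak_list"` of treated-only band positions.
#' @export
differential_bands <- function(treated, control, config = peak_config(),
                               tolerance = 10) {
  stopifnot(inherits(treated, "raman_spectrum"),
            inherits(control, "raman_spectrum"))
  if (length(treated$axis) != length(control$axis) ||
      any(treated$axis != control$axis)) {
    stop("treated and control spectra must share a common axis")
  }
  pt <- find_peaks(treated, config)
  pc <- find_peaks(control, config)
  if (nrow(pt) == 0L) return(pt)
  if (nrow(pc) == 0L) return(pt)
  new <- vapply(pt$position,
                function(p) min(abs(pc$position - p)) > tolerance,
                logical(1))
  out <- pt[new, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}
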