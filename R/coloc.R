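#' @title Two-tag colocalization scatter, partition and back-projection
#' @description Assembles per-pixel (nitrile, alkyne) normalized band-area
#'   pairs within the cell mask, locates the density mode of the scatter,
#'   partitions the cloud into four segments -- a ratio wedge on either side
#'   of the central line through the origin and the density mode, split at
#'   an intensity boundary along that line -- and projects the segment
#'   labels back onto the pixel grid.
#' @name coloc
NULL

#' Assemble colocalization points
#'
#' One point per cell-mask pixel: `x` is the normalized nitrile (CN,
#' drug) band area, `y` the normalized alkyne (CC, lipid tag) band area.
#' Pixels with a negative `x` and/or `y` are excluded from the scatter but
#' retained in the `excluded` list so the back-projection can mark them.
#'
#' @param cn_map,cc_map normalized `"area_map"`s of the 2223 and 2115
#'   cm^-1 windows.
#' @param cell_mask logical cell mask.
#' @return a list of class `"coloc_points"`: `points` (data frame `row`,
#'   `col`, `x`, `y`), `excluded` (same columns), and `shape`.
#' @export
coloc_points <- function(cn_map, cc_map, cell_mask) {
  x <- unclass(cn_map); y <- unclass(cc_map); m <- unclass(cell_mask)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(m))) {
    stop("cn map, cc map and cell mask shapes differ")
  }
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cell mask selects no pixels")
  df <- data.frame(row = idx[, 1L], col = idx[, 2L],
                   x = x[idx], y = y[idx])
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  neg <- df$x < 0 | df$y < 0
  pts <- df[!neg, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no retained points: every cell pixel has a ",
                            "negative coordinate")
  structure(list(points = pts, excluded = df[neg, , drop = FALSE],
                 shape = dim(x)),
            class = "coloc_points")
}

#' Density mode of the scatter
#'
#' Kernel density estimate (normal-reference bandwidths) over the retained
#' points, evaluated on a `grid x grid` lattice; returns the lattice point
#' of maximal density.
#'
#' @param points a `"coloc_points"`.
#' @param grid evaluation grid size per axis (default 256).
#' @return `c(x, y)` of the density mode.
#' @export
density_mode <- function(points, grid = 256L) {
  stopifnot(inherits(points, "coloc_points"))
  p <- points$points
  if (nrow(p) < 10L) {
    stop("density mode needs >= 10 retained points (got ", nrow(p),
         "); use a larger phantom or cell")
  }
  h <- c(MASS::bandwidth.nrd(p$x), MASS::bandwidth.nrd(p$y))
  h[h <= 0] <- diff(range(p$x, p$y)) / 25 + 1e-12
  kd <- MASS::kde2d(p$x, p$y, h = h, n = grid)
  i <- which(kd$z == max(kd$z), arr.ind = TRUE)[1L, ]
  c(x = kd$x[i[1L]], y = kd$y[i[2L]])
}

#' Construct the four-segment partition geometry
#'
#' The central line through the origin has slope `s = y* / x*`, the
#' CC/CN ratio at the density mode. The intensity boundary `t0` sits at
#' `t0_factor` times the mode's projection along the central direction --
#' just beyond the point of highest density -- splitting each ratio wedge
#' into a low- and a high-intensity segment.
#'
#' @param points a `"coloc_points"`.
#' @param t0_factor multiplier on the mode projection (default 1.05).
#' @param mode optionally a precomputed density mode `c(x, y)`.
#' @return a list of class `"coloc_partition"` with `slope`, `t0`, `mode`.
#' @export
coloc_partition <- function(points, t0_factor = 1.05, mode = NULL) {
  if (is.null(mode)) mode <- density_mode(points)
  if (mode[1L] <= 0) {
    stop("density mode has nonpositive x; central slope undefined")
  }
  s <- unname(mode[2L] / mode[1L])
  if (s <= 0) stop("central slope must be positive; the mode lies on an axis")
  t_mode <- unname(mode[1L] + s * mode[2L]) / sqrt(1 + s^2)
  structure(list(slope = s, t0 = t0_factor * t_mode, mode = mode,
                 t0_factor = t0_factor),
            class = "coloc_partition")
}

#' Segment labels of the colocalization points
#'
#' Each retained point is labeled by its side of the central line (ratio
#' `y/x` above or below the slope `s`) and its projection
#' `t = (x + s y) / sqrt(1 + s^2)` below or above the intensity boundary
#' `t0`. Boundary points go to the lower-ratio / lower-intensity segment.
#'
#' Codes: 1 low ratio, low intensity; 2 low ratio, high intensity;
#' 3 high ratio, low intensity; 4 high ratio, high intensity.
#'
#' @param points a `"coloc_points"`.
#' @param geometry a `"coloc_partition"`.
#' @return integer vector of segment codes, one per retained point.
#' @export
partition_labels <- function(points, geometry) {
  stopifnot(inherits(points, "coloc_points"),
            inherits(geometry, "coloc_partition"))
  p <- points$points
  s <- geometry$slope
  high_ratio <- p$y > s * p$x          # boundary -> lower-ratio side
  t <- (p$x + s * p$y) / sqrt(1 + s^2)
  high_int <- t > geometry$t0          # boundary -> lower-intensity side
  1L + 1L * high_int + 2L * high_ratio
}

#' Back-project segment labels onto the pixel grid
#'
#' @param points a `"coloc_points"`.
#' @param labels integer segment codes from [partition_labels()].
#' @param shape `c(rows, cols)` of the target image (default: the shape
#'   recorded in `points`).
#' @return integer matrix: 0 outside the cell mask, 1-4 for the segments,
#'   5 for excluded (negative-coordinate) pixels.
#' @export
back_project <- function(points, labels, shape = points$shape) {
  stopifnot(inherits(points, "coloc_points"))
  p <- points$points
  if (length(labels) != nrow(p)) {
    stop("need exactly one label per retained point (", nrow(p),
         "), got ", length(labels))
  }
  if (any(p$row > shape[1L]) || any(p$col > shape[2L])) {
    stop("point coordinates exceed the requested image shape")
  }
  img <- matrix(0L, shape[1L], shape[2L])
  img[cbind(p$row, p$col)] <- as.integer(labels)
  e <- points$excluded
  if (nrow(e) > 0L) img[cbind(e$row, e$col)] <- 5L
  img
}

#' Read segment labels back from a back-projection image
#' @param image integer matrix from [back_project()].
#' @param points the `"coloc_points"` used to build it.
#' @return integer vector of segment codes per retained point.
#' @export
labels_from_image <- function(image, points) {
  p <- points$points
  image[cbind(p$row, p$col)]
}
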