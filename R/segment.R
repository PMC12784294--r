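#' @title Compartment segmentation and cell-mask extraction
#' @description Builds an eight-band feature stack of chord-corrected band
#'   areas, trains a per-pixel random-forest compartment classifier on
#'   partial annotations, predicts full class maps, and derives the binary
#'   cell mask by thresholding plus morphological clean-up.
#' @name segment
NULL

#' The eight segmentation feature windows
#'
#' Band-area integration windows (each +/- 15 cm^-1) chosen from DNA,
#' protein and lipid marker bands while deliberately omitting the drug's
#' own bands (2223, 1618, 1510 cm^-1), so that segmentation is insensitive
#' to drug loading.
#'
#' @return list of eight `"band_window"` objects.
#' @export
segmentation_windows <- function() {
  centers <- c(789, 1342, 1267, 1100, 1447, 1661, 2850, 2940)
  lapply(centers, band_window, half_width = 15)
}

#' Build the segmentation feature stack
#'
#' One chord-corrected band-area map per configured window, in the listed
#' order.
#'
#' @param cube a pre-processed `"hyper_cube"`.
#' @param windows list of `"band_window"` (default
#'   [segmentation_windows()]).
#' @return an object of class `"feature_stack"`: numeric array
#'   `rows x cols x n_windows` with attribute `windows`.
#' @export
build_feature_stack <- function(cube, windows = segmentation_windows()) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$intensities)
  m <- cube_matrix(cube)
  feats <- vapply(windows,
                  function(w) band_area_matrix(m, cube$axis, w),
                  numeric(nrow(m)))
  arr <- array(NA_real_, dim = c(d[1L], d[2L], length(windows)))
  for (i in seq_along(windows)) {
    arr[, , i] <- matrix(feats[, i], d[1L], d[2L], byrow = TRUE)
  }
  structure(arr, windows = windows,
            class = c("feature_stack", "array"))
}

stack_feature_matrix <- function(stack) {
  d <- dim(stack)
  m <- matrix(unclass(stack), nrow = d[1L] * d[2L], ncol = d[3L])
  colnames(m) <- vapply(attr(stack, "windows"),
                        function(w) paste0("w", w$center), "")
  m
}

check_window_match <- function(model, stack) {
  got <- vapply(attr(stack, "windows"), function(w) w$center, numeric(1))
  want <- model$window_centers
  if (length(got) != length(want) || any(got != want)) {
    stop("feature stack windows (", paste(got, collapse = ", "),
         ") do not match the model's training windows (",
         paste(want, collapse = ", "), ")")
  }
}

#' Train the compartment classifier
#'
#' Fits a random forest (100 trees, unrestricted depth) on the labeled
#' pixels of one or more annotated feature stacks. Annotations use 0 for
#' unlabeled pixels and the compartment codes 1-4 elsewhere; only labeled
#' pixels enter the fit. Training is deterministic under `seed`.
#'
#' @param stacks a `"feature_stack"` or list of them.
#' @param annotations matching annotation matrix or list of matrices
#'   (values in `{0,1,2,3,4}`).
#' @param seed RNG seed.
#' @param ntree number of trees (default 100).
#' @return a `"compartment_model"`: the fitted forest plus the window list,
#'   seed, and per-class training counts; training accuracy is reported in
#'   the `training_accuracy` field.
#' @export
train_classifier <- function(stacks, annotations, seed = 1L, ntree = 100L) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (is.matrix(annotations)) annotations <- list(annotations)
  if (length(stacks) != length(annotations)) {
    stop("need one annotation per feature stack")
  }
  xs <- list(); ys <- list()
  for (i in seq_along(stacks)) {
    ann <- unclass(annotations[[i]])
    if (!all(ann %in% 0:4)) {
      stop("annotation ", i, " contains labels outside {0,1,2,3,4}")
    }
    d <- dim(stacks[[i]])
    if (!all(dim(ann) == d[1:2])) {
      stop("annotation ", i, " shape does not match its stack")
    }
    lab <- which(ann != 0L)
    xs[[i]] <- stack_feature_matrix(stacks[[i]])[lab, , drop = FALSE]
    ys[[i]] <- ann[lab]
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  counts <- table(factor(y, levels = 1:4))
  if (sum(counts > 0) < 2L) {
    stop("annotations contain a single class; need at least 2")
  }
  if (length(y) < 4L * sum(counts > 0)) {
    stop("too few labeled pixels (", length(y), ") for ",
         sum(counts > 0), " classes")
  }
  yf <- factor(y, levels = 1:4)
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = yf, ntree = ntree))
  pred <- stats::predict(fit, x)
  structure(list(forest = fit,
                 window_centers = vapply(attr(stacks[[1L]], "windows"),
                                         function(w) w$center, numeric(1)),
                 seed = as.integer(seed),
                 class_counts = as.integer(counts),
                 training_accuracy = mean(pred == yf)),
            class = "compartment_model")
}

#' Predict a compartment class map
#'
#' Classifies every pixel of a feature stack independently (no spatial
#' features), so predictions are permutation-equivariant over pixels.
#'
#' @param model a `"compartment_model"`.
#' @param stack a `"feature_stack"` built with the model's windows.
#' @return a `"class_map"` with labels in `{1,2,3,4}`.
#' @export
predict_classmap <- function(model, stack) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(stack, "feature_stack"))
  check_window_match(model, stack)
  d <- dim(stack)
  pred <- stats::predict(model$forest, stack_feature_matrix(stack))
  class_map(matrix(as.integer(as.character(pred)), d[1L], d[2L]))
}

# 8-connected component labeling by breadth-first flood fill
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      nbr_r <- r + off_r
      nbr_c <- cc + off_c
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nb <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# fill holes: background flood fill from the border; anything not reached
# and not foreground is a hole
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  border <- unique(c(which(row(mask) == 1L), which(row(mask) == nr),
                     which(col(mask) == 1L), which(col(mask) == nc)))
  queue <- border[!mask[border]]
  outside[queue] <- TRUE
  off_r <- c(-1L, 0L, 0L, 1L)
  off_c <- c(0L, -1L, 1L, 0L)
  while (length(queue) > 0L) {
    p <- queue[length(queue)]
    queue <- queue[-length(queue)]
    r <- (p - 1L) %% nr + 1L
    cc <- (p - 1L) %/% nr + 1L
    nbr_r <- r + off_r
    nbr_c <- cc + off_c
    ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
    nb <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
    nb <- nb[!mask[nb] & !outside[nb]]
    outside[nb] <- TRUE
    queue <- c(queue, nb)
  }
  mask | !outside
}

#' Derive the binary cell mask from a class map
#'
#' Thresholds the class map at 1.5 (everything that is not background),
#' applies one 3x3 erosion and one 3x3 dilation, keeps only the largest
#' 8-connected component (discarding partly measured cells at the image
#' boundary unless tightly connected to the main cell), and fills interior
#' holes. The operation is idempotent on its own output. An empty mask is a
#' valid result.
#'
#' @param class_map a `"class_map"` or integer matrix.
#' @param override optional logical matrix combined with the automatic mask
#'   by element-wise AND, supporting manual repair of misclassified
#'   background (NULL to disable).
#' @return a logical `"cell_mask"` matrix.
#' @export
cell_mask <- function(class_map, override = NULL) {
  cm <- unclass(class_map)
  mask <- cm >= 1.5
  if (any(mask)) {
    kern <- EBImage::makeBrush(3L, shape = "box")
    m <- EBImage::dilate(EBImage::erode(mask * 1, kern), kern) > 0.5
    lab <- label_components8(m)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      m <- lab == which.max(sizes)
      m <- fill_holes(m)
    } else {
      m <- lab > 0L
    }
  } else {
    m <- mask
  }
  if (!is.null(override)) {
    if (!all(dim(override) == dim(m))) {
      stop("override mask shape differs from class map")
    }
    m <- m & override
  }
  cell_mask_matrix(m)
}

#' Pixel accuracy of a predicted class map against ground truth
#' @param predicted,truth integer label matrices of equal shape.
#' @return fraction of pixels with matching labels.
#' @export
pixel_accuracy <- function(predicted, truth) {
  p <- unclass(predicted); t <- unclass(truth)
  if (!all(dim(p) == dim(t))) stop("label map shapes differ")
  mean(p == t)
}
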