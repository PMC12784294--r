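#' @title File input/output for cubes, spectra, masks and mode tables
#' @name spectra-io
NULL

#' Write / read a hyperspectral cube
#'
#' Cubes are stored as a single self-describing serialized container
#' (R's native serialization, version 3) holding the intensity array,
#' the wavenumber axis and the pixel size. The round trip is lossless:
#' reading a written cube reproduces axis, intensities and pixel size
#' bit-exactly.
#'
#' @param cube a `"hyper_cube"`.
#' @param path file path (conventionally `.rds`).
#' @return `read_cube` returns a `"hyper_cube"`; `write_cube` returns
#'   `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  saveRDS(unclass(cube), path, version = 3L)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("cube format error: empty file ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cube format error in ", path,
                                           ": ", conditionMessage(e)))
  if (!is.list(obj) || !all(c("intensities", "axis", "pixel_size") %in%
                            names(obj))) {
    stop("cube format error: ", path,
         " does not contain intensities/axis/pixel_size")
  }
  hyper_cube(obj$intensities, obj$axis, obj$pixel_size)
}

#' Export a cube as a directory of per-channel TIFF images
#'
#' Interoperability fallback: one 32-bit float TIFF per channel named by its
#' wavenumber, plus an `axis.tsv` index. Not lossless (float32); the
#' serialized container of [write_cube()] is the archival format.
#'
#' @param cube a `"hyper_cube"`.
#' @param dir output directory, created if missing.
#' @return `dir` invisibly.
#' @export
export_cube_tiffs <- function(cube, dir) {
  stopifnot(inherits(cube, "hyper_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- length(cube$axis)
  files <- sprintf("channel_%04d.tif", seq_len(k))
  for (i in seq_len(k)) {
    tiff::writeTIFF(cube$intensities[, , i], file.path(dir, files[i]),
                    bits.per.sample = 32L)
  }
  utils::write.table(
    data.frame(file = files, wavenumber = as.numeric(cube$axis),
               pixel_size = cube$pixel_size),
    file.path(dir, "axis.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write / read a spectrum as a two-column delimited table
#'
#' Plain text, tab-separated, columns `wavenumber` and `intensity`, full
#' double precision. `read_spectrum` tolerates a single header line when
#' `header = TRUE` and reports the line number of any non-numeric row.
#'
#' @param spectrum a `"raman_spectrum"`.
#' @param path file path.
#' @param header whether the file carries (or should be written with) a
#'   one-line column header.
#' @return `read_spectrum` returns a `"raman_spectrum"`.
#' @export
write_spectrum <- function(spectrum, path, header = TRUE) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  df <- data.frame(wavenumber = spectrum$axis, intensity = spectrum$intensity)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

read_two_columns <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (header) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (length(lines) == 0L) stop("spectrum table ", path, " has no data rows")
  parts <- strsplit(lines, "[\t,;[:space:]]+")
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    stop("spectrum table ", path, ": line ",
         which(ncols < 2L)[1L] + offset,
         " has fewer than two columns")
  }
  wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(wn) | is.na(it))
  if (length(bad) > 0L) {
    stop("spectrum table ", path, ": non-numeric value on line ",
         bad[1L] + offset)
  }
  list(first = wn, second = it)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, header = TRUE) {
  cols <- read_two_columns(path, header)
  raman_spectrum(cols$first, cols$second)
}

#' Write / read compartment label images
#'
#' Class maps and cell masks are stored as single-channel 8-bit TIFF or PNG
#' (chosen by file extension); label values are preserved exactly. On read,
#' a class-map image must only contain values in `{0,1,2,3,4}` (0 marks
#' unlabeled pixels in annotation images); a cell mask is any image read as
#' `value >= 1`.
#'
#' @param labels integer matrix (class map / annotation) or logical matrix
#'   (cell mask).
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return readers return an integer matrix (`read_class_map`) or a logical
#'   matrix (`read_cell_mask`).
#' @export
write_label_image <- function(labels, path) {
  if (is.logical(labels)) labels <- labels * 1L
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels < 0 | labels > 255 | labels != round(labels))) {
    stop("label values must be integers in [0, 255]")
  }
  img <- unclass(labels) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported label image extension: .", ext)
  }
  invisible(path)
}

read_label_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported label image extension: .", ext)
  }
  if (length(dim(img)) != 2L) {
    stop("label image ", path, " must be single-channel, got ",
         dim(img)[3L], " channels")
  }
  round(img * 255)
}

#' @rdname write_label_image
#' @export
read_class_map <- function(path) {
  v <- read_label_raw(path)
  bad <- !(v %in% 0:4)
  if (any(bad)) {
    stop("class map ", path, " contains value(s) outside {0,1,2,3,4}: ",
         paste(utils::head(unique(v[bad])), collapse = ", "))
  }
  storage.mode(v) <- "integer"
  v
}

#' @rdname write_label_image
#' @export
read_cell_mask <- function(path) {
  read_label_raw(path) >= 1
}

#' Write a continuous map as a scaled 16-bit TIFF
#'
#' For exporting ground-truth loading maps or area maps for viewing in
#' external tools. Values are divided by `scale` and clipped to `[0, 1]`
#' before 16-bit quantization, so the export is approximate by design.
#'
#' @param values numeric matrix.
#' @param path output `.tif` path.
#' @param scale value mapped to full intensity (default: the matrix maximum).
#' @export
write_map_tiff <- function(values, path, scale = max(values)) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (!is.finite(scale) || scale <= 0) scale <- 1
  img <- pmin(pmax(unclass(values) / scale, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a quantum-chemistry Raman mode table
#'
#' Delimited text with two columns: mode frequency (cm^-1) and Raman
#' activity (A^4 amu^-1). Modes are returned sorted by frequency.
#'
#' @param path file path.
#' @param header whether the first line is a header.
#' @return a `data.frame` with columns `frequency` and `activity`, of class
#'   `"raman_mode_table"`.
#' @export
read_activity_table <- function(path, header = TRUE) {
  cols <- read_two_columns(path, header)
  raman_mode_table(cols$first, cols$second)
}

#' Construct a Raman mode table
#'
#' @param frequency mode frequencies (cm^-1), all positive.
#' @param activity Raman activities (A^4 amu^-1), all nonnegative.
#' @param intensity optional converted intensities (see
#'   [activity_to_intensity()]).
#' @return a `data.frame` of class `"raman_mode_table"`, sorted by frequency.
#' @export
raman_mode_table <- function(frequency, activity, intensity = NULL) {
  frequency <- as.numeric(frequency)
  activity <- as.numeric(activity)
  if (length(frequency) != length(activity)) {
    stop("frequency and activity lengths differ")
  }
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("mode frequencies must be positive and finite")
  }
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop("Raman activities must be nonnegative")
  }
  ord <- order(frequency)
  tab <- data.frame(frequency = frequency[ord], activity = activity[ord])
  if (!is.null(intensity)) tab$intensity <- as.numeric(intensity)[ord]
  class(tab) <- c("raman_mode_table", "data.frame")
  tab
}
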