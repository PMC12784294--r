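#' @title End-to-end workflows
#' @description The two study workflows as single calls: single-tag
#'   localization (pre-processing, segmentation, nitrile band quantitation
#'   normalized to the nuclear DNA reference, per-compartment summaries)
#'   and two-tag colocalization (both silent-region maps, scatter
#'   partition, back-projection).
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Bundles the stage configurations shared by [run_localization()] and
#' [run_coloc()].
#'
#' @param preprocess a `"preprocess_config"`.
#' @param cn_window nitrile (drug) integration window, 2223 +/- 15 cm^-1.
#' @param cc_window alkyne (lipid tag) window, 2115 +/- 15 cm^-1.
#' @param dna_window nuclear DNA reference window, 789 +/- 15 cm^-1.
#' @param feature_windows segmentation feature windows.
#' @param t0_factor colocalization intensity-boundary factor.
#' @param seed seed recorded in output manifests.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            cn_window = band_window(2223, 15),
                            cc_window = band_window(2115, 15),
                            dna_window = band_window(789, 15),
                            feature_windows = segmentation_windows(),
                            t0_factor = 1.05,
                            seed = 1L) {
  structure(list(preprocess = preprocess, cn_window = cn_window,
                 cc_window = cc_window, dna_window = dna_window,
                 feature_windows = feature_windows,
                 t0_factor = t0_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

segment_stage <- function(cube, model, config) {
  pre <- preprocess_cube(cube, config$preprocess)
  stack <- build_feature_stack(pre$cube, config$feature_windows)
  cmap <- predict_classmap(model, stack)
  mask <- cell_mask(cmap)
  # nuclear reference comes from the cell's own nucleus: labels outside
  # the cell mask are treated as background
  cm_in_cell <- unclass(cmap)
  cm_in_cell[!unclass(mask)] <- CLASS_CODES[["background"]]
  list(pre = pre, stack = stack, class_map = cmap,
       class_map_in_cell = class_map(cm_in_cell), mask = mask)
}

write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Single-tag localization workflow
#'
#' Pre-processes the cube, segments it with the supplied compartment
#' model, derives the cell mask, maps the nitrile band area, normalizes it
#' by the mean nuclear DNA reference area, and summarizes the normalized
#' (and arsinh-transformed) values per compartment.
#'
#' @param cube a raw `"hyper_cube"`.
#' @param model a trained `"compartment_model"`.
#' @param config a `"pipeline_config"`.
#' @param outdir optional output directory; when given, per-class value
#'   tables, the summary and a JSON run manifest are written there.
#' @return list with `class_map`, `cell_mask`, `normalized_map`,
#'   `reference` (the nuclear DNA area), `distributions` (per-class values
#'   and summary of the normalized map), `arsinh_distributions` (same on
#'   the arsinh scale), and the pre-processing `log`.
#' @export
run_localization <- function(cube, model, config = pipeline_config(),
                             outdir = NULL) {
  seg <- segment_stage(cube, model, config)
  cn <- area_map(seg$pre$cube, config$cn_window)
  dna <- area_map(seg$pre$cube, config$dna_window)
  ref <- nuclear_reference(dna, seg$class_map_in_cell)
  norm <- normalize_map(cn, ref)
  dist <- compartment_distributions(norm, seg$class_map, seg$mask)
  adist <- compartment_distributions(arsinh_transform(norm),
                                     seg$class_map, seg$mask)
  res <- list(class_map = seg$class_map, cell_mask = seg$mask,
              normalized_map = norm, reference = ref,
              distributions = dist, arsinh_distributions = adist,
              log = seg$pre$log)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    per_class <- do.call(rbind, lapply(names(dist$values), function(nm) {
      v <- dist$values[[nm]]
      if (length(v) == 0L) return(NULL)
      data.frame(class = nm, value = v, arsinh = asinh(v))
    }))
    write_tsv(per_class, file.path(outdir, "compartment_values.tsv"))
    write_tsv(dist$summary, file.path(outdir, "compartment_summary.tsv"))
    write_label_image(unclass(seg$class_map),
                      file.path(outdir, "class_map.png"))
    write_label_image(unclass(seg$mask),
                      file.path(outdir, "cell_mask.png"))
    manifest <- list(workflow = "localization", seed = config$seed,
                     reference = ref, n_flagged = seg$pre$log$n_flagged,
                     shift = seg$pre$log$shift)
    writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  }
  res
}

#' Two-tag colocalization workflow
#'
#' Pre-processes the cube, segments it, normalizes the nitrile (CN) and
#' alkyne (CC) band-area maps by the nuclear DNA reference, assembles the
#' scatter, partitions it into four segments around the density mode, and
#' back-projects the segment labels onto the pixel grid.
#'
#' @inheritParams run_localization
#' @return list with `points` (a `"coloc_points"`), `geometry` (the
#'   `"coloc_partition"`), `labels`, `image` (the back-projection),
#'   `scatter` (data frame `row`, `col`, `x`, `y`, `segment`),
#'   `class_map`, `cell_mask` and the pre-processing `log`.
#' @export
run_coloc <- function(cube, model, config = pipeline_config(),
                      outdir = NULL) {
  seg <- segment_stage(cube, model, config)
  cn <- area_map(seg$pre$cube, config$cn_window)
  cc <- area_map(seg$pre$cube, config$cc_window)
  dna <- area_map(seg$pre$cube, config$dna_window)
  ref <- nuclear_reference(dna, seg$class_map_in_cell)
  cn_n <- normalize_map(cn, ref)
  cc_n <- normalize_map(cc, ref)
  pts <- coloc_points(cn_n, cc_n, seg$mask)
  geom <- coloc_partition(pts, t0_factor = config$t0_factor)
  labels <- partition_labels(pts, geom)
  img <- back_project(pts, labels)
  scatter <- cbind(pts$points, segment = labels)
  res <- list(points = pts, geometry = geom, labels = labels,
              image = img, scatter = scatter,
              class_map = seg$class_map, cell_mask = seg$mask,
              reference = ref, log = seg$pre$log)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(scatter, file.path(outdir, "scatter.tsv"))
    write_label_image(img, file.path(outdir, "coloc_labels.png"))
    manifest <- list(workflow = "coloc", seed = config$seed,
                     slope = geom$slope, t0 = geom$t0,
                     reference = ref, n_flagged = seg$pre$log$n_flagged)
    writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  }
  res
}
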