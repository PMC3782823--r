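#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end pipeline
#' (preprocess -> pectoral removal -> graph-cut segmentation -> density).
#' Defaults follow the printed study values where they exist (data cost
#' weight 10, smooth cost weight 20, downsample factor 4) and this
#' package's documented choices elsewhere.
#'
#' @param threshold_method `"otsu"` or `"fixed"` breast binarization.
#' @param threshold Fixed threshold when `threshold_method = "fixed"`.
#' @param opening_radius Disk radius of the morphological opening (full
#'   resolution pixels).
#' @param margin Crop margin around the breast bounding box, in pixels.
#' @param factor Downsampling factor.
#' @param median_kernel Odd median-filter window (1 disables).
#' @param side Chest-wall side: `"auto"`, `"left"` or `"right"`.
#' @param remove_pectoral Extract and remove the pectoral muscle.
#' @param pect_tolerance Region-growing tolerance, gray levels.
#' @param pect_inset Inward corner offset of the pectoral seed, pixels.
#' @param gc A [gc_params()] object.
#' @param include_mass Count mass pixels as dense tissue in the density.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_method = c("otsu", "fixed"),
                            threshold = NULL, opening_radius = 2, margin = 8,
                            factor = 4, median_kernel = 3,
                            side = c("auto", "left", "right"),
                            remove_pectoral = TRUE, pect_tolerance = 16,
                            pect_inset = 3, gc = gc_params(),
                            include_mass = TRUE) {
  structure(list(threshold_method = match.arg(threshold_method),
                 threshold = threshold, opening_radius = opening_radius,
                 margin = margin, factor = as.integer(factor),
                 median_kernel = as.integer(median_kernel),
                 side = match.arg(side), remove_pectoral = remove_pectoral,
                 pect_tolerance = pect_tolerance,
                 pect_inset = pect_inset, gc = gc,
                 include_mass = include_mass),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()] object.
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path)
  gc <- do.call(gc_params, x$gc)
  x$gc <- NULL
  do.call(pipeline_config, c(x, list(gc = gc)))
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$gc <- unclass(x$gc)
  x
}

#' Run the full pipeline
#'
#' Executes, in order: breast binarization, background artifact removal,
#' cropping, downsampling, median enhancement, orientation
#' (chest-wall-left), pectoral extraction and removal, seed-constrained
#' graph-cut segmentation, and density quantification. Seeds are supplied
#' in the source image frame and are mapped through crop, downsample and
#' flip automatically. Removed background and pectoral pixels are pinned
#' to the background label during segmentation; if no background seed
#' survives the crop, one is placed on an excluded pixel automatically.
#'
#' A rerun with identical inputs and configuration is bit-identical, and
#' when `out_dir` is given every artifact (intermediate images, label
#' maps, JSON report) is written there along with a `MANIFEST.json`
#' carrying an md5 content hash per file. If a stage fails, the error
#' names the stage and the partial manifest is marked incomplete.
#'
#' @param image Grayscale matrix (the source mammogram or phantom image).
#' @param seeds Seed data frame in source coordinates (1-based `row`,
#'   `col`, region-name `label`).
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `mammo_pipeline`: list with `labels` (label-id
#'   matrix in the processed frame), `image` (the preprocessed, oriented,
#'   pectoral-removed image the labels refer to), `density` (a `density_report`),
#'   `energy`, `segmentation`, `mask`, `pectoral_mask`, `offset`,
#'   `factor`, `flipped`, `side`, `seeds` (transformed), and `manifest`
#'   (when `out_dir` was given).
#' @export
run_pipeline <- function(image, seeds, config = pipeline_config(),
                         out_dir = NULL) {
  check_gray(image)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        write_manifest(out_dir, written, complete = FALSE,
                       failed_stage = name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    invisible(path)
  }

  mask <- stage("binarize", binarize_breast(image, config$threshold_method,
                                            config$threshold,
                                            config$opening_radius))
  clean <- stage("artifact_removal", remove_background_artifacts(image, mask))
  crop <- stage("crop", crop_to_breast(clean, mask, config$margin))
  img <- stage("downsample", downsample(crop$image, config$factor))
  msk <- downsample(crop$mask * 255L, config$factor)
  msk <- matrix((msk >= 128) * 1L, nrow(msk), ncol(msk))
  img <- stage("median", median_enhance(img, config$median_kernel))
  img[msk == 0] <- 0L                   # keep the background exactly black

  side <- if (config$side == "auto") detect_side(msk) else config$side
  ori <- stage("orient", orient_mlo(img, side))
  img <- ori$image
  if (ori$flipped) msk <- msk[, ncol(msk):1, drop = FALSE]

  sd_tr <- stage("seed_transform",
                 transform_seeds(seeds, crop$offset, dim(crop$image),
                                 config$factor, ori$flipped, dim(img)))
  if (!"background" %in% sd_tr$label) {
    bg <- which(msk == 0)[1]
    if (is.na(bg)) stop("no excluded pixel available for a background seed")
    sd_tr <- rbind(sd_tr,
                   data.frame(row = ((bg - 1) %% nrow(msk)) + 1L,
                              col = ((bg - 1) %/% nrow(msk)) + 1L,
                              label = "background", stringsAsFactors = FALSE))
  }

  if (config$remove_pectoral) {
    pseed <- stage("pectoral", pectoral_seed(msk, config$pect_inset))
    pect <- stage("pectoral", grow_pectoral(img, pseed,
                                            config$pect_tolerance))
    img <- stage("pectoral", remove_pectoral(img, pect))
  } else {
    pect <- matrix(0L, nrow(img), ncol(img))
  }

  fixed <- matrix(NA_integer_, nrow(img), ncol(img))
  fixed[msk == 0 | pect == 1] <- label_id("background")
  keep <- is.na(fixed[cbind(sd_tr$row, sd_tr$col)]) |
    sd_tr$label == "background"
  sd_tr <- sd_tr[keep, , drop = FALSE]  # drop seeds landing on pinned pixels

  seg <- stage("segment", gc_segment(img, sd_tr, config$gc, fixed = fixed))
  dens <- stage("density", density_percentage(seg$labels,
                                              config$include_mass))

  emit("preprocessed.pgm", function(p) write_gray(img, p))
  emit("breast_mask.pgm", function(p) write_pgm(msk, p))
  emit("pectoral_mask.pgm", function(p) write_pgm(pect, p))
  emit("labels.pgm", function(p) {
    ps <- write_labelmap(seg$labels, p)
    written <<- c(written, ps$legend)
  })
  emit("labels.png", function(p) write_label_png(seg$labels, p))
  emit("seeds.csv", function(p) write_seeds(sd_tr, p))
  emit("config.json", function(p) write_pipeline_config(config, p))
  emit("report.json", function(p)
    jsonlite::write_json(list(density = unclass(dens),
                              energy = seg$energy, sweeps = seg$sweeps,
                              side = side, flipped = ori$flipped,
                              offset = as.list(crop$offset),
                              factor = config$factor),
                         p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
  manifest <- if (!is.null(out_dir))
    write_manifest(out_dir, written, complete = TRUE)

  structure(list(labels = seg$labels, density = dens, energy = seg$energy,
                 segmentation = seg, image = img, mask = msk,
                 pectoral_mask = pect,
                 offset = crop$offset, factor = config$factor,
                 flipped = ori$flipped, side = side, seeds = sd_tr,
                 manifest = manifest),
            class = "mammo_pipeline")
}

#' @export
print.mammo_pipeline <- function(x, ...) {
  cat("mammogram pipeline run (side:", x$side,
      if (x$flipped) "flipped" else "", ")\n")
  print(x$density)
  invisible(x)
}

# map source-frame seeds through crop, downsample and flip; seeds falling
# outside the crop are dropped
transform_seeds <- function(seeds, offset, crop_dim, factor, flipped,
                            out_dim) {
  s <- seeds
  s$row <- s$row - offset[["row"]] + 1L
  s$col <- s$col - offset[["col"]] + 1L
  s <- s[s$row >= 1 & s$row <= crop_dim[1] &
           s$col >= 1 & s$col <= crop_dim[2], , drop = FALSE]
  if (nrow(s) == 0) stop("no seeds remain inside the cropped region")
  s$row <- (s$row - 1L) %/% factor + 1L
  s$col <- (s$col - 1L) %/% factor + 1L
  if (flipped) s$col <- out_dim[2] - s$col + 1L
  key <- paste(s$row, s$col)
  conflict <- tapply(s$label, key, function(v) length(unique(v)) > 1)
  if (any(conflict))
    stop("seeds of different labels collide after downsampling; ",
         "thin the seed set or lower the factor")
  s[!duplicated(key), c("row", "col", "label"), drop = FALSE]
}

write_manifest <- function(out_dir, files, complete, failed_stage = NULL) {
  files <- unique(files)
  entries <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  manifest <- list(complete = complete, artifacts = entries)
  if (!is.null(failed_stage)) manifest$failed_stage <- failed_stage
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
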