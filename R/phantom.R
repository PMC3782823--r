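#' Specify a synthetic MLO phantom
#'
#' A phantom is a geometric stand-in for a mediolateral-oblique mammogram:
#' a half-ellipse breast attached to the chest-wall border, with a thin
#' skin-air band, an uncompressed-fat band, a compressed-fat interior, a
#' central glandular blob, an optional hyperdense mass disk inside the
#' glandular region, an optional pectoral right-triangle at the top
#' chest-wall corner, and an optional bright rectangular label artifact in
#' the background. Each region has a constant mean intensity; additive
#' Gaussian noise (clipped to 0..255, rounded to integers) is layered on
#' top. The exact per-pixel ground-truth label map accompanies the image.
#'
#' Region mean intensities must be strictly ordered
#' `background < skin_air < uncompressed_fat < compressed_fat < glandular
#' < mass`, with `pectoral >= glandular`, mirroring the radiodensity
#' ordering in real mammograms.
#'
#' @param height,width Image dimensions in pixels (each at least 32).
#' @param side Which vertical border the chest wall touches: `"left"` or
#'   `"right"`.
#' @param means Named numeric vector of per-region mean intensities
#'   (0..255). Must contain the five core regions; `mass` is required iff
#'   `has_mass`, `pectoral` iff `has_pectoral`.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   gray levels (>= 0).
#' @param has_mass Include a mass disk inside the glandular blob.
#' @param mass_center Optional `(row, col)` of the mass centre (1-based, in
#'   the chest-wall-left frame); defaults to the glandular centre.
#' @param mass_radius Mass disk radius in pixels; defaults to
#'   `round(0.10 * min(height, width))`.
#' @param has_pectoral Include the pectoral triangle.
#' @param has_artifact Include a bright rectangular background artifact
#'   (exercises artifact removal).
#' @param artifact_intensity Gray level of the artifact (must be at least
#'   the glandular mean, as real film labels are radio-opaque).
#' @param rng_seed Integer seed making image noise reproducible.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(height = 128, width = 128, side = c("left", "right"),
                         means = c(background = 5, skin_air = 40,
                                   uncompressed_fat = 80, compressed_fat = 120,
                                   glandular = 180, mass = 220, pectoral = 200),
                         noise_sd = 5, has_mass = TRUE, mass_center = NULL,
                         mass_radius = NULL, has_pectoral = TRUE,
                         has_artifact = TRUE, artifact_intensity = 230,
                         rng_seed = 1L) {
  side <- match.arg(side)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 32 || width < 32) stop("phantom dimensions must be >= 32x32")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  core <- c("background", "skin_air", "uncompressed_fat", "compressed_fat",
            "glandular")
  need <- c(core, if (has_mass) "mass", if (has_pectoral) "pectoral")
  missing <- setdiff(need, names(means))
  if (length(missing) > 0)
    stop("means missing for region(s): ", paste(missing, collapse = ", "))
  means <- means[need]
  if (any(means < 0 | means > 255)) stop("region means must lie in [0, 255]")
  ord <- means[c(core, if (has_mass) "mass")]
  if (any(diff(ord) <= 0))
    stop("region means must be strictly ordered: background < skin_air < ",
         "uncompressed_fat < compressed_fat < glandular",
         if (has_mass) " < mass")
  if (has_pectoral && means[["pectoral"]] < means[["glandular"]])
    stop("pectoral mean must be >= glandular mean")
  if (has_artifact && artifact_intensity < means[["glandular"]])
    stop("artifact_intensity must be >= glandular mean")

  if (is.null(mass_radius)) mass_radius <- round(0.10 * min(height, width))
  if (is.null(mass_center))
    mass_center <- c(round((height + 1) / 2), 1 + round(0.22 * width))

  structure(list(height = height, width = width, side = side, means = means,
                 noise_sd = noise_sd, has_mass = has_mass,
                 mass_center = as.numeric(mass_center),
                 mass_radius = as.numeric(mass_radius),
                 has_pectoral = has_pectoral, has_artifact = has_artifact,
                 artifact_intensity = artifact_intensity,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a synthetic mammogram phantom
#'
#' Rasterizes the geometry described by a [phantom_spec()]: a pixel belongs
#' to a region when its centre lies inside the region's analytic shape, and
#' inner (later-drawn) regions override outer ones. The image is the
#' region-mean raster plus clipped, rounded Gaussian noise; the truth label
#' map records the exact region of every pixel (the background artifact,
#' being a non-anatomical film label, keeps the background truth label).
#' The same spec and `rng_seed` always reproduce bit-identical output.
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `phantom`: list with `image` (integer matrix),
#'   `truth` (integer label matrix), `legend` (named id vector of the labels
#'   in use) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64, noise_sd = 0))
#' table(label_name(ph$truth))
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  h <- spec$height; w <- spec$width
  r <- matrix(seq_len(h), h, w)          # pixel-centre row coordinates
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  cy <- (h + 1) / 2

  in_ellipse <- function(a, b) {
    a > 0 & b > 0 & ((r - cy) / a)^2 + ((cc - 1) / b)^2 <= 1
  }
  a0 <- 0.46 * h; b0 <- 0.72 * w         # outer breast half-ellipse
  skin_t <- 3; fat_t <- 6                # band thicknesses in pixels

  lab <- region_labels()
  truth <- matrix(lab[["background"]], h, w)
  truth[in_ellipse(a0, b0)] <- lab[["skin_air"]]
  truth[in_ellipse(a0 - skin_t, b0 - skin_t)] <- lab[["uncompressed_fat"]]
  truth[in_ellipse(a0 - skin_t - fat_t, b0 - skin_t - fat_t)] <-
    lab[["compressed_fat"]]
  gc_row <- cy; gc_col <- 1 + 0.22 * w   # glandular blob centre
  ga <- 0.24 * h; gb <- 0.30 * w
  gland <- ((r - gc_row) / ga)^2 + ((cc - gc_col) / gb)^2 <= 1
  truth[gland] <- lab[["glandular"]]

  if (spec$has_mass) {
    mc <- spec$mass_center; mr <- spec$mass_radius
    mass <- (r - mc[1])^2 + (cc - mc[2])^2 <= mr^2
    if (!any(mass)) stop("mass disk rasterizes to zero pixels")
    if (any(mass & !gland))
      stop("mass disk is not entirely inside the glandular region")
    truth[mass] <- lab[["mass"]]
  }
  if (spec$has_pectoral) {
    ph_ <- 0.42 * h; pw_ <- 0.30 * w
    pect <- (r - 1) / ph_ + (cc - 1) / pw_ <= 1
    truth[pect] <- lab[["pectoral"]]
  }

  image <- matrix(spec$means[label_name(truth)], h, w)
  if (spec$has_artifact) {
    ar <- max(1, floor(0.05 * h)):floor(0.16 * h)
    ac <- floor(0.82 * w):floor(0.95 * w)
    if (any(truth[ar, ac] != lab[["background"]]))
      stop("artifact rectangle overlaps the breast")
    image[ar, ac] <- spec$artifact_intensity   # truth stays background
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$rng_seed,
                       matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    image <- image + noise
  }
  image <- matrix(as.integer(pmin(255, pmax(0, round(image)))), h, w)

  if (spec$side == "right") {            # mirror so the chest wall is right
    image <- image[, w:1, drop = FALSE]
    truth <- truth[, w:1, drop = FALSE]
  }
  present <- sort(unique(as.integer(truth)))
  structure(list(image = image,
                 truth = matrix(as.integer(truth), h, w),
                 legend = stats::setNames(present, label_name(present)),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("MLO phantom", nrow(x$image), "x", ncol(x$image),
      "(side:", x$spec$side, ")\n")
  cat("regions:", paste(names(x$legend), collapse = ", "), "\n")
  cat("noise sd:", x$spec$noise_sd, " rng seed:", x$spec$rng_seed, "\n")
  invisible(x)
}

#' Sample seed pixels from a truth label map
#'
#' Draws `per_label` pixels uniformly at random from each requested region
#' of a ground-truth label map, for use as graph-cut hard constraints. This
#' emulates a reader clicking a few representative points per region.
#'
#' @param truth Integer label matrix (e.g. `phantom$truth`).
#' @param per_label Seeds per region.
#' @param labels Region names to seed; defaults to every label present
#'   except `pectoral` (which is removed before segmentation).
#' @param rng_seed Integer seed for reproducible sampling.
#' @return Seed data frame with 1-based `row`, `col`, `label`.
#' @export
sample_seeds <- function(truth, per_label = 3, labels = NULL, rng_seed = 1L) {
  present <- label_name(sort(unique(as.integer(truth))))
  if (is.null(labels)) labels <- setdiff(present, "pectoral")
  missing <- setdiff(labels, present)
  if (length(missing) > 0)
    stop("truth has no pixels for region(s): ", paste(missing, collapse = ", "))
  with_seed(rng_seed, {
    out <- lapply(labels, function(nm) {
      idx <- which(truth == label_id(nm))
      pick <- idx[sample.int(length(idx), min(per_label, length(idx)))]
      data.frame(row = ((pick - 1) %% nrow(truth)) + 1L,
                 col = ((pick - 1) %/% nrow(truth)) + 1L,
                 label = nm, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
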