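#' Separate the breast profile from the background
#'
#' Thresholds the image globally (Otsu's criterion by default), cleans the
#' foreground with a morphological opening, and keeps only the largest
#' 8-connected foreground component. Film labels, opaque markers and
#' scanning artifacts are bright but disconnected from the breast, so the
#' largest-component rule removes them.
#'
#' The Otsu threshold is computed on the log-intensity histogram
#' (`log(1 + I)`). Mammographic foregrounds are strongly multimodal (fat,
#' glandular tissue and pectoral muscle are far apart in intensity), and
#' on a linear histogram the maximum-variance split can land between
#' tissue classes inside the breast; the log transform compresses the
#' bright modes so the dominant gap -- dark background versus everything
#' else -- wins. The returned threshold operates on raw intensities.
#'
#' @param image Grayscale matrix (0..255).
#' @param method `"otsu"` for an automatic global threshold, or `"fixed"`
#'   to use `threshold`.
#' @param threshold Fixed global threshold (foreground is strictly above
#'   it); required when `method = "fixed"`.
#' @param opening_radius Radius in pixels of the disk structuring element
#'   used for the opening; `0` skips the opening. The image is padded by
#'   edge replication for the opening, so the breast is not eroded where
#'   it touches the image border.
#' @return Binary mask matrix (1 = breast) of the same shape.
#' @export
binarize_breast <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, opening_radius = 2) {
  check_gray(image)
  method <- match.arg(method)
  if (method == "otsu") {
    lg <- log1p(image) / log1p(255)
    tlog <- EBImage::otsu(EBImage::Image(t(lg)), range = c(0, 1),
                          levels = 256)
    threshold <- expm1(tlog * log1p(255))
  } else if (is.null(threshold)) {
    stop("method = \"fixed\" requires a threshold")
  }
  mask <- (image > threshold) * 1L
  if (!any(mask == 1)) stop("no breast found: no foreground after threshold")
  if (opening_radius > 0) {
    k <- as.integer(opening_radius)
    h <- nrow(mask); w <- ncol(mask)
    ridx <- pmin(pmax(seq(1 - k, h + k), 1), h)   # replicate-pad borders
    cidx <- pmin(pmax(seq(1 - k, w + k), 1), w)
    brush <- EBImage::makeBrush(2L * k + 1L, "disc")
    op <- t(EBImage::imageData(
      EBImage::opening(EBImage::Image(t(mask[ridx, cidx])), brush)))
    mask <- op[k + seq_len(h), k + seq_len(w)]
  }
  if (!any(mask == 1)) stop("no breast found: opening removed all foreground")
  comp <- label_components8(mask)
  sizes <- tabulate(comp[comp > 0])
  keep <- which.max(sizes)
  matrix((comp == keep) * 1L, nrow(image), ncol(image))
}

# 8-connected component labeling of a binary mask (EBImage's bwlabel is
# 4-connected); components found via igraph on the pixel adjacency graph
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1)
  if (length(fg) == 0) return(matrix(0L, h, w))
  pr <- neighbor_pairs(h, w, 8L)
  keep <- mask[pr$i] == 1 & mask[pr$j] == 1
  vid <- integer(h * w); vid[fg] <- seq_along(fg)
  g <- igraph::graph_from_edgelist(cbind(vid[pr$i[keep]], vid[pr$j[keep]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, h, w)
  out[fg] <- as.integer(memb)
  out
}

#' Blank everything outside the breast mask
#'
#' Background noise and artifacts are replaced by black pixels; pixels
#' inside the mask are left untouched (exact equality).
#'
#' @param image Grayscale matrix.
#' @param mask Binary breast mask of the same shape.
#' @return Grayscale matrix with the background zeroed.
#' @export
remove_background_artifacts <- function(image, mask) {
  check_gray(image)
  check_mask(mask, image)
  out <- image
  out[mask == 0] <- 0L
  out
}

#' Crop to the breast region of interest
#'
#' Takes the tight bounding box of the mask, dilates it by `margin` pixels
#' and clips to the image. The crop offset is recorded so downstream
#' results can be mapped back into source coordinates.
#'
#' @param image Grayscale matrix.
#' @param mask Binary mask with at least one foreground pixel.
#' @param margin Extra pixels to keep on every side of the tight box.
#' @return List with `image` (the crop), `mask` (cropped mask), `offset`
#'   (1-based row/col of the crop origin in the source) and `bbox`
#'   (`row0, col0, row1, col1`, half-open, 0-based).
#' @export
crop_to_breast <- function(image, mask, margin = 0) {
  check_gray(image)
  check_mask(mask, image)
  if (!any(mask == 1)) stop("cannot crop: mask is empty")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  margin <- as.integer(margin)
  r0 <- max(1L, rows[1] - margin); r1 <- min(nrow(image), rows[2] + margin)
  c0 <- max(1L, cols[1] - margin); c1 <- min(ncol(image), cols[2] + margin)
  list(image = image[r0:r1, c0:c1, drop = FALSE],
       mask = mask[r0:r1, c0:c1, drop = FALSE],
       offset = c(row = r0, col = c0),
       bbox = c(row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1))
}

#' Downsample by block averaging
#'
#' Each output pixel is the mean of its `factor x factor` source block,
#' rounded half-up to an integer gray level; partial blocks at the bottom
#' and right edges are averaged over the pixels available. Output
#' dimensions are `ceiling(dim / factor)`.
#'
#' @param image Grayscale matrix.
#' @param factor Integer reduction factor (>= 1); 4 is the conventional
#'   choice for digitized film mammograms.
#' @return Downsampled grayscale matrix.
#' @export
downsample <- function(image, factor = 4) {
  check_gray(image)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be an integer >= 1")
  if (factor == 1) return(image)
  gr <- (seq_len(nrow(image)) - 1L) %/% factor + 1L
  gc_ <- (seq_len(ncol(image)) - 1L) %/% factor + 1L
  sums <- rowsum(image, gr)             # collapse rows
  sums <- t(rowsum(t(sums), gc_))       # collapse cols
  cnt <- outer(tabulate(gr), tabulate(gc_))
  matrix(as.integer(floor(sums / cnt + 0.5)), nrow(sums), ncol(sums))
}

#' Median-filter enhancement
#'
#' Replaces every pixel by the median of its `kernel x kernel` window,
#' suppressing impulse noise (speckle, scratches) while preserving edges.
#' Image borders are handled by edge replication.
#'
#' @param image Grayscale matrix.
#' @param kernel Odd window size (>= 1).
#' @return Filtered grayscale matrix.
#' @export
median_enhance <- function(image, kernel = 3) {
  check_gray(image)
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1 || kernel %% 2 == 0)
    stop("kernel must be an odd integer >= 1")
  if (kernel == 1) return(image)
  k <- kernel %/% 2
  h <- nrow(image); w <- ncol(image)
  ridx <- pmin(pmax(seq(1 - k, h + k), 1), h)   # edge replication
  cidx <- pmin(pmax(seq(1 - k, w + k), 1), w)
  pad <- image[ridx, cidx, drop = FALSE]
  windows <- array(0, c(h, w, kernel * kernel))
  s <- 0L
  for (dr in 0:(kernel - 1)) for (dc in 0:(kernel - 1)) {
    s <- s + 1L
    windows[, , s] <- pad[dr + seq_len(h), dc + seq_len(w)]
  }
  matrix(as.integer(apply(windows, c(1, 2), stats::median)), h, w)
}
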