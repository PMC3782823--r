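#' Detect the chest-wall side of an MLO image
#'
#' In an MLO view the breast (and the pectoral muscle) touch one vertical
#' image border. The side whose border column contains more foreground
#' pixels is taken to be the chest-wall side; ties resolve to left.
#'
#' @param mask Binary breast mask.
#' @return `"left"` or `"right"`.
#' @export
detect_side <- function(mask) {
  check_mask(mask)
  if (!any(mask == 1)) stop("cannot detect side: mask is empty")
  if (sum(mask[, ncol(mask)]) > sum(mask[, 1])) "right" else "left"
}

#' Normalize MLO orientation
#'
#' Orients the image so the chest wall -- and with it the pectoral muscle
#' -- sits at the left border, the convention every later stage assumes.
#' An image whose chest wall is already left passes through unchanged; a
#' chest-wall-right image is flipped by exact column reversal. Flipping
#' twice restores the original exactly, and the `flipped` flag lets
#' results be mapped back to source coordinates.
#'
#' @param image Grayscale matrix.
#' @param side Chest-wall side of the input (`"left"` or `"right"`),
#'   e.g. from [detect_side()].
#' @return List with `image` (chest wall at left), `flipped` (TRUE iff a
#'   column reversal was applied) and `side` (the input side).
#' @export
orient_mlo <- function(image, side = c("left", "right")) {
  side <- match.arg(side)
  flipped <- side == "right"
  if (flipped) image <- image[, ncol(image):1, drop = FALSE]
  list(image = image, flipped = flipped, side = side)
}

#' Place the pectoral region-growing seed
#'
#' The pectoral muscle occupies the top chest-wall corner of an oriented
#' MLO image, so the seed is the foreground pixel nearest to the top-left
#' corner offset inward by a few pixels.
#'
#' @param mask Binary breast mask of the oriented image.
#' @param inset Inward offset from the corner, in pixels.
#' @return `(row, col)` integer vector (1-based).
#' @export
pectoral_seed <- function(mask, inset = 3) {
  check_mask(mask)
  fg <- which(mask == 1)
  if (length(fg) == 0) stop("cannot place pectoral seed: mask is empty")
  rr <- ((fg - 1) %% nrow(mask)) + 1L
  cc <- ((fg - 1) %/% nrow(mask)) + 1L
  target <- inset + 1
  best <- which.min((rr - target)^2 + (cc - target)^2)
  c(row = rr[best], col = cc[best])
}

#' Extract the pectoral muscle by seeded region growing
#'
#' Grows a 4-connected region from the seed by breadth-first search. A
#' frontier pixel is admitted when its intensity differs from the current
#' region mean by at most `tolerance` gray levels; the mean is updated
#' incrementally as pixels are admitted, in BFS order. 4-connectivity is
#' used because 8-connected growth leaks across thin diagonal boundaries.
#'
#' @param image Grayscale matrix (oriented, background removed).
#' @param seed `(row, col)` seed position (1-based), on a nonzero pixel.
#' @param tolerance Homogeneity tolerance in gray levels.
#' @return Binary mask of the grown region (always 4-connected, always
#'   containing the seed).
#' @export
grow_pectoral <- function(image, seed, tolerance = 16) {
  check_gray(image)
  h <- nrow(image); w <- ncol(image)
  sr <- as.integer(seed[1]); sc <- as.integer(seed[2])
  if (is.na(sr) || is.na(sc) || sr < 1 || sr > h || sc < 1 || sc > w)
    stop("seed out of image bounds")
  if (image[sr, sc] == 0)
    stop("seed lies on a removed-background (zero) pixel")
  if (tolerance < 0) stop("tolerance must be >= 0")

  start <- (sc - 1L) * h + sr           # linear index, column-major
  inreg <- logical(h * w)
  inreg[start] <- TRUE
  queue <- integer(h * w)
  queue[1] <- start
  head <- 1L; tail <- 1L
  total <- as.numeric(image[start]); nreg <- 1L
  repeat {
    if (head > tail) break
    p <- queue[head]; head <- head + 1L
    pr <- ((p - 1L) %% h) + 1L
    pc <- ((p - 1L) %/% h) + 1L
    for (nb in c(if (pr > 1) p - 1L, if (pr < h) p + 1L,
                 if (pc > 1) p - h, if (pc < w) p + h)) {
      if (!inreg[nb] && abs(image[nb] - total / nreg) <= tolerance) {
        inreg[nb] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nb
        total <- total + image[nb]
        nreg <- nreg + 1L
      }
    }
  }
  matrix(as.integer(inreg), h, w)
}

#' Remove the pectoral muscle
#'
#' Sets pectoral pixels to 0 so they join the excluded background: they
#' take no part in the graph-cut segmentation and never enter the
#' breast-area denominator of the density percentage.
#'
#' @param image Grayscale matrix.
#' @param pect Binary pectoral mask of the same shape.
#' @return Grayscale matrix with the pectoral region blacked out.
#' @export
remove_pectoral <- function(image, pect) {
  check_gray(image)
  check_mask(pect, image, arg = "pect")
  out <- image
  out[pect == 1] <- 0L
  out
}
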