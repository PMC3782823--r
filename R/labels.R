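#' Anatomical region labels
#'
#' The segmentation works over a fixed scheme of anatomical regions. Integer
#' ids are stable so that label maps written to disk are self-describing
#' together with their JSON legend. Ids 0--5 are the segmentation scheme
#' (between 3 and 6 of them are in use for any one segmentation); id 6
#' (`pectoral`) occurs only in phantom ground truth, because the pectoral
#' muscle is removed before segmentation and its pixels join the background.
#'
#' @return Named integer vector mapping region name to label id.
#' @export
#' @examples
#' region_labels()
region_labels <- function() {
  c(background = 0L, skin_air = 1L, uncompressed_fat = 2L,
    compressed_fat = 3L, glandular = 4L, mass = 5L, pectoral = 6L)
}

#' Look up label ids by region name
#'
#' @param names Character vector of region names.
#' @return Integer vector of label ids.
#' @export
label_id <- function(names) {
  lab <- region_labels()
  bad <- setdiff(names, names(lab))
  if (length(bad) > 0)
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  unname(lab[names])
}

#' Look up region names by label id
#'
#' @param ids Integer vector of label ids.
#' @return Character vector of region names.
#' @export
label_name <- function(ids) {
  lab <- region_labels()
  idx <- match(as.integer(ids), unname(lab))
  if (anyNA(idx)) stop("unknown label id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  names(lab)[idx]
}

#' Fixed display palette for label maps
#'
#' One RGB colour per region, used when a label map is written as a colour
#' PNG. Background is black; dense tissue and mass are warm colours so the
#' regions of clinical interest stand out.
#'
#' @return Named character vector of hex colours, one per region.
#' @export
label_palette <- function() {
  c(background = "#000000", skin_air = "#4363d8", uncompressed_fat = "#3cb44b",
    compressed_fat = "#9a6324", glandular = "#f58231", mass = "#e6194b",
    pectoral = "#911eb4")
}

# internal: validate that a matrix is an 8-bit grayscale image
check_gray <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(arg, " must be a numeric matrix")
  if (length(image) == 0) stop(arg, " must be nonempty")
  if (any(image < 0 | image > 255)) stop(arg, " values must lie in [0, 255]")
  invisible(image)
}

# internal: validate a binary mask against an image shape
check_mask <- function(mask, image = NULL, arg = "mask") {
  if (!is.matrix(mask)) stop(arg, " must be a matrix")
  if (!all(mask %in% c(0, 1))) stop(arg, " must contain only 0/1")
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop(arg, " shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(image), collapse = "x"))
  invisible(mask)
}
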