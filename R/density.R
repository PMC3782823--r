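#' Breast-density percentage from a label map
#'
#' Density is the dense (glandular) fraction of the breast:
#' `100 * glandular_pixels / breast_pixels`. The breast region is every
#' pixel not carrying an excluded label: the skin-air interface and both
#' fat layers count as breast, while background -- and the pectoral
#' muscle, removed upstream -- do not. A mass, being hyperdense tissue
#' embedded in the glandular region, counts as dense by default.
#'
#' @param labels Integer matrix of region label ids.
#' @param include_mass Count mass pixels as dense tissue.
#' @param exclude_labels Region names excluded from the breast region.
#' @return Object of class `density_report`: list with `glandular_pixels`,
#'   `breast_pixels`, `percentage`, `birads_category` and
#'   `birads_estimate` (the raw linear-model output, see
#'   [estimate_birads()]).
#' @export
#' @examples
#' m <- matrix(label_id("compressed_fat"), 10, 10)
#' m[1:5, 1:5] <- label_id("glandular")
#' density_percentage(m)$percentage  # 25
density_percentage <- function(labels, include_mass = TRUE,
                               exclude_labels = c("background", "pectoral")) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  label_name(unique(as.integer(labels)))  # validates scheme membership
  breast <- !(labels %in% label_id(exclude_labels))
  nb <- sum(breast)
  if (nb == 0) stop("breast region is empty")
  dense_ids <- label_id(c("glandular", if (include_mass) "mass"))
  ng <- sum(labels %in% dense_ids)
  pct <- 100 * ng / nb
  structure(list(glandular_pixels = ng, breast_pixels = nb,
                 percentage = pct,
                 birads_category = birads_category(pct),
                 birads_estimate = estimate_birads(pct)),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("breast density: %.2f%% (%d / %d pixels)\n",
              x$percentage, x$glandular_pixels, x$breast_pixels))
  cat(sprintf("BIRADS category: %d (threshold table); %.3f (linear model)\n",
              x$birads_category, x$birads_estimate))
  invisible(x)
}

#' BIRADS density category from a percentage
#'
#' The four-category scheme of the American College of Radiology:
#' 1 predominantly fat (up to 25% fibroglandular content);
#' 2 fat with some fibroglandular tissue (25--50%);
#' 3 heterogeneously dense (50--75%);
#' 4 extremely dense (above 75%).
#' Boundaries are half-open upward: exactly 25 maps to 1, exactly 50 to 2,
#' exactly 75 to 3.
#'
#' @param percentage Density percentage in 0..100 (vectorized).
#' @return Integer category 1..4.
#' @export
#' @examples
#' birads_category(c(10, 30, 60, 80))  # 1 2 3 4
birads_category <- function(percentage) {
  if (any(is.na(percentage) | percentage < 0 | percentage > 100))
    stop("percentage must lie in [0, 100]")
  ifelse(percentage <= 25, 1L,
         ifelse(percentage <= 50, 2L,
                ifelse(percentage <= 75, 3L, 4L)))
}

#' Linear BIRADS estimate from a density percentage
#'
#' When the breast region includes the low-contrast skin-air band the
#' computed density percentage runs systematically lower than the BIRADS
#' category implies, so a linear calibration maps percentage to an
#' estimated category: `y = 1.327 + 0.040 * x`. The raw (unclipped,
#' unrounded) value is returned; set `round = TRUE` for a convenience
#' integer category (nearest integer, clipped to 1..4), which is a derived
#' convention rather than part of the fitted model.
#'
#' @param percentage Density percentage in 0..100 (vectorized).
#' @param round Return the nearest integer category clipped to 1..4.
#' @return Numeric estimate (or integer category when `round = TRUE`).
#' @export
#' @examples
#' estimate_birads(0)    # 1.327, the model intercept
#' estimate_birads(25)   # 2.327
estimate_birads <- function(percentage, round = FALSE) {
  if (any(is.na(percentage) | percentage < 0 | percentage > 100))
    stop("percentage must lie in [0, 100]")
  y <- 1.327 + 0.040 * percentage
  if (round) as.integer(pmin(4, pmax(1, round(y)))) else y
}
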