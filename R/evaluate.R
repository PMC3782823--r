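#' Pixel-wise confusion counts
#'
#' 2x2 contingency of a predicted binary mask against ground truth: TP are
#' pixels segmented as dense/mass that are dense in the truth, FP are
#' segmented-dense pixels that are other tissue in the truth, FN are
#' missed truth-dense pixels, TN the rest.
#'
#' @param pred,truth Binary masks of identical shape.
#' @return Named integer vector `TP`, `FP`, `FN`, `TN` (summing to the
#'   number of pixels).
#' @export
confusion <- function(pred, truth) {
  check_mask(pred, arg = "pred")
  check_mask(truth, arg = "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  c(TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    FN = sum(pred == 0 & truth == 1),
    TN = sum(pred == 0 & truth == 0))
}

#' Completeness, correctness and quality
#'
#' Region-overlap metrics of a segmentation against ground truth:
#' completeness `CM = TP / (TP + FN)` (how much of the truth region is
#' recovered), correctness `CR = TP / (TP + FP)` (how much of the
#' segmented region is right), and the combined quality
#' `rho = TP / (TP + FP + FN)`. The optimum of all three is 1.
#'
#' Degenerate denominators: if both the truth and the prediction are empty
#' (TP+FN = 0 and TP+FP = 0) all three metrics are 1 (perfect agreement on
#' emptiness); if exactly one of the two is empty, the metric with the
#' zero denominator is 0.
#'
#' @param counts Named vector with `TP`, `FP`, `FN` (e.g. from
#'   [confusion()]).
#' @return Named numeric vector `completeness`, `correctness`, `quality`,
#'   each in 0..1 with `quality <= min(completeness, correctness)`.
#' @export
#' @examples
#' overlap_metrics(c(TP = 8, FP = 2, FN = 2))
overlap_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0 && tp + fp == 0)
    return(c(completeness = 1, correctness = 1, quality = 1))
  cm <- if (tp + fn == 0) 0 else tp / (tp + fn)
  cr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  q <- tp / (tp + fp + fn)
  c(completeness = cm, correctness = cr, quality = q)
}

#' Binarize the dense-tissue class of a label map
#'
#' The positive class for evaluation is the union of the glandular label
#' and (by default) the mass label, matching the evaluation of
#' "glandular tissue/mass" as a single dense class.
#'
#' @param labels Integer matrix of region label ids.
#' @param include_mass Include the mass label in the positive class.
#' @return Binary mask matrix.
#' @export
dense_mask <- function(labels, include_mass = TRUE) {
  ids <- label_id(c("glandular", if (include_mass) "mass"))
  matrix((labels %in% ids) * 1L, nrow(labels), ncol(labels))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two numeric vectors, used to compare
#' computed density percentages against reference (ground-truth) density
#' percentages across a set of images.
#'
#' @param xs,ys Numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return Correlation in -1..1.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 2) stop("need at least 2 observations")
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(xs, ys, method = "pearson")
}

#' Batch evaluation with per-group means
#'
#' Evaluates a list of cases (predicted label map or binary mask, truth
#' dense mask, breast-type tag) and reports per-case confusion counts and
#' metrics plus unweighted per-group and overall means, the customary
#' reporting for fatty / fatty-glandular / dense-glandular image sets.
#'
#' @param cases List of lists with elements `pred` (label matrix or binary
#'   mask), `truth` (binary mask), `group` (tag) and optionally `image`
#'   (an identifier).
#' @param include_mass Include the mass label in the positive class when
#'   `pred` is a label map.
#' @return Data frame with one row per case plus one summary row per group
#'   and an overall row (`image == "<mean>"`).
#' @export
batch_evaluate <- function(cases, include_mass = TRUE) {
  if (length(cases) == 0) stop("no cases to evaluate")
  rows <- lapply(seq_along(cases), function(k) {
    cs <- cases[[k]]
    pred <- cs$pred
    if (!all(pred %in% c(0, 1))) pred <- dense_mask(pred, include_mass)
    cnt <- confusion(pred, cs$truth)
    met <- overlap_metrics(cnt)
    data.frame(image = if (is.null(cs$image)) paste0("case", k) else cs$image,
               group = as.character(cs$group),
               TP = cnt[["TP"]], FP = cnt[["FP"]],
               FN = cnt[["FN"]], TN = cnt[["TN"]],
               completeness = met[["completeness"]],
               correctness = met[["correctness"]],
               quality = met[["quality"]],
               stringsAsFactors = FALSE)
  })
  percase <- do.call(rbind, rows)
  groups <- unique(percase$group)
  summarize <- function(df, tag) {
    data.frame(image = "<mean>", group = tag, TP = NA, FP = NA, FN = NA,
               TN = NA,
               completeness = mean(df$completeness),
               correctness = mean(df$correctness),
               quality = mean(df$quality), stringsAsFactors = FALSE)
  }
  means <- do.call(rbind, lapply(groups, function(g)
    summarize(percase[percase$group == g, ], g)))
  rbind(percase, means, summarize(percase, "overall"))
}
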