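#' Graph-cut segmentation parameters
#'
#' Parameters of the Potts energy
#' `E(L) = lambda * sum_p D_p(L_p) + mu * sum_{p,q in N} V_pq * [L_p != L_q]`
#' minimized by the segmentation. `D_p` is the negative log-likelihood of
#' the pixel intensity under the label's seed-derived histogram model;
#' `V_pq` is a contrast-sensitive boundary weight.
#'
#' @param lambda Data-cost weight (>= 0). Default 10.
#' @param mu Smooth-cost weight (>= 0). Default 20.
#' @param neighborhood Pixel adjacency: 4 or 8 neighbors. Default 8.
#' @param sigma Boundary contrast scale, in gray levels (> 0): intensity
#'   steps much larger than `sigma` cost little to cut. Default 10.
#' @param hard_cost Large finite data cost charged when a seeded pixel is
#'   assigned a non-seed label; must dominate any achievable energy.
#' @param epsilon Likelihood floor applied to histogram bins so the data
#'   cost stays finite at intensities unseen among the seeds.
#' @param max_sweeps Maximum number of full expansion sweeps.
#' @return An object of class `gc_params`.
#' @export
gc_params <- function(lambda = 10, mu = 20, neighborhood = 8, sigma = 10,
                      hard_cost = 1e9, epsilon = 1e-6, max_sweeps = 10) {
  if (lambda < 0 || mu < 0) stop("lambda and mu must be >= 0")
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  if (sigma <= 0) stop("sigma must be > 0")
  if (epsilon <= 0 || epsilon >= 1 / 256) stop("epsilon must be in (0, 1/256)")
  if (hard_cost < 1e6)
    stop("hard_cost must be large enough to dominate any finite energy")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  structure(list(lambda = lambda, mu = mu,
                 neighborhood = as.integer(neighborhood), sigma = sigma,
                 hard_cost = hard_cost, epsilon = epsilon,
                 max_sweeps = as.integer(max_sweeps)),
            class = "gc_params")
}

#' Estimate per-label intensity models from seeds
#'
#' Each label's likelihood is the normalized 256-bin histogram of its seed
#' pixels' intensities, floored at `params$epsilon` and renormalized so
#' every bin stays strictly positive (the data cost `-log p` then stays
#' finite everywhere). Histograms make no parametric assumption and are
#' exactly reproducible.
#'
#' @param image Grayscale matrix.
#' @param seeds Seed data frame (`row`, `col`, `label`, 1-based).
#' @param params A [gc_params()] object.
#' @param labels Optional character vector of labels that must be in use;
#'   any of them lacking a seed is an error.
#' @return Named list (by region name) of length-256 probability vectors.
#' @export
estimate_label_models <- function(image, seeds, params = gc_params(),
                                  labels = NULL) {
  check_gray(image)
  seeds <- check_seeds(seeds, dim(image))
  if (is.null(labels)) labels <- unique(seeds$label)
  unseeded <- setdiff(labels, seeds$label)
  if (length(unseeded) > 0)
    stop("unseeded label(s): ", paste(unseeded, collapse = ", "))
  labels <- labels[order(label_id(labels))]
  models <- lapply(labels, function(nm) {
    px <- image[cbind(seeds$row, seeds$col)][seeds$label == nm]
    hist <- tabulate(px + 1L, nbins = 256L)
    hist <- hist / sum(hist)
    hist <- pmax(hist, params$epsilon)
    hist / sum(hist)
  })
  stats::setNames(models, labels)
}

#' Data cost of assigning a label to an intensity
#'
#' `-log` of the label model's probability at that intensity. Seed
#' overrides (cost 0 for the seeded label, `hard_cost` otherwise) are
#' applied inside [gc_segment()], not here.
#'
#' @param models Output of [estimate_label_models()].
#' @param intensity Integer intensity vector (0..255).
#' @param label Region name.
#' @return Numeric vector of costs.
#' @export
data_cost <- function(models, intensity, label) {
  if (!label %in% names(models)) stop("no model for label: ", label)
  -log(models[[label]][as.integer(intensity) + 1L])
}

#' Contrast-sensitive boundary weight
#'
#' `V_pq = exp(-(ip - iq)^2 / (2 sigma^2)) / dist`: label discontinuities
#' are cheap across strong intensity edges and expensive inside
#' homogeneous regions; diagonal neighbor interactions are attenuated by
#' their `sqrt(2)` spacing.
#'
#' @param ip,iq Neighboring pixel intensities.
#' @param dist Pixel-centre distance (1 for axial, `sqrt(2)` for diagonal
#'   neighbors).
#' @param params A [gc_params()] object.
#' @return Numeric weight(s) in (0, 1].
#' @export
smooth_weight <- function(ip, iq, dist = 1, params = gc_params()) {
  exp(-(ip - iq)^2 / (2 * params$sigma^2)) / dist
}

#' Neighbor pairs of a pixel grid
#'
#' Enumerates each unordered neighbor pair once, as column-major linear
#' indices, with the pixel-centre distance.
#'
#' @param h,w Grid dimensions.
#' @param neighborhood 4 or 8.
#' @return List with integer vectors `i`, `j` and numeric `dist`.
#' @export
neighbor_pairs <- function(h, w, neighborhood = 8) {
  idx <- seq_len(h * w)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  right <- idx[cc < w]
  down <- idx[r < h]
  i <- c(right, down)
  j <- c(right + h, down + 1L)
  d <- rep(1, length(i))
  if (neighborhood == 8) {
    dr <- idx[r < h & cc < w]           # down-right diagonal
    ur <- idx[r > 1 & cc < w]           # up-right diagonal
    i <- c(i, dr, ur)
    j <- c(j, dr + h + 1L, ur + h - 1L)
    d <- c(d, rep(sqrt(2), length(dr) + length(ur)))
  }
  list(i = i, j = j, dist = d)
}

# Precompute everything a segmentation needs: the per-pixel/per-label data
# cost matrix (with seed and fixed-pixel hard-constraint overrides already
# applied), the neighbor pair list and its smoothness weights.
gc_precompute <- function(image, seeds, params, labels = NULL, fixed = NULL) {
  check_gray(image)
  seeds <- check_seeds(seeds, dim(image))
  models <- estimate_label_models(image, seeds, params, labels)
  lv <- names(models)                   # ascending label id
  n <- length(image)
  D <- vapply(lv, function(nm) data_cost(models, image, nm), numeric(n))
  sidx <- (seeds$col - 1L) * nrow(image) + seeds$row
  scol <- match(seeds$label, lv)
  D[sidx, ] <- params$hard_cost
  D[cbind(sidx, scol)] <- 0
  if (!is.null(fixed)) {
    fidx <- which(!is.na(fixed))
    fcol <- match(label_name(fixed[fidx]), lv)
    if (anyNA(fcol)) stop("fixed pixels carry a label not in use")
    D[fidx, ] <- params$hard_cost
    D[cbind(fidx, fcol)] <- 0
  }
  pr <- neighbor_pairs(nrow(image), ncol(image), params$neighborhood)
  V <- smooth_weight(image[pr$i], image[pr$j], pr$dist, params)
  list(image = image, models = models, labels = lv, D = D,
       pairs = pr, V = V, params = params,
       seed_idx = sidx, seed_col = scol)
}

# energy of a labeling given a precompute; `lab` is a vector of column
# indices into pre$labels
energy_impl <- function(pre, lab) {
  data_term <- sum(pre$D[cbind(seq_along(lab), lab)])
  cut <- lab[pre$pairs$i] != lab[pre$pairs$j]
  smooth_term <- sum(pre$V[cut])
  list(total = pre$params$lambda * data_term + pre$params$mu * smooth_term,
       data_term = data_term, smooth_term = smooth_term)
}

#' Energy of a labeling
#'
#' Evaluates the segmentation energy
#' `lambda * sum_p D_p(L_p) + mu * sum_{p,q} V_pq * [L_p != L_q]`, with
#' each unordered neighbor pair counted once. `data_term` and
#' `smooth_term` are the unweighted sums.
#'
#' @param image Grayscale matrix.
#' @param labeling Integer matrix of region label ids (same shape).
#' @param seeds Seed data frame (hard-constraint overrides are applied to
#'   the data term).
#' @param params A [gc_params()] object.
#' @param labels Optional label names in use (defaults to those seeded).
#' @return List with `total`, `data_term`, `smooth_term`.
#' @export
gc_energy <- function(image, labeling, seeds, params = gc_params(),
                      labels = NULL) {
  if (!identical(dim(image), dim(labeling)))
    stop("labeling shape does not match image")
  pre <- gc_precompute(image, seeds, params, labels)
  lab <- match(label_name(labeling), pre$labels)
  if (anyNA(lab))
    stop("labeling contains a label outside the scheme in use")
  energy_impl(pre, lab)
}

# One alpha-expansion move as a single exact min-cut. Binary variable
# x_p = 1 means p switches to alpha, x_p = 0 keeps its label. The pairwise
# Potts terms are submodular, so the standard decomposition applies: for a
# pair (i, j) with costs th00/th01/th10/th11 = A/B/C/0, the residual edge
# i->j gets capacity B + C - A (>= 0) and the linear parts fold into the
# terminal links. Min-cut computed exactly by igraph's max-flow.
expansion_impl <- function(pre, cur, ai) {
  n <- length(cur)
  lam <- pre$params$lambda; mu <- pre$params$mu
  a <- lam * pre$D[, ai]                              # cost of x = 1
  b <- lam * pre$D[cbind(seq_len(n), cur)]            # cost of x = 0
  i <- pre$pairs$i; j <- pre$pairs$j
  Vw <- mu * pre$V
  A <- Vw * (cur[i] != cur[j])
  B <- Vw * (cur[i] != ai)
  C <- Vw * (cur[j] != ai)
  ui <- C - A                                         # linear term on i
  a <- a + accum(i, pmax(ui, 0), n)
  b <- b + accum(i, pmax(-ui, 0), n)
  b <- b + accum(j, C, n)                             # linear term on j: -C
  ecap <- B + C - A

  s <- n + 1L; t <- n + 2L
  ka <- which(a > 0); kb <- which(b > 0); ke <- which(ecap > 0)
  el <- rbind(cbind(s, ka), cbind(kb, t), cbind(i[ke], j[ke]))
  cap <- c(a[ka], b[kb], ecap[ke])
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  if (igraph::vcount(g) < t) g <- igraph::add_vertices(g, t - igraph::vcount(g))
  mf <- igraph::max_flow(g, source = s, target = t, capacity = cap)
  take <- as.integer(mf$partition2)                   # sink side: x = 1
  take <- take[take <= n]
  new <- cur
  new[take] <- ai
  new
}

# weighted accumulation of w over integer bins idx, result length n
accum <- function(idx, w, n) {
  out <- numeric(n)
  nz <- w != 0
  if (any(nz)) {
    s <- rowsum(w[nz], idx[nz])
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' One alpha-expansion move
#'
#' Returns the better of the input labeling and the minimum-energy
#' labeling among all labelings in which every pixel either keeps its
#' current label or switches to `alpha` (computed by one exact min-cut).
#' The energy never increases; seeded pixels never abandon their seed
#' label because the hard-constraint cost dominates.
#'
#' @param labeling Integer matrix of region label ids.
#' @param alpha Region name to expand.
#' @param image Grayscale matrix.
#' @param seeds Seed data frame.
#' @param params A [gc_params()] object.
#' @param labels Optional label names in use.
#' @return Integer label matrix of the same shape.
#' @export
expansion_move <- function(labeling, alpha, image, seeds,
                           params = gc_params(), labels = NULL) {
  pre <- gc_precompute(image, seeds, params, labels)
  cur <- match(label_name(labeling), pre$labels)
  if (anyNA(cur)) stop("labeling contains a label outside the scheme in use")
  ai <- match(alpha, pre$labels)
  if (is.na(ai)) stop("alpha is not among the labels in use")
  cand <- expansion_impl(pre, cur, ai)
  keep <- if (energy_impl(pre, cand)$total <= energy_impl(pre, cur)$total)
    cand else cur
  matrix(label_id(pre$labels)[keep], nrow(image), ncol(image))
}

#' Seed-constrained multi-label graph-cut segmentation
#'
#' Minimizes the Potts energy (see [gc_params()]) by alpha-expansion:
#' starting from the per-pixel data-cost argmin (ties to the smallest
#' label id), labels are expanded in ascending id order, each move being
#' one exact min-cut; sweeps repeat until a full sweep yields no energy
#' decrease or `max_sweeps` is reached. Seeds are hard constraints and are
#' always preserved. Between 3 and 6 labels must be in use.
#'
#' @param image Grayscale matrix.
#' @param seeds Seed data frame (`row`, `col`, `label`, 1-based); every
#'   label in use needs at least one seed.
#' @param params A [gc_params()] object.
#' @param labels Optional character vector naming the labels in use
#'   (defaults to the seeded labels).
#' @param fixed Optional integer matrix (same shape, `NA` = free) of
#'   pre-assigned labels treated as additional hard constraints; the
#'   pipeline uses this to pin removed background and pectoral pixels to
#'   the background label.
#' @return Object of class `gc_segmentation`: list with `labels` (integer
#'   label-id matrix), `legend`, `energy` (`total`, `data_term`,
#'   `smooth_term`), `trace` (energy after every accepted move; never
#'   increasing) and `sweeps`.
#' @export
#' @examples
#' img <- matrix(50L, 8, 8); img[, 5:8] <- 200L
#' img[1, 1] <- 49L  # make left half inhomogeneous but near-constant
#' seeds <- data.frame(row = c(4, 4, 1), col = c(2, 7, 8),
#'                     label = c("compressed_fat", "glandular", "background"))
#' seg <- gc_segment(img, seeds)
#' table(label_name(seg$labels))
gc_segment <- function(image, seeds, params = gc_params(), labels = NULL,
                       fixed = NULL) {
  check_gray(image)
  pre <- gc_precompute(image, seeds, params, labels, fixed)
  L <- length(pre$labels)
  if (L < 3 || L > 6)
    stop("between 3 and 6 labels must be in use (got ", L, ")")

  cur <- max.col(-pre$D, ties.method = "first")   # data-cost argmin init
  e <- energy_impl(pre, cur)
  trace <- data.frame(sweep = 0L, alpha = NA_character_, total = e$total)
  tol <- 1e-7 * max(1, abs(e$total))
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (ai in seq_len(L)) {
      cand <- expansion_impl(pre, cur, ai)
      ce <- energy_impl(pre, cand)
      if (ce$total < e$total - tol) {
        cur <- cand
        e <- ce
        improved <- TRUE
        trace <- rbind(trace, data.frame(sweep = sweeps,
                                         alpha = pre$labels[ai],
                                         total = e$total))
      }
    }
    if (!improved || sweeps >= pre$params$max_sweeps) break
  }
  ids <- label_id(pre$labels)
  structure(list(labels = matrix(ids[cur], nrow(image), ncol(image)),
                 legend = stats::setNames(ids, pre$labels),
                 energy = e, trace = trace, sweeps = sweeps),
            class = "gc_segmentation")
}

#' @export
print.gc_segmentation <- function(x, ...) {
  cat("graph-cut segmentation:", paste(dim(x$labels), collapse = "x"),
      "pixels,", length(x$legend), "labels,", x$sweeps, "sweep(s)\n")
  cat("energy:", format(x$energy$total),
      "(data", format(x$energy$data_term),
      ", smooth", format(x$energy$smooth_term), ")\n")
  print(table(label_name(x$labels)))
  invisible(x)
}
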