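# Independent oracles for the graph-cut energy, written from the energy
# definition with naive loops / exhaustive enumeration; they share no code
# with the package's optimizer.

# per-label data costs computed from scratch (histogram floored at epsilon,
# renormalized, -log), with seed overrides
oracle_data_costs <- function(image, seeds, params, labels) {
  n <- length(image)
  D <- matrix(NA_real_, n, length(labels))
  for (k in seq_along(labels)) {
    px <- c()
    for (s in seq_len(nrow(seeds)))
      if (seeds$label[s] == labels[k])
        px <- c(px, image[seeds$row[s], seeds$col[s]])
    hist <- rep(0, 256)
    for (v in px) hist[v + 1] <- hist[v + 1] + 1
    hist <- hist / sum(hist)
    hist <- pmax(hist, params$epsilon)
    hist <- hist / sum(hist)
    D[, k] <- -log(hist[as.integer(image) + 1])
  }
  for (s in seq_len(nrow(seeds))) {
    p <- (seeds$col[s] - 1) * nrow(image) + seeds$row[s]
    D[p, ] <- params$hard_cost
    D[p, match(seeds$label[s], labels)] <- 0
  }
  D
}

# neighbor pairs by explicit offset loops, each unordered pair once
oracle_pairs <- function(h, w, neighborhood) {
  offs <- list(c(0, 1), c(1, 0))
  if (neighborhood == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  i <- c(); j <- c(); d <- c()
  for (r in 1:h) for (cc in 1:w) for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      i <- c(i, (cc - 1) * h + r)
      j <- c(j, (c2 - 1) * h + r2)
      d <- c(d, sqrt(sum(o^2)))
    }
  }
  list(i = i, j = j, dist = d)
}

# energy of one labeling (vector of indices into `labels`)
oracle_energy <- function(image, lab, seeds, params, labels) {
  D <- oracle_data_costs(image, seeds, params, labels)
  data <- 0
  for (p in seq_along(lab)) data <- data + D[p, lab[p]]
  pr <- oracle_pairs(nrow(image), ncol(image), params$neighborhood)
  smooth <- 0
  for (k in seq_along(pr$i)) {
    if (lab[pr$i[k]] != lab[pr$j[k]]) {
      ip <- image[pr$i[k]]; iq <- image[pr$j[k]]
      smooth <- smooth + exp(-(ip - iq)^2 / (2 * params$sigma^2)) / pr$dist[k]
    }
  }
  params$lambda * data + params$mu * smooth
}

# exhaustive minimum over all 2^n labelings of a 2-label problem
# (vectorized over labelings for speed; still pure enumeration)
oracle_min_energy_2label <- function(image, seeds, params, labels) {
  stopifnot(length(labels) == 2, length(image) <= 16)
  n <- length(image)
  D <- oracle_data_costs(image, seeds, params, labels)
  pr <- oracle_pairs(nrow(image), ncol(image), params$neighborhood)
  V <- exp(-(image[pr$i] - image[pr$j])^2 / (2 * params$sigma^2)) / pr$dist
  m <- 2^n
  labmat <- vapply(seq_len(n),
                   function(p) bitwAnd(0:(m - 1), 2^(p - 1)) > 0,
                   logical(m))
  data <- as.numeric(labmat %*% D[, 2] + (!labmat) %*% D[, 1])
  smooth <- numeric(m)
  for (k in seq_along(pr$i))
    smooth <- smooth + V[k] * (labmat[, pr$i[k]] != labmat[, pr$j[k]])
  min(params$lambda * data + params$mu * smooth)
}

# random test instance: image plus one random seed per label
random_instance <- function(h, w, labels, rng_seed) {
  set.seed(rng_seed)
  image <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
  pos <- sample(h * w, length(labels))
  seeds <- data.frame(row = ((pos - 1) %% h) + 1L,
                      col = ((pos - 1) %/% h) + 1L,
                      label = labels, stringsAsFactors = FALSE)
  list(image = image, seeds = seeds)
}

# small fast phantom used across tests
test_phantom <- function(noise_sd = 0, rng_seed = 1, has_pectoral = TRUE,
                         has_artifact = TRUE, has_mass = TRUE, side = "left",
                         h = 64, w = 64) {
  generate_phantom(phantom_spec(height = h, width = w, side = side,
                                noise_sd = noise_sd, has_mass = has_mass,
                                has_pectoral = has_pectoral,
                                has_artifact = has_artifact,
                                rng_seed = rng_seed))
}
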