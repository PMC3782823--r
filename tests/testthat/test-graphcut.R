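test_that("label models are seed histograms, floored and renormalized", {
  img <- matrix(0L, 5, 5)
  img[1, 1] <- 50L; img[2, 1] <- 50L; img[3, 1] <- 150L
  seeds <- data.frame(row = 1:3, col = 1, label = "glandular")
  p <- gc_params()
  m <- estimate_label_models(img, seeds, p)
  expect_equal(sum(m$glandular), 1, tolerance = 1e-12)
  expect_true(all(m$glandular > 0))
  expect_equal(m$glandular[51] / m$glandular[151], 2)   # 2:1 seed ratio
  # degenerate single-intensity model puts almost all mass in one bin
  s2 <- data.frame(row = 1, col = 2, label = "mass")
  img[1, 2] <- 100L
  m2 <- estimate_label_models(img, s2, p)
  expect_equal(m2$mass[101], 1 / (1 + 255 * p$epsilon), tolerance = 1e-12)
  # identical seed intensities give identical models
  both <- rbind(data.frame(row = 1, col = 1, label = "glandular"),
                data.frame(row = 2, col = 1, label = "mass"))
  m3 <- estimate_label_models(img, both, p)
  expect_identical(m3$glandular, m3$mass)
  expect_error(estimate_label_models(img, s2, p,
                                     labels = c("mass", "background")),
               "unseeded")
})

test_that("data cost is the negative log-likelihood", {
  uniform <- list(background = rep(1 / 256, 256))
  expect_equal(data_cost(uniform, 0:255, "background"),
               rep(log(256), 256), tolerance = 1e-12)
  peaked <- list(mass = c(rep(1e-9, 255), 1 - 255e-9))
  expect_lt(data_cost(peaked, 255, "mass"), 1e-6)  # mode costs ~ -ln(1) = 0
  expect_error(data_cost(uniform, 10, "mass"), "no model")
})

test_that("boundary weights follow the contrast-sensitive Gaussian", {
  p <- gc_params(sigma = 10)
  expect_equal(smooth_weight(100, 100, 1, p), 1)
  expect_equal(smooth_weight(100, 110, 1, p), exp(-0.5), tolerance = 1e-12)
  expect_equal(smooth_weight(100, 100, sqrt(2), p), 1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("energy decomposes as lambda*data + mu*smooth", {
  # 2x1 image, both pixels seeded with different labels: data term exactly 0
  img <- matrix(c(120L, 120L), 2, 1)
  seeds <- data.frame(row = 1:2, col = 1,
                      label = c("glandular", "compressed_fat"))
  p <- gc_params(mu = 20)
  lab <- matrix(label_id(c("glandular", "compressed_fat")), 2, 1)
  e <- gc_energy(img, lab, seeds, p)
  expect_equal(e$data_term, 0)
  expect_equal(e$smooth_term, 1)        # equal intensities, axial pair
  expect_equal(e$total, p$mu)
  expect_equal(e$total, p$lambda * e$data_term + p$mu * e$smooth_term)
  # uniform labeling has zero smooth term
  lab2 <- matrix(label_id("glandular"), 2, 1)
  expect_equal(gc_energy(img, lab2, seeds, p)$smooth_term, 0)
  # label outside the scheme in use is rejected
  expect_error(gc_energy(img, matrix(label_id("mass"), 2, 1), seeds, p),
               "outside the scheme")
})

test_that("energy matches the naive oracle on random 2x2 labelings", {
  for (s in 1:5) {
    inst <- random_instance(2, 2, c("background", "glandular"), s)
    p <- gc_params(neighborhood = if (s %% 2) 8 else 4)
    labels <- c("background", "glandular")
    for (code in 0:15) {
      lab <- label_id(labels)[1 + as.integer(intToBits(code))[1:4]]
      e <- gc_energy(inst$image, matrix(lab, 2, 2), inst$seeds, p, labels)
      expect_equal(e$total,
                   oracle_energy(inst$image,
                                 1 + as.integer(intToBits(code))[1:4],
                                 inst$seeds, p, labels),
                   tolerance = 1e-9)
    }
  }
})

test_that("one expansion solves the binary problem to global optimality", {
  for (s in 1:10) {
    inst <- random_instance(3, 3, c("compressed_fat", "glandular"), s)
    p <- gc_params()
    start <- matrix(label_id("compressed_fat"), 3, 3)
    out <- expansion_move(start, "glandular", inst$image, inst$seeds, p,
                          labels = c("compressed_fat", "glandular"))
    e <- gc_energy(inst$image, out, inst$seeds, p,
                   labels = c("compressed_fat", "glandular"))
    opt <- oracle_min_energy_2label(inst$image, inst$seeds, p,
                                    c("compressed_fat", "glandular"))
    expect_equal(e$total, opt, tolerance = 1e-7)
  }
})

test_that("expansion keeps an all-alpha labeling and honors seeds", {
  inst <- random_instance(4, 4, c("background", "skin_air", "glandular"), 3)
  p <- gc_params()
  all_bg <- matrix(label_id("background"), 4, 4)
  out <- expansion_move(all_bg, "background", inst$image, inst$seeds, p,
                        labels = c("background", "skin_air", "glandular"))
  expect_identical(out, all_bg)
  seg <- gc_segment(inst$image, inst$seeds, p)
  expect_identical(unname(seg$labels[cbind(inst$seeds$row, inst$seeds$col)]),
                   label_id(inst$seeds$label))
})

test_that("segmentation recovers a two-intensity image exactly", {
  img <- matrix(50L, 4, 4); img[, 3:4] <- 200L
  img[1, 1] <- 0L                       # a black corner carries the third label
  seeds <- data.frame(row = c(2, 2, 1), col = c(1, 4, 1),
                      label = c("compressed_fat", "glandular", "background"))
  seg <- gc_segment(img, seeds, gc_params())
  expect_true(all(seg$labels[, 3:4] == label_id("glandular")))
  expect_true(all(seg$labels[, 1:2][img[, 1:2] == 50L] ==
                    label_id("compressed_fat")))
  expect_identical(unname(seg$labels[1, 1]), label_id("background"))
  # the achieved energy is the exhaustive optimum of the binary sub-problem
  # restricted to the two dominant labels
  seeds2 <- seeds[1:2, ]
  start <- matrix(label_id("compressed_fat"), 4, 4)
  out <- expansion_move(start, "glandular", img, seeds2, gc_params(),
                        labels = c("compressed_fat", "glandular"))
  e <- gc_energy(img, out, seeds2, gc_params(),
                 labels = c("compressed_fat", "glandular"))
  opt <- oracle_min_energy_2label(img, seeds2, gc_params(),
                                  c("compressed_fat", "glandular"))
  expect_equal(e$total, opt, tolerance = 1e-7)
})

test_that("with mu = 0 the labeling is the per-pixel data-cost argmin", {
  inst <- random_instance(6, 6, c("background", "glandular", "mass"), 8)
  p <- gc_params(mu = 0)
  seg <- gc_segment(inst$image, inst$seeds, p)
  models <- estimate_label_models(inst$image, inst$seeds, p)
  D <- vapply(names(models),
              function(nm) data_cost(models, inst$image, nm),
              numeric(36))
  sidx <- (inst$seeds$col - 1) * 6 + inst$seeds$row
  free <- setdiff(1:36, sidx)
  chosen <- D[cbind(free, match(label_name(seg$labels[free]),
                                names(models)))]
  expect_equal(chosen, apply(D[free, ], 1, min), tolerance = 1e-12)
})

test_that("energy is non-increasing across sweeps and moves", {
  for (s in 1:5) {
    inst <- random_instance(10, 10,
                            c("background", "skin_air", "glandular", "mass"),
                            100 + s)
    seg <- gc_segment(inst$image, inst$seeds, gc_params())
    expect_true(all(diff(seg$trace$total) <= 0))
  }
})

test_that("scaling lambda and mu together leaves the labeling unchanged", {
  inst <- random_instance(8, 8, c("background", "compressed_fat",
                                  "glandular"), 21)
  a <- gc_segment(inst$image, inst$seeds, gc_params(lambda = 10, mu = 20))
  b <- gc_segment(inst$image, inst$seeds, gc_params(lambda = 30, mu = 60))
  expect_identical(a$labels, b$labels)
  expect_equal(b$energy$total / a$energy$total, 3, tolerance = 1e-9)
})

test_that("segmentation is deterministic", {
  inst <- random_instance(12, 12, c("background", "glandular", "mass"), 77)
  a <- gc_segment(inst$image, inst$seeds, gc_params())
  b <- gc_segment(inst$image, inst$seeds, gc_params())
  expect_identical(a$labels, b$labels)
  expect_identical(a$energy, b$energy)
})

test_that("label-count bounds and unseeded labels are enforced", {
  img <- matrix(10L, 5, 5)
  two <- data.frame(row = c(1, 2), col = 1,
                    label = c("background", "glandular"))
  expect_error(gc_segment(img, two), "3 and 6")
  three <- rbind(two, data.frame(row = 3, col = 1, label = "mass"))
  expect_error(gc_segment(img, three,
                          labels = c("background", "glandular", "mass",
                                     "skin_air")),
               "unseeded")
})

test_that("noiseless phantom segmentation matches truth almost everywhere", {
  ph <- test_phantom(has_pectoral = FALSE, has_artifact = FALSE)
  seeds <- sample_seeds(ph$truth, per_label = 3, rng_seed = 2)
  seg <- gc_segment(ph$image, seeds, gc_params())
  expect_gte(mean(seg$labels == ph$truth), 0.99)
})
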