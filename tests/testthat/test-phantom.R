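test_that("noiseless phantom image equals region means of its truth labels", {
  ph <- test_phantom(noise_sd = 0)
  means <- ph$spec$means
  # the artifact rectangle is the one deliberate image/truth mismatch
  expected <- matrix(means[label_name(ph$truth)], 64, 64)
  artifact <- ph$image == ph$spec$artifact_intensity &
    ph$truth == label_id("background")
  expect_true(all(ph$image[!artifact] == expected[!artifact]))
  expect_gt(sum(artifact), 0)
  # at most one intensity per region plus the artifact value
  expect_lte(length(unique(as.vector(ph$image))), 8)
})

test_that("same spec and seed give bit-identical phantoms", {
  a <- test_phantom(noise_sd = 6, rng_seed = 42)
  b <- test_phantom(noise_sd = 6, rng_seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- test_phantom(noise_sd = 6, rng_seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("truth regions partition the image and match the spec labels", {
  for (hm in c(TRUE, FALSE)) {
    ph <- test_phantom(has_mass = hm)
    expect_identical(sum(table(ph$truth)), 64L * 64L)
    expect_identical("mass" %in% label_name(unique(as.vector(ph$truth))), hm)
    expect_true("background" %in% names(ph$legend))
  }
  no_pect <- test_phantom(has_pectoral = FALSE)
  expect_false("pectoral" %in% names(no_pect$legend))
})

test_that("flipping the side mirrors image and truth exactly", {
  l <- test_phantom(noise_sd = 4, rng_seed = 5, side = "left")
  r <- generate_phantom(phantom_spec(height = 64, width = 64, side = "right",
                                     noise_sd = 4, rng_seed = 5))
  expect_identical(r$image, l$image[, 64:1])
  expect_identical(r$truth, l$truth[, 64:1])
})

test_that("mass disk is glandular-embedded with near-analytic pixel count", {
  ph <- test_phantom()
  r <- ph$spec$mass_radius
  n_mass <- sum(ph$truth == label_id("mass"))
  expect_lte(abs(n_mass - pi * r^2), r)
  # every 8-neighbor of a mass pixel is glandular or mass
  idx <- which(ph$truth == label_id("mass"), arr.ind = TRUE)
  ok <- label_id(c("glandular", "mass"))
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    nb <- ph$truth[cbind(idx[, 1] + o[1], idx[, 2] + o[2])]
    expect_true(all(nb %in% ok))
  }
})

test_that("invalid specs are rejected with a diagnostic", {
  expect_error(phantom_spec(height = 16), "32x32")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(means = c(background = 50, skin_air = 40,
                                      uncompressed_fat = 80,
                                      compressed_fat = 120, glandular = 180,
                                      mass = 220, pectoral = 200)),
               "ordered")
  expect_error(phantom_spec(means = c(background = 5, skin_air = 40,
                                      uncompressed_fat = 80,
                                      compressed_fat = 120, glandular = 180,
                                      mass = 220, pectoral = 100)),
               "pectoral")
  # mass pushed outside the glandular blob
  expect_error(generate_phantom(phantom_spec(height = 64, width = 64,
                                             mass_center = c(5, 60),
                                             mass_radius = 4)),
               "glandular")
})

test_that("seeds sampled from truth carry the right labels", {
  ph <- test_phantom()
  sd <- sample_seeds(ph$truth, per_label = 3, rng_seed = 11)
  expect_true(all(ph$truth[cbind(sd$row, sd$col)] == label_id(sd$label)))
  expect_false("pectoral" %in% sd$label)
  expect_identical(as.integer(table(sd$label)[unique(sd$label)]),
                   rep(3L, length(unique(sd$label))))
  expect_identical(sample_seeds(ph$truth, 3, rng_seed = 11), sd)
})
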