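test_that("binarization recovers the breast profile and drops artifacts", {
  ph <- test_phantom(noise_sd = 0)
  mask <- binarize_breast(ph$image)
  truthmask <- (ph$truth != label_id("background")) * 1L
  expect_identical(mask, truthmask)     # artifact excluded, profile exact
  # moving the artifact elsewhere in the background leaves the mask alone
  img2 <- matrix(ph$spec$means[label_name(ph$truth)], 64, 64)
  img2[55:60, 50:60] <- ph$spec$artifact_intensity
  expect_identical(binarize_breast(img2), truthmask)
  expect_error(binarize_breast(matrix(0, 8, 8)), "no breast found")
})

test_that("binarization stays accurate under moderate noise", {
  for (s in 1:3) {
    ph <- test_phantom(noise_sd = 5, rng_seed = s)
    mask <- binarize_breast(ph$image)
    tm <- (ph$truth != label_id("background")) * 1L
    dice <- 2 * sum(mask * tm) / (sum(mask) + sum(tm))
    expect_gte(dice, 0.95)
  }
})

test_that("background removal zeroes outside and never touches inside", {
  ph <- test_phantom(noise_sd = 5)
  mask <- binarize_breast(ph$image)
  out <- remove_background_artifacts(ph$image, mask)
  expect_true(all(out[mask == 0] == 0))
  expect_identical(out[mask == 1], ph$image[mask == 1])
  expect_identical(remove_background_artifacts(ph$image,
                                               matrix(1L, 64, 64)),
                   ph$image)
  expect_true(all(remove_background_artifacts(ph$image,
                                              matrix(0L, 64, 64)) == 0))
  expect_error(remove_background_artifacts(ph$image, matrix(1L, 2, 2)),
               "shape")
})

test_that("cropping returns the mask bounding box dilated by the margin", {
  img <- matrix(7L, 40, 50)
  mask <- matrix(0L, 40, 50); mask[11, 21] <- 1L
  cr <- crop_to_breast(img, mask, margin = 0)
  expect_identical(unname(cr$bbox), c(10L, 20L, 11L, 21L))  # 0-based, half-open
  expect_identical(dim(cr$image), c(1L, 1L))
  full <- crop_to_breast(img, matrix(1L, 40, 50), margin = 0)
  expect_identical(full$image, img)
  # phantom: bbox equals the truth-profile bounds +/- margin
  ph <- test_phantom(has_pectoral = FALSE, has_artifact = FALSE)
  tm <- (ph$truth != label_id("background")) * 1L
  cr2 <- crop_to_breast(ph$image, tm, margin = 2)
  rr <- range(which(rowSums(tm) > 0)); cc <- range(which(colSums(tm) > 0))
  expect_identical(unname(cr2$offset),
                   c(max(1L, rr[1] - 2L), max(1L, cc[1] - 2L)))
  expect_identical(unname(cr2$bbox[3:4]),
                   c(min(64L, rr[2] + 2L), min(64L, cc[2] + 2L)))
  expect_error(crop_to_breast(img, matrix(0L, 40, 50)), "empty")
})

test_that("downsampling averages blocks with half-up rounding", {
  expect_identical(dim(downsample(matrix(0L, 100, 80), 4)), c(25L, 20L))
  const <- matrix(37L, 10, 10)
  expect_true(all(downsample(const, 3) == 37L))
  blk <- matrix(0:15, 4, 4)             # one block, mean 7.5 -> 8
  expect_identical(downsample(blk, 4), matrix(8L, 1, 1))
  expect_error(downsample(blk, 0), "factor")
  # factor-1 identity and idempotence
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_identical(downsample(img, 1), img)
  # full-block downsampling preserves mean within one gray level
  big <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_lte(abs(mean(downsample(big, 4)) - mean(big)), 1)
})

test_that("median filtering removes impulses and respects borders", {
  const <- matrix(100L, 9, 9)
  expect_identical(median_enhance(const, 3), const)
  salt <- const; salt[5, 5] <- 255L
  expect_identical(median_enhance(salt, 3), const)
  m <- matrix(c(1, 4, 7, 2, 100, 8, 3, 6, 9), 3, 3)  # rows 1..3
  expect_identical(median_enhance(m, 3)[2, 2], 6L)   # median of all nine
  expect_error(median_enhance(const, 4), "odd")
  # idempotent on piecewise-constant images away from borders between regions
  pc <- matrix(10L, 12, 12); pc[, 7:12] <- 200L
  expect_identical(median_enhance(median_enhance(pc, 3), 3),
                   median_enhance(pc, 3))
})
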