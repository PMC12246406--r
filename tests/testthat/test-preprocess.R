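phantom_image <- function(seed = 1) {
  cfg <- cohort_config(n_patients = 1, image_height = 96, image_width = 64,
                       px_per_mm = 1, seed = seed)
  cohort <- generate_cohort(cfg)
  r <- render_mammogram(cohort[1, ], 0, cfg)
  r
}

test_that("breast segmentation recovers the phantom footprint", {
  r <- phantom_image(4)
  mask <- segment_breast(r$image)
  expect_type(mask, "logical")
  expect_equal(dim(mask), dim(r$image))
  iou <- sum(mask & r$mask) / sum(mask | r$mask)
  expect_gte(iou, 0.95)
  # one connected component by construction
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  expect_equal(max(lab), 1)
  expect_error(segment_breast(matrix(0, 10, 10)), "constant")
})

test_that("intensity normalization clips percentiles and zeroes background", {
  r <- phantom_image(5)
  mask <- segment_breast(r$image)
  norm <- normalize_intensity(r$image, mask)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_true(all(norm[!mask] == 0))
  # constant inside mask: degenerate range maps to zero
  img_const <- matrix(0.4, 20, 20)
  mask_c <- matrix(TRUE, 20, 20)
  expect_true(all(normalize_intensity(img_const, mask_c) == 0))
  # one hot pixel saturates under (1, 99) clipping
  img <- matrix(runif(2500, 0.2, 0.4), 50, 50)
  img[25, 25] <- 50
  nm <- normalize_intensity(img, matrix(TRUE, 50, 50))
  expect_equal(nm[25, 25], 1)
  q99 <- quantile(img, 0.99)
  expect_true(all(nm[img >= q99] == 1))
  expect_error(normalize_intensity(img, matrix(FALSE, 50, 50)), "empty mask")
})

test_that("patch tiling is grid-complete with the tissue-fraction rule", {
  img <- matrix(runif(1024 * 768), 1024, 768)
  mask <- matrix(TRUE, 1024, 768)
  cfg <- preprocess_config(patch_size = 256, patch_stride = 256,
                           min_tissue_fraction = 0)
  tp <- tile_patches(img, mask, cfg)
  expect_equal(length(tp$patches), 12)        # 4 x 3 grid
  expect_equal(nrow(tp$grid), 12)
  expect_true(all(tp$grid$retained))
  # half-empty mask with min fraction 1: only fully-covered patches retained
  mask2 <- mask; mask2[, 385:768] <- FALSE
  cfg2 <- preprocess_config(patch_size = 256, min_tissue_fraction = 1)
  tp2 <- tile_patches(img, mask2, cfg2)
  expect_equal(sum(tp2$grid$retained), 4)     # first full column of patches
  expect_equal(nrow(tp2$grid), 12)            # retained + rejected = grid
  expect_equal(length(tp2$patches), sum(tp2$grid$retained))
  # patch content equals the image window at its coordinates
  g <- tp$grid[7, ]
  expect_equal(tp$patches[[7]],
               img[(g$row + 1):(g$row + 256), (g$col + 1):(g$col + 256)])
  # oversize patches: empty result with warning, not an error
  expect_warning(tp3 <- tile_patches(matrix(0, 10, 10), matrix(TRUE, 10, 10),
                                     preprocess_config(patch_size = 64)),
                 "exceeds")
  expect_equal(length(tp3$patches), 0)
})

test_that("ROI extraction pads with zeros and preserves shape", {
  img <- matrix(runif(600 * 550), 600, 550)
  ann <- list(center_x = 300, center_y = 280)
  roi <- extract_roi(img, ann, 500)
  expect_equal(dim(roi), c(500, 500))
  # interior crop equals the sub-array
  expect_equal(roi, img[(280 - 250 + 1):(280 + 250), (300 - 250 + 1):(300 + 250)])
  # corner center: three quarters of the window zero-padded
  roi0 <- extract_roi(img, list(center_x = 0, center_y = 0), 500)
  expect_equal(dim(roi0), c(500, 500))
  expect_equal(mean(roi0 == 0) >= 0.75 - 1e-6, TRUE)
  expect_equal(roi0[251:500, 251:500], img[1:250, 1:250])
  # windowed-sum oracle at a border center
  ann_b <- list(center_x = 10, center_y = 580)
  roi_b <- extract_roi(img, ann_b, 100)
  rows <- (580 - 50):min(599, 580 + 49) + 1
  cols <- max(0, 10 - 50):(10 + 49) + 1
  expect_equal(sum(roi_b), sum(img[rows, cols]))
  expect_error(extract_roi(img, list(center_x = -1, center_y = 5), 100),
               "outside")
})

test_that("preprocess config invariants", {
  expect_error(preprocess_config(patch_size = 64, patch_stride = 128),
               "stride")
  expect_error(preprocess_config(roi_size = 0), "positive")
  expect_error(preprocess_config(clip_percentiles = c(99, 1)), "low, high")
})
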