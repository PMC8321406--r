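test_that("patch classifier trains, is deterministic, and validates input", {
  ph <- worm_phantom(length_um = 110, max_radius_um = 11, bend_amplitude = 5,
                     menorah_spacing_um = 30, pixel_size_um = 0.5,
                     psf_sigma_px = 1, noise = "poisson", n_granules = 5,
                     seed = 9)
  set.seed(3)
  patches <- list(); labels <- list()
  for (i in 1:12) {
    y0 <- sample(nrow(ph$image) - 64, 1); x0 <- sample(ncol(ph$image) - 64, 1)
    patches[[i]] <- ph$image[y0 + 1:64, x0 + 1:64]
    labels[[i]] <- ph$mask[y0 + 1:64, x0 + 1:64] * 1
  }
  m <- train_patch_classifier(patches, labels, epochs = 6, seed = 1)
  ## training cross-entropy strictly decreases over the first epochs
  expect_true(all(diff(m$loss[1:5]) < 0))
  m2 <- train_patch_classifier(patches, labels, epochs = 6, seed = 1)
  expect_identical(m$loss, m2$loss)

  ## degenerate label set: all-background training predicts background
  mb <- train_patch_classifier(patches[1:4],
                               lapply(1:4, function(i) matrix(0, 64, 64)),
                               epochs = 4, seed = 2)
  expect_lt(mean(predict_patch(mb, patches[[5]])), 0.5)

  expect_error(train_patch_classifier(list(matrix(0, 32, 32)),
                                      list(matrix(0, 32, 32))), "64x64")
  expect_error(train_patch_classifier(list(), list()), "at least one")

  ## sliding-window reassembly matches the input raster size and segments
  cmN <- classify_image(ph$image, model = m, mode = "cnn")
  expect_equal(dim(cmN$prob), dim(ph$image))
  expect_true(all(cmN$prob >= 0 & cmN$prob <= 1))
  iou <- sum(cmN$binary & ph$mask) / sum(cmN$binary | ph$mask)
  expect_gt(iou, 0.5)
})

test_that("fallback pixel classification segments phantoms and rejects non-neuron input", {
  p <- fx_phantom()
  iou <- sum(p$cm$binary & p$ph$mask) / sum(p$cm$binary | p$ph$mask)
  expect_gte(iou, 0.6)
  expect_true(all(p$cm$prob >= 0 & p$cm$prob <= 1))
  expect_equal(dim(p$cm$prob), dim(p$ph$image))
  ## binary map is the probability map thresholded at 0.5 (up to the
  ## granule-shape filter, which only removes pixels)
  expect_true(all(p$cm$prob[p$cm$binary] >= 0.5))

  ## uniform image -> empty map
  cu <- classify_image(matrix(0.3, 60, 60))
  expect_false(any(cu$binary))

  ## granule-only image -> discs removed by the isolated-blob filter
  gimg <- matrix(0.05, 80, 80)
  for (cc in list(c(20, 20), c(50, 60), c(65, 25))) {
    for (dy in -3:3) for (dx in -3:3) {
      if (dy^2 + dx^2 <= 9) gimg[cc[1] + dy, cc[2] + dx] <- 0.9
    }
  }
  gimg <- EBImage::gblur(gimg, 1)
  cg <- classify_image(gimg)
  expect_false(any(cg$binary))

  ## determinism
  c2 <- classify_image(p$ph$image)
  expect_identical(p$cm$prob, c2$prob)
})

test_that("skeletonization produces one-pixel-wide graphs with correct topology", {
  ## straight bar: one edge, two tips, no vertices
  g <- skeletonize(make_bar())
  expect_equal(nrow(g$edges), 1)
  expect_equal(sum(g$nodes$type == "tip"), 2)
  expect_equal(sum(g$nodes$type == "vertex"), 0)

  ## plus-shaped blob: one degree-4 vertex and four tips
  img <- matrix(0, 60, 60)
  img[28:32, 10:50] <- 1
  img[10:50, 28:32] <- 1
  g2 <- skeletonize(img)
  expect_equal(sum(g2$nodes$type == "vertex"), 1)
  expect_equal(max(g2$nodes$degree), 4)
  expect_equal(sum(g2$nodes$type == "tip"), 4)

  ## skeleton is one pixel wide (no 2x2 solid block) and inside the map
  s <- g2$skeleton
  expect_false(any(s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] &
                     s[-nrow(s), -1] & s[-1, -1]))
  expect_true(all(img[g2$skeleton == 1] > 0))

  ## empty map -> empty graph
  g0 <- skeletonize(matrix(0, 10, 10))
  expect_equal(nrow(g0$edges), 0)
})

test_that("phantom skeletons recover junction count and total length", {
  p <- fx_phantom()
  expect_true(all(p$cm$binary[p$sk$skeleton == 1]))
  n_vert <- sum(p$sk$nodes$type == "vertex")
  n_gt <- nrow(p$ph$tree$junctions)
  expect_lte(abs(n_vert - n_gt) / n_gt, 0.05)

  gt_len_px <- sum(p$ph$tree$meta$length_um) / 0.5
  expect_lt(abs(skeleton_length(p$sk) - gt_len_px) / gt_len_px, 0.10)
})
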