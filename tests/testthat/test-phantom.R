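test_that("worm frame is arclength-parameterized, tapered, and validated", {
  wf0 <- worm_frame(200, 15, bend_amplitude = 0, seed = 1)
  expect_true(all(wf0$midline$tangent_deg == 0))
  expect_true(all(diff(wf0$midline$s) > 0))
  expect_true(all(wf0$midline$r > 0))

  ## numerical arclength oracle: sum of segment lengths
  wf <- worm_frame(600, 25, bend_amplitude = 10, seed = 1)
  arc <- sum(sqrt(diff(wf$midline$x)^2 + diff(wf$midline$y)^2))
  expect_lt(abs(arc - 600) / 600, 0.01)
  ## s increases head -> tail (posteriorly)
  expect_equal(wf$midline$s[1], 0)
  expect_equal(max(wf$midline$s), 600)
  ## taper towards both ends
  mid_r <- wf$midline$r[which.min(abs(wf$midline$s - 300))]
  expect_lt(wf$midline$r[2], mid_r / 2)

  expect_error(worm_frame(-5, 10), "positive")
  expect_error(worm_frame(100, 0), "positive")
})

test_that("ground-truth trees have exact T-junctions, consistent lengths, and are reproducible", {
  for (sd in 1:3) {
    wf <- worm_frame(150, 14, bend_amplitude = 8, seed = sd)
    tree <- pvd_tree(wf, menorah_spacing_um = 30, jitter = 0, seed = sd)
    sums <- tree$junctions$a1 + tree$junctions$a2 + tree$junctions$a3
    expect_true(all(abs(sums - 360) < 1e-9))
    ## unjittered grid: every triplet contains a right angle
    dev90 <- apply(cbind(tree$junctions$a1, tree$junctions$a2,
                         tree$junctions$a3), 1,
                   function(a) min(abs(a - 90)))
    expect_true(all(dev90 < 1))
    ## all junctions three-way when the four-way fraction is 0
    expect_true(all(tree$junctions$k == 3))
    ## total length equals the sum of per-class lengths exactly
    cl <- tree_class_lengths(tree)
    expect_equal(sum(cl$length_um[!is.na(cl$class)]),
                 cl$length_um[is.na(cl$class)])
  }
  ## determinism under a fixed seed
  wf <- worm_frame(150, 14, bend_amplitude = 8, seed = 2)
  t1 <- pvd_tree(wf, menorah_spacing_um = 30, seed = 7)
  t2 <- pvd_tree(wf, menorah_spacing_um = 30, seed = 7)
  expect_identical(t1$polylines, t2$polylines)
  expect_identical(t1$junctions, t2$junctions)

  ## optional four-way junctions
  t4 <- pvd_tree(wf, menorah_spacing_um = 30, four_way_frac = 1, seed = 3)
  expect_true(any(t4$junctions$k == 4))

  expect_error(pvd_tree(wf, menorah_spacing_um = 200), "smaller")
})

test_that("element azimuths have modes at 0 and +/-35 degrees", {
  co <- fx_cohort()
  tree <- attr(co$traces[[1]], "tree")
  phi <- unlist(lapply(tree$coords, function(d) d$phi))
  h <- hist(phi, breaks = seq(-91, 91, 2), plot = FALSE)
  mid <- h$mids
  mode_near_0 <- mid[which.max(h$counts * (abs(mid) <= 10))]
  mode_pos <- mid[which.max(h$counts * (mid >= 20 & mid <= 60))]
  mode_neg <- mid[which.max(h$counts * (mid <= -20 & mid >= -60))]
  expect_lte(abs(mode_near_0), 2)
  expect_lte(abs(mode_pos - 35), 2)
  expect_lte(abs(mode_neg + 35), 2)
})

test_that("rendering marks neuron pixels, draws exact granule counts, and is deterministic", {
  wf <- worm_frame(100, 11, bend_amplitude = 5, seed = 4)
  tree <- pvd_tree(wf, menorah_spacing_um = 28, seed = 4)

  ## noiseless, granule-free: every neuron pixel strictly above background
  r0 <- render_worm_image(tree, pixel_size_um = 0.5, psf_sigma_px = 1,
                          noise = "none", n_granules = 0, seed = 1)
  expect_true(all(r0$image[r0$mask] > r0$bg_level))

  ## connected-component oracle for the granule count
  rg <- render_worm_image(tree, pixel_size_um = 0.5, psf_sigma_px = 1,
                          noise = "none", n_granules = 12, seed = 2)
  off <- rg$image
  off[EBImage::dilate(rg$mask * 1, EBImage::makeBrush(9, "disc")) > 0] <- 0
  lab <- EBImage::bwlabel(off > rg$bg_level + 0.3)
  expect_equal(max(lab), 12)

  ## PSF monotonically widens a ridge cross-section (FWHM oracle on a
  ## single rendered process)
  fwhm_of <- function(sigma) {
    rr <- render_junction_image(0, size_px = 81, ray_len_px = 30,
                                width_px = 3, psf_sigma_px = sigma)
    prof <- rr$image[, round(rr$center[1]) + 15]
    ## half-maximum width by linear interpolation of the crossing points
    half <- max(prof) / 2
    above <- which(prof >= half)
    i0 <- min(above); i1 <- max(above)
    lo <- if (i0 > 1) i0 - (prof[i0] - half) / (prof[i0] - prof[i0 - 1]) else i0
    hi <- if (i1 < length(prof)) i1 + (prof[i1] - half) / (prof[i1] - prof[i1 + 1]) else i1
    hi - lo
  }
  f <- vapply(c(0, 1, 2), fwhm_of, numeric(1))
  expect_true(all(diff(f) > 0))

  ## bit-exact reproducibility
  ra <- render_worm_image(tree, pixel_size_um = 0.5, noise = "poisson",
                          n_granules = 6, seed = 11)
  rb <- render_worm_image(tree, pixel_size_um = 0.5, noise = "poisson",
                          n_granules = 6, seed = 11)
  expect_identical(ra$image, rb$image)
  expect_identical(ra$mask, rb$mask)

  expect_error(render_worm_image(tree, pixel_size_um = -1), "positive")
})
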