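test_that("midline extraction recovers the body frame from the neuron mask", {
  ## straight worm: midline within 2 px RMS of ground truth
  ph0 <- worm_phantom(length_um = 150, max_radius_um = 14,
                      bend_amplitude = 0, menorah_spacing_um = 30,
                      pixel_size_um = 0.5, psf_sigma_px = 1, noise = "none",
                      n_granules = 0, seed = 1)
  fr0 <- extract_midline(ph0$mask, pixel_size_um = 0.5)
  mpx <- attr(fr0, "midline_px")
  gtpx <- um_to_px(ph0$geometry, cbind(ph0$frame$midline$x,
                                       ph0$frame$midline$y))
  d <- vapply(seq_len(nrow(mpx)), function(i) {
    min(sqrt((gtpx[, 1] - mpx[i, 1])^2 + (gtpx[, 2] - mpx[i, 2])^2))
  }, numeric(1))
  expect_lte(sqrt(mean(d^2)), 2)

  ## s spans the worm length within 5%
  expect_lte(abs(fr0$length_um - 150) / 150, 0.05)
  expect_true(all(diff(fr0$midline$s) > 0))

  ## bent worm: radius profile recovered over the central 80%; the body
  ## surface is only marked by dendrites, so accuracy is bounded by arbor
  ## coverage near the margins of that window
  ph2 <- worm_phantom(length_um = 150, max_radius_um = 14,
                      bend_amplitude = 8, menorah_spacing_um = 30,
                      pixel_size_um = 0.5, psf_sigma_px = 1, noise = "none",
                      n_granules = 0, seed = 2)
  fr2 <- extract_midline(ph2$mask, pixel_size_um = 0.5)
  mpx2 <- attr(fr2, "midline_px")
  gtpx2 <- um_to_px(ph2$geometry, cbind(ph2$frame$midline$x,
                                        ph2$frame$midline$y))
  idx <- vapply(seq_len(nrow(mpx2)), function(i) {
    which.min((gtpx2[, 1] - mpx2[i, 1])^2 + (gtpx2[, 2] - mpx2[i, 2])^2)
  }, integer(1))
  rel <- mpx2[, 3] / (ph2$frame$midline$r[idx] / 0.5) - 1
  cen <- ph2$frame$midline$s[idx] >= 15 & ph2$frame$midline$s[idx] <= 135
  expect_lte(median(abs(rel[cen])), 0.10)
  expect_gte(mean(abs(rel[cen]) <= 0.20), 0.90)

  ## head-end convention: flipping the flag reverses the arclength origin
  frR <- extract_midline(ph0$mask, pixel_size_um = 0.5, head = "right")
  expect_gt(frR$midline$x[1], frR$midline$x[nrow(frR$midline)])
  expect_lt(fr0$midline$x[1], fr0$midline$x[nrow(fr0$midline)])

  expect_error(extract_midline(matrix(FALSE, 10, 10)), "empty")
})

test_that("element coordinates satisfy the azimuth and orientation identities", {
  co <- fx_cohort()
  tr <- co$traces[[1]]
  wf <- attr(tr, "frame")

  ## phi = asin(d / r): exact inverse-sine identity on synthetic elements
  s_test <- 75
  f <- pvdmorph:::frame_at(wf, s_test)
  for (phi_true in c(0, 35, -35, 60)) {
    d <- f$r * sin(pvdmorph:::deg2rad(phi_true))
    p_um <- pvdmorph:::frame_point(wf, s_test, d)
    geom <- phantom_geometry(wf, 0.5)
    p_px <- um_to_px(geom, p_um)
    fake <- tr
    fake$elements <- tr$elements[1, ]
    fake$elements$x <- p_px[1]; fake$elements$y <- p_px[2]
    fake$elements$psi <- f$tangent_deg
    fake <- element_coords(fake, frame = wf, pixel_size_um = 0.5)
    expect_lt(abs(fake$coords$phi - phi_true), 1)
    expect_lt(fake$coords$theta, 1.5)
  }

  ## phantom class-1 elements lie near azimuth zero (ground-truth frame)
  phi1 <- abs(tr$coords$phi[tr$elements$class_true == 1])
  expect_gte(mean(phi1 <= 5, na.rm = TRUE), 0.9)

  ## with the estimated frame the identity degrades gracefully
  frE <- extract_midline(
    render_worm_image(attr(tr, "tree"), pixel_size_um = 0.5,
                      psf_sigma_px = 1, noise = "none", n_granules = 0,
                      seed = 1)$mask,
    pixel_size_um = 0.5)
  trE <- element_coords(tr, frame = frE, pixel_size_um = 0.5)
  phi1E <- abs(trE$coords$phi[trE$elements$class_true == 1])
  expect_lte(median(phi1E, na.rm = TRUE), 3)
  expect_gte(mean(phi1E <= 10, na.rm = TRUE), 0.85)

  ## elements far outside the body are flagged and excluded
  fake <- tr
  fake$elements <- tr$elements[1, ]
  geom <- phantom_geometry(wf, 0.5)
  p_px <- um_to_px(geom, pvdmorph:::frame_point(wf, 75, f$r * 1.5))
  fake$elements$x <- p_px[1]; fake$elements$y <- p_px[2]
  fake <- element_coords(fake, frame = wf, pixel_size_um = 0.5)
  expect_true(fake$coords$excluded)
  expect_true(is.na(fake$coords$phi))
})

test_that("theta is invariant to rigid rotation of the image plane", {
  co <- fx_cohort()
  tr <- co$traces[[2]]
  wf <- attr(tr, "frame")
  th0 <- tr$coords$theta

  ## rotate the frame and all elements by 30 degrees in micrometre space
  rot <- function(pts, a) {
    cbind(pts[, 1] * cos(a) - pts[, 2] * sin(a),
          pts[, 1] * sin(a) + pts[, 2] * cos(a))
  }
  a <- pvdmorph:::deg2rad(30)
  wf_rot <- wf
  mr <- rot(cbind(wf$midline$x, wf$midline$y), a)
  wf_rot$midline$x <- mr[, 1]; wf_rot$midline$y <- mr[, 2]
  wf_rot$midline$tangent_deg <- wf$midline$tangent_deg + 30

  geom <- phantom_geometry(wf, 0.5)
  el_um <- px_to_um(geom, cbind(tr$elements$x, tr$elements$y))
  el_rot <- rot(el_um, a)
  tr_rot <- tr
  ## feed rotated micrometre coordinates through a unit-pixel identity
  ## geometry: x_px = x_um, y_px = -y_um
  tr_rot$elements$x <- el_rot[, 1] / 0.5
  tr_rot$elements$y <- -el_rot[, 2] / 0.5
  tr_rot$elements$psi <- tr$elements$psi + 30
  wf_rot2 <- wf_rot
  wf_rot2$source <- "estimated"     # already in the raster-derived frame
  tr_rot <- element_coords(tr_rot, frame = wf_rot2, pixel_size_um = 0.5)
  dth <- abs(tr_rot$coords$theta - th0)
  expect_lt(max(dth, na.rm = TRUE), 2)
})

test_that("projection correction of junction angles behaves as the cylinder unprojection", {
  wf <- worm_frame(150, 14, bend_amplitude = 0, seed = 1)

  ## identity at the lateral midline
  tri0 <- correct_junction_angles(wf, c(0, 90, 180), s = 75, phi = 0)
  expect_equal(sort(tri0$triplet), c(90, 90, 180))
  expect_false(tri0$excluded)

  ## closed-form unprojection oracle at phi = 60: (dS, dD) -> (dS, dD/cos)
  dirs <- c(10, 130, 250)
  phi <- 60
  oracle <- sapply(dirs, function(a) {
    r <- pvdmorph:::deg2rad(a)
    pvdmorph:::rad2deg(atan2(sin(r) / cos(pvdmorph:::deg2rad(phi)), cos(r)))
  })
  oracle_trip <- sort(pvdmorph:::circular_gaps(oracle))
  got <- correct_junction_angles(wf, dirs, s = 75, phi = phi)
  expect_equal(got$triplet, oracle_trip, tolerance = 1e-9)
  expect_equal(sum(got$triplet), 360)

  ## oblique rays steepen towards the transverse axis while longitudinal
  ## and purely transverse rays are fixed points of the unprojection
  gi <- correct_junction_angles(wf, c(0, 45, 180), s = 75, phi = 60)
  corr45 <- sort(pvdmorph:::wrap360(gi$dirs))[2]
  expect_gt(corr45, 45)
  expect_lt(corr45, 90)

  ## corrected triplets always sum to 360; high-azimuth junctions excluded
  for (phi in c(-50, 0, 20, 70)) {
    g <- correct_junction_angles(wf, c(5, 100, 222), s = 60, phi = phi)
    expect_equal(sum(g$angles), 360, tolerance = 1e-9)
  }
  g85 <- correct_junction_angles(wf, c(0, 90, 180), s = 75, phi = 85)
  expect_true(g85$excluded)
})

test_that("phantom azimuth distributions are symmetric about the midline", {
  co <- fx_cohort()
  phi <- co$pooled$phi[!is.na(co$pooled$phi) & abs(co$pooled$phi) > 10]
  n_pos <- sum(phi > 0); n_neg <- sum(phi < 0)
  p <- stats::binom.test(n_pos, n_pos + n_neg, 0.5)$p.value
  expect_gt(p, 0.01)
})
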