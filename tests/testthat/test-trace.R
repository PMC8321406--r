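test_that("rectangle score matches pixel-counting oracles", {
  img <- make_bar(width = 6, y0 = 28)       # rows 28:33 bright
  expect_equal(rect_score(img, c(70, 50), 0, 4, 8, 0, 1), 0)
  expect_equal(rect_score(img, c(70, 30.5), 0, 4, 8, 0, 1), 1)
  ## mask half-covering the bar edge: pixel-counting oracle
  half <- rect_score(img, c(70, 33.5), 0, 6, 12, 0, 1)
  expect_lt(abs(half - 0.5), 0.05)
  expect_error(rect_score(img, c(2, 2), 0, 10, 20, 0, 1),
               class = "pvdmorph_oob")
})

test_that("background estimation pools flanks and detects neighbours", {
  u <- matrix(0.3, 50, 50)
  bg <- estimate_background(u, c(25, 25), 0, 4, 8)
  expect_equal(bg$mean, 0.3)
  expect_equal(bg$sd, 0)

  ## linear intensity ramp: symmetric flanks average to the centre value
  ramp <- matrix(rep(seq(0, 1, length.out = 60), each = 60), 60, 60)
  bgr <- estimate_background(ramp, c(30, 30), 90, 4, 8)
  expect_lt(abs(bgr$mean - ramp[30, 30]) / ramp[30, 30], 0.02)

  ## a parallel neighbouring process inflates the flank SD
  one_bar <- make_bar(width = 4, y0 = 28)
  two_bar <- one_bar + make_bar(width = 4, y0 = 35)
  sd1 <- estimate_background(one_bar, c(70, 29.5), 0, 4, 8)$sd
  sd2 <- estimate_background(two_bar, c(70, 29.5), 0, 4, 8)$sd
  expect_gt(sd2, sd1)
})

test_that("orientation fitting finds ridge direction with a smoothness tie-break", {
  img <- make_bar(width = 4, y0 = 28)
  prev <- list(center = c(60, 29.5), psi = 0, w = 4, l = 8)
  expect_equal(fit_orientation(img, prev, center = c(70, 29.5))$psi, 0)

  ## bent bar: exhaustive-search oracle at 0.5-degree resolution
  img2 <- matrix(0, 90, 140)
  for (t in seq(0, 50, 0.2)) {    # horizontal arm then 30-degree arm
    img2[round(45 + 0:3), round(15 + t)] <- 1
  }
  bend <- c(65, 46.5)
  for (t in seq(0, 40, 0.2)) {
    x <- bend[1] + t * cos(pi / 6); y <- bend[2] - t * sin(pi / 6)
    img2[round(y) + 0:3, round(x)] <- 1
  }
  probe <- bend + 8 * c(cos(pi / 6), -sin(pi / 6)) + c(0, 1.5)
  prev2 <- list(center = bend, psi = 0, w = 4, l = 8)
  fine <- vapply(seq(-60, 60, 0.5), function(d) {
    rect_score(img2, probe, d, 4, 8, 0, 1)
  }, numeric(1))
  oracle <- seq(-60, 60, 0.5)[which.max(fine)]
  got <- fit_orientation(img2, prev2, center = probe)$psi
  expect_lte(abs(got - oracle), 2)
  expect_lte(abs(got - 30), 6)

  ## all-tie case (uniform signal): the smoothness prior keeps the
  ## previous orientation
  uni <- matrix(1, 80, 80)
  prevu <- list(center = c(40, 40), psi = 12, w = 3, l = 6)
  expect_equal(fit_orientation(uni, prevu, center = c(40, 40))$psi, 12)
})

test_that("width fitting locates the score decay onset", {
  img6 <- make_bar(width = 6, y0 = 28)      # rows 28:33, centre 30.5
  w6 <- fit_width(img6, c(70, 30.5), 0, bg_mean = 0, signal_ref = 1)
  expect_lte(abs(w6 - 6), 1)

  ## doubling the bar width doubles the fitted width
  img12 <- make_bar(nrow = 80, width = 12, y0 = 30)  # rows 30:41, centre 35.5
  w12 <- fit_width(img12, c(70, 35.5), 0, bg_mean = 0, signal_ref = 1)
  expect_lte(abs(w12 - 12), 1)
  expect_lte(abs(w12 - 2 * w6), 2)

  ## floor at 2 px for sub-resolution ridges
  img1 <- make_bar(width = 1, y0 = 30)
  expect_equal(fit_width(img1, c(70, 30), 0, bg_mean = 0, signal_ref = 1), 2)

  ## flat profile on background signals no ridge
  expect_error(fit_width(matrix(0.2, 60, 60), c(30, 30), 0,
                         bg_mean = 0.2, signal_ref = 1),
               class = "pvdmorph_no_ridge")
})

test_that("segment tracing covers a bar and flags background paths", {
  img <- make_bar(ncol = 160, width = 4, y0 = 28, x = 21:141)
  path <- cbind(x = 21:141, y = 29.5)
  ts <- trace_segment(img, path)
  expect_false(ts$partial)
  expect_gt(nrow(ts$elements), 5)
  arclen <- sum(sqrt(diff(ts$elements$x)^2 + diff(ts$elements$y)^2))
  span <- max(ts$elements$x) - min(ts$elements$x)
  expect_lte(abs(span - 120) , 2 * median(ts$elements$l))
  expect_true(all(ts$elements$score >= 0.15))

  ## skeleton path through pure background: empty chain, flagged
  ts0 <- trace_segment(img, cbind(x = 10:150, y = 55))
  expect_equal(nrow(ts0$elements), 0)
  expect_true(ts0$partial)
})

test_that("junction fitting recovers angles on synthetic junctions", {
  y <- render_junction_image(c(0, 120, 240))
  jy <- fit_junction(y$image, y$mask, y$center)
  expect_equal(jy$k, 3L)
  expect_true(all(abs(jy$triplet - c(120, 120, 120)) <= 2))

  t <- render_junction_image(c(0, 90, 180))
  jt <- fit_junction(t$image, t$mask, t$center)
  expect_equal(jt$k, 3L)
  expect_true(all(abs(jt$triplet - c(90, 90, 180)) <= 2))
  expect_equal(sum(jt$triplet), 360)

  ## four arms accepted, five would be an artifact; two is degenerate
  x4 <- render_junction_image(c(10, 100, 190, 280))
  j4 <- fit_junction(x4$image, x4$mask, x4$center)
  expect_equal(j4$k, 4L)
  expect_false(j4$artifact)

  l2 <- render_junction_image(c(0, 90))
  j2 <- fit_junction(l2$image, l2$mask, l2$center)
  expect_true(j2$degenerate)
  expect_true(all(is.na(j2$triplet)))
})

test_that("full phantom tracing is accurate, complete, and deterministic", {
  p <- fx_phantom()
  tr <- p$tr

  ## coverage: fraction of ground-truth arbor within an element's footprint
  gtpts <- do.call(rbind, lapply(p$ph$tree$polylines, function(poly) {
    um_to_px(p$ph$geometry, pvdmorph:::resample_polyline(poly, 1))
  }))
  el <- tr$elements
  covered <- vapply(seq_len(nrow(gtpts)), function(i) {
    d2 <- (el$x - gtpts[i, 1])^2 + (el$y - gtpts[i, 2])^2
    any(d2 <= (el$l / 2 + el$w)^2)
  }, logical(1))
  expect_gte(mean(covered), 0.95)

  ## junction localization within 3 px for at least 90% of junctions
  gtj <- um_to_px(p$ph$geometry, cbind(p$ph$tree$junctions$x,
                                       p$ph$tree$junctions$y))
  dj <- vapply(seq_len(nrow(tr$junctions)), function(i) {
    min(sqrt((gtj[, 1] - tr$junctions$x[i])^2 +
               (gtj[, 2] - tr$junctions$y[i])^2))
  }, numeric(1))
  expect_gte(mean(dj <= 3), 0.9)

  ## segment count within 5% of ground truth
  n_gt <- nrow(phantom_trace(p$ph$tree, 0.5)$segments)
  expect_lte(abs(nrow(tr$segments) - n_gt) / n_gt, 0.05)

  ## accepted elements satisfy the score threshold; angle triplets of
  ## three-way junctions sum to 360 exactly
  expect_true(all(tr$elements$score >= 0.15))
  three <- tr$junctions[tr$junctions$k == 3, ]
  expect_true(all(abs(three$a1 + three$a2 + three$a3 - 360) < 1e-9))

  ## no randomness: retracing is bit-identical
  tr2 <- trace_neuron(p$ph$image, p$cm, p$sk, pixel_size_um = 0.5)
  expect_identical(tr$elements, tr2$elements)
  expect_identical(tr$junctions, tr2$junctions)
})

test_that("assembling a single bar yields one segment with two tips", {
  img <- EBImage::gblur(make_bar(width = 4, y0 = 28) * 0.9 + 0.05, 1)
  cm <- classify_image(img)
  tr <- trace_neuron(img, cm, pixel_size_um = 1)
  expect_equal(nrow(tr$segments), 1)
  expect_equal(nrow(tr$tips), 2)
  expect_equal(nrow(tr$junctions), 0)
})
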