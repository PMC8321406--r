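test_that("the class model finds four clusters matching the generator", {
  co <- fx_cohort()
  m <- co$model
  expect_s3_class(m, "pvd_class_model")
  expect_equal(sort(m$modes$class), 1:4)

  ## cluster modes within 10 degrees of the per-class density modes of the
  ## generating elements (densest 5-degree bin, the generator archetypes)
  lab <- co$pooled |>
    dplyr::mutate(class_true = unlist(lapply(co$traces, function(t)
      t$elements$class_true))) |>
    dplyr::filter(!is.na(theta), !is.na(phi))
  for (k in 1:4) {
    sub <- lab[lab$class_true == k, ]
    bt <- floor(sub$theta / 5); bp <- floor(abs(sub$phi) / 5)
    key <- paste(bt, bp)
    top <- names(sort(table(key), decreasing = TRUE))[1]
    tru <- as.numeric(strsplit(top, " ")[[1]]) * 5 + 2.5
    got <- m$modes[m$modes$class == k, ]
    expect_lte(abs(got$theta - tru[1]), 10)
    expect_lte(abs(got$aphi - tru[2]), 10)
  }

  ## every point of the plane is assigned a class
  expect_true(all(m$class_map %in% 1:4))

  ## determinism: rebuilding on the same cohort gives the same model
  m2 <- build_class_model(co$pooled)
  expect_identical(m$tau, m2$tau)
  expect_identical(m$class_map, m2$class_map)

  ## degenerate input: a single tight cluster cannot split into four
  one <- tibble::tibble(theta = rnorm(2000, 5, 1), phi = rnorm(2000, 2, 1))
  expect_error(build_class_model(one), "4 clusters")
  expect_error(build_class_model(co$pooled[1:10, ]), "at least")
})

test_that("segments take the length-weighted majority class of their elements", {
  co <- fx_cohort()
  for (tr in co$traces) {
    cls <- classify_segments(tr, co$model)
    expect_gte(segment_agreement(cls), 0.9)
    ## segments whose elements are all one class get that class
    el <- dplyr::left_join(cls$elements, cls$coords[, c("id", "class")],
                           by = "id")
    pure <- el |>
      dplyr::group_by(segment) |>
      dplyr::summarise(n = dplyr::n_distinct(class), cls = class[1])
    pure <- pure[pure$n == 1, ]
    got <- cls$segments$class[match(pure$segment, cls$segments$id)]
    expect_true(all(got == pure$cls))
  }

  ## explicit 60/40 length split: majority class wins
  tr <- co$traces[[1]]
  fake <- tr
  fake$elements <- tr$elements[1:5, ]
  fake$elements$segment <- 1L
  fake$elements$l <- c(6, 6, 6, 4, 4)        # class A 18 px, class B 8 px
  fake$segments <- tr$segments[1, ]
  fake$segments$id <- 1L
  fake$coords <- tr$coords[1:5, ]
  fake$coords$id <- fake$elements$id
  fake$coords$theta <- c(5, 5, 5, 85, 85)    # classes 1,1,1,2,2
  fake$coords$phi <- c(1, 1, 1, 15, 15)
  cls <- classify_segments(fake, co$model)
  expect_equal(cls$segments$class[1], 1L)
})

test_that("curvature matches the analytic circle and ranks quaternary highest", {
  ## chain sampled on a circle of radius 10 um -> kappa = 0.1 per um
  theta <- seq(0, 300, by = 5)
  R_px <- 10 / 0.5
  pts <- cbind(x = 100 + R_px * cos(pvdmorph:::deg2rad(theta)),
               y = 100 - R_px * sin(pvdmorph:::deg2rad(theta)))
  eln <- tibble::tibble(
    id = seq_along(theta), x = pts[, 1], y = pts[, 2],
    psi = pvdmorph:::wrap180(theta + 90), w = 3, l = 6, score = 1,
    bg_mean = 0, bg_sd = 0, segment = 1L,
    prev = NA_integer_, nxt = NA_integer_)
  trc <- structure(list(
    elements = eln,
    segments = tibble::tibble(id = 1L, node_from = 1, node_to = 2,
                              n_elements = nrow(eln), length_px = 0,
                              partial = FALSE),
    junctions = tibble::tibble(), tips = tibble::tibble(),
    pixel_size_um = 0.5), class = "pvd_trace")
  k <- element_curvature(trc, 0.5)
  expect_lt(abs(mean(k$curvature, na.rm = TRUE) - 0.1), 0.005)

  ## straight chain has zero curvature
  eln2 <- eln
  eln2$x <- seq(10, 10 + 2 * (nrow(eln) - 1), by = 2); eln2$y <- 50
  eln2$psi <- 0
  trc2 <- trc; trc2$elements <- eln2
  k2 <- element_curvature(trc2, 0.5)
  expect_true(all(abs(k2$curvature) < 1e-9, na.rm = TRUE))

  ## phantom: L-shaped quaternary terminals make class 4 the most curved
  co <- fx_cohort()
  cls <- classify_segments(co$traces[[1]], co$model)
  kap <- element_curvature(cls, 0.5) |>
    dplyr::left_join(cls$coords[, c("id", "class")], by = "id")
  km <- tapply(kap$curvature, kap$class, mean, na.rm = TRUE)
  expect_gt(km[["4"]], km[["1"]])
})

test_that("morphometry summaries are definitional and additive", {
  co <- fx_cohort()
  traces <- lapply(co$traces, classify_segments, model = co$model)
  sm <- summarize_morphometry(traces, pixel_size_um = 0.5)

  ## class lengths sum to total traced length (float tolerance)
  expect_equal(sum(sm$per_class$length_um), sm$totals$total_length_um)
  expect_equal(sum(sm$per_class$length_pct), 100)
  expect_true(all(sm$per_class$junction_density_per_100um >= 0, na.rm = TRUE))

  ## per-class lengths: with ground-truth labels the measured lengths match
  ## the generator within 10% (length measurement oracle); with model
  ## classes the residual misclassification between tertiary and quaternary
  ## segments shifts up to ~20% of those classes' mass
  gt_len <- vapply(1:4, function(k) {
    sum(vapply(co$traces, function(t) {
      tree <- attr(t, "tree")
      sum(tree$meta$length_um[tree$meta$class == k])
    }, numeric(1)))
  }, numeric(1))
  tr_true <- lapply(co$traces, function(t) {
    seggt <- tapply(t$elements$class_true, t$elements$segment,
                    function(x) x[1])
    t$segments$class <- as.integer(seggt[as.character(t$segments$id)])
    t$coords$class <- t$elements$class_true
    t
  })
  smt <- summarize_morphometry(tr_true, pixel_size_um = 0.5)
  for (k in 1:4) {
    expect_lte(abs(smt$per_class$length_um[k] - gt_len[k]) / gt_len[k], 0.10)
    expect_lte(abs(sm$per_class$length_um[k] - gt_len[k]) / gt_len[k], 0.25)
  }

  ## junction density: count/length vs reciprocal mean inter-junction
  ## distance agree within 15% on the primary backbone, whose junctions
  ## tile the branch (terminal stubs break the identity on short spans)
  sm1 <- summarize_morphometry(traces[1], pixel_size_um = 0.5)
  tr1 <- traces[[1]]
  ps <- sm1$per_segment
  jn_ids <- tr1$junctions$id
  runs <- ps[!is.na(ps$class) & ps$class == 1 &
               ps$node_from %in% jn_ids & ps$node_to %in% jn_ids, ]
  recip <- 100 / mean(runs$length_um[runs$length_um > 0])
  direct <- sm1$per_class$junction_density_per_100um[1]
  expect_lte(abs(direct - recip) / recip, 0.15)

  ## two disjoint traces summarized together: counts add
  sm_a <- summarize_morphometry(traces[1], pixel_size_um = 0.5)
  sm_b <- summarize_morphometry(traces[2], pixel_size_um = 0.5)
  sm_ab <- summarize_morphometry(traces[1:2], pixel_size_um = 0.5)
  expect_equal(sm_ab$totals$n_junctions,
               sm_a$totals$n_junctions + sm_b$totals$n_junctions)
  expect_equal(sm_ab$totals$n_tips, sm_a$totals$n_tips + sm_b$totals$n_tips)
  expect_equal(sm_ab$totals$total_length_um,
               sm_a$totals$total_length_um + sm_b$totals$total_length_um)

  ## definitional density on a synthetic single-class summary: junction
  ## density is count over length
  expect_equal(sm$per_class$junction_density_per_100um,
               100 * sm$per_class$junctions / sm$per_class$length_um)
})

test_that("halving the junction spacing doubles the junction density", {
  ## junctions on the tertiary backbone per unit tertiary length scale
  ## inversely with the menorah spacing
  mk <- function(sp) {
    wf <- worm_frame(160, 14, bend_amplitude = 0, seed = 3)
    tree <- pvd_tree(wf, menorah_spacing_um = sp, seed = 3)
    on3 <- abs(tree$junctions$phi) > 20 & abs(tree$junctions$phi) < 50
    sum(on3) / sum(tree$meta$length_um[tree$meta$class == 3])
  }
  rho20 <- mk(20); rho40 <- mk(40)
  expect_lte(abs(rho40 / rho20 - 0.5) / 0.5, 0.10)
})

test_that("group comparison reproduces the exact rank-sum test", {
  a <- tibble::tibble(m = c(3.1, 4.2, 2.8, 5.0, 3.7, 4.4))
  b_shift <- tibble::tibble(m = a$m + 100)
  res <- compare_groups(tibble::tibble(m = 1:10 + 0.5),
                        tibble::tibble(m = 1:10 + 100.5))
  expect_lt(res$p, 0.0005)
  expect_equal(res$stars, "***")

  ## identical groups
  expect_equal(compare_groups(a, a)$p, 1)

  ## equivalence with exact enumeration for small n
  set.seed(11)
  for (rep in 1:3) {
    x <- round(rnorm(6, 10, 2), 2); y <- round(rnorm(6, 12, 2), 2)
    got <- compare_groups(tibble::tibble(m = x), tibble::tibble(m = y))$p
    expect_equal(got, exact_ranksum_p(x, y), tolerance = 1e-6)
  }

  ## guards
  expect_error(compare_groups(tibble::tibble(m = 1),
                              tibble::tibble(m = 2)), "3 worms")
  cst <- compare_groups(tibble::tibble(m = rep(1, 5)),
                        tibble::tibble(m = rep(1, 5)))
  expect_equal(cst$p, 1)
  expect_equal(cst$flag, "constant")
})
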