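test_that("junction simulation preserves the 360-degree sum and symmetry", {
  ## noiseless limit: every triplet is the intrinsic configuration
  t0 <- simulate_junctions(junction_config(c(90, 120, 150), 0), 10, seed = 2)
  expect_true(all(abs(sweep(t0, 2, c(90, 120, 150))) < 1e-9))

  cfg <- junction_config(c(120, 120, 120), 19)
  tr <- simulate_junctions(cfg, 1e5, seed = 3)
  expect_lt(max(abs(rowSums(tr) - 360)), 1e-9)
  expect_true(all(tr[, 1] <= tr[, 2] & tr[, 2] <= tr[, 3]))
  ## symmetric configuration: the middle sorted angle stays at 120
  expect_lt(abs(mean(tr[, 2]) - 120), 0.5)

  ## deformation spread grows monotonically with the angular noise
  spread <- vapply(seq(5, 40, 5), function(sg) {
    m <- simulate_junctions(junction_config(c(120, 120, 120), sg), 4000,
                            seed = 5)
    var(m[, 3] - m[, 1])
  }, numeric(1))
  expect_true(all(diff(spread) > 0))

  expect_error(junction_config(c(-10, 180, 190), 5), "positive")
  expect_error(junction_config(c(100, 100, 100), 5), "360")
  expect_error(junction_config(c(120, 120, 120), -1), ">= 0")
  expect_error(simulate_junctions(cfg, 0), ">= 1")
})

test_that("sorted-angle order statistics are consistent and stable", {
  st <- angle_order_stats(matrix(c(90, 120, 150), 1))
  expect_equal(unname(st$means), c(90, 120, 150))

  ## linearity: the rank means always sum to 360
  m <- simulate_junctions(junction_config(c(100, 120, 140), 22), 5e4,
                          seed = 4)
  st2 <- angle_order_stats(m)
  expect_equal(sum(st2$means), 360, tolerance = 1e-9)

  ## Monte Carlo stability of the spread across seeds at n = 1e5
  g1 <- angle_order_stats(simulate_junctions(junction_config(c(120, 120, 120), 19),
                                             1e5, seed = 10))
  g2 <- angle_order_stats(simulate_junctions(junction_config(c(120, 120, 120), 19),
                                             1e5, seed = 20))
  expect_lt(abs((g1$means[3] - g1$means[1]) - (g2$means[3] - g2$means[1])), 1)

  expect_error(angle_order_stats(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("the grid fit recovers asymmetric configurations and is stable", {
  ## self-recovery for a strongly asymmetric configuration
  cfg <- junction_config(c(90, 90, 180), 26)
  obs <- simulate_junctions(cfg, 4000, seed = 8)
  fit <- fit_junction_mc(obs, alpha1 = seq(60, 120, 4), alpha2_step = 4,
                         sigma = seq(14, 38, 3), n_sim = 1e4, seed = 9)
  expect_lte(abs(fit$best$alpha1 - 90), 4)
  expect_lte(abs(fit$best$alpha2 - 90), 4)
  expect_lte(abs(fit$best$sigma - 26), 3)

  ## split-half stability: both halves select the same neighbourhood
  obs2 <- simulate_junctions(cfg, 10000, seed = 12)
  f1 <- fit_junction_mc(obs2[1:5000, ], alpha1 = seq(60, 120, 4),
                        alpha2_step = 4, sigma = seq(14, 38, 3),
                        n_sim = 1e4, seed = 9)
  f2 <- fit_junction_mc(obs2[5001:10000, ], alpha1 = seq(60, 120, 4),
                        alpha2_step = 4, sigma = seq(14, 38, 3),
                        n_sim = 1e4, seed = 9)
  expect_lte(abs(f1$best$alpha1 - f2$best$alpha1), 4)
  expect_lte(abs(f1$best$alpha2 - f2$best$alpha2), 4)

  ## separation: the residual at the generating cell beats every cell at
  ## least three grid steps away
  g <- fit$grid
  at_truth <- min(g$residual[g$alpha1 == 88 | g$alpha1 == 92])
  far <- g$residual[abs(g$alpha1 - 90) >= 12 & abs(g$alpha2 - 90) >= 12]
  expect_true(all(far > at_truth))

  ## tidiers expose the grid and the optimum
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_error(fit_junction_mc(obs[1:10, ]), "at least 100")
})
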