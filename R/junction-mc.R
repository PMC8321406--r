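## Monte Carlo characterization of three-way junction geometry. An intrinsic
## junction configuration {alpha1, alpha2, alpha3} (sorted, summing to 360
## degrees) is deformed by perturbing the three ray DIRECTIONS with
## independent zero-mean Gaussian noise of SD sigma_alpha; the resulting
## inter-ray angles sum to 360 automatically. A grid fit compares the
## sorted-angle marginals of simulated junctions against observed triplets.

#' Validate and build a junction configuration
#' @param alpha Numeric vector of three intrinsic angles (degrees); they are
#'   sorted and must be positive and sum to 360.
#' @param sigma Angular noise SD (degrees, >= 0).
#' @return A `junction_config` list.
#' @export
junction_config <- function(alpha, sigma) {
  if (length(alpha) != 3 || any(alpha <= 0)) {
    abort("a junction configuration needs three positive angles")
  }
  if (abs(sum(alpha) - 360) > 1e-6) abort("angles must sum to 360 degrees")
  if (sigma < 0) abort("sigma must be >= 0")
  structure(list(alpha = sort(alpha), sigma = sigma),
            class = "junction_config")
}

#' Simulate deformed junction angle triplets
#'
#' Places three rays at circular positions `0`, `alpha1`, `alpha1 + alpha2`,
#' perturbs each ray direction by independent Gaussian angular noise with SD
#' `sigma`, and returns the sorted inter-ray angle triplets (which sum to
#' 360 degrees by construction).
#'
#' @param config A `junction_config` (or list with `alpha`, `sigma`).
#' @param n Number of junctions to simulate.
#' @param seed Integer seed.
#' @return `n x 3` matrix of sorted triplets (columns `a1 <= a2 <= a3`).
#' @export
simulate_junctions <- function(config, n, seed = 1) {
  if (!inherits(config, "junction_config")) {
    config <- junction_config(config$alpha, config$sigma)
  }
  if (n < 1) abort("n must be >= 1")
  a <- config$alpha
  with_seed(derive_seed(seed, "mc"), {
    z <- matrix(rnorm(3 * n), n, 3)
    triplets_from_noise(a[1], a[2], config$sigma * z)
  })
}

## deterministic core: positions + noise -> sorted triplets
triplets_from_noise <- function(a1, a2, delta) {
  n <- nrow(delta)
  p1 <- (0 + delta[, 1]) %% 360
  p2 <- (a1 + delta[, 2]) %% 360
  p3 <- (a1 + a2 + delta[, 3]) %% 360
  lo <- pmin(p1, p2, p3)
  hi <- pmax(p1, p2, p3)
  mid <- p1 + p2 + p3 - lo - hi
  g1 <- mid - lo
  g2 <- hi - mid
  g3 <- 360 - g1 - g2
  s_lo <- pmin(g1, g2, g3)
  s_hi <- pmax(g1, g2, g3)
  cbind(a1 = s_lo, a2 = g1 + g2 + g3 - s_lo - s_hi, a3 = s_hi)
}

#' Order statistics of sorted angle triplets
#'
#' @param triplets `n x 3` matrix (or data frame) of sorted angle triplets.
#' @param bin_width Histogram bin width in degrees.
#' @return List with `means`, `sds` (length-3, per rank) and `hist`
#'   (tibble: `rank`, `mid`, `density`).
#' @export
angle_order_stats <- function(triplets, bin_width = 2) {
  m <- as.matrix(triplets)
  if (nrow(m) < 1) abort("need at least one triplet")
  breaks <- seq(0, 360, by = bin_width)
  hist_tbl <- lapply(1:3, function(r) {
    h <- hist(m[, r], breaks = breaks, plot = FALSE)
    tibble(rank = r, mid = h$mids, density = h$density)
  }) |> bind_rows()
  list(means = colMeans(m), sds = apply(m, 2, sd), hist = hist_tbl,
       n = nrow(m))
}

## binned proportions of each sorted-angle marginal (2-degree bins)
marginal_bins <- function(m, bin_width = 2) {
  nb <- 360 / bin_width
  sapply(1:3, function(r) {
    tabulate(pmin(nb, pmax(1, ceiling(m[, r] / bin_width))), nbins = nb) / nrow(m)
  })
}

#' Grid fit of the intrinsic junction configuration
#'
#' Simulates junction deformation for every candidate configuration on a
#' grid over `(alpha1, alpha2, sigma)` (with
#' `alpha3 = 360 - alpha1 - alpha2` and `alpha1 <= alpha2 <= alpha3`) and
#' computes a nondimensional residual against the observed triplets: the sum
#' over the three sorted-angle marginals of the integrated squared
#' difference between simulated and observed binned densities, normalized by
#' the observed densities' total squared mass. The same standard-normal
#' noise draw is reused across grid cells (scaled per sigma), which removes
#' between-cell Monte Carlo variance from the residual surface.
#'
#' @param observed `n x 3` matrix/data frame of observed sorted triplets
#'   (at least 100).
#' @param alpha1 Candidate grid for the smallest angle (degrees).
#' @param alpha2_step Step of the alpha2 grid (its range is
#'   `[alpha1, (360 - alpha1) / 2]`).
#' @param sigma Candidate grid for the angular noise SD (degrees).
#' @param n_sim Simulated junctions per grid cell.
#' @param bin_width Histogram bin width (degrees).
#' @param seed Integer seed.
#' @return A `junction_mc_fit`: `grid` tibble (`alpha1`, `alpha2`, `alpha3`,
#'   `sigma`, `residual`), `best` (the argmin row), and `sigma_surface`
#'   (per-(alpha1, alpha2) best sigma and residual).
#' @export
fit_junction_mc <- function(observed,
                            alpha1 = seq(60, 120, by = 2),
                            alpha2_step = 2,
                            sigma = seq(5, 40, by = 1),
                            n_sim = 1e4, bin_width = 2, seed = 1) {
  m <- as.matrix(observed)
  if (nrow(m) < 100) abort("need at least 100 observed triplets")
  obs <- marginal_bins(m, bin_width)
  norm <- sum(obs^2)
  z <- with_seed(derive_seed(seed, "mcfit"), matrix(rnorm(3 * n_sim), n_sim, 3))
  rows <- list()
  for (sg in sigma) {
    delta <- sg * z
    for (a1 in alpha1) {
      a2max <- (360 - a1) / 2
      a2s <- seq(a1, a2max, by = alpha2_step)
      for (a2 in a2s) {
        sim <- triplets_from_noise(a1, a2, delta)
        sb <- marginal_bins(sim, bin_width)
        res <- sum((sb - obs)^2) / norm
        rows[[length(rows) + 1]] <- c(a1, a2, 360 - a1 - a2, sg, res)
      }
    }
  }
  grid <- as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(grid) <- c("alpha1", "alpha2", "alpha3", "sigma", "residual")
  best <- grid[which.min(grid$residual), ]
  sigma_surface <- grid |>
    group_by(.data$alpha1, .data$alpha2) |>
    summarise(sigma = .data$sigma[which.min(.data$residual)],
              residual = min(.data$residual), .groups = "drop")
  out <- list(grid = grid, best = best, sigma_surface = sigma_surface,
              n_obs = nrow(m), n_sim = n_sim, bin_width = bin_width,
              seed = seed)
  class(out) <- "junction_mc_fit"
  out
}

#' @export
print.junction_mc_fit <- function(x, ...) {
  b <- x$best
  cat("<junction_mc_fit> best configuration: {",
      b$alpha1, ", ", b$alpha2, ", ", b$alpha3, "}, sigma = ", b$sigma,
      " deg (residual ", signif(b$residual, 3), ", n_obs = ", x$n_obs,
      ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.junction_mc_fit <- function(x, ...) x$grid

#' @export
glance.junction_mc_fit <- function(x, ...) {
  tibble(alpha1 = x$best$alpha1, alpha2 = x$best$alpha2,
         alpha3 = x$best$alpha3, sigma = x$best$sigma,
         residual = x$best$residual, n_obs = x$n_obs, n_sim = x$n_sim)
}

#' @export
tidy.pvd_class_model <- function(x, ...) x$modes

#' @export
glance.pvd_class_model <- function(x, ...) {
  tibble(tau = x$tau, n_elements = x$n_elements, bw = x$bw)
}
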