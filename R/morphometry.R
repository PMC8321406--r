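## Morphological classification and per-class morphometry. Elements are
## clustered in (theta, |phi|) space into the four classes that correspond
## to the conventional menorah branch orders: class 1 (primary,
## longitudinal on the lateral midline), class 2 (secondary, transverse),
## class 3 (tertiary, longitudinal at |phi| ~ 35 deg), class 4 (quaternary,
## transverse at high azimuth).

CLASS_ARCHETYPES <- tibble(
  class = 1:4,
  theta = c(0, 90, 0, 90),
  aphi = c(0, 17, 35, 60)
)

#' Build the four-class model from pooled element coordinates
#'
#' Estimates a 2-D kernel density over `(theta, |phi|)` for elements pooled
#' across a cohort, and finds the density threshold at which the
#' super-threshold set splits into exactly four connected clusters. Classes
#' are labeled by proximity of the cluster modes to the four archetypes
#' (low-theta/low-phi = 1, high-theta/mid-phi = 2, low-theta/phi~35 = 3,
#' high-theta/high-phi = 4). Every point of the `(theta, |phi|)` plane is
#' assigned to the nearest cluster, so classification is total.
#'
#' @param coords Data frame with `theta` and `phi` columns (degrees), e.g.
#'   pooled `coords` tibbles of several traces.
#' @param grid_n Density grid resolution per axis.
#' @param bw Kernel bandwidth (degrees) passed to [MASS::kde2d()].
#' @param min_elements Minimal pooled element count.
#' @return A `pvd_class_model`: density grid, threshold `tau`, cluster
#'   label grid, and a total `class_map` grid.
#' @export
build_class_model <- function(coords, grid_n = 91, bw = 12,
                              min_elements = 1000) {
  ok <- !is.na(coords$theta) & !is.na(coords$phi)
  th <- coords$theta[ok]; ap <- abs(coords$phi[ok])
  if (length(th) < min_elements) {
    abort(sprintf("need at least %d elements pooled across the cohort (got %d)",
                  min_elements, length(th)))
  }
  kd <- MASS::kde2d(th, ap, n = grid_n, h = c(bw, bw),
                    lims = c(0, 90, 0, 90))
  dens <- kd$z
  ## scan thresholds from high to low and take the first level whose
  ## super-level set has exactly four connected clusters
  levels <- quantile(as.vector(dens)[dens > 0],
                     probs = seq(0.999, 0.01, length.out = 400))
  tau <- NA_real_
  achieved <- integer(0)
  for (lv in levels) {
    lab <- EBImage::bwlabel((dens >= lv) * 1)
    ncomp <- max(lab)
    achieved <- c(achieved, ncomp)
    if (ncomp == 4) { tau <- lv; break }
  }
  if (is.na(tau)) {
    abort(sprintf(
      "no density threshold yields 4 clusters (component counts seen: %s)",
      paste(sort(unique(achieved)), collapse = ", ")))
  }
  lab <- EBImage::bwlabel((dens >= tau) * 1)
  ## cluster modes -> archetype assignment (greedy best-match)
  modes <- lapply(1:4, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    dsub <- dens[idx]
    m <- idx[which.max(dsub), ]
    c(theta = kd$x[m[1]], aphi = kd$y[m[2]])
  })
  cost <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      cost[i, j] <- sqrt((modes[[i]]["theta"] - CLASS_ARCHETYPES$theta[j])^2 +
                           (modes[[i]]["aphi"] - CLASS_ARCHETYPES$aphi[j])^2)
    }
  }
  assign <- integer(4)
  free_i <- 1:4; free_j <- 1:4
  for (step in 1:4) {
    sub <- cost[free_i, free_j, drop = FALSE]
    w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    assign[free_i[w[1]]] <- free_j[w[2]]
    free_i <- free_i[-w[1]]; free_j <- free_j[-w[2]]
  }
  ## total class map: nearest super-threshold cluster (grid Euclidean)
  cluster_grid <- matrix(0L, grid_n, grid_n)
  for (k in 1:4) cluster_grid[lab == k] <- assign[k]
  filled <- nearest_label_fill(cluster_grid)
  out <- list(
    theta_grid = kd$x, aphi_grid = kd$y, density = dens, tau = tau,
    clusters = cluster_grid, class_map = filled,
    modes = tibble(
      class = assign,
      theta = vapply(modes, function(m) unname(m["theta"]), numeric(1)),
      aphi = vapply(modes, function(m) unname(m["aphi"]), numeric(1))
    ) |> arrange(.data$class),
    n_elements = length(th), bw = bw
  )
  class(out) <- "pvd_class_model"
  out
}

## fill zero cells of a label grid with the nearest labelled cell
nearest_label_fill <- function(grid) {
  lab_idx <- which(grid > 0, arr.ind = TRUE)
  zero_idx <- which(grid == 0, arr.ind = TRUE)
  if (nrow(zero_idx) == 0) return(grid)
  labs <- grid[lab_idx]
  for (r in seq_len(nrow(zero_idx))) {
    dd <- (lab_idx[, 1] - zero_idx[r, 1])^2 + (lab_idx[, 2] - zero_idx[r, 2])^2
    grid[zero_idx[r, 1], zero_idx[r, 2]] <- labs[which.min(dd)]
  }
  grid
}

#' Classify elements and segments with a class model
#'
#' Looks up every element's `(theta, |phi|)` in the model's class map, then
#' assigns each segment the length-weighted majority class of its elements
#' (ties towards the lower class id). Elements without valid coordinates are
#' left unclassified (`NA`), and segments with no classified elements are
#' flagged.
#'
#' @param trace A `pvd_trace` with `coords` attached ([element_coords()]).
#' @param model A `pvd_class_model`.
#' @return The trace with `class` columns added to `coords` and `segments`.
#' @export
classify_segments <- function(trace, model) {
  stopifnot(inherits(trace, "pvd_trace"), inherits(model, "pvd_class_model"))
  if (is.null(trace$coords)) abort("run element_coords() first")
  co <- trace$coords
  cls <- rep(NA_integer_, nrow(co))
  ok <- !is.na(co$theta) & !is.na(co$phi)
  ix <- findInterval(clamp(co$theta[ok], 0, 90), model$theta_grid,
                     all.inside = TRUE)
  iy <- findInterval(clamp(abs(co$phi[ok]), 0, 90), model$aphi_grid,
                     all.inside = TRUE)
  cls[ok] <- model$class_map[cbind(ix, iy)]
  trace$coords$class <- cls
  el <- trace$elements |>
    left_join(trace$coords |> select("id", "class"), by = "id")
  segcls <- el |>
    group_by(segment = .data$segment) |>
    summarise(class = {
      x <- .data$class[!is.na(.data$class)]
      wl <- .data$l[!is.na(.data$class)]
      if (length(x) == 0) NA_integer_
      else {
        tab <- tapply(wl, x, sum)
        as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
      }
    }, .groups = "drop")
  trace$segments <- trace$segments |>
    select(-dplyr::any_of("class")) |>
    left_join(segcls, by = c(id = "segment"))
  trace
}

#' Per-element unsigned curvature along segments
#'
#' The curvature of element `i` is the turn angle between successive element
#' orientations divided by the inter-centre arclength,
#' `kappa_i = |delta psi| / delta s`, in radians per micrometre. Endpoint
#' elements get the one-sided estimate; pairs with coincident centres are
#' skipped.
#'
#' @param trace A `pvd_trace`.
#' @param pixel_size_um Pixel size in micrometers.
#' @return Tibble `id`, `segment`, `curvature` (1/um).
#' @export
element_curvature <- function(trace, pixel_size_um = NULL) {
  psz <- pixel_size_um %||% trace$pixel_size_um
  if (is.null(psz) || is.na(psz)) psz <- 1
  el <- trace$elements
  out <- vector("list", length(unique(el$segment)))
  i <- 0
  for (seg in unique(el$segment)) {
    e <- el[el$segment == seg, ]
    n <- nrow(e)
    kap <- rep(NA_real_, n)
    if (n >= 2) {
      dpsi <- abs(fold90(diff(e$psi)))          # turn angles, orientation-folded
      ds <- sqrt(diff(e$x)^2 + diff(e$y)^2) * psz
      pairk <- ifelse(ds > 1e-9, deg2rad(dpsi) / ds, NA_real_)
      ## element curvature: mean of its adjacent pair estimates
      kap[1] <- pairk[1]
      kap[n] <- pairk[n - 1]
      if (n > 2) {
        kap[2:(n - 1)] <- rowMeans(cbind(pairk[-(n - 1)], pairk[-1]),
                                   na.rm = TRUE)
      }
    }
    i <- i + 1
    out[[i]] <- tibble(id = e$id, segment = seg, curvature = kap)
  }
  bind_rows(out)
}

#' Morphometry summary of one or more classified traces
#'
#' Computes, per morphological class: total dendritic length (um and % of
#' total), junction count and density (junctions per 100 um of class
#' dendrite; the reciprocal of the mean inter-junction distance), tip count
#' and density, and mean unsigned curvature. Junctions are assigned the
#' class most represented among their incident segments (ties to the lower
#' class); tips take their segment's class. Also returns tips per 100 um of
#' midline and the midline length-density profile (traced length per
#' 10 um midline bin, per class).
#'
#' @param traces A classified `pvd_trace` or list of them.
#' @param pixel_size_um Pixel size (defaults to each trace's own).
#' @param midline_bin_um Bin width of the midline profile.
#' @return A `pvd_morphometry`: list with `per_class`, `totals`, `profile`.
#' @export
summarize_morphometry <- function(traces, pixel_size_um = NULL,
                                  midline_bin_um = 10) {
  if (inherits(traces, "pvd_trace")) traces <- list(traces)
  per_tr <- lapply(traces, function(tr) {
    psz <- pixel_size_um %||% tr$pixel_size_um
    if (is.null(psz) || is.na(psz)) psz <- 1
    if (is.null(tr$segments$class)) abort("classify_segments() first")
    el <- tr$elements |> left_join(tr$coords, by = "id")
    seg <- tr$segments
    ## per-segment length in um: element-chain arclength plus the links
    ## from the chain ends to the segment's junction/tip nodes (elements
    ## keep clear of junction discs, so the chain alone undercounts)
    node_pos <- function(nid) {
      j <- which(tr$junctions$id == nid)
      if (length(j)) return(c(tr$junctions$x[j[1]], tr$junctions$y[j[1]]))
      t <- which(tr$tips$node == nid)
      if (length(t)) return(c(tr$tips$x[t[1]], tr$tips$y[t[1]]))
      c(NA_real_, NA_real_)
    }
    seg_len <- vapply(seq_len(nrow(seg)), function(i) {
      e <- el[el$segment == seg$id[i], ]
      if (nrow(e) < 1) return(0)
      len <- if (nrow(e) >= 2) polyline_length(cbind(e$x, e$y)) else 0
      for (endp in list(list(node_pos(seg$node_from[i]), c(e$x[1], e$y[1])),
                        list(node_pos(seg$node_to[i]),
                             c(e$x[nrow(e)], e$y[nrow(e)])))) {
        if (!any(is.na(endp[[1]]))) {
          len <- len + sqrt(sum((endp[[1]] - endp[[2]])^2))
        }
      }
      len * psz
    }, numeric(1))
    seg$length_um <- seg_len
    ## junction class: majority of incident segments
    jt <- tr$junctions
    jclass <- rep(NA_integer_, nrow(jt))
    if (nrow(jt)) {
      for (i in seq_len(nrow(jt))) {
        inc <- seg$class[seg$node_from == jt$id[i] | seg$node_to == jt$id[i]]
        inc <- inc[!is.na(inc)]
        if (length(inc)) {
          tab <- table(inc)
          jclass[i] <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
        }
      }
    }
    ## tip class: class of the segment ending at the tip
    tclass <- rep(NA_integer_, nrow(tr$tips))
    if (nrow(tr$tips)) {
      for (i in seq_len(nrow(tr$tips))) {
        incs <- seg$class[seg$node_from == tr$tips$node[i] |
                            seg$node_to == tr$tips$node[i]]
        incs <- incs[!is.na(incs)]
        if (length(incs)) tclass[i] <- incs[1]
      }
    }
    kap <- element_curvature(tr, psz) |>
      left_join(tr$coords |> select("id", "class"), by = "id")
    midline_len <- if (!is.null(tr$frame)) tr$frame$length_um else NA_real_
    list(seg = seg, jclass = jclass, tclass = tclass, kap = kap,
         coords = tr$coords, el = el, psz = psz, midline_len = midline_len)

  })

  per_class <- lapply(1:4, function(k) {
    len <- sum(vapply(per_tr, function(p)
      sum(p$seg$length_um[p$seg$class == k], na.rm = TRUE), numeric(1)))
    jn <- sum(vapply(per_tr, function(p) sum(p$jclass == k, na.rm = TRUE),
                     numeric(1)))
    tp <- sum(vapply(per_tr, function(p) sum(p$tclass == k, na.rm = TRUE),
                     numeric(1)))
    mk <- unlist(lapply(per_tr, function(p)
      p$kap$curvature[!is.na(p$kap$class) & p$kap$class == k]))
    tibble(class = k, length_um = len,
           junctions = jn, tips = tp,
           junction_density_per_100um = if (len > 0) 100 * jn / len else NA_real_,
           tip_density_per_100um = if (len > 0) 100 * tp / len else NA_real_,
           mean_curvature = mean(mk, na.rm = TRUE))
  }) |> bind_rows()
  total_len <- sum(per_class$length_um)
  per_class$length_pct <- 100 * per_class$length_um / total_len
  midline_total <- sum(vapply(per_tr, function(p) p$midline_len, numeric(1)))
  totals <- tibble(
    total_length_um = total_len,
    n_junctions = sum(per_class$junctions),
    n_tips = sum(per_class$tips),
    junction_density_per_100um = 100 * sum(per_class$junctions) / total_len,
    midline_length_um = midline_total,
    tips_per_100um_midline = if (!is.na(midline_total) && midline_total > 0)
      100 * sum(per_class$tips) / midline_total else NA_real_
  )
  ## midline profile: traced length per class per midline bin
  prof <- lapply(seq_along(per_tr), function(ti) {
    p <- per_tr[[ti]]
    co <- p$el
    if (is.null(co$s) || all(is.na(co$s))) return(NULL)
    co |>
      filter(!is.na(.data$s), !is.na(.data$class)) |>
      mutate(bin = floor(.data$s / midline_bin_um) * midline_bin_um,
             worm = ti) |>
      group_by(.data$worm, .data$bin, .data$class) |>
      summarise(length_um = sum(.data$l) / 2 * p$psz, .groups = "drop")
  }) |> bind_rows()
  per_segment <- bind_rows(lapply(seq_along(per_tr), function(i) {
    per_tr[[i]]$seg |> mutate(worm = i)
  }))
  out <- list(per_class = per_class, totals = totals, profile = prof,
              per_segment = per_segment, n_worms = length(per_tr))
  class(out) <- "pvd_morphometry"
  out
}

#' Compare per-worm morphometric metrics between two groups
#'
#' For every metric column, performs a two-sided Mann-Whitney U test
#' (Wilcoxon rank-sum) between the two groups of per-worm values and
#' annotates significance stars (`***` p < 0.0005, `**` p < 0.005,
#' `*` p < 0.05). Metrics constant across both groups are reported with
#' p = 1 and flagged.
#'
#' @param a,b Data frames of per-worm metrics (one row per worm), or numeric
#'   vectors for a single metric.
#' @param metrics Columns to test (defaults to shared numeric columns).
#' @return Tibble with `metric`, `U`, `p`, `stars`, `flag`.
#' @export
compare_groups <- function(a, b, metrics = NULL) {
  if (is.numeric(a)) a <- tibble(value = a)
  if (is.numeric(b)) b <- tibble(value = b)
  if (nrow(a) < 3 || nrow(b) < 3) {
    abort("need at least 3 worms per group")
  }
  if (is.null(metrics)) {
    metrics <- intersect(names(a)[vapply(a, is.numeric, logical(1))],
                         names(b)[vapply(b, is.numeric, logical(1))])
  }
  rows <- lapply(metrics, function(m) {
    x <- a[[m]]; y <- b[[m]]
    if (length(unique(c(x, y))) == 1) {
      return(tibble(metric = m, U = NA_real_, p = 1, stars = "",
                    flag = "constant"))
    }
    wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
    p <- wt$p.value
    stars <- if (p < 0.0005) "***" else if (p < 0.005) "**"
             else if (p < 0.05) "*" else ""
    tibble(metric = m, U = unname(wt$statistic), p = p, stars = stars,
           flag = "")
  })
  bind_rows(rows)
}

#' @export
print.pvd_morphometry <- function(x, ...) {
  cat("<pvd_morphometry> ", x$n_worms, " worm(s), total length ",
      round(x$totals$total_length_um, 1), " um\n", sep = "")
  print(x$per_class)
  invisible(x)
}
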