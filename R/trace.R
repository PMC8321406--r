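## Rectangle-element tracing: a simplified region-based active contour.
## The neuron is represented by chains of rectangular masks fitted to the
## grayscale image and guided by the classification skeleton. Angles follow
## the y-up convention: psi = atan2(-dy, dx) so that angles measured on the
## raster agree with the worm-frame (dorsal-up) angles.

## pixels under a rotated rectangle; returns index matrix (row, col)
rect_pixels <- function(dim_img, center, psi, w, l) {
  half_diag <- sqrt(w^2 + l^2) / 2
  xr <- max(1, floor(center[1] - half_diag)):min(dim_img[2], ceiling(center[1] + half_diag))
  yr <- max(1, floor(center[2] - half_diag)):min(dim_img[1], ceiling(center[2] + half_diag))
  if (!length(xr) || !length(yr)) return(matrix(integer(0), 0, 2))
  xx <- rep(xr, each = length(yr))
  yy <- rep(yr, times = length(xr))
  relx <- xx - center[1]
  rely <- -(yy - center[2])     # y-up
  cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
  u <- relx * cp + rely * sp
  v <- -relx * sp + rely * cp
  keep <- abs(u) <= l / 2 & abs(v) <= w / 2
  cbind(yy[keep], xx[keep])
}

rect_in_bounds <- function(dim_img, center, psi, w, l) {
  cp <- abs(cos(deg2rad(psi))); sp <- abs(sin(deg2rad(psi)))
  hx <- (l * cp + w * sp) / 2
  hy <- (l * sp + w * cp) / 2
  center[1] - hx >= 0.5 && center[1] + hx <= dim_img[2] + 0.5 &&
    center[2] - hy >= 0.5 && center[2] + hy <= dim_img[1] + 0.5
}

rect_mean <- function(image, center, psi, w, l) {
  px <- rect_pixels(dim(image), center, psi, w, l)
  if (nrow(px) == 0) return(NA_real_)
  mean(image[px])
}

#' Fit score of a rectangular mask
#'
#' Normalized mean intensity under a rotated rectangular mask:
#' `clamp((mean - bg_mean) / (signal_ref - bg_mean), 0, 1)`. The score is 0
#' for a mask on pure background and 1 for a mask filled with signal at the
#' reference level.
#'
#' @param image Numeric matrix.
#' @param center `c(x, y)` rectangle centre in pixels.
#' @param psi In-plane orientation in degrees (y-up convention).
#' @param w,l Rectangle width and length in pixels.
#' @param bg_mean Local background mean.
#' @param signal_ref Signal reference intensity (> `bg_mean`).
#' @return Score in `[0, 1]`.
#' @export
rect_score <- function(image, center, psi, w, l, bg_mean, signal_ref) {
  if (!rect_in_bounds(dim(image), center, psi, w, l)) {
    abort("rectangle extends outside the image", class = "pvdmorph_oob")
  }
  m <- rect_mean(image, center, psi, w, l)
  clamp((m - bg_mean) / max(signal_ref - bg_mean, 1e-9), 0, 1)
}

#' Local background statistics from flanking rectangles
#'
#' Samples the pixels of two rectangles of the same size as the element,
#' offset laterally by `1.5 w` on each side, and pools their mean and SD.
#' If both flanks fall outside the image, a global robust estimate
#' (median and MAD-based SD) is returned.
#'
#' @inheritParams rect_score
#' @return List with pooled `mean`, `sd`, `n` (pixel count; 0 for the global
#'   fallback), and `lo_mean`, `lo_sd`: statistics of the dimmer flank,
#'   which stay clean when the other flank overlaps a neighbouring process
#'   in dense arbor regions.
#' @export
estimate_background <- function(image, center, psi, w, l) {
  nu <- deg2rad(psi + 90)
  off <- 1.5 * w
  p1 <- rect_pixels(dim(image), center + off * c(cos(nu), -sin(nu)), psi, w, l)
  p2 <- rect_pixels(dim(image), center - off * c(cos(nu), -sin(nu)), psi, w, l)
  px <- rbind(p1, p2)
  if (nrow(px) == 0) {
    g <- median(image)
    return(list(mean = g, sd = mad(image), n = 0L,
                lo_mean = g, lo_sd = mad(image)))
  }
  v <- image[px]
  flanks <- list(if (nrow(p1)) image[p1] else NULL,
                 if (nrow(p2)) image[p2] else NULL)
  flanks <- flanks[!vapply(flanks, is.null, logical(1))]
  fmeans <- vapply(flanks, mean, numeric(1))
  lo <- flanks[[which.min(fmeans)]]
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v),
       lo_mean = mean(lo), lo_sd = if (length(lo) > 1) sd(lo) else 0)
}

#' Optimal element orientation by fan search
#'
#' Scores candidate orientations `psi_prev + delta` for `|delta| <=
#' dpsi_max` in steps of `dpsi_step` and returns the orientation maximizing
#' the rectangle score. Ties are broken towards the smallest deviation
#' (the smoothness prior on successive rectangle orientations). The
#' candidate rectangle pivots about the preceding element: its centre is
#' advanced by `l/2` along the candidate direction unless a fixed `center`
#' is supplied.
#'
#' @param image Numeric matrix.
#' @param prev List with `center`, `psi`, `w`, `l` of the preceding element.
#' @param dpsi_max,dpsi_step Fan half-width and step (degrees).
#' @param bg_mean,signal_ref Score normalization (see [rect_score()]).
#' @param center Optional fixed centre `c(x, y)`.
#' @return List with `psi`, `score`, `center` of the best candidate.
#' @export
fit_orientation <- function(image, prev, dpsi_max = 60, dpsi_step = 2,
                            bg_mean = 0, signal_ref = 1, center = NULL) {
  deltas <- seq(0, dpsi_max, by = dpsi_step)
  deltas <- c(0, as.vector(rbind(deltas[-1], -deltas[-1])))  # 0, +2, -2, ...
  best <- list(psi = prev$psi, score = -Inf, center = center)
  for (d in deltas) {
    psi <- prev$psi + d
    cen <- if (is.null(center)) {
      prev$center + (prev$l / 2) * c(cos(deg2rad(psi)), -sin(deg2rad(psi)))
    } else center
    if (!rect_in_bounds(dim(image), cen, psi, prev$w, prev$l)) next
    sc <- rect_score(image, cen, psi, prev$w, prev$l, bg_mean, signal_ref)
    if (sc > best$score + 1e-12) best <- list(psi = wrap180(psi), score = sc,
                                              center = cen)
  }
  if (!is.finite(best$score)) {
    abort("no in-bounds orientation candidate", class = "pvdmorph_oob")
  }
  best
}

#' Apparent element width from the score decay profile
#'
#' Scans the rectangle score over widths `1..w_max` at fixed length and
#' locates the onset of score decay: the first width at which the discrete
#' second derivative of the score profile reaches a substantial fraction of
#' its maximum (the earliest strong decay onset; in dense arbors the profile
#' can kink again where the mask reaches a neighbouring process, so the
#' first onset is the apparent width). The fitted width is the apparent
#' fluorescent width, floored at `w_floor` (true dendrite diameters are
#' below optical resolution).
#'
#' @inheritParams rect_score
#' @param w_max Maximal width scanned.
#' @param w_floor Lower bound on the returned width.
#' @param l_fixed Rectangle length held fixed during the scan.
#' @param flat_tol Profile range below which the location is declared
#'   background (no ridge) and an error of class `pvdmorph_no_ridge` is
#'   thrown.
#' @return Fitted width `w*` in pixels.
#' @export
fit_width <- function(image, center, psi, w_max = 16, w_floor = 2,
                      l_fixed = 12, bg_mean = 0, signal_ref = 1,
                      flat_tol = 0.05) {
  ws <- seq_len(w_max)
  sc <- vapply(ws, function(w) {
    m <- rect_mean(image, center, psi, w, l_fixed)
    clamp((m - bg_mean) / max(signal_ref - bg_mean, 1e-9), 0, 1)
  }, numeric(1))
  if (max(sc) - min(sc) < flat_tol) {
    abort("flat score profile: no ridge at this location",
          class = "pvdmorph_no_ridge")
  }
  ## d2[i] is the second derivative at width i + 1; the decay onset is the
  ## width just before the first strong positive-curvature sample
  d2 <- sc[seq_len(w_max - 2)] - 2 * sc[seq(2, w_max - 1)] + sc[seq(3, w_max)]
  strong <- which(d2 >= 0.6 * max(d2))
  w_star <- strong[1]
  clamp(w_star, w_floor, w_max)
}

## signal reference: high quantile of image intensity along a pixel path
path_signal_ref <- function(image, path) {
  idx <- cbind(clamp(round(path[, 2]), 1, nrow(image)),
               clamp(round(path[, 1]), 1, ncol(image)))
  as.numeric(quantile(image[idx], 0.9, names = FALSE))
}

## direction (deg, y-up) of a path at arclength t, looking forward (+1) or
## backward (-1) over a reach of a few pixels
path_direction <- function(path, cl, t, sense, reach = 4) {
  t2 <- clamp(t + sense * reach, 0, cl[length(cl)])
  p1 <- path_point(path, cl, t); p2 <- path_point(path, cl, t2)
  v <- p2 - p1
  if (all(v == 0)) return(0)
  rad2deg(atan2(-(v[2]), v[1]))
}

path_point <- function(path, cl, t) {
  c(approx(cl, path[, 1], t)$y, approx(cl, path[, 2], t)$y)
}

#' Trace one skeleton segment with chained rectangular elements
#'
#' Grows two element chains inward from the two endpoints of a skeleton
#' edge, merging where they meet. Each accepted element is centred on the
#' skeleton path (so it contains skeleton pixels of its own edge), advances
#' the chain by half an element length (50% overlap), has its orientation
#' re-fitted within `dpsi_max` of its predecessor and its width constrained
#' to change by at most 25% between neighbours. Elements are accepted when
#' the mask mean exceeds the local background by `2 SD` and the normalized
#' score exceeds `s_min`; on acceptance the local background mean is
#' subtracted from the element footprint in the working image. If an
#' endpoint cannot be reached the chain is flagged partial.
#'
#' @param image Numeric matrix (a working copy is modified internally).
#' @param path Pixel path of the skeleton edge: matrix with columns x, y
#'   (including both endpoints).
#' @param s_min Minimal accepted score.
#' @param dpsi_max,dpsi_step Orientation fan parameters (degrees).
#' @param w_floor,w_max Width bounds (px).
#' @param working Optional working image (with previously traced elements
#'   background-subtracted); defaults to `image`.
#' @param margin_from,margin_to Chains start this many pixels inside the two
#'   path endpoints (used to keep elements clear of junction discs, whose
#'   arms contaminate the flanking background samples).
#' @return List with `elements` (tibble), `partial` (logical), and the
#'   updated `working` image.
#' @export
trace_segment <- function(image, path, s_min = 0.15, dpsi_max = 60,
                          dpsi_step = 2, w_floor = 2, w_max = 16,
                          working = NULL, margin_from = 0, margin_to = 0) {
  if (is.null(working)) working <- image
  if (nrow(path) < 2) {
    return(list(elements = empty_elements(), partial = TRUE, working = working))
  }
  cl <- polyline_cumlen(path)
  L <- cl[length(cl)]
  ref <- path_signal_ref(image, path)
  t_lo <- min(margin_from, L / 2)
  t_hi <- max(L - margin_to, L / 2)

  seed_element <- function(t, sense) {
    cen <- path_point(path, cl, t)
    psi <- path_direction(path, cl, t, sense)
    bg <- estimate_background(working, cen, psi, 4, 8)
    w <- tryCatch(
      fit_width(working, cen, psi, w_max = w_max, w_floor = w_floor,
                bg_mean = bg$lo_mean, signal_ref = ref),
      pvdmorph_no_ridge = function(e) NA_real_)
    if (is.na(w)) return(NULL)
    list(center = cen, psi = psi, w = w, l = 2 * w)
  }

  grow_chain <- function(sense) {
    t <- if (sense > 0) t_lo else t_hi
    els <- list()
    prev <- seed_element(t, sense)
    if (is.null(prev)) return(list(els = els, t = t, partial = TRUE))
    w_seed <- prev$w
    partial <- FALSE
    repeat {
      cen <- path_point(path, cl, t)
      psi_guide <- path_direction(path, cl, t, sense)
      ## normalize against the dimmer flank: in dense regions one flank may
      ## overlap a neighbouring process
      bg <- estimate_background(working, cen, prev$psi, prev$w, prev$l)
      cand <- tryCatch(
        fit_orientation(working, prev, dpsi_max, dpsi_step,
                        bg_mean = bg$lo_mean, signal_ref = ref, center = cen),
        pvdmorph_oob = function(e) NULL)
      if (is.null(cand)) { partial <- TRUE; break }
      ## keep orientation near the skeleton guide to avoid drifting onto
      ## crossing processes
      if (fold90(cand$psi - psi_guide) > 50) cand$psi <- psi_guide
      w <- tryCatch(
        fit_width(working, cen, cand$psi, w_max = w_max, w_floor = w_floor,
                  bg_mean = bg$lo_mean, signal_ref = ref),
        pvdmorph_no_ridge = function(e) NA_real_)
      if (is.na(w)) { partial <- TRUE; break }
      w <- clamp(w, prev$w * 0.75, prev$w * 1.25)  # internal energy on widths
      w <- clamp(w, w_floor, min(w_max, 2.5 * w_seed))
      l <- 2 * w
      m <- rect_mean(working, cen, cand$psi, w, l)
      score <- clamp((m - bg$lo_mean) / max(ref - bg$lo_mean, 1e-9), 0, 1)
      accept <- score >= s_min && m >= bg$lo_mean + 2 * bg$lo_sd
      if (!accept) { partial <- TRUE; break }
      el <- list(x = cen[1], y = cen[2], psi = cand$psi, w = w, l = l,
                 score = score, bg_mean = bg$lo_mean, bg_sd = bg$lo_sd, t = t)
      els[[length(els) + 1]] <- el
      ## subtract the local background from the footprint
      fp <- rect_pixels(dim(working), cen, cand$psi, w, l)
      if (nrow(fp)) working[fp] <<- pmax(working[fp] - bg$lo_mean, 0)
      prev <- list(center = cen, psi = cand$psi, w = w, l = l)
      t_next <- t + sense * l / 2
      if (t_next < t_lo || t_next > t_hi) break
      t <- t_next
    }
    list(els = els, t = t, partial = partial)
  }

  fwd <- grow_chain(+1)
  ## the backward chain stops where the forward chain already reached
  t_meet <- if (length(fwd$els)) fwd$t else t_lo
  bwd <- list(els = list(), partial = FALSE)
  if (t_hi - t_meet > 1) {
    bwd_full <- grow_chain(-1)
    keep <- vapply(bwd_full$els, function(e) e$t > t_meet + 1e-9, logical(1))
    bwd <- list(els = bwd_full$els[keep], partial = bwd_full$partial)
  }
  els <- c(fwd$els, rev(bwd$els))
  partial <- (fwd$partial && bwd$partial) ||
    (length(els) == 0) ||
    (fwd$partial && length(bwd$els) == 0)
  elements <- if (length(els)) {
    tibble(
      x = vapply(els, `[[`, numeric(1), "x"),
      y = vapply(els, `[[`, numeric(1), "y"),
      psi = vapply(els, `[[`, numeric(1), "psi"),
      w = vapply(els, `[[`, numeric(1), "w"),
      l = vapply(els, `[[`, numeric(1), "l"),
      score = vapply(els, `[[`, numeric(1), "score"),
      bg_mean = vapply(els, `[[`, numeric(1), "bg_mean"),
      bg_sd = vapply(els, `[[`, numeric(1), "bg_sd"),
      t = vapply(els, `[[`, numeric(1), "t")
    )
  } else empty_elements()
  list(elements = elements, partial = partial, working = working)
}

empty_elements <- function() {
  tibble(x = numeric(), y = numeric(), psi = numeric(), w = numeric(),
         l = numeric(), score = numeric(), bg_mean = numeric(),
         bg_sd = numeric(), t = numeric())
}

#' Fit a junction as a circle with radially emanating rectangles
#'
#' Starting from a skeleton-vertex guess, the junction centre and radius are
#' found by optimally fitting a circular mask to the binary neuron map: the
#' largest disc whose neuron-pixel fraction stays above `frac_min`
#' (the largest circle inscribed in the junction blob), tie-broken towards
#' the guess. The directions of the processes leaving the junction are the
#' peaks of the score of a radially aligned rectangular mask convolved
#' against the grayscale image over orientations sampled every
#' `angle_step` degrees (circularly smoothed; peaks must exceed a
#' prominence threshold). The junction angles are the circular differences
#' of the sorted peak directions, so the sorted triplet sums to 360 degrees
#' exactly.
#'
#' @param image Numeric matrix.
#' @param binary Binary neuron map (matrix).
#' @param vertex_guess `c(x, y)` initial centre (skeleton vertex).
#' @param search_px Centre search half-window around the guess.
#' @param r_range Disc radius search range (px).
#' @param frac_min Minimal neuron-pixel fraction for an acceptable disc.
#' @param angle_step Orientation sampling step (degrees).
#' @param rect_w Width of the radial rectangle (px).
#' @param rect_len Radial extent of the rectangle beyond the disc (px).
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   angular score range.
#' @return A list (`junction_fit_1`): `center`, `R`, `k`, `dirs`,
#'   `angles` (circular gaps), `triplet` (sorted, `NA` unless `k == 3`),
#'   `degenerate` (fewer than 3 directions), `artifact` (more than 4).
#' @export
fit_junction <- function(image, binary, vertex_guess, search_px = 5,
                         r_range = c(2, 15), frac_min = 0.88, angle_step = 2,
                         rect_w = 3, rect_len = 6, prominence_frac = 0.15) {
  dims <- dim(image)
  gx <- round(vertex_guess[1]); gy <- round(vertex_guess[2])
  disc_search <- function(span) {
    best <- list(R = -Inf, d2 = Inf, cx = gx, cy = gy, frac = -Inf)
    for (R in seq(r_range[1], r_range[2])) {
      offs <- disc_offsets_cached(R)
      for (dy in -span:span) {
        for (dx in -span:span) {
          cy <- gy + dy; cx <- gx + dx
          yy <- cy + offs$dy; xx <- cx + offs$dx
          ok <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
          if (!any(ok)) next
          frac <- mean(binary[cbind(yy[ok], xx[ok])])
          d2 <- dy^2 + dx^2
          better <- if (frac >= frac_min) {
            best$frac < frac_min || R > best$R || (R == best$R && d2 < best$d2)
          } else {
            best$frac < frac_min &&
              (frac > best$frac + 1e-9 ||
                 (abs(frac - best$frac) <= 1e-9 && d2 < best$d2))
          }
          if (better) best <- list(R = R, d2 = d2, cx = cx, cy = cy,
                                   frac = frac)
        }
      }
    }
    best
  }
  ## prefer discs at/near the skeleton vertex; in crowded regions a larger
  ## inscribed disc bridging two nearby junctions would otherwise win
  best <- disc_search(0)
  if (best$frac < frac_min) best <- disc_search(min(2, search_px))
  if (best$frac < frac_min && search_px > 2) best <- disc_search(search_px)
  center <- c(best$cx, best$cy); R <- max(best$R, r_range[1])

  angs <- seq(0, 360 - angle_step, by = angle_step)
  score <- vapply(angs, function(a) {
    dir <- c(cos(deg2rad(a)), -sin(deg2rad(a)))
    cen <- center + (R + rect_len / 2) * dir
    m <- rect_mean(image, cen, a, rect_w, rect_len)
    if (is.na(m)) 0 else m
  }, numeric(1))
  ## circular smoothing (5-sample moving mean)
  n <- length(score)
  sm <- (score +
           score[c(n, 1:(n - 1))] + score[c(2:n, 1)] +
           score[c(n - 1, n, 1:(n - 2))] + score[c(3:n, 1, 2)]) / 5
  peaks <- circular_peaks(sm, prominence_frac)
  dirs <- angs[peaks]
  ## keep only directions whose ray is contiguously neuron in the binary map
  ## (a bright neighbouring process crossing the scan annulus, or the filled
  ## inner corner between two arms, produces a score peak that is not an
  ## arm). The inner portion of the ray must be neuron and so must the outer
  ## half; a small angular tolerance absorbs arm curvature.
  if (length(dirs)) {
    ray_frac <- function(a, rr) {
      xs <- clamp(round(center[1] + rr * cos(deg2rad(a))), 1, dims[2])
      ys <- clamp(round(center[2] - rr * sin(deg2rad(a))), 1, dims[1])
      mean(binary[cbind(ys, xs)])
    }
    rr_in <- seq(max(1, R - 1), R + ceiling(rect_len / 2), by = 1)
    rr_out <- seq(R + ceiling(rect_len / 2), R + rect_len, by = 1)
    ok <- vapply(dirs, function(a) {
      any(vapply(c(a - 4, a, a + 4), function(aa) {
        ray_frac(aa, rr_in) >= 0.7 && ray_frac(aa, rr_out) >= 0.5
      }, logical(1)))
    }, logical(1))
    dirs <- dirs[ok]
  }
  k <- length(dirs)
  artifact <- k > 4
  degenerate <- k < 3
  gaps <- if (k >= 2) circular_gaps(dirs) else numeric(0)
  triplet <- if (k == 3) sort(gaps) else rep(NA_real_, 3)
  structure(list(center = center, R = R, k = k, dirs = dirs, angles = gaps,
                 triplet = triplet, degenerate = degenerate,
                 artifact = artifact, angular_score = sm),
            class = "junction_fit_1")
}

.disc_cache <- new.env(parent = emptyenv())
disc_offsets_cached <- function(R) {
  key <- as.character(R)
  if (is.null(.disc_cache[[key]])) {
    k <- ceiling(R)
    g <- expand.grid(dy = -k:k, dx = -k:k)
    .disc_cache[[key]] <- g[g$dy^2 + g$dx^2 <= R^2 + 1e-9, ]
  }
  .disc_cache[[key]]
}

## local maxima of a circular signal with a prominence criterion
circular_peaks <- function(x, prominence_frac) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng <= 0) return(integer(0))
  left <- x[c(n, 1:(n - 1))]; right <- x[c(2:n, 1)]
  cand <- which(x > left & x >= right)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]; h <- x[p]
    ## walk both ways until a higher value; prominence = h - max(min_l, min_r)
    min_l <- h; j <- p
    for (stp in seq_len(n - 1)) {
      j <- if (j == 1) n else j - 1
      if (x[j] > h) break
      min_l <- min(min_l, x[j])
    }
    min_r <- h; j <- p
    for (stp in seq_len(n - 1)) {
      j <- if (j == n) 1 else j + 1
      if (x[j] > h) break
      min_r <- min(min_r, x[j])
    }
    keep[i] <- (h - max(min_l, min_r)) >= prominence_frac * rng ||
      h == max(x)  # the global maximum is always a peak
  }
  cand[keep]
}

#' Assemble element chains and junctions into a trace graph
#'
#' Traces every skeleton edge with [trace_segment()], fits every skeleton
#' vertex with [fit_junction()], and assembles the results into a
#' `pvd_trace`: elements grouped into segments (maximal chains between two
#' junctions/tips), junction nodes, and tip nodes, with connectivity
#' inherited from the skeleton graph. Tracing is deterministic.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param classmap A `pixel_classmap` (or binary matrix).
#' @param skeleton A `skeleton_graph` from [skeletonize()]; computed from
#'   `classmap` when `NULL`.
#' @param pixel_size_um Pixel size carried through to coordinate analyses.
#' @param ... Passed to [trace_segment()].
#' @return A `pvd_trace`: list of tibbles `elements`, `segments`,
#'   `junctions`, `tips`.
#' @export
trace_neuron <- function(image, classmap, skeleton = NULL,
                         pixel_size_um = NA_real_, ...) {
  binary <- if (inherits(classmap, "pixel_classmap")) classmap$binary else classmap > 0
  if (is.null(skeleton)) skeleton <- skeletonize(classmap)
  g <- skeleton
  nodepos <- g$nodes
  ## junctions first: their fitted radii set the element margins so that
  ## rectangular elements stay clear of the junction discs
  vertices <- nodepos[nodepos$type == "vertex", ]
  jfits <- lapply(seq_len(nrow(vertices)), function(i) {
    fit_junction(image, binary, c(vertices$x[i], vertices$y[i]))
  })
  jmargin <- setNames(vapply(jfits, function(j) j$R + 2, numeric(1)),
                      vertices$id)
  margin_of <- function(nid) {
    m <- jmargin[as.character(nid)]
    if (is.na(m)) 0 else m
  }
  working <- image
  chains <- vector("list", nrow(g$edges))
  partial <- logical(nrow(g$edges))
  for (ei in seq_len(nrow(g$edges))) {
    nf <- nodepos[nodepos$id == g$edges$from[ei], ]
    nt <- nodepos[nodepos$id == g$edges$to[ei], ]
    path <- rbind(c(nf$x, nf$y), g$edges$chain[[ei]], c(nt$x, nt$y))
    res <- trace_segment(image, path, working = working,
                         margin_from = margin_of(g$edges$from[ei]),
                         margin_to = margin_of(g$edges$to[ei]), ...)
    working <- res$working
    chains[[ei]] <- res$elements
    partial[ei] <- res$partial
  }
  assemble_trace(chains, partial, jfits, g, pixel_size_um = pixel_size_um)
}

#' @rdname trace_neuron
#' @param chains List of element tibbles, one per skeleton edge.
#' @param partial Logical vector flagging incompletely traced edges.
#' @param jfits List of `junction_fit_1` results, one per skeleton vertex.
#' @param skeleton_graph The guiding `skeleton_graph`.
#' @export
assemble_trace <- function(chains, partial, jfits, skeleton_graph,
                           pixel_size_um = NA_real_) {
  g <- skeleton_graph
  vertices <- g$nodes[g$nodes$type == "vertex", ]
  tipnodes <- g$nodes[g$nodes$type == "tip", ]
  el_list <- list(); seg_list <- list()
  eid <- 0L
  for (ei in seq_along(chains)) {
    ch <- chains[[ei]]
    n <- nrow(ch)
    len <- if (n >= 2) polyline_length(cbind(ch$x, ch$y)) else 0
    seg_list[[ei]] <- tibble(
      id = ei, node_from = g$edges$from[ei], node_to = g$edges$to[ei],
      n_elements = n, length_px = len, partial = partial[ei]
    )
    if (n > 0) {
      ids <- eid + seq_len(n)
      eid <- eid + n
      el_list[[ei]] <- ch |>
        mutate(id = ids, segment = ei,
               prev = c(NA_integer_, ids[-n]),
               nxt = c(ids[-1], NA_integer_)) |>
        select("id", "x", "y", "psi", "w", "l", "score",
               "bg_mean", "bg_sd", "segment", "prev", "nxt")
    }
  }
  elements <- bind_rows(el_list)
  segments <- bind_rows(seg_list)
  junctions <- if (nrow(vertices)) {
    tibble(
      id = vertices$id,
      x = vapply(jfits, function(j) j$center[1], numeric(1)),
      y = vapply(jfits, function(j) j$center[2], numeric(1)),
      R = vapply(jfits, function(j) j$R, numeric(1)),
      k = vapply(jfits, function(j) j$k, integer(1)),
      dirs = lapply(jfits, function(j) j$dirs),
      a1 = vapply(jfits, function(j) j$triplet[1], numeric(1)),
      a2 = vapply(jfits, function(j) j$triplet[2], numeric(1)),
      a3 = vapply(jfits, function(j) j$triplet[3], numeric(1)),
      degenerate = vapply(jfits, function(j) j$degenerate, logical(1)),
      artifact = vapply(jfits, function(j) j$artifact, logical(1))
    )
  } else {
    tibble(id = integer(), x = numeric(), y = numeric(), R = numeric(),
           k = integer(), dirs = list(), a1 = numeric(), a2 = numeric(),
           a3 = numeric(), degenerate = logical(), artifact = logical())
  }
  tips <- tibble(node = tipnodes$id, x = tipnodes$x, y = tipnodes$y)
  out <- list(elements = elements, segments = segments,
              junctions = junctions, tips = tips,
              skeleton = g, pixel_size_um = pixel_size_um,
              source = "trace")
  class(out) <- "pvd_trace"
  out
}

#' @export
print.pvd_trace <- function(x, ...) {
  cat("<pvd_trace> ", nrow(x$elements), " elements in ",
      nrow(x$segments), " segments; ", nrow(x$junctions), " junctions (",
      sum(x$junctions$k == 3), " three-way), ", nrow(x$tips), " tips\n",
      sep = "")
  invisible(x)
}
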