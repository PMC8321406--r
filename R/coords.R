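## Worm-intrinsic coordinates. The moving frame (S^, D^, R^) is recovered
## from the traced neuron itself: the trace footprint is closed into a single
## body blob, its medial axis gives the longitudinal midline (arclength s,
## positive towards the tail), and the transverse blob half-width gives the
## local body radius r(s). Since the PVD hugs the body surface, the signed
## transverse image distance d maps to the azimuth phi = asin(d / r(s));
## theta is the element orientation relative to the local midline tangent.

## paint the trace footprint (elements joined segment-wise) into a canvas
footprint_from_trace <- function(trace, dims = NULL) {
  if (is.null(dims)) {
    dims <- if (!is.null(trace$skeleton)) dim(trace$skeleton$skeleton)
            else c(trace$geometry$ny, trace$geometry$nx)
  }
  canvas <- matrix(FALSE, dims[1], dims[2])
  el <- trace$elements
  if (nrow(el) == 0) return(canvas)
  for (seg in unique(el$segment)) {
    e <- el[el$segment == seg, ]
    pts <- cbind(e$x, e$y)
    path <- resample_polyline(pts, 0.5)
    wbar <- max(1.5, median(e$w) / 2)
    k <- ceiling(wbar)
    g <- expand.grid(dy = -k:k, dx = -k:k)
    g <- g[g$dy^2 + g$dx^2 <= wbar^2 + 1e-9, ]
    for (i in seq_len(nrow(path))) {
      yy <- round(path[i, 2]) + g$dy
      xx <- round(path[i, 1]) + g$dx
      ok <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
      canvas[cbind(yy[ok], xx[ok])] <- TRUE
    }
  }
  canvas
}

#' Extract the worm midline and radius profile from a trace or mask
#'
#' Closes the neuron footprint into a single body blob (morphological
#' dilation followed by erosion with an automatically sized disc), takes the
#' blob's medial axis as the approximate midline, and refines it with a
#' sliding transverse recentring pass: at each midline sample the blob
#' boundary is found along the local normal on both sides, the midline point
#' is moved to the mid-crossing and the local radius `r(s)` is half the
#' crossing distance. Arclength `s` starts at 0 at the head end (by
#' convention the leftmost end unless `head = "right"`) and increases
#' towards the tail.
#'
#' @param x A `pvd_trace`, a `pixel_classmap`, or a binary matrix.
#' @param pixel_size_um Pixel size in micrometers.
#' @param head Which image side is the head: `"left"` or `"right"`.
#' @param dorsal Which image side is dorsal: `"up"` or `"down"`.
#' @param close_radius_px Disc radius for the closing; `NULL` chooses it
#'   automatically from the largest internal gap of the footprint.
#' @return A `worm_frame` whose midline is expressed in micrometers in a
#'   y-up frame derived from the raster (`x = col * pixel`,
#'   `y = -row * pixel`), with attribute `midline_px` holding the pixel-space
#'   midline and radius for direct comparison with raster data.
#' @export
extract_midline <- function(x, pixel_size_um = 1, head = c("left", "right"),
                            dorsal = c("up", "down"), close_radius_px = NULL) {
  head <- match.arg(head); dorsal <- match.arg(dorsal)
  fp <- if (inherits(x, "pvd_trace")) footprint_from_trace(x)
        else if (inherits(x, "pixel_classmap")) x$binary
        else x > 0
  if (!any(fp)) abort("empty footprint")
  dims <- dim(fp)

  if (is.null(close_radius_px)) {
    ## largest internal gap: distance-to-neuron inside the body envelope
    ## (row span of the footprint in a running window of columns, so strips
    ## between sparsely placed branches count as internal)
    dm <- EBImage::distmap(1 - fp)
    cols <- which(colSums(fp) > 0)
    W <- max(10, round(0.15 * (max(cols) - min(cols))))
    minrow <- rep(NA_integer_, dims[2]); maxrow <- rep(NA_integer_, dims[2])
    for (j in cols) {
      rows <- which(fp[, j])
      minrow[j] <- rows[1]; maxrow[j] <- rows[length(rows)]
    }
    hull <- matrix(FALSE, dims[1], dims[2])
    for (j in min(cols):max(cols)) {
      win <- max(1, j - W):min(dims[2], j + W)
      top <- suppressWarnings(min(minrow[win], na.rm = TRUE))
      bot <- suppressWarnings(max(maxrow[win], na.rm = TRUE))
      if (is.finite(top) && is.finite(bot)) hull[top:bot, j] <- TRUE
    }
    close_radius_px <- min(60, ceiling(max(dm[hull])) + 2)
  }
  brush <- EBImage::makeBrush(2 * close_radius_px + 1, "disc")
  ## pad before closing: erosion at the raster border otherwise keeps the
  ## dilated band that was clipped by the edge
  pad <- close_radius_px + 2
  fpp <- matrix(0, dims[1] + 2 * pad, dims[2] + 2 * pad)
  fpp[pad + seq_len(dims[1]), pad + seq_len(dims[2])] <- fp * 1
  blob <- EBImage::closing(fpp, brush)
  blob <- EBImage::fillHull(blob)
  blob <- blob[pad + seq_len(dims[1]), pad + seq_len(dims[2])]
  ## clip the closing overshoot at the tapered ends with a tight column
  ## envelope of the footprint (body assumed roughly along the x axis)
  cols2 <- which(colSums(fp) > 0)
  env <- matrix(0, dims[1], dims[2])
  w2 <- close_radius_px
  mn2 <- rep(NA_integer_, dims[2]); mx2 <- rep(NA_integer_, dims[2])
  for (j in cols2) {
    rows <- which(fp[, j])
    mn2[j] <- rows[1]; mx2[j] <- rows[length(rows)]
  }
  for (j in min(cols2):max(cols2)) {
    win <- max(1, j - w2):min(dims[2], j + w2)
    top <- suppressWarnings(min(mn2[win], na.rm = TRUE))
    bot <- suppressWarnings(max(mx2[win], na.rm = TRUE))
    if (is.finite(top) && is.finite(bot)) {
      env[max(1, top - 2):min(dims[1], bot + 2), j] <- 1
    }
  }
  blob <- blob * env
  lab <- EBImage::bwlabel(blob)
  nlab <- max(lab)
  if (nlab > 1) {
    ## keep the largest component; fail if fragments are substantial
    areas <- tabulate(lab[lab > 0], nbins = nlab)
    if (sort(areas, decreasing = TRUE)[2] > 0.05 * max(areas)) {
      abort("body blob fragments into multiple components")
    }
    blob <- (lab == which.max(areas)) * 1
  }
  blob <- matrix(as.numeric(blob), dims[1], dims[2])

  ## medial axis -> longest path through the skeleton graph
  g <- build_skeleton_graph(thin_binary(blob))
  if (nrow(g$edges) == 0) abort("degenerate body blob (no medial axis)")
  path_px <- graph_diameter_path(g)
  path_px <- resample_polyline(path_px, 2)
  path_px <- cbind(smooth_ma(path_px[, 1], 7), smooth_ma(path_px[, 2], 7))

  ## extend both ends along the local tangent to the blob boundary
  path_px <- extend_to_boundary(path_px, blob)

  ## transverse recentring + radius measurement: the raw medial axis of the
  ## closed blob weaves between branch bulges, so the sliding-window
  ## recentring is iterated with strong smoothing until it settles on the
  ## transverse mid-crossing line
  rmax_px <- max(EBImage::distmap(blob))
  r_px <- numeric(nrow(path_px))
  for (pass in 1:4) {
    n <- nrow(path_px)
    r_px <- numeric(n)
    for (i in seq_len(n)) {
      j0 <- max(1, i - 3); j1 <- min(n, i + 3)
      v <- path_px[j1, ] - path_px[j0, ]
      nv <- sqrt(sum(v^2)); if (nv == 0) next
      nu <- c(-v[2], v[1]) / nv
      tpos <- march_to_boundary(blob, path_px[i, ], nu, 1.6 * rmax_px)
      tneg <- march_to_boundary(blob, path_px[i, ], -nu, 1.6 * rmax_px)
      r_px[i] <- (tpos + tneg) / 2
      path_px[i, ] <- path_px[i, ] + nu * (tpos - tneg) / 2
    }
    win <- if (pass < 3) 15 else 7
    path_px <- smooth_path_keep_ends(path_px, win)
    r_px <- smooth_ma(r_px, 5)
  }
  ## the blob's closing cap biases the path over the last cap-length at each
  ## end; replace those portions by straight extrapolation from the adjacent
  ## stable interior, extended to the blob boundary
  path_px <- straighten_ends(path_px, blob, cap_len = 2 * close_radius_px,
                               rmax_px = rmax_px)
  ## final radius-only measurement pass at the settled positions
  n <- nrow(path_px)
  r_px <- numeric(n)
  for (i in seq_len(n)) {
    j0 <- max(1, i - 3); j1 <- min(n, i + 3)
    v <- path_px[j1, ] - path_px[j0, ]
    nv <- sqrt(sum(v^2)); if (nv == 0) next
    nu <- c(-v[2], v[1]) / nv
    r_px[i] <- (march_to_boundary(blob, path_px[i, ], nu, 1.6 * rmax_px) +
                  march_to_boundary(blob, path_px[i, ], -nu, 1.6 * rmax_px)) / 2
  }
  r_px <- smooth_ma(r_px, 5)
  ## drop degenerate (coincident) samples
  keep <- c(TRUE, sqrt(diff(path_px[, 1])^2 + diff(path_px[, 2])^2) > 1e-6)
  path_px <- path_px[keep, , drop = FALSE]
  r_px <- r_px[keep]

  if ((head == "left") != (path_px[1, 1] < path_px[nrow(path_px), 1])) {
    path_px <- path_px[rev(seq_len(nrow(path_px))), ]
    r_px <- rev(r_px)
  }

  ## micrometre y-up frame; dorsal flag flips d-sign handling downstream
  x_um <- path_px[, 1] * pixel_size_um
  y_um <- -path_px[, 2] * pixel_size_um
  s <- polyline_cumlen(cbind(x_um, y_um))
  tangent <- rad2deg(atan2(c(diff(y_um), tail(diff(y_um), 1)),
                           c(diff(x_um), tail(diff(x_um), 1))))
  out <- list(
    midline = tibble(s = s, x = x_um, y = y_um,
                     tangent_deg = tangent,
                     r = pmax(r_px, 0.5) * pixel_size_um),
    length_um = s[length(s)],
    max_radius_um = max(r_px) * pixel_size_um,
    pixel_size_um = pixel_size_um,
    dorsal = dorsal,
    source = "estimated"
  )
  attr(out, "midline_px") <- cbind(path_px, r_px = r_px)
  class(out) <- "worm_frame"
  out
}

## replace the first/last `cap_len` of the path (biased by the closing cap)
## by a tracked extension: step outward from the stable interior, recentring
## transversally at each step, until the blob pinches out
straighten_ends <- function(path, blob, cap_len, rmax_px = NULL) {
  if (is.null(rmax_px)) rmax_px <- max(EBImage::distmap(blob))
  step <- 3
  for (endi in 1:2) {
    if (endi == 2) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
    cl <- polyline_cumlen(path)
    L <- cl[length(cl)]
    if (L > 3 * cap_len) {
      i_cut <- which(cl > cap_len)[1]
      i_ref <- which(cl > cap_len + 40)[1]
      if (is.na(i_ref)) i_ref <- min(i_cut + 15, nrow(path))
      u <- path[i_cut, ] - path[i_ref, ]
      nu0 <- sqrt(sum(u^2))
      if (nu0 > 0) {
        u <- u / nu0
        t <- march_to_boundary(blob, path[i_cut, ], u, 1.5 * cap_len)
        ## replace the cap by the ray only if the ray reaches at least as
        ## far as most of the cap; otherwise keep the original cap
        if (t >= 0.75 * cap_len) {
          steps_out <- seq(min(t, 1.2 * cap_len), 2, by = -2)
          new_pts <- cbind(path[i_cut, 1] + steps_out * u[1],
                           path[i_cut, 2] + steps_out * u[2])
          path <- rbind(new_pts, path[i_cut:nrow(path), , drop = FALSE])
        }
      }
    }
    if (endi == 2) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  }
  path
}

## moving-average smoothing of a polyline that keeps the endpoints pinned
## (plain windowed averaging retracts the path ends inward)
smooth_path_keep_ends <- function(path, win) {
  sm <- cbind(smooth_ma(path[, 1], win), smooth_ma(path[, 2], win))
  n <- nrow(path)
  h <- min(max(2, win), floor(n / 2))
  for (i in seq_len(h)) {
    a <- (h - i + 1) / h
    sm[i, ] <- a * path[i, ] + (1 - a) * sm[i, ]
    sm[n - i + 1, ] <- a * path[n - i + 1, ] + (1 - a) * sm[n - i + 1, ]
  }
  sm
}

## walk from p along unit direction u until leaving the blob
march_to_boundary <- function(blob, p, u, tmax) {
  dims <- dim(blob)
  t <- 0
  repeat {
    t <- t + 0.5
    q <- p + t * u
    qy <- round(q[2]); qx <- round(q[1])
    if (qy < 1 || qy > dims[1] || qx < 1 || qx > dims[2] ||
        blob[qy, qx] == 0) return(t - 0.5)
    if (t > tmax) return(t)
  }
}

extend_to_boundary <- function(path, blob, tmax = NULL) {
  if (is.null(tmax)) tmax <- max(dim(blob))
  for (endi in c(1, 2)) {
    n <- nrow(path)
    if (endi == 1) { p <- path[1, ]; v <- path[1, ] - path[min(8, n), ] }
    else { p <- path[n, ]; v <- path[n, ] - path[max(1, n - 7), ] }
    nv <- sqrt(sum(v^2)); if (nv == 0) next
    u <- v / nv
    t <- min(march_to_boundary(blob, p, u, tmax), tmax)
    if (t >= 1) {
      ext <- outer(seq(1, floor(t), by = 1), u) +
        matrix(p, nrow = length(seq(1, floor(t))), ncol = 2, byrow = TRUE)
      path <- if (endi == 1) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], path)
              else rbind(path, ext)
    }
  }
  path
}

## longest path (by edge length) between two tips of a skeleton graph
graph_diameter_path <- function(g) {
  nodes <- g$nodes$id
  adj <- lapply(setNames(nodes, nodes), function(i) {
    e1 <- which(g$edges$from == i); e2 <- which(g$edges$to == i)
    rbind(
      if (length(e1)) cbind(g$edges$to[e1], g$edges$length_px[e1], e1),
      if (length(e2)) cbind(g$edges$from[e2], g$edges$length_px[e2], e2)
    )
  })
  ## shortest-path distances from src (SPFA); the midline is the pair of
  ## nodes at maximal shortest-path distance, robust to small cycles in the
  ## medial axis
  farthest <- function(src) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    pred <- setNames(rep(NA_integer_, length(nodes)), nodes)
    prede <- setNames(rep(NA_integer_, length(nodes)), nodes)
    dist[as.character(src)] <- 0
    queue <- src
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      a <- adj[[as.character(cur)]]
      if (is.null(a)) next
      for (r in seq_len(nrow(a))) {
        nd <- dist[as.character(cur)] + a[r, 2]
        key <- as.character(a[r, 1])
        if (nd < dist[key] - 1e-9) {
          dist[key] <- nd; pred[key] <- cur; prede[key] <- a[r, 3]
          queue <- c(queue, a[r, 1])
        }
      }
    }
    reach <- dist[is.finite(dist)]
    list(node = as.integer(names(which.max(reach))), dist = dist,
         pred = pred, prede = prede)
  }
  f1 <- farthest(nodes[1])
  f2 <- farthest(f1$node)
  ## reconstruct pixel path from f2$node back to f1$node
  pathpts <- list()
  cur <- f2$node
  while (!is.na(f2$pred[as.character(cur)])) {
    ei <- f2$prede[as.character(cur)]
    prev <- f2$pred[as.character(cur)]
    nf <- g$nodes[g$nodes$id == prev, ]; nt <- g$nodes[g$nodes$id == cur, ]
    ch <- g$edges$chain[[ei]]
    ## chains are stored walking from `from` to `to`; orient prev -> cur
    if (g$edges$from[ei] != prev && nrow(ch)) {
      ch <- ch[rev(seq_len(nrow(ch))), , drop = FALSE]
    }
    seg <- rbind(c(nf$x, nf$y), ch, c(nt$x, nt$y))
    pathpts[[length(pathpts) + 1]] <- seg
    cur <- prev
  }
  pts <- do.call(rbind, rev(pathpts))
  pts[rev(seq_len(nrow(pts))), , drop = FALSE]
}

#' Worm-intrinsic coordinates of traced elements
#'
#' Maps every element of a trace into the worm frame: arclength `s` of the
#' nearest midline point (micrometers, 0 at the head), signed transverse
#' distance `d` (positive dorsal), azimuth `phi = asin(d / r(s))` in
#' degrees, and midline orientation `theta` (the element orientation
#' relative to the local midline tangent, folded to `[0, 90]`; the signed
#' variant is kept in `theta_signed`). Elements whose `|d|` exceeds
#' `r(s)` by more than 10% are flagged `excluded` (and get `phi = NA`);
#' smaller excesses are clamped to `|phi| = 90`.
#'
#' @param trace A `pvd_trace`.
#' @param frame A `worm_frame` (estimated via [extract_midline()] when
#'   `NULL`).
#' @param pixel_size_um Pixel size; defaults to the trace's.
#' @return The trace with a `coords` tibble (`id`, `s`, `d`, `phi`,
#'   `theta`, `theta_signed`, `excluded`) and `frame` attached.
#' @export
element_coords <- function(trace, frame = NULL, pixel_size_um = NULL) {
  stopifnot(inherits(trace, "pvd_trace"))
  psz <- pixel_size_um %||% trace$pixel_size_um
  if (is.null(psz) || is.na(psz)) psz <- 1
  if (is.null(frame)) frame <- extract_midline(trace, pixel_size_um = psz)
  el <- trace$elements
  pts <- cbind(el$x * psz, -el$y * psz)
  if (!is.null(frame$source) && frame$source == "estimated") {
    ## frame already lives in the raster-derived y-up micrometre system
  } else if (inherits(frame, "worm_frame") && is.null(frame$source)) {
    ## ground-truth phantom frame: convert pixel coords through the phantom
    ## geometry so both live in the same micrometre system
    geom <- phantom_geometry(frame, psz)
    pts <- px_to_um(geom, cbind(el$x, el$y))
  }
  ic <- intrinsic_of_points(frame, pts)
  dsign <- if (!is.null(frame$dorsal) && frame$dorsal == "down") -1 else 1
  d <- ic$d * dsign
  excess <- abs(d) / ic$r
  excluded <- excess > 1.1
  phi <- rad2deg(asin(clamp(d / ic$r, -1, 1)))
  phi[excluded] <- NA_real_
  tangent <- approx(frame$midline$s, frame$midline$tangent_deg, ic$s,
                    ties = "ordered")$y
  rel <- el$psi - tangent
  theta_signed <- wrap180(rel)
  theta_signed[theta_signed > 90] <- theta_signed[theta_signed > 90] - 180
  theta_signed[theta_signed <= -90] <- theta_signed[theta_signed <= -90] + 180
  trace$coords <- tibble(
    id = el$id, s = ic$s, d = d, r = ic$r, phi = phi,
    theta = fold90(rel), theta_signed = theta_signed,
    excluded = excluded
  )
  trace$frame <- frame
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct junction angles for the projection to the image plane
#'
#' The worm's surface is curved; a junction at azimuth `phi` is seen in the
#' lateral projection with its transverse length components foreshortened
#' by `cos(phi)` (from `d = r sin(phi)`). Each incident image-plane ray
#' `(dS, dD)` (components along the local midline tangent and dorsal
#' normal) is unprojected to the body surface tangent plane as
#' `(dS, dD / cos(phi))`, the angles are recomputed as circular differences
#' of the corrected ray directions and re-sorted. At `phi = 0` the
#' correction is the identity. Junctions with `|phi| > 80` degrees are
#' flagged unstable and excluded from angle statistics.
#'
#' @param frame A `worm_frame`.
#' @param dirs Numeric vector of image-plane ray directions (degrees, y-up).
#' @param s Arclength of the junction (micrometers).
#' @param phi Azimuth of the junction (degrees).
#' @return List with `dirs` (corrected), `angles`, `triplet` (sorted, for
#'   3-way junctions), and `excluded`.
#' @export
correct_junction_angles <- function(frame, dirs, s, phi) {
  tangent <- approx(frame$midline$s, frame$midline$tangent_deg, s, ties = "ordered")$y
  if (is.na(phi) || abs(phi) > 80) {
    return(list(dirs = dirs, angles = circular_gaps(dirs),
                triplet = rep(NA_real_, 3), excluded = TRUE))
  }
  rel <- deg2rad(dirs - tangent)
  dS <- cos(rel); dD <- sin(rel) / cos(deg2rad(phi))
  corr <- wrap360(tangent + rad2deg(atan2(dD, dS)))
  gaps <- circular_gaps(corr)
  list(dirs = corr, angles = gaps,
       triplet = if (length(dirs) == 3) sort(gaps) else rep(NA_real_, 3),
       excluded = FALSE)
}

#' Attach corrected junction coordinates and angles to a trace
#'
#' Computes (s, phi) for every junction and applies
#' [correct_junction_angles()], appending `s`, `phi`, and the corrected
#' sorted triplet (`a1c`, `a2c`, `a3c`) plus an `excluded_angles` flag to
#' the trace's `junctions` tibble.
#'
#' @inheritParams element_coords
#' @return The augmented trace.
#' @export
junction_coords <- function(trace, frame = NULL, pixel_size_um = NULL) {
  stopifnot(inherits(trace, "pvd_trace"))
  psz <- pixel_size_um %||% trace$pixel_size_um
  if (is.null(psz) || is.na(psz)) psz <- 1
  if (is.null(frame)) frame <- trace$frame %||% extract_midline(trace, pixel_size_um = psz)
  jt <- trace$junctions
  if (nrow(jt) == 0) { trace$frame <- frame; return(trace) }
  pts <- cbind(jt$x * psz, -jt$y * psz)
  if (inherits(frame, "worm_frame") && is.null(frame$source)) {
    geom <- phantom_geometry(frame, psz)
    pts <- px_to_um(geom, cbind(jt$x, jt$y))
  }
  ic <- intrinsic_of_points(frame, pts)
  dsign <- if (!is.null(frame$dorsal) && frame$dorsal == "down") -1 else 1
  phi <- rad2deg(asin(clamp(ic$d * dsign / ic$r, -1, 1)))
  a1c <- a2c <- a3c <- rep(NA_real_, nrow(jt))
  excluded <- logical(nrow(jt))
  for (i in seq_len(nrow(jt))) {
    if (jt$k[i] != 3 || isTRUE(jt$degenerate[i])) { excluded[i] <- TRUE; next }
    cr <- correct_junction_angles(frame, jt$dirs[[i]], ic$s[i], phi[i])
    excluded[i] <- cr$excluded
    if (!cr$excluded) { a1c[i] <- cr$triplet[1]; a2c[i] <- cr$triplet[2]
      a3c[i] <- cr$triplet[3] }
  }
  trace$junctions <- jt |>
    mutate(s = ic$s, phi = phi, a1c = a1c, a2c = a2c, a3c = a3c,
           excluded_angles = excluded)
  trace$frame <- frame
  trace
}
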