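#' Generate a synthetic worm body frame
#'
#' Builds a smooth, arclength-parameterized midline for a synthetic
#' C. elegans body in the lateral (left-side) view, together with a radius
#' profile `r(s)` that tapers towards both ends. The worm lies with its
#' anterior (head) at `s = 0`; `s` increases posteriorly towards the tail.
#' Coordinates are in micrometers with the dorsal direction along +y.
#'
#' The midline is integrated from a sinusoidal heading profile, so its total
#' arclength equals `length_um` by construction.
#'
#' @param length_um Body length in micrometers (> 0).
#' @param max_radius_um Maximal body radius in micrometers (> 0).
#' @param bend_amplitude Maximal heading deviation of the midline from the
#'   horizontal, in degrees. `0` gives a straight horizontal midline.
#' @param n_bends Number of bend periods along the body.
#' @param seed Integer seed controlling the bend phase.
#' @return A `worm_frame` object: a list with a `midline` tibble
#'   (`s`, `x`, `y`, `tangent_deg`, `r`) and scalar metadata.
#' @examples
#' wf <- worm_frame(200, 15, bend_amplitude = 10, seed = 1)
#' head(wf$midline)
#' @export
worm_frame <- function(length_um, max_radius_um, bend_amplitude = 0,
                       n_bends = 1.5, seed = 1) {
  if (!is.numeric(length_um) || length_um <= 0) {
    abort("`length_um` must be a positive number.")
  }
  if (!is.numeric(max_radius_um) || max_radius_um <= 0) {
    abort("`max_radius_um` must be a positive number.")
  }
  phase <- with_seed(derive_seed(seed, "frame"), runif(1, 0, 2 * pi))
  ds <- min(1, length_um / 200)
  s <- seq(0, length_um, by = ds)
  if (s[length(s)] < length_um) s <- c(s, length_um)
  heading <- deg2rad(bend_amplitude) * sin(2 * pi * n_bends * s / length_um + phase)
  if (bend_amplitude == 0) heading[] <- 0
  ## trapezoidal integration of the unit-speed curve
  n <- length(s)
  dx <- diff(s) * (cos(heading[-n]) + cos(heading[-1])) / 2
  dy <- diff(s) * (sin(heading[-n]) + sin(heading[-1])) / 2
  x <- c(0, cumsum(dx))
  y <- c(0, cumsum(dy))
  ## chord lengths slightly undershoot ds for curved headings; rescale so the
  ## polyline arclength matches length_um
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (arc > 0) {
    x <- x * length_um / arc
    y <- y * length_um / arc
  }
  u <- s / length_um
  r <- max_radius_um * pmax((4 * u * (1 - u))^0.35, 0.02)
  out <- list(
    midline = tibble(
      s = s, x = x, y = y,
      tangent_deg = rad2deg(heading),
      r = r
    ),
    length_um = length_um,
    max_radius_um = max_radius_um,
    bend_amplitude = bend_amplitude,
    seed = seed
  )
  class(out) <- "worm_frame"
  out
}

## interpolate frame quantities at arbitrary arclengths
frame_at <- function(frame, s) {
  m <- frame$midline
  s <- clamp(s, min(m$s), max(m$s))
  list(
    s = s,
    x = approx(m$s, m$x, s, ties = "ordered")$y,
    y = approx(m$s, m$y, s, ties = "ordered")$y,
    tangent_deg = approx(m$s, m$tangent_deg, s, ties = "ordered")$y,
    r = approx(m$s, m$r, s, ties = "ordered")$y
  )
}

## body point at (s, d): midline plus signed offset along the local normal
## (+d is dorsal)
frame_point <- function(frame, s, d) {
  f <- frame_at(frame, s)
  nu <- deg2rad(f$tangent_deg + 90)
  cbind(x = f$x + d * cos(nu), y = f$y + d * sin(nu))
}

## constant-offset polyline (offset curve of the midline at signed distance d)
offset_polyline <- function(frame, s_seq, d) {
  pts <- frame_point(frame, s_seq, d)
  list(pts = pts, s = s_seq)
}

## map arbitrary image-plane points (um, y-up dorsal) to intrinsic (s, d, phi)
## by nearest-midline-point association
intrinsic_of_points <- function(frame, pts) {
  m <- frame$midline
  n <- nrow(pts)
  s <- numeric(n); d <- numeric(n)
  mx <- m$x; my <- m$y
  for (i in seq_len(n)) {
    dd <- (mx - pts[i, 1])^2 + (my - pts[i, 2])^2
    j <- which.min(dd)
    s[i] <- m$s[j]
    nu <- deg2rad(m$tangent_deg[j] + 90)
    d[i] <- (pts[i, 1] - mx[j]) * cos(nu) + (pts[i, 2] - my[j]) * sin(nu)
  }
  r <- approx(m$s, m$r, s, ties = "ordered")$y
  phi <- rad2deg(asin(clamp(d / r, -1, 1)))
  tibble(s = s, d = d, r = r, phi = phi)
}

rotate_about <- function(pts, center, angle_deg) {
  a <- deg2rad(angle_deg)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  cbind(x = center[1] + dx * cos(a) - dy * sin(a),
        y = center[2] + dx * sin(a) + dy * cos(a))
}

#' Generate a ground-truth PVD dendritic tree on a worm frame
#'
#' Lays out an idealized PVD arbor as repeating candelabrum ("menorah")
#' motifs: a primary (class-1) process running longitudinally along the
#' lateral midline (azimuth 0), secondary (class-2) processes leaving it
#' transversely, tertiary (class-3) processes running longitudinally at
#' azimuth about +/-35 degrees, and quaternary (class-4) processes leaving
#' the tertiaries transversely towards the dorsal/ventral margins, ending in
#' short L-shaped hooks. All junctions are three-way T-junctions by
#' construction (an optional fraction of four-way junctions can be added).
#' Exact junction positions, outgoing ray directions, sorted angle triplets,
#' per-point intrinsic coordinates and tip locations are recorded as ground
#' truth.
#'
#' @param frame A `worm_frame`.
#' @param menorah_spacing_um Arclength spacing between candelabra (menorahs).
#' @param class_azimuths_deg Named numeric: azimuth of the primary
#'   (`class1`) and unsigned azimuth of the tertiary (`class3`) processes.
#' @param class4_azimuth_deg Unsigned azimuth reached by quaternary tips.
#' @param jitter Dimensionless deformation scale in `[0, 1]`: `0` gives the
#'   exact T-junction grid; positive values rotate branches by Gaussian
#'   angles with SD `15 * jitter` degrees and displace branch points.
#' @param four_way_frac Fraction of menorahs whose primary junction receives
#'   an extra opposite-side stub, making it four-way.
#' @param seed Integer seed.
#' @return A `pvd_tree` object with `polylines` (list of micrometre point
#'   matrices), `meta` (per-polyline class/length tibble), `coords`
#'   (per-point intrinsic coordinates), `junctions`, `tips`, and `frame`.
#' @export
pvd_tree <- function(frame,
                     menorah_spacing_um = 30,
                     class_azimuths_deg = c(class1 = 0, class3 = 35),
                     class4_azimuth_deg = 80,
                     jitter = 0,
                     four_way_frac = 0,
                     seed = 1) {
  stopifnot(inherits(frame, "worm_frame"))
  L <- frame$length_um
  sp <- menorah_spacing_um
  if (sp >= L) abort("`menorah_spacing_um` must be smaller than the worm length.")
  az3 <- unname(class_azimuths_deg["class3"])
  if (is.na(az3)) az3 <- 35
  az4 <- class4_azimuth_deg
  step <- 1

  polys <- list()    # each: list(pts, class, attach = list(list(i, jid)))
  juncs <- list()    # each: list(x, y, incident = list(list(poly, i, kind)))
  tips  <- list()

  add_poly <- function(pts, class) {
    polys[[length(polys) + 1]] <<- list(pts = pts, class = class,
                                        attach = list())
    length(polys)
  }
  add_junction <- function(p) {
    juncs[[length(juncs) + 1]] <<- list(x = p[1], y = p[2], incident = list())
    length(juncs)
  }
  link <- function(jid, pid, i, kind) {
    juncs[[jid]]$incident[[length(juncs[[jid]]$incident) + 1]] <<-
      list(poly = pid, i = i, kind = kind)
    polys[[pid]]$attach[[length(polys[[pid]]$attach) + 1]] <<-
      list(i = i, jid = jid)
  }
  nearest_idx <- function(pts, p) {
    which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
  }

  with_seed(derive_seed(seed, "tree"), {
    s0 <- 0.02 * L; s1 <- 0.98 * L
    prim <- offset_polyline(frame, seq(s0, s1, by = step), 0)
    pid1 <- add_poly(prim$pts, 1L)
    tips[[length(tips) + 1]] <- list(p = prim$pts[1, ], poly = pid1)
    tips[[length(tips) + 1]] <- list(p = prim$pts[nrow(prim$pts), ], poly = pid1)

    ## menorahs alternate sides every half-spacing, so each side carries a
    ## candelabrum every `sp` micrometers and the tertiary spans tile the
    ## body on both sides (as the dense wild-type arbor does)
    s_k <- seq(s0 + 0.35 * sp, s1 - 0.35 * sp, by = sp / 2)
    if (length(s_k) < 1) abort("`menorah_spacing_um` leaves no room for menorahs.")
    side0 <- sample(c(-1L, 1L), 1)   # no fixed dorsal/ventral preference
    jit_ang <- function() if (jitter > 0) rnorm(1, 0, 15 * jitter) else 0
    jit_pos <- function() if (jitter > 0) rnorm(1, 0, 0.1 * jitter * sp) else 0
    four_way <- runif(length(s_k)) < four_way_frac

    for (k in seq_along(s_k)) {
      sk <- s_k[k] + jit_pos()
      sig <- side0 * (if (k %% 2 == 1) 1 else -1)
      fk <- frame_at(frame, sk)
      d_abs <- fk$r * sin(deg2rad(az3))
      base <- c(fk$x, fk$y)
      u2 <- fk$tangent_deg + 90 * sig + jit_ang()
      t2 <- seq(0, d_abs, by = step)
      if (t2[length(t2)] < d_abs) t2 <- c(t2, d_abs)
      p2 <- cbind(x = base[1] + t2 * cos(deg2rad(u2)),
                  y = base[2] + t2 * sin(deg2rad(u2)))
      pid2 <- add_poly(p2, 2L)
      top <- p2[nrow(p2), ]

      ## primary junction (class1 through + class2 base)
      ja <- add_junction(base)
      link(ja, pid1, nearest_idx(polys[[pid1]]$pts, base), "interior")
      link(ja, pid2, 1L, "base")
      if (four_way[k]) {
        ## opposite-side stub makes this junction four-way
        us <- fk$tangent_deg - 90 * sig
        ts <- seq(0, 0.4 * d_abs, by = step)
        ps <- cbind(x = base[1] + ts * cos(deg2rad(us)),
                    y = base[2] + ts * sin(deg2rad(us)))
        pids <- add_poly(ps, 2L)
        link(ja, pids, 1L, "base")
        tips[[length(tips) + 1]] <- list(p = ps[nrow(ps), ], poly = pids)
      }

      ## tertiary: constant-offset (offset-curve) polyline through `top`
      half3 <- 0.43 * sp
      s3 <- seq(max(s0, sk - half3), min(s1, sk + half3), by = step)
      ideal <- offset_polyline(frame, s3, sig * d_abs)
      anchor <- frame_point(frame, sk, sig * d_abs)
      p3 <- sweep(ideal$pts, 2, anchor - top)      # translate so it meets top
      p3 <- rotate_about(p3, top, jit_ang() * 0.6)
      pid3 <- add_poly(p3, 3L)
      i3c <- nearest_idx(p3, top)
      jb <- add_junction(top)
      link(jb, pid2, nrow(p2), "end")
      link(jb, pid3, i3c, "interior")
      tips[[length(tips) + 1]] <- list(p = p3[1, ], poly = pid3)
      tips[[length(tips) + 1]] <- list(p = p3[nrow(p3), ], poly = pid3)

      ## quaternaries off the tertiary, transverse, with terminal hooks
      cl3 <- polyline_cumlen(p3)
      len3 <- cl3[length(cl3)]
      for (f in c(-0.30, -0.12, 0.12, 0.30)) {
        tq <- clamp(len3 / 2 + f * len3, 1, len3 - 1)
        iq <- which.min(abs(cl3 - tq))
        q <- p3[iq, ]
        i_lo <- max(1, iq - 2); i_hi <- min(nrow(p3), iq + 2)
        v3 <- p3[i_hi, ] - p3[i_lo, ]
        v3 <- v3 / sqrt(sum(v3^2))
        ## outward = the rotation of v3 that increases |d|
        cand <- rbind(c(-v3[2], v3[1]), c(v3[2], -v3[1]))
        dq <- intrinsic_of_points(frame, rbind(q))$d
        pick <- if (dq >= 0) which.max(cand[, 2] * 1) else which.min(cand[, 2])
        ## robust: choose candidate whose small step increases |d|
        d_step <- vapply(1:2, function(ci) {
          abs(intrinsic_of_points(frame, rbind(q + 2 * cand[ci, ]))$d)
        }, numeric(1))
        pick <- which.max(d_step)
        u4d <- rad2deg(atan2(cand[pick, 2], cand[pick, 1])) + jit_ang() * 0.6
        sq <- intrinsic_of_points(frame, rbind(q))$s
        rq <- frame_at(frame, sq)$r
        len4 <- max(2, rq * (sin(deg2rad(az4)) - sin(deg2rad(az3))))
        t4 <- seq(0, len4, by = step)
        if (t4[length(t4)] < len4) t4 <- c(t4, len4)
        p4 <- cbind(x = q[1] + t4 * cos(deg2rad(u4d)),
                    y = q[2] + t4 * sin(deg2rad(u4d)))
        ## L-shaped terminal on the outer quaternaries: a tight quarter-arc
        ## turning away from the menorah, so neighbouring branches stay well
        ## separated and quaternary terminals are strongly curved
        if (abs(f) > 0.2) {
          v3s <- sign(f) * v3
          turn <- if (v3s[1] * cos(deg2rad(u4d + 90)) +
                        v3s[2] * sin(deg2rad(u4d + 90)) > 0) 1 else -1
          hr <- 0.06 * sp                      # arc radius
          arc <- seq(10, 90, by = 10) * turn
          e4 <- p4[nrow(p4), ]
          ctr <- e4 + hr * c(cos(deg2rad(u4d + 90 * turn)),
                             sin(deg2rad(u4d + 90 * turn)))
          base_ang <- u4d - 90 * turn
          ph <- cbind(x = ctr[1] + hr * cos(deg2rad(base_ang + arc)),
                      y = ctr[2] + hr * sin(deg2rad(base_ang + arc)))
          p4 <- rbind(p4, ph)
        }
        pid4 <- add_poly(p4, 4L)
        jc <- add_junction(q)
        link(jc, pid3, iq, "interior")
        link(jc, pid4, 1L, "base")
        tips[[length(tips) + 1]] <- list(p = p4[nrow(p4), ], poly = pid4)
      }
    }
  })

  ## numeric outgoing ray directions at each junction (degrees, y-up frame)
  ray_dir <- function(pts, i, forward, reach = 1.5) {
    cl <- polyline_cumlen(pts)
    target <- cl[i] + (if (forward) reach else -reach)
    j <- which.min(abs(cl - target))
    if (j == i) j <- i + (if (forward) 1L else -1L)
    j <- clamp(j, 1L, nrow(pts))
    v <- pts[j, ] - pts[i, ]
    rad2deg(atan2(v[2], v[1]))
  }
  jn <- length(juncs)
  jx <- numeric(jn); jy <- numeric(jn)
  dirs_list <- vector("list", jn)
  for (j in seq_len(jn)) {
    J <- juncs[[j]]
    jx[j] <- J$x; jy[j] <- J$y
    dirs <- c()
    for (inc in J$incident) {
      pts <- polys[[inc$poly]]$pts
      if (inc$kind == "interior") {
        dirs <- c(dirs, ray_dir(pts, inc$i, TRUE), ray_dir(pts, inc$i, FALSE))
      } else if (inc$kind == "base") {
        dirs <- c(dirs, ray_dir(pts, inc$i, TRUE))
      } else {
        dirs <- c(dirs, ray_dir(pts, inc$i, FALSE))
      }
    }
    dirs_list[[j]] <- unname(wrap360(dirs))
  }
  jint <- intrinsic_of_points(frame, cbind(jx, jy))
  ktab <- vapply(dirs_list, length, integer(1))
  trip <- t(vapply(seq_len(jn), function(j) {
    if (ktab[j] == 3) sorted_triplet(dirs_list[[j]]) else rep(NA_real_, 3)
  }, numeric(3)))

  meta <- tibble(
    id = seq_along(polys),
    class = vapply(polys, function(p) p$class, integer(1)),
    length_um = vapply(polys, function(p) polyline_length(p$pts), numeric(1))
  )
  coords <- lapply(polys, function(p) intrinsic_of_points(frame, p$pts))
  out <- list(
    polylines = lapply(polys, function(p) p$pts),
    meta = meta,
    coords = coords,
    attachments = lapply(polys, function(p) p$attach),
    junctions = tibble(
      id = seq_len(jn), x = jx, y = jy,
      s = jint$s, phi = jint$phi, k = ktab,
      dirs = dirs_list,
      a1 = trip[, 1], a2 = trip[, 2], a3 = trip[, 3]
    ),
    tips = tibble(
      x = vapply(tips, function(t) t$p[1], numeric(1)),
      y = vapply(tips, function(t) t$p[2], numeric(1)),
      polyline = vapply(tips, function(t) t$poly, numeric(1))
    ),
    frame = frame,
    menorah_spacing_um = menorah_spacing_um,
    seed = seed
  )
  class(out) <- "pvd_tree"
  out
}

#' Total and per-class ground-truth lengths of a phantom tree
#' @param tree A `pvd_tree`.
#' @return Tibble with one row per class and a total row.
#' @export
tree_class_lengths <- function(tree) {
  per <- tree$meta |>
    group_by(class = .data$class) |>
    summarise(length_um = sum(.data$length_um), .groups = "drop")
  bind_rows(per, tibble(class = NA_integer_, length_um = sum(per$length_um)))
}

#' Raster geometry of a phantom rendering
#'
#' Defines the micrometre-to-pixel mapping used by [render_worm_image()]:
#' pixels are 1-based and pixel-centred, x is the column (increasing
#' rightward/posteriorly) and y is the row (dorsal at the top).
#'
#' @param frame A `worm_frame`.
#' @param pixel_size_um Pixel size in micrometers.
#' @param margin_um Canvas margin around the body bounding box.
#' @return A list with origin, pixel size and raster dimensions.
#' @export
phantom_geometry <- function(frame, pixel_size_um, margin_um = 8) {
  m <- frame$midline
  rmax <- max(m$r)
  x0 <- min(m$x) - rmax - margin_um
  x1 <- max(m$x) + rmax + margin_um
  y0 <- min(m$y) - rmax - margin_um
  y1 <- max(m$y) + rmax + margin_um
  list(
    pixel_size_um = pixel_size_um,
    x0 = x0, y1 = y1,
    nx = as.integer(ceiling((x1 - x0) / pixel_size_um)) + 1L,
    ny = as.integer(ceiling((y1 - y0) / pixel_size_um)) + 1L
  )
}

#' Convert micrometre points to pixel coordinates (and back)
#' @param geom Geometry from [phantom_geometry()].
#' @param pts Two-column matrix of points.
#' @return Two-column matrix.
#' @export
um_to_px <- function(geom, pts) {
  cbind(x = (pts[, 1] - geom$x0) / geom$pixel_size_um + 1,
        y = (geom$y1 - pts[, 2]) / geom$pixel_size_um + 1)
}

#' @rdname um_to_px
#' @export
px_to_um <- function(geom, pts) {
  cbind(x = geom$x0 + (pts[, 1] - 1) * geom$pixel_size_um,
        y = geom$y1 - (pts[, 2] - 1) * geom$pixel_size_um)
}

## dense resampling of a pixel-space polyline at a given step
resample_polyline <- function(pts, step) {
  cl <- polyline_cumlen(pts)
  L <- cl[length(cl)]
  if (L == 0) return(pts[1, , drop = FALSE])
  keep <- c(TRUE, diff(cl) > 1e-12)   # drop coincident samples
  cl <- cl[keep]; pts <- pts[keep, , drop = FALSE]
  t <- seq(0, L, by = step)
  cbind(x = approx(cl, pts[, 1], t)$y, y = approx(cl, pts[, 2], t)$y)
}

#' Render a phantom fluorescence image from a ground-truth tree
#'
#' Draws each process as a ridge of per-process apparent width (drawn from
#' `width_px_range`; true dendrite diameters are below optical resolution, so
#' only the apparent fluorescent width is modelled), with smooth +/-30%
#' intensity variation along the process, blurs with a Gaussian PSF, adds
#' bright off-neuron discs mimicking autofluorescent gut granules, and
#' applies shot/read noise. Rendering is bit-exact under a fixed seed.
#'
#' @param tree A `pvd_tree`.
#' @param pixel_size_um Pixel size (default 0.16 um/px, a 40x-objective scale).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 disables blurring).
#' @param noise One of `"none"`, `"poisson"`, `"gaussian"`,
#'   `"poisson+gaussian"`.
#' @param n_granules Number of gut-granule discs drawn off the neuron.
#' @param seed Integer seed.
#' @param width_px_range Range of apparent ridge widths (pixels).
#' @param bg_level Constant background level in `[0, 1]`.
#' @param photons Photon budget per unit intensity for Poisson noise.
#' @param read_sd Gaussian read-noise SD.
#' @return A `worm_image`: list with `image` (matrix in `[0, 1]`,
#'   rows = y), `mask` (logical neuron footprint), `geometry`, `granules`.
#' @export
render_worm_image <- function(tree, pixel_size_um = 0.16, psf_sigma_px = 1,
                              noise = "poisson", n_granules = 10, seed = 1,
                              width_px_range = c(2, 5), bg_level = 0.08,
                              photons = 60, read_sd = 0.01) {
  stopifnot(inherits(tree, "pvd_tree"))
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  geom <- phantom_geometry(tree$frame, pixel_size_um)
  ny <- geom$ny; nx <- geom$nx
  ridge <- matrix(0, ny, nx)

  disc_offsets <- function(radius) {
    r <- max(0.5, radius)
    k <- ceiling(r)
    g <- expand.grid(dy = -k:k, dx = -k:k)
    g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  }

  with_seed(derive_seed(seed, "render"), {
    widths <- runif(length(tree$polylines), width_px_range[1], width_px_range[2])
    phases <- runif(length(tree$polylines), 0, 2 * pi)
    for (j in seq_along(tree$polylines)) {
      pp <- um_to_px(geom, tree$polylines[[j]])
      pp <- resample_polyline(pp, 0.35)
      offs <- disc_offsets(widths[j] / 2)
      cl <- seq_len(nrow(pp)) * 0.35 * pixel_size_um
      inten <- 1 + 0.3 * sin(2 * pi * cl / 25 + phases[j])
      for (i in seq_len(nrow(pp))) {
        yy <- round(pp[i, 2]) + offs$dy
        xx <- round(pp[i, 1]) + offs$dx
        ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
        if (any(ok)) {
          idx <- cbind(yy[ok], xx[ok])
          ridge[idx] <- pmax(ridge[idx], inten[i])
        }
      }
    }
    mask <- ridge > 0

    granule <- matrix(0, ny, nx)
    gran_tbl <- NULL
    if (n_granules > 0) {
      dm <- EBImage::distmap(1 - mask)   # distance to nearest neuron pixel
      placed <- 0; tries <- 0
      gx <- numeric(0); gy <- numeric(0); gr <- numeric(0)
      while (placed < n_granules && tries < 20000) {
        tries <- tries + 1
        r_g <- runif(1, 1.5, 3)
        cx <- sample.int(nx - 12, 1) + 6
        cy <- sample.int(ny - 12, 1) + 6
        clearance <- r_g + 4 + 2 * psf_sigma_px
        if (dm[cy, cx] <= clearance) next
        if (placed > 0 &&
            any(sqrt((gx - cx)^2 + (gy - cy)^2) <= gr + r_g + 4 + 4 * psf_sigma_px)) next
        placed <- placed + 1
        gx <- c(gx, cx); gy <- c(gy, cy); gr <- c(gr, r_g)
        offs <- disc_offsets(r_g)
        yy <- cy + offs$dy; xx <- cx + offs$dx
        ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
        granule[cbind(yy[ok], xx[ok])] <- 0.9
      }
      if (placed < n_granules) {
        warn("could not place all requested granules; canvas too crowded")
      }
      gran_tbl <- tibble(x = gx, y = gy, radius = gr)
    }

    img <- bg_level + 0.8 * ridge + granule
    if (psf_sigma_px > 0) {
      img <- EBImage::gblur(img, sigma = psf_sigma_px)
    }
    if (grepl("poisson", noise)) {
      img <- matrix(rpois(length(img), pmax(img, 0) * photons) / photons, ny, nx)
    }
    if (grepl("gaussian", noise)) {
      img <- img + matrix(rnorm(length(img), 0, read_sd), ny, nx)
    }
    img <- clamp(img, 0, 1)

    out <- list(image = img, mask = mask, geometry = geom,
                granules = gran_tbl, bg_level = bg_level,
                pixel_size_um = pixel_size_um, seed = seed,
                widths_px = widths)
    class(out) <- "worm_image"
    out
  })
}

#' One-call phantom: frame + tree + rendering
#'
#' Convenience wrapper generating a complete synthetic worm: body frame,
#' ground-truth PVD tree, and rendered image with neuron mask.
#'
#' @inheritParams worm_frame
#' @inheritParams pvd_tree
#' @inheritParams render_worm_image
#' @return A list with `frame`, `tree`, and the rendered `worm_image`
#'   fields (`image`, `mask`, `geometry`, ...).
#' @export
worm_phantom <- function(length_um = 600, max_radius_um = 25,
                         bend_amplitude = 8, menorah_spacing_um = 30,
                         jitter = 0, four_way_frac = 0,
                         pixel_size_um = 0.16, psf_sigma_px = 1,
                         noise = "poisson", n_granules = 10, seed = 1, ...) {
  frame <- worm_frame(length_um, max_radius_um, bend_amplitude, seed = seed)
  tree <- pvd_tree(frame, menorah_spacing_um = menorah_spacing_um,
                   jitter = jitter, four_way_frac = four_way_frac, seed = seed)
  render <- render_worm_image(tree, pixel_size_um = pixel_size_um,
                              psf_sigma_px = psf_sigma_px, noise = noise,
                              n_granules = n_granules, seed = seed, ...)
  list(frame = frame, tree = tree, image = render$image, mask = render$mask,
       geometry = render$geometry, render = render)
}

#' Render a synthetic junction image
#'
#' Draws rays emanating from the image centre at the given directions as
#' ridges of constant width, optionally blurred — a minimal synthetic
#' junction for testing the junction-geometry fit.
#'
#' @param dirs_deg Ray directions in degrees (y-up convention).
#' @param size_px Square image side.
#' @param ray_len_px Ray length.
#' @param width_px Ridge width.
#' @param psf_sigma_px Gaussian blur sigma (0 = none).
#' @param bg_level Background level.
#' @return List with `image`, `mask`, `center`.
#' @export
render_junction_image <- function(dirs_deg, size_px = 121, ray_len_px = 40,
                                  width_px = 3, psf_sigma_px = 0,
                                  bg_level = 0) {
  img <- matrix(0, size_px, size_px)
  cen <- c((size_px + 1) / 2, (size_px + 1) / 2)
  k <- ceiling(width_px / 2)
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g <- g[g$dy^2 + g$dx^2 <= (width_px / 2)^2 + 1e-9, ]
  for (a in dirs_deg) {
    for (t in seq(0, ray_len_px, by = 0.25)) {
      x <- round(cen[1] + t * cos(deg2rad(a)))
      y <- round(cen[2] - t * sin(deg2rad(a)))
      yy <- y + g$dy; xx <- x + g$dx
      ok <- yy >= 1 & yy <= size_px & xx >= 1 & xx <= size_px
      img[cbind(yy[ok], xx[ok])] <- 1
    }
  }
  mask <- img > 0
  out <- bg_level + (1 - bg_level) * img
  if (psf_sigma_px > 0) out <- EBImage::gblur(out, sigma = psf_sigma_px)
  list(image = clamp(out, 0, 1), mask = mask, center = cen)
}

#' Ground-truth trace of a phantom tree
#'
#' Converts the exact phantom geometry into the same trace representation the
#' tracer produces (elements, segments, junctions, tips, in pixel
#' coordinates), with the true class label attached to every element. This
#' lets the coordinate and morphometry stages be exercised against exact
#' inputs, independent of tracing accuracy.
#'
#' @param tree A `pvd_tree`.
#' @param pixel_size_um Pixel size of the target raster geometry.
#' @param element_spacing_um Spacing between consecutive elements.
#' @param width_px Nominal element width.
#' @param junction_margin_um Linear elements start this far away from
#'   junction centres (rectangular elements never overlap the junction
#'   disc), as in traced data.
#' @return A `pvd_trace` object (see [assemble_trace()]) whose `elements`
#'   tibble carries a `class_true` column.
#' @export
phantom_trace <- function(tree, pixel_size_um = 0.5, element_spacing_um = 2,
                          width_px = 3, junction_margin_um = 1.5) {
  stopifnot(inherits(tree, "pvd_tree"))
  geom <- phantom_geometry(tree$frame, pixel_size_um)
  npoly <- length(tree$polylines)

  ## nodes: ground-truth junctions then per-polyline split points
  jn <- nrow(tree$junctions)
  jpx <- um_to_px(geom, cbind(tree$junctions$x, tree$junctions$y))

  elements <- list(); segments <- list(); tips <- list()
  next_node <- jn
  eid <- 0L
  for (p in seq_len(npoly)) {
    pts <- tree$polylines[[p]]
    cl <- polyline_cumlen(pts)
    att <- tree$attachments[[p]]
    cuts <- sort(unique(c(
      0, cl[length(cl)],
      vapply(att, function(a) cl[a$i], numeric(1))
    )))
    node_of_cut <- function(tcut) {
      for (a in att) if (abs(cl[a$i] - tcut) < 1e-6) return(a$jid)
      NA_integer_
    }
    for (ci in seq_len(length(cuts) - 1)) {
      t0 <- cuts[ci]; t1 <- cuts[ci + 1]
      if (t1 - t0 < 1e-6) next
      ## keep elements clear of junction discs; stagger the sampling phase
      ## per segment so element positions are not quantized identically
      ## across the cohort
      ta <- if (!is.na(node_of_cut(t0))) t0 + junction_margin_um else t0
      tb <- if (!is.na(node_of_cut(t1))) t1 - junction_margin_um else t1
      if (tb - ta < element_spacing_um / 2) { ta <- t0; tb <- t1 }
      ta <- min(ta + (length(segments) %% 4) / 4 * element_spacing_um, (ta + tb) / 2)
      tt <- seq(ta, tb, by = element_spacing_um)
      if (tt[length(tt)] < tb - 1e-9) tt <- c(tt, tb)
      xs <- approx(cl, pts[, 1], tt)$y
      ys <- approx(cl, pts[, 2], tt)$y
      ppx <- um_to_px(geom, cbind(xs, ys))
      nseg <- length(segments) + 1L
      ids <- eid + seq_along(tt)
      eid <- eid + length(tt)
      dx <- c(diff(ppx[, 1]), diff(ppx[, 1])[length(tt) - 1])
      dy <- c(diff(ppx[, 2]), diff(ppx[, 2])[length(tt) - 1])
      psi <- wrap180(rad2deg(atan2(-dy, dx)))
      elements[[nseg]] <- tibble(
        id = ids, x = ppx[, 1], y = ppx[, 2], psi = psi,
        w = width_px, l = 2 * width_px, score = 1,
        bg_mean = 0, bg_sd = 0, segment = nseg,
        prev = c(NA_integer_, ids[-length(ids)]),
        nxt = c(ids[-1], NA_integer_),
        class_true = tree$meta$class[p]
      )
      n0 <- node_of_cut(t0); n1 <- node_of_cut(t1)
      if (is.na(n0)) { next_node <- next_node + 1L; n0 <- next_node
        tips[[length(tips) + 1]] <- list(node = n0, x = ppx[1, 1], y = ppx[1, 2]) }
      if (is.na(n1)) { next_node <- next_node + 1L; n1 <- next_node
        tips[[length(tips) + 1]] <- list(node = n1, x = ppx[nrow(ppx), 1],
                                         y = ppx[nrow(ppx), 2]) }
      segments[[nseg]] <- tibble(
        id = nseg, node_from = n0, node_to = n1,
        n_elements = length(tt),
        length_px = (t1 - t0) / pixel_size_um,
        partial = FALSE
      )
    }
  }
  el <- bind_rows(elements)
  sg <- bind_rows(segments)
  ## junction directions in pixel-frame angles equal the micrometre-frame
  ## angles because the y-flip is compensated in the angle convention
  jt <- tibble(
    id = seq_len(jn), x = jpx[, 1], y = jpx[, 2],
    R = width_px, k = tree$junctions$k,
    dirs = tree$junctions$dirs,
    a1 = tree$junctions$a1, a2 = tree$junctions$a2, a3 = tree$junctions$a3,
    degenerate = FALSE
  )
  tp <- if (length(tips)) {
    tibble(node = vapply(tips, `[[`, numeric(1), "node"),
           x = vapply(tips, `[[`, numeric(1), "x"),
           y = vapply(tips, `[[`, numeric(1), "y"))
  } else tibble(node = integer(), x = numeric(), y = numeric())
  out <- list(elements = el, segments = sg, junctions = jt, tips = tp,
              geometry = geom, pixel_size_um = pixel_size_um,
              source = "phantom-ground-truth")
  class(out) <- "pvd_trace"
  out
}
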