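#' Classify image pixels as neuron / non-neuron
#'
#' Produces a per-pixel neuron probability map and a binary map. Two paths
#' are available:
#'
#' * `"cnn"`: a trained [train_patch_classifier()] model is slid over the
#'   image in overlapping 64x64 patches (stride `stride`); overlapping
#'   predictions are averaged and the probability map is thresholded at 0.5.
#' * `"fallback"` (default): a deterministic classical pipeline -
#'   morphological background subtraction (grayscale opening), mild
#'   smoothing, hysteresis thresholding, and removal of compact bright
#'   blobs (autofluorescent gut granules) by an area/circularity filter.
#'
#' @param image Numeric matrix in `[0, 1]` (rows = y, cols = x).
#' @param model Optional `patch_classifier`; supplying one selects the CNN
#'   path unless `mode = "fallback"`.
#' @param mode `"auto"`, `"fallback"` or `"cnn"`.
#' @param stride Patch stride for the CNN path (<= 64).
#' @param bg_radius Structuring-element radius (px) for background opening.
#' @param granule_area_max Components smaller than this AND rounder than
#'   `granule_circularity` are removed as granules.
#' @param granule_circularity Circularity threshold (4*pi*A/P^2).
#' @param min_signal Absolute floor on the enhanced-signal maximum below
#'   which the image is declared empty.
#' @return A `pixel_classmap`: list with `prob`, `binary`, `provenance`.
#' @export
classify_image <- function(image, model = NULL,
                           mode = c("auto", "fallback", "cnn"),
                           stride = 32, bg_radius = 7,
                           granule_area_max = 150,
                           granule_circularity = 0.8,
                           min_signal = 0.03) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.null(model)) "fallback" else "cnn"
  if (mode == "cnn" && is.null(model)) abort("cnn mode needs a trained model")
  stopifnot(is.matrix(image))

  if (mode == "cnn") {
    prob <- cnn_classify(image, model, stride)
    provenance <- "network"
  } else {
    prob <- fallback_classify(image, bg_radius, min_signal)
    provenance <- "fallback"
  }
  binary <- prob >= 0.5
  binary <- remove_granule_components(binary, granule_area_max,
                                      granule_circularity)
  out <- list(prob = prob, binary = binary, provenance = provenance)
  class(out) <- "pixel_classmap"
  out
}

cnn_classify <- function(image, model, stride) {
  ny <- nrow(image); nx <- ncol(image)
  py <- max(PATCH_SIZE, ceiling(ny / stride) * stride + (PATCH_SIZE - stride))
  px <- max(PATCH_SIZE, ceiling(nx / stride) * stride + (PATCH_SIZE - stride))
  pad <- matrix(median(image), py, px)
  pad[seq_len(ny), seq_len(nx)] <- image
  acc <- matrix(0, py, px); cnt <- matrix(0, py, px)
  ys <- seq(1, py - PATCH_SIZE + 1, by = stride)
  xs <- seq(1, px - PATCH_SIZE + 1, by = stride)
  for (y0 in ys) {
    for (x0 in xs) {
      sel_y <- y0:(y0 + PATCH_SIZE - 1); sel_x <- x0:(x0 + PATCH_SIZE - 1)
      p <- classifier_forward(model, pad[sel_y, sel_x])$prob
      acc[sel_y, sel_x] <- acc[sel_y, sel_x] + p
      cnt[sel_y, sel_x] <- cnt[sel_y, sel_x] + 1
    }
  }
  (acc / pmax(cnt, 1))[seq_len(ny), seq_len(nx)]
}

fallback_classify <- function(image, bg_radius, min_signal) {
  brush <- EBImage::makeBrush(2 * bg_radius + 1, shape = "disc")
  bg <- EBImage::opening(image, brush)
  enh <- pmax(image - bg, 0)
  enh <- EBImage::gblur(enh, sigma = 0.7)
  enh <- pmax(enh, 0)
  mx <- max(enh)
  if (mx < min_signal) return(matrix(0, nrow(image), ncol(image)))
  med <- median(enh); md <- mad(enh)
  hi <- max(0.35 * mx, med + 5 * md)
  lo <- max(0.18 * mx, med + 3 * md)
  weak <- enh >= lo
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[enh >= hi & lab > 0])
  kept <- matrix(lab %in% keep, nrow(image), ncol(image)) & weak
  prob <- matrix(0, nrow(image), ncol(image))
  prob[kept] <- 0.5 + 0.5 * clamp((enh[kept] - lo) / max(hi - lo, 1e-9), 0, 1)
  prob[!kept] <- 0.49 * clamp(enh[!kept] / lo, 0, 1)
  prob
}

## component perimeter estimated as the count of component pixels with a
## 4-neighbour outside the component
component_stats <- function(lab) {
  nlab <- max(lab)
  if (nlab == 0) return(tibble(label = integer(), area = integer(),
                               perimeter = integer(), circularity = numeric()))
  inside <- lab > 0
  pad <- function(dy, dx) shift_mat(inside * 1, dy, dx)
  boundary <- inside & (pad(1, 0) + pad(-1, 0) + pad(0, 1) + pad(0, -1) < 4)
  area <- tabulate(lab[inside], nbins = nlab)
  per <- tabulate(lab[boundary], nbins = nlab)
  tibble(label = seq_len(nlab), area = area, perimeter = per,
         circularity = 4 * pi * area / pmax(per, 1)^2)
}

remove_granule_components <- function(binary, area_max, circ_min) {
  lab <- EBImage::bwlabel(binary)
  st <- component_stats(lab)
  drop <- st$label[st$area < area_max & st$circularity > circ_min]
  if (length(drop)) binary[matrix(lab %in% drop, nrow(binary))] <- FALSE
  binary
}

#' Apply manual mask edits to a pixel class map
#'
#' Overlay-based manual correction: pixels in `add` are forced to neuron,
#' pixels in `remove` are forced to background. Overlays may be logical
#' matrices or paths to PNG masks (nonzero = selected).
#'
#' @param classmap A `pixel_classmap`.
#' @param add,remove Logical matrices or PNG paths; `NULL` to skip.
#' @return The edited `pixel_classmap` (provenance `"manual-edit"`).
#' @export
apply_mask_edits <- function(classmap, add = NULL, remove = NULL) {
  stopifnot(inherits(classmap, "pixel_classmap"))
  as_mask <- function(m) {
    if (is.character(m)) m <- png::readPNG(m)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0
  }
  if (!is.null(add)) {
    a <- as_mask(add)
    classmap$binary[a] <- TRUE
    classmap$prob[a] <- pmax(classmap$prob[a], 0.51)
  }
  if (!is.null(remove)) {
    r <- as_mask(remove)
    classmap$binary[r] <- FALSE
    classmap$prob[r] <- pmin(classmap$prob[r], 0.49)
  }
  classmap$provenance <- "manual-edit"
  classmap
}

## ---- skeletonization -------------------------------------------------------

## one Guo-Hall thinning pass (both sub-iterations); binary 0/1 matrix
guo_hall_pass <- function(img) {
  for (iter in 1:2) {
    p2 <- shift_mat(img, 1, 0)   # north neighbour (row - 1)
    p3 <- shift_mat(img, 1, -1)  # NE
    p4 <- shift_mat(img, 0, -1)  # E
    p5 <- shift_mat(img, -1, -1) # SE
    p6 <- shift_mat(img, -1, 0)  # S
    p7 <- shift_mat(img, -1, 1)  # SW
    p8 <- shift_mat(img, 0, 1)   # W
    p9 <- shift_mat(img, 1, 1)   # NW
    C <- (1 - p2) * pmax(p3, p4) + (1 - p4) * pmax(p5, p6) +
      (1 - p6) * pmax(p7, p8) + (1 - p8) * pmax(p9, p2)
    N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
    N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
    N <- pmin(N1, N2)
    m <- if (iter == 1) pmax(pmin(pmax(p6, p7), 1), 1 - p9) * p8
         else pmax(pmin(pmax(p2, p3), 1), 1 - p5) * p4
    del <- img == 1 & C == 1 & N >= 2 & N <= 3 & m == 0
    img[del] <- 0
  }
  img
}

## 8-connectivity crossing number of the neighbourhood of one pixel
local_connectivity <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  at <- function(dy, dx) {
    yy <- y + dy; xx <- x + dx
    if (yy < 1 || yy > ny || xx < 1 || xx > nx) 0 else img[yy, xx]
  }
  p <- c(at(-1, 0), at(-1, 1), at(0, 1), at(1, 1),
         at(1, 0), at(1, -1), at(0, -1), at(-1, -1))
  sum(p == 1 & c(p[-1], p[1]) == 0)
}

## remove pixels that are part of a solid 2x2 block but redundant for
## connectivity (keeps the skeleton strictly one pixel wide)
thin_blocks <- function(img) {
  repeat {
    b <- img[-nrow(img), -ncol(img)] & img[-1, -ncol(img)] &
      img[-nrow(img), -1] & img[-1, -1]
    if (!any(b)) break
    idx <- which(b, arr.ind = TRUE)
    removed <- FALSE
    for (r in seq_len(nrow(idx))) {
      for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        y <- idx[r, 1] + off[1]; x <- idx[r, 2] + off[2]
        if (img[y, x] == 1 && local_connectivity(img, y, x) == 1) {
          img[y, x] <- 0
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }
  img
}

## medial-axis thinning of a binary matrix down to a 1-px skeleton
thin_binary <- function(binary) {
  img <- (binary > 0) * 1
  repeat {
    new <- guo_hall_pass(img)
    if (identical(new, img)) break
    img <- new
  }
  thin_blocks(img)
}

#' Reduce a pixel class map to a topological skeleton graph
#'
#' Thins the binary neuron map to a one-pixel-wide medial axis, labels tips
#' (skeleton pixels with exactly one neighbour) and vertices (pixels with
#' three or more neighbours), prunes short terminal spurs, and extracts the
#' pixel chains connecting the nodes.
#'
#' @param classmap A `pixel_classmap`, or a logical/binary matrix.
#' @param prune_len Terminal spurs shorter than this many pixels are removed.
#' @param vertex_merge_px Pairs of vertices connected by a chain shorter
#'   than this are contracted to one vertex (thinning can split a single
#'   anatomical junction into two nearby skeleton vertices).
#' @return A `skeleton_graph`: list with `skeleton` (binary matrix), `nodes`
#'   (tibble: `id`, `x`, `y`, `type`, `degree`), `edges` (tibble: `from`,
#'   `to`, `length_px`, `chain` list-column of pixel paths).
#' @export
skeletonize <- function(classmap, prune_len = 5, vertex_merge_px = 4) {
  binary <- if (inherits(classmap, "pixel_classmap")) classmap$binary else classmap > 0
  if (!any(binary)) {
    return(structure(list(
      skeleton = matrix(0, nrow(binary), ncol(binary)),
      nodes = tibble(id = integer(), x = numeric(), y = numeric(),
                     type = character(), degree = integer()),
      edges = tibble(id = integer(), from = integer(), to = integer(),
                     length_px = numeric(), chain = list())
    ), class = "skeleton_graph"))
  }
  skel <- thin_binary(binary)
  g <- build_skeleton_graph(skel)
  ## spur pruning, then rebuild (degrees change)
  for (pass in 1:3) {
    tips <- g$nodes$id[g$nodes$type == "tip"]
    spur <- g$edges$length_px < prune_len &
      ((g$edges$from %in% tips) | (g$edges$to %in% tips)) &
      !(g$edges$from %in% tips & g$edges$to %in% tips)
    if (!any(spur)) break
    for (ei in which(spur)) {
      ch <- g$edges$chain[[ei]]
      tip_node <- if (g$edges$from[ei] %in% tips) g$edges$from[ei] else g$edges$to[ei]
      np <- g$nodes[g$nodes$id == tip_node, ]
      if (nrow(ch)) skel[cbind(ch[, 2], ch[, 1])] <- 0
      skel[round(np$y), round(np$x)] <- 0
    }
    skel <- thin_blocks(skel)
    g <- build_skeleton_graph(skel)
  }
  g <- merge_close_vertices(g, vertex_merge_px)
  g$skeleton <- skel
  g
}

## contract short vertex-vertex chains: a single anatomical junction can be
## represented by two adjacent skeleton vertices after thinning
merge_close_vertices <- function(g, radius) {
  if (radius <= 0 || nrow(g$edges) == 0) return(g)
  repeat {
    vids <- g$nodes$id[g$nodes$type == "vertex"]
    cand <- which(g$edges$length_px < radius &
                    g$edges$from %in% vids & g$edges$to %in% vids &
                    g$edges$from != g$edges$to)
    if (!length(cand)) break
    ei <- cand[1]
    a <- g$edges$from[ei]; b <- g$edges$to[ei]
    ia <- which(g$nodes$id == a); ib <- which(g$nodes$id == b)
    g$nodes$x[ia] <- (g$nodes$x[ia] + g$nodes$x[ib]) / 2
    g$nodes$y[ia] <- (g$nodes$y[ia] + g$nodes$y[ib]) / 2
    g$nodes <- g$nodes[-ib, ]
    g$edges$from[g$edges$from == b] <- a
    g$edges$to[g$edges$to == b] <- a
    g$edges <- g$edges[-ei, ]
    g$edges <- g$edges[!(g$edges$from == g$edges$to &
                           g$edges$length_px < radius), ]
  }
  ## recompute degrees/types from the contracted edge list
  degs <- table(c(g$edges$from, g$edges$to))
  g$nodes$degree <- as.integer(degs[as.character(g$nodes$id)])
  g$nodes$degree[is.na(g$nodes$degree)] <- 0L
  g$nodes$type <- ifelse(g$nodes$degree <= 1, "tip", "vertex")
  g
}

build_skeleton_graph <- function(skel) {
  nb <- shift_mat(skel, 1, 0) + shift_mat(skel, -1, 0) +
    shift_mat(skel, 0, 1) + shift_mat(skel, 0, -1) +
    shift_mat(skel, 1, 1) + shift_mat(skel, 1, -1) +
    shift_mat(skel, -1, 1) + shift_mat(skel, -1, -1)
  deg <- nb * skel
  node_mask <- skel == 1 & (deg == 1 | deg >= 3)
  ## isolated pixels are their own (degenerate) nodes
  node_mask[skel == 1 & deg == 0] <- TRUE
  node_lab <- EBImage::bwlabel(node_mask)
  ## merge 8-adjacent node pixels into one node: bwlabel is 4-connected, so
  ## dilate labels over diagonal links via a union-find sweep
  node_lab <- merge_diagonal_labels(node_lab)
  n_nodes <- length(unique(node_lab[node_lab > 0]))
  relab <- setNames(seq_len(n_nodes), sort(unique(node_lab[node_lab > 0])))
  idx <- which(node_lab > 0, arr.ind = TRUE)
  node_id <- matrix(0L, nrow(skel), ncol(skel))
  node_id[idx] <- as.integer(relab[as.character(node_lab[idx])])

  nodes <- tibble(
    label = node_id[idx], y = idx[, 1], x = idx[, 2],
    degree = deg[idx]
  ) |>
    group_by(id = .data$label) |>
    summarise(x = mean(.data$x), y = mean(.data$y),
              degree = max(.data$degree), .groups = "drop") |>
    mutate(type = ifelse(.data$degree <= 1, "tip", "vertex"))

  ## walk chains between nodes
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  edges <- list()
  ny <- nrow(skel); nx <- ncol(skel)
  neigh <- function(y, x) {
    dy <- rep(-1:1, times = 3); dx <- rep(-1:1, each = 3)
    yy <- y + dy; xx <- x + dx
    ok <- (dy != 0 | dx != 0) & yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    cbind(yy[ok], xx[ok])
  }
  node_pixels <- which(node_id > 0, arr.ind = TRUE)
  seen_pairs <- character()
  for (r in seq_len(nrow(node_pixels))) {
    y0 <- node_pixels[r, 1]; x0 <- node_pixels[r, 2]
    nid0 <- node_id[y0, x0]
    nb0 <- neigh(y0, x0)
    for (q in seq_len(nrow(nb0))) {
      y <- nb0[q, 1]; x <- nb0[q, 2]
      if (skel[y, x] != 1) next
      if (node_id[y, x] > 0) {
        nid1 <- node_id[y, x]
        if (nid1 != nid0) {
          key <- paste(min(nid0, nid1), max(nid0, nid1), sep = "-")
          if (!(key %in% seen_pairs)) {
            seen_pairs <- c(seen_pairs, key)
            edges[[length(edges) + 1]] <- list(
              from = nid0, to = nid1,
              chain = matrix(numeric(0), 0, 2),
              length_px = sqrt((y - y0)^2 + (x - x0)^2))
          }
        }
        next
      }
      if (visited[y, x]) next
      ## walk through degree-2 pixels until the next node
      chain <- list(c(x, y))
      visited[y, x] <- TRUE
      prev <- c(y0, x0); cur <- c(y, x)
      end_node <- NA_integer_
      repeat {
        nb1 <- neigh(cur[1], cur[2])
        cand <- nb1[skel[nb1] == 1 &
                      !(nb1[, 1] == prev[1] & nb1[, 2] == prev[2]), ,
                    drop = FALSE]
        nodecand <- cand[node_id[cand] > 0, , drop = FALSE]
        if (nrow(nodecand) > 0) {
          ## prefer a node pixel that is not the start cluster, else accept
          other <- nodecand[node_id[nodecand] != nid0, , drop = FALSE]
          pickrow <- if (nrow(other)) other[1, ] else nodecand[1, ]
          end_node <- node_id[pickrow[1], pickrow[2]]
          chain[[length(chain) + 1]] <- c(pickrow[2], pickrow[1])
          break
        }
        freecand <- cand[!visited[cand], , drop = FALSE]
        if (nrow(freecand) == 0) { end_node <- nid0; break }
        nxt <- freecand[1, ]
        visited[nxt[1], nxt[2]] <- TRUE
        chain[[length(chain) + 1]] <- c(nxt[2], nxt[1])
        prev <- cur; cur <- nxt
      }
      ch <- do.call(rbind, chain)
      full <- rbind(c(x0, y0), ch)
      len <- sum(sqrt(diff(full[, 1])^2 + diff(full[, 2])^2))
      interior <- ch[seq_len(nrow(ch) - 1), , drop = FALSE]
      edges[[length(edges) + 1]] <- list(from = nid0, to = end_node,
                                         chain = interior, length_px = len)
    }
  }
  ## deduplicate chains walked from both ends (same pixel set)
  if (length(edges)) {
    keys <- vapply(edges, function(e) {
      if (nrow(e$chain) == 0) paste("z", min(e$from, e$to), max(e$from, e$to))
      else paste(sort(paste(e$chain[, 1], e$chain[, 2])), collapse = ";")
    }, character(1))
    edges <- edges[!duplicated(keys)]
  }
  ed <- if (length(edges)) {
    tibble(
      id = seq_along(edges),
      from = vapply(edges, function(e) e$from, numeric(1)),
      to = vapply(edges, function(e) e$to, numeric(1)),
      length_px = vapply(edges, function(e) e$length_px, numeric(1)),
      chain = lapply(edges, function(e) e$chain)
    )
  } else {
    tibble(id = integer(), from = integer(), to = integer(),
           length_px = numeric(), chain = list())
  }
  structure(list(skeleton = skel, nodes = nodes, edges = ed),
            class = "skeleton_graph")
}

#' Chain-code arclength of a skeleton
#'
#' Sums the lengths of all 8-neighbour adjacencies in the one-pixel-wide
#' skeleton (1 for orthogonal, sqrt(2) for diagonal steps), each counted
#' once. For a thin curve this approximates its arclength in pixels.
#'
#' @param x A `skeleton_graph` or a binary skeleton matrix.
#' @return Length in pixels.
#' @export
skeleton_length <- function(x) {
  s <- if (inherits(x, "skeleton_graph")) x$skeleton else (x > 0) * 1
  o <- sum(s * shift_mat(s, 0, 1)) + sum(s * shift_mat(s, 1, 0))
  d <- sum(s * shift_mat(s, 1, 1)) + sum(s * shift_mat(s, 1, -1))
  o + d * sqrt(2)
}

## join diagonally adjacent positive labels (bwlabel is 4-connected)
merge_diagonal_labels <- function(lab) {
  repeat {
    changed <- FALSE
    for (sh in list(c(1, 1), c(1, -1))) {
      a <- lab
      b <- shift_mat(lab, sh[1], sh[2])
      both <- a > 0 & b > 0 & a != b
      if (any(both)) {
        pairs <- unique(cbind(a[both], b[both]))
        for (r in seq_len(nrow(pairs))) {
          hi <- max(pairs[r, ]); lo <- min(pairs[r, ])
          if (hi != lo) { lab[lab == hi] <- lo; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  lab
}
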