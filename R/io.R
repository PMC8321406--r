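## File I/O: grayscale images (TIFF/PNG), SWC morphology export/import, the
## JSON trace database, and the batch pipeline.

DB_SCHEMA_VERSION <- 1L

#' Read a grayscale image
#'
#' Reads a single-channel TIFF or PNG as a numeric matrix in `[0, 1]`
#' (rows = y, columns = x). Multi-channel images are only accepted when a
#' `channel` is named.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param channel Channel index for multi-channel images.
#' @param pixel_size_um Pixel size carried as an attribute (metadata).
#' @return Numeric matrix with attribute `pixel_size_um`.
#' @export
read_image <- function(path, channel = NULL, pixel_size_um = NA_real_) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path), class = "pvdmorph_io")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported image format: .%s", ext), class = "pvdmorph_io")
  )
  if (length(dim(img)) == 3) {
    if (is.null(channel)) {
      if (dim(img)[3] > 1 &&
          !all(img[, , 1] == img[, , min(2, dim(img)[3])])) {
        abort("multi-channel image: specify `channel`", class = "pvdmorph_io")
      }
      channel <- 1L
    }
    img <- img[, , channel]
  }
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write a grayscale image
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path; format from extension (TIFF written as 16-bit,
#'   PNG as 16-bit).
#' @export
write_image <- function(image, path) {
  img <- clamp(unclass(image), 0, 1)
  attributes(img) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    abort(sprintf("unsupported image format: .%s", ext), class = "pvdmorph_io")
  )
  invisible(path)
}

#' Export a trace as an SWC morphology file
#'
#' Writes one SWC node per element centre with parent links along segments;
#' junction nodes become branch points. The SWC type field carries the
#' morphological class id (0 when unclassified). SWC is a tree format, so if
#' the trace graph contains cycles each cycle is broken at its longest
#' segment (with a warning).
#'
#' @param trace A `pvd_trace`.
#' @param path Output file.
#' @param pixel_size_um Pixel size used to write coordinates in micrometers.
#' @return Invisibly, the number of SWC nodes written.
#' @export
export_swc <- function(trace, path, pixel_size_um = NULL) {
  psz <- pixel_size_um %||% trace$pixel_size_um
  if (is.null(psz) || is.na(psz)) psz <- 1
  el <- trace$elements
  seg <- trace$segments
  if (nrow(el) == 0) abort("empty trace")
  segcls <- if ("class" %in% names(seg)) {
    setNames(ifelse(is.na(seg$class), 0L, seg$class), seg$id)
  } else setNames(rep(0L, nrow(seg)), seg$id)

  ## node set: junctions (by graph node id) + element chains
  jt <- trace$junctions
  nodes <- unique(c(seg$node_from, seg$node_to))
  ## connected-component roots (BFS over node-segment adjacency)
  visited <- setNames(logical(length(nodes)), nodes)
  comps <- list()
  for (root in nodes) {
    if (visited[as.character(root)]) next
    visited[as.character(root)] <- TRUE
    comps[[length(comps) + 1]] <- root
    queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      inc <- which(seg$node_from == cur | seg$node_to == cur)
      for (ei in inc) {
        oth <- if (seg$node_from[ei] == cur) seg$node_to[ei] else seg$node_from[ei]
        key <- as.character(oth)
        if (!visited[key]) { visited[key] <- TRUE; queue <- c(queue, oth) }
      }
    }
  }
  ## a connected graph with cycles has more segments than nodes - components;
  ## cycles are broken where the emit walk below re-encounters a node
  if (nrow(seg) > length(nodes) - length(comps)) {
    warn("trace graph contains cycles; each cycle broken at one segment end")
  }

  ## assemble SWC rows
  rows <- list()
  next_id <- 0L
  node_swc <- new.env(parent = emptyenv())
  node_xy <- function(nid) {
    j <- which(jt$id == nid)
    if (length(j)) return(c(jt$x[j[1]], jt$y[j[1]], max(jt$R[j[1]], 1)))
    t <- which(trace$tips$node == nid)
    if (length(t)) return(c(trace$tips$x[t[1]], trace$tips$y[t[1]], 1))
    ## fall back: first element of an incident segment
    si <- which(seg$node_from == nid | seg$node_to == nid)[1]
    e <- el[el$segment == seg$id[si], ]
    c(e$x[1], e$y[1], e$w[1] / 2)
  }
  add_row <- function(x, y, radius, type, parent) {
    next_id <<- next_id + 1L
    rows[[next_id]] <<- c(next_id, type, x * psz, -y * psz, 0,
                          radius * psz, parent)
    next_id
  }
  emit_node <- function(nid, parent) {
    key <- as.character(nid)
    if (!is.null(node_swc[[key]])) return(node_swc[[key]])
    xy <- node_xy(nid)
    id <- add_row(xy[1], xy[2], xy[3], 0L, parent)
    node_swc[[key]] <- id
    id
  }
  emit_segment <- function(sid, from_swc, from_node) {
    e <- el[el$segment == sid, ]
    srow <- seg[seg$id == sid, ]
    if (nrow(e) == 0) return(from_swc)
    ## orient the chain from `from_node`
    fxy <- node_xy(from_node)
    d_first <- (e$x[1] - fxy[1])^2 + (e$y[1] - fxy[2])^2
    d_last <- (e$x[nrow(e)] - fxy[1])^2 + (e$y[nrow(e)] - fxy[2])^2
    if (d_last < d_first) e <- e[rev(seq_len(nrow(e))), ]
    parent <- from_swc
    typ <- unname(segcls[as.character(sid)])
    for (i in seq_len(nrow(e))) {
      parent <- add_row(e$x[i], e$y[i], e$w[i] / 2, typ, parent)
    }
    parent
  }
  emitted_seg <- logical(nrow(seg))
  for (root in unlist(comps)) {
    root_swc <- emit_node(root, -1L)
    queue <- list(list(node = root, swc = root_swc))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      inc <- which((seg$node_from == cur$node | seg$node_to == cur$node) &
                     !emitted_seg)
      for (ei in inc) {
        if (emitted_seg[ei]) next
        emitted_seg[ei] <- TRUE
        oth <- if (seg$node_from[ei] == cur$node) seg$node_to[ei] else seg$node_from[ei]
        last_swc <- emit_segment(seg$id[ei], cur$swc, cur$node)
        if (is.null(node_swc[[as.character(oth)]])) {
          oth_swc <- emit_node(oth, last_swc)
          queue[[length(queue) + 1]] <- list(node = oth, swc = oth_swc)
        }
        ## if `oth` was already emitted this segment closed a cycle: leave
        ## its chain attached on one side only (cycle broken here)
      }
    }
  }
  mat <- do.call(rbind, rows)
  header <- c("# SWC export", "# columns: id type x y z radius parent",
              sprintf("# pixel_size_um %g", psz))
  writeLines(c(header, apply(mat, 1, function(r)
    paste(c(sprintf("%d", r[1]), sprintf("%d", r[2]),
            sprintf("%.4f", r[3:6]), sprintf("%d", r[7])), collapse = " "))),
    path)
  invisible(nrow(mat))
}

#' Read an SWC morphology file
#'
#' @param path SWC file.
#' @return Tibble with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "pvdmorph_io")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  tibble(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
         x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
         parent = as.integer(m[, 7]))
}

#' Total cable length of an SWC morphology
#' @param swc Tibble from [read_swc()].
#' @return Sum of parent-child edge lengths.
#' @export
swc_total_length <- function(swc) {
  idx <- match(swc$parent, swc$id)
  ok <- !is.na(idx) & swc$parent > 0
  sum(sqrt((swc$x[ok] - swc$x[idx[ok]])^2 +
             (swc$y[ok] - swc$y[idx[ok]])^2 +
             (swc$z[ok] - swc$z[idx[ok]])^2))
}

## ---- trace database --------------------------------------------------------

#' Write and read the JSON trace database
#'
#' The database is a schema-versioned JSON document holding, per image:
#' elements, segments, junctions, tips, coordinates and classes. The
#' round trip `read_trace_db(write_trace_db(db))` is lossless (up to double
#' precision).
#'
#' @param db A list of `pvd_trace` objects (named by image id) or a single
#'   trace.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_trace_db <- function(db, path) {
  if (inherits(db, "pvd_trace")) db <- list(trace = db)
  ser <- lapply(db, function(tr) {
    list(
      elements = tr$elements,
      segments = tr$segments,
      junctions = tr$junctions |> mutate(dirs = lapply(.data$dirs, as.numeric)),
      tips = tr$tips,
      coords = tr$coords,
      pixel_size_um = tr$pixel_size_um,
      source = tr$source
    )
  })
  jsonlite::write_json(
    list(schema_version = DB_SCHEMA_VERSION, traces = ser),
    path, digits = NA, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trace_db
#' @export
read_trace_db <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "pvdmorph_io")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(raw$schema_version) || raw$schema_version > DB_SCHEMA_VERSION) {
    abort("unsupported trace database schema version", class = "pvdmorph_io")
  }
  traces <- lapply(raw$traces, function(tr) {
    jt <- as_tibble(tr$junctions)
    if (!is.null(jt$dirs)) jt$dirs <- lapply(jt$dirs, as.numeric)
    out <- list(
      elements = as_tibble(tr$elements),
      segments = as_tibble(tr$segments),
      junctions = jt,
      tips = as_tibble(tr$tips),
      coords = if (!is.null(tr$coords)) as_tibble(tr$coords) else NULL,
      pixel_size_um = tr$pixel_size_um %||% NA_real_,
      source = tr$source %||% "db"
    )
    class(out) <- "pvd_trace"
    out
  })
  traces
}

## ---- pipeline --------------------------------------------------------------

#' Run the full tracing and morphometry pipeline on a batch of images
#'
#' For every entry of `images`, classifies pixels, skeletonizes, traces,
#' recovers worm coordinates, and (after pooling coordinates across the
#' cohort) classifies segments and summarizes morphometry. A failure in one
#' image is recorded and the batch continues. All randomness derives from
#' the single `seed` through named substreams, so a rerun with the same
#' configuration yields identical results.
#'
#' @param images Character vector of image paths, or a list of numeric
#'   matrices (named).
#' @param pixel_size_um Pixel size of the images.
#' @param mode Segmentation mode: `"fallback"` or `"cnn"`.
#' @param model Optional `patch_classifier` for `mode = "cnn"`.
#' @param seed Integer master seed.
#' @param out_dir Optional directory for the JSON database and CSV
#'   summaries.
#' @param verbose Print per-stage progress.
#' @return List with `traces` (named list), `errors` (named list of failure
#'   messages), `class_model`, `summary` (cohort `pvd_morphometry`).
#' @export
run_pipeline <- function(images, pixel_size_um = 0.16,
                         mode = c("fallback", "cnn"), model = NULL,
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.character(images)) {
    paths <- images
    if (is.null(names(paths))) {
      names(paths) <- tools::file_path_sans_ext(basename(paths))
    }
    images <- lapply(paths, function(p) NULL)
    loader <- function(i) read_image(paths[i])
  } else {
    if (is.null(names(images))) names(images) <- paste0("image", seq_along(images))
    loader <- function(i) images[[i]]
  }
  traces <- list(); errors <- list()
  for (i in seq_along(images)) {
    nm <- names(images)[i]
    t0 <- Sys.time()
    res <- tryCatch({
      img <- loader(i)
      cm <- classify_image(img, model = model, mode = mode)
      sk <- skeletonize(cm)
      tr <- trace_neuron(img, cm, sk, pixel_size_um = pixel_size_um)
      tr <- element_coords(tr, pixel_size_um = pixel_size_um)
      tr <- junction_coords(tr, pixel_size_um = pixel_size_um)
      tr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      if (verbose) message(nm, ": FAILED (", errors[[nm]], ")")
    } else {
      traces[[nm]] <- res
      if (verbose) {
        message(nm, ": ", nrow(res$elements), " elements in ",
                round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
      }
    }
  }
  model_cls <- NULL; summary <- NULL
  if (length(traces)) {
    pooled <- bind_rows(lapply(traces, function(tr) tr$coords))
    n_valid <- sum(!is.na(pooled$theta) & !is.na(pooled$phi))
    model_cls <- tryCatch(
      build_class_model(pooled, min_elements = min(1000, n_valid)),
      error = function(e) NULL)
    if (!is.null(model_cls)) {
      traces <- lapply(traces, classify_segments, model = model_cls)
      summary <- summarize_morphometry(traces, pixel_size_um = pixel_size_um)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace_db(traces, file.path(out_dir, "traces.json"))
    if (!is.null(summary)) {
      utils::write.csv(summary$per_class,
                       file.path(out_dir, "per_class_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(summary$totals,
                       file.path(out_dir, "totals.csv"), row.names = FALSE)
    }
  }
  list(traces = traces, errors = errors, class_model = model_cls,
       summary = summary)
}
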