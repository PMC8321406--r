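## Lazily built, cached fixtures shared across test files. Everything is
## generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## standard noiseless phantom worm + segmentation + full trace
fx_phantom <- function() fx("phantom", function() {
  ph <- worm_phantom(
    length_um = 120, max_radius_um = 12, bend_amplitude = 6,
    menorah_spacing_um = 30, pixel_size_um = 0.5, psf_sigma_px = 1,
    noise = "none", n_granules = 0, seed = 5)
  cm <- classify_image(ph$image)
  sk <- skeletonize(cm)
  tr <- trace_neuron(ph$image, cm, sk, pixel_size_um = 0.5)
  list(ph = ph, cm = cm, sk = sk, tr = tr)
})

## three-worm ground-truth cohort with coordinates and a class model
fx_cohort <- function() fx("cohort", function() {
  traces <- lapply(1:3, function(sd) {
    wf <- worm_frame(150, 14, bend_amplitude = 6, seed = sd)
    tree <- pvd_tree(wf, menorah_spacing_um = 30, seed = sd)
    tr <- phantom_trace(tree, 0.5)
    tr <- element_coords(tr, frame = wf, pixel_size_um = 0.5)
    attr(tr, "tree") <- tree
    attr(tr, "frame") <- wf
    tr
  })
  pooled <- dplyr::bind_rows(lapply(traces, function(t) t$coords))
  model <- build_class_model(pooled)
  list(traces = traces, pooled = pooled, model = model)
})

## synthetic bar image: horizontal ridge of given width (rows) and length
make_bar <- function(nrow = 60, ncol = 140, width = 6, value = 1,
                     y0 = NULL, x = 20:120) {
  img <- matrix(0, nrow, ncol)
  if (is.null(y0)) y0 <- round(nrow / 2 - width / 2)
  img[y0 + seq_len(width) - 1, x] <- value
  img
}

## exact per-segment ground-truth class agreement of a classified trace
segment_agreement <- function(trace) {
  el <- dplyr::left_join(trace$elements,
                         trace$coords[, c("id", "class")], by = "id")
  gt <- el |>
    dplyr::group_by(segment) |>
    dplyr::summarise(gt = class_true[1])
  sc <- trace$segments
  sc$gt <- gt$gt[match(sc$id, gt$segment)]
  mean(sc$class == sc$gt, na.rm = TRUE)
}

## exact two-sided rank-sum p-value by full enumeration (oracle)
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
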