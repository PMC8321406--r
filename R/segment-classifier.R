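## Compact trainable encoder-decoder patch segmenter.
##
## Maps a 64x64 grayscale patch to a 64x64 per-pixel neuron probability map.
## Architecture: zero-centered input -> 5x5 conv (nf filters) + ReLU ->
## 2x2 max-pool -> 3x3 conv (nf -> nf) + ReLU -> 2x nearest-neighbour
## upsample -> 1x1 conv -> sigmoid, trained with per-pixel cross-entropy by
## plain SGD. Convolutions and their gradients are implemented with explicit
## shift-and-add operations, which is fast enough at this patch size.

PATCH_SIZE <- 64L

## out[i, j] = m[i - dy, j - dx], zero padded
shift_mat <- function(m, dy, dx) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(0, n, k)
  ys <- max(1, 1 + dy):min(n, n + dy)
  xs <- max(1, 1 + dx):min(k, k + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

## same-size 2-D convolution (correlation form) with an odd square kernel
conv2same <- function(x, k) {
  c0 <- (nrow(k) + 1L) / 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] != 0) out <- out + k[a, b] * shift_mat(x, a - c0, b - c0)
    }
  }
  out
}

## gradient of conv2same output wrt the kernel
conv2same_gradk <- function(x, dy_out, ksize) {
  c0 <- (ksize + 1L) / 2L
  g <- matrix(0, ksize, ksize)
  for (a in seq_len(ksize)) {
    for (b in seq_len(ksize)) {
      g[a, b] <- sum(dy_out * shift_mat(x, a - c0, b - c0))
    }
  }
  g
}

## gradient of conv2same output wrt the input
conv2same_gradx <- function(k, dy_out) {
  c0 <- (nrow(k) + 1L) / 2L
  out <- matrix(0, nrow(dy_out), ncol(dy_out))
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] != 0) out <- out + k[a, b] * shift_mat(dy_out, c0 - a, c0 - b)
    }
  }
  out
}

maxpool2 <- function(m) {
  a <- m[c(TRUE, FALSE), c(TRUE, FALSE)]
  b <- m[c(TRUE, FALSE), c(FALSE, TRUE)]
  cc <- m[c(FALSE, TRUE), c(TRUE, FALSE)]
  d <- m[c(FALSE, TRUE), c(FALSE, TRUE)]
  p <- pmax(a, b, cc, d)
  which_max <- 1L * (a == p)
  which_max[b == p & which_max == 0] <- 2L
  which_max[cc == p & which_max == 0] <- 3L
  which_max[d == p & which_max == 0] <- 4L
  list(p = p, arg = which_max)
}

maxunpool2 <- function(grad, arg) {
  n2 <- nrow(grad) * 2L; k2 <- ncol(grad) * 2L
  out <- matrix(0, n2, k2)
  out[c(TRUE, FALSE), c(TRUE, FALSE)] <- grad * (arg == 1L)
  out[c(TRUE, FALSE), c(FALSE, TRUE)] <- grad * (arg == 2L)
  out[c(FALSE, TRUE), c(TRUE, FALSE)] <- grad * (arg == 3L)
  out[c(FALSE, TRUE), c(FALSE, TRUE)] <- grad * (arg == 4L)
  out
}

upsample2 <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
}

downsample2_sum <- function(m) {
  m[c(TRUE, FALSE), c(TRUE, FALSE)] + m[c(TRUE, FALSE), c(FALSE, TRUE)] +
    m[c(FALSE, TRUE), c(TRUE, FALSE)] + m[c(FALSE, TRUE), c(FALSE, TRUE)]
}

classifier_forward <- function(model, patch, keep = FALSE) {
  x <- patch - mean(patch)   # zero-centering normalization
  nf <- model$nf
  h1 <- vector("list", nf); h1pre <- vector("list", nf)
  for (f in seq_len(nf)) {
    z <- conv2same(x, model$W1[, , f]) + model$b1[f]
    h1pre[[f]] <- z
    h1[[f]] <- pmax(z, 0)
  }
  p1 <- lapply(h1, maxpool2)
  h2 <- vector("list", nf); h2pre <- vector("list", nf)
  for (g in seq_len(nf)) {
    z <- matrix(model$b2[g], PATCH_SIZE / 2, PATCH_SIZE / 2)
    for (f in seq_len(nf)) z <- z + conv2same(p1[[f]]$p, model$W2[, , f, g])
    h2pre[[g]] <- z
    h2[[g]] <- pmax(z, 0)
  }
  logit <- matrix(model$b3, PATCH_SIZE, PATCH_SIZE)
  for (g in seq_len(nf)) logit <- logit + model$W3[g] * upsample2(h2[[g]])
  prob <- 1 / (1 + exp(-logit))
  if (!keep) return(list(prob = prob))
  list(prob = prob, x = x, h1 = h1, h1pre = h1pre, p1 = p1,
       h2 = h2, h2pre = h2pre)
}

classifier_loss <- function(prob, labels) {
  eps <- 1e-7
  -mean(labels * log(prob + eps) + (1 - labels) * log(1 - prob + eps))
}

classifier_sgd_step <- function(model, patch, labels, lr) {
  fw <- classifier_forward(model, patch, keep = TRUE)
  nf <- model$nf
  npix <- PATCH_SIZE^2
  dlogit <- (fw$prob - labels) / npix
  dW3 <- numeric(nf)
  dp1 <- lapply(seq_len(nf), function(f) matrix(0, PATCH_SIZE / 2, PATCH_SIZE / 2))
  db2 <- numeric(nf)
  dW2 <- model$W2 * 0
  for (g in seq_len(nf)) {
    u2 <- upsample2(fw$h2[[g]])
    dW3[g] <- sum(dlogit * u2)
    dh2 <- downsample2_sum(dlogit) * model$W3[g] * (fw$h2pre[[g]] > 0)
    db2[g] <- sum(dh2)
    for (f in seq_len(nf)) {
      dW2[, , f, g] <- conv2same_gradk(fw$p1[[f]]$p, dh2, 3L)
      dp1[[f]] <- dp1[[f]] + conv2same_gradx(model$W2[, , f, g], dh2)
    }
  }
  db3 <- sum(dlogit)
  dW1 <- model$W1 * 0
  db1 <- numeric(nf)
  for (f in seq_len(nf)) {
    dh1 <- maxunpool2(dp1[[f]], fw$p1[[f]]$arg) * (fw$h1pre[[f]] > 0)
    db1[f] <- sum(dh1)
    dW1[, , f] <- conv2same_gradk(fw$x, dh1, 5L)
  }
  model$W1 <- model$W1 - lr * dW1
  model$b1 <- model$b1 - lr * db1
  model$W2 <- model$W2 - lr * dW2
  model$b2 <- model$b2 - lr * db2
  model$W3 <- model$W3 - lr * dW3
  model$b3 <- model$b3 - lr * db3
  model
}

#' Train the patch-based pixel classifier
#'
#' Trains a compact encoder-decoder segmenter on 64x64 grayscale patches
#' with per-pixel binary labels, minimizing pixel cross-entropy by
#' stochastic gradient descent. Inputs are zero-centered at the input layer.
#' Intended for small-scale training on phantom data; the shipped default
#' segmentation path is the classical fallback in [classify_image()].
#'
#' @param patches List of 64x64 numeric matrices (or a single matrix).
#' @param labels List of 64x64 binary matrices, same length as `patches`.
#' @param epochs Number of passes over the patch set.
#' @param lr SGD learning rate.
#' @param nf Number of convolution filters per layer.
#' @param seed Integer seed for weight initialization (training is
#'   deterministic given the seed).
#' @return A `patch_classifier` model; `$loss` holds the full-set
#'   cross-entropy evaluated after each epoch.
#' @export
train_patch_classifier <- function(patches, labels, epochs = 20, lr = 0.2,
                                   nf = 8, seed = 1) {
  if (is.matrix(patches)) patches <- list(patches)
  if (is.matrix(labels)) labels <- list(labels)
  if (length(patches) < 1) abort("need at least one labeled patch")
  if (length(patches) != length(labels)) {
    abort("`patches` and `labels` must have the same length")
  }
  for (p in patches) {
    if (!all(dim(p) == PATCH_SIZE)) {
      abort("all patches must be 64x64")
    }
  }
  for (l in labels) {
    if (!all(dim(l) == PATCH_SIZE)) abort("all label maps must be 64x64")
  }
  model <- with_seed(derive_seed(seed, "training"), list(
    nf = nf,
    W1 = array(rnorm(5 * 5 * nf, 0, 0.1), c(5, 5, nf)),
    b1 = numeric(nf),
    W2 = array(rnorm(3 * 3 * nf * nf, 0, 0.1), c(3, 3, nf, nf)),
    b2 = numeric(nf),
    W3 = rnorm(nf, 0, 0.1),
    b3 = 0
  ))
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    for (i in seq_along(patches)) {
      model <- classifier_sgd_step(model, patches[[i]], labels[[i]], lr)
    }
    loss[e] <- mean(vapply(seq_along(patches), function(i) {
      classifier_loss(classifier_forward(model, patches[[i]])$prob, labels[[i]])
    }, numeric(1)))
  }
  model$loss <- loss
  class(model) <- "patch_classifier"
  model
}

#' Predict a pixel probability map for one 64x64 patch
#' @param model A `patch_classifier`.
#' @param patch 64x64 numeric matrix.
#' @return 64x64 matrix of neuron probabilities in `[0, 1]`.
#' @export
predict_patch <- function(model, patch) {
  stopifnot(inherits(model, "patch_classifier"))
  if (!all(dim(patch) == PATCH_SIZE)) abort("patch must be 64x64")
  classifier_forward(model, patch)$prob
}
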