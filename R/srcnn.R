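#' Architecture of the three-layer 3-D super-resolution network
#'
#' The restoration network is three 3-D convolutions with kernel edges
#' 9, 3, 5 and channel counts 32, 16, 1 (the classic SRCNN design extended
#' to 3-D), ReLU between layers, a linear output layer, and a residual path
#' that averages the final feature map with the interpolated input:
#' \deqn{y = (1 - w)\,x + w\,f(x)}
#' with `w = residual_weight` (arithmetic mean at the default 0.5) and
#' \eqn{f} the convolution stack.  All convolutions use "same" zero
#' padding, so output dimensions equal input dimensions.
#'
#' @param kernel_edges three odd positive integers, the cubic kernel edge
#'   lengths per layer.
#' @param channels three positive integers, output channels per layer; the
#'   last must be 1.
#' @param residual_weight weight of the learned branch in `[0, 1]`.
#' @param init_scale standard deviation of the Gaussian weight
#'   initialization.
#' @param seed integer RNG seed for the initialization draw.
#' @return An object of class `"srcnn_spec"`.
#' @export
srcnn_spec <- function(kernel_edges = c(9L, 3L, 5L),
                       channels = c(32L, 16L, 1L),
                       residual_weight = 0.5,
                       init_scale = 1e-3,
                       seed = 1L) {
  kernel_edges <- as.integer(kernel_edges)
  channels <- as.integer(channels)
  if (length(kernel_edges) != 3L || any(kernel_edges < 1L) ||
      any(kernel_edges %% 2L == 0L))
    dwisr_stop("`kernel_edges` must be three odd positive integers", "config")
  if (length(channels) != 3L || any(channels < 1L))
    dwisr_stop("`channels` must be three positive integers", "config")
  if (channels[3L] != 1L)
    dwisr_stop("the last layer must have exactly 1 output channel", "config")
  stopifnot_scalar_number(residual_weight, "residual_weight")
  if (residual_weight < 0 || residual_weight > 1)
    dwisr_stop("`residual_weight` must lie in [0, 1]", "config")
  if (!is.numeric(init_scale) || init_scale < 0)
    dwisr_stop("`init_scale` must be >= 0", "config")
  structure(list(kernel_edges = kernel_edges, channels = channels,
                 residual_weight = residual_weight,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "srcnn_spec")
}

#' Initialize an untrained super-resolution network
#'
#' Draws kernel weights from a zero-mean Gaussian of scale
#' `spec$init_scale` (biases zero), deterministically for a given spec
#' seed.  The result is a full model object (class `"srcnn"`) with an
#' iteration count of zero; [fit_srcnn()] continues from it.
#'
#' @param spec an [srcnn_spec()].
#' @return An object of class `"srcnn"` with elements `weights` (a list of
#'   three layers, each with a 5-D kernel array `W` of dim
#'   `c(k, k, k, c_in, c_out)` and bias vector `b`), `spec` and
#'   `iterations = 0`.
#' @export
init_srcnn <- function(spec = srcnn_spec()) {
  stopifnot(inherits(spec, "srcnn_spec"))
  cin <- c(1L, spec$channels[1L], spec$channels[2L])
  weights <- with_seed(spec$seed, lapply(1:3, function(l) {
    k <- spec$kernel_edges[l]
    n <- k^3 * cin[l] * spec$channels[l]
    W <- array(rnorm(n, sd = spec$init_scale),
               c(k, k, k, cin[l], spec$channels[l]))
    list(W = W, b = numeric(spec$channels[l]))
  }))
  structure(list(weights = weights, spec = spec, iterations = 0L,
                 log = NULL, checkpoints = list(), control = NULL),
            class = "srcnn")
}

check_net_input <- function(model, interpolated) {
  stopifnot(inherits(model, "srcnn"))
  if (!is.array(interpolated) || length(dim(interpolated)) != 3L)
    dwisr_stop("input must be a 3-D array", "shape")
  if (!all(is.finite(interpolated)))
    dwisr_stop("input contains non-finite values", "data")
  invisible(dim(interpolated))
}

#' Forward pass of the super-resolution network
#'
#' Applies the three-layer convolution stack to an interpolated volume and
#' averages the result with the input through the residual path.  Output
#' dimensions always equal input dimensions ("same" zero padding).
#'
#' @param model an `"srcnn"` object.
#' @param interpolated 3-D numeric array (the interpolated low-resolution
#'   volume).
#' @return 3-D array of the same dimensions.
#' @export
srcnn_forward <- function(model, interpolated) {
  dims <- check_net_input(model, interpolated)
  sp <- model$spec
  out <- srcnn_pass(as.numeric(interpolated), as.integer(dims),
                    model$weights, sp$kernel_edges, sp$channels,
                    sp$residual_weight)
  array(out, dims)
}

# Reusable im2col buffers for the training loop: one neighbourhood matrix
# per convolution (P1..P3, reused for the weight gradients) and two for
# the transposed convolutions of the backward pass.  Buffers are filled in
# place at every iteration, so the ~200 MB (at default architecture and
# 24^3-scale volumes) is allocated once per fit, not once per iteration.
srcnn_workspace <- function(spec, dims) {
  nvox <- prod(dims)
  k <- spec$kernel_edges
  ch <- spec$channels
  ws <- new.env(parent = emptyenv())
  ws$dims <- as.integer(dims)
  ws$P1 <- matrix(0, nvox, k[1L]^3)
  ws$P2 <- matrix(0, nvox, k[2L]^3 * ch[1L])
  ws$P3 <- matrix(0, nvox, k[3L]^3 * ch[2L])
  ws$Pd3 <- matrix(0, nvox, k[3L]^3)
  ws$Pd2 <- matrix(0, nvox, k[2L]^3 * ch[2L])
  ws
}

# Kernel flattened for the transposed convolution of the backward pass:
# spatially flipped, with input/output channel roles swapped.
flipped_wmat <- function(W) {
  k <- dim(W)[1L]
  Wf <- W[k:1, k:1, k:1, , , drop = FALSE]
  Wf <- aperm(Wf, c(1L, 2L, 3L, 5L, 4L))
  matrix(Wf, nrow = k^3 * dim(W)[5L], ncol = dim(W)[4L])
}

# Mean-squared-error loss and its gradient w.r.t. all weights and biases
# for a single (source, target) pair.  Backpropagation through the im2col
# matrices: each convolution is a GEMM against the neighbourhood matrix,
# the weight gradient is the matching crossprod, and the input gradient is
# a convolution of the upstream gradient with the flipped kernel.
srcnn_loss_grad <- function(model, source, target, ws = NULL) {
  dims <- check_net_input(model, source)
  if (!identical(dim(target), dims))
    dwisr_stop("source and target dimensions differ", "shape")
  sp <- model$spec
  k <- as.integer(sp$kernel_edges)
  ch <- sp$channels
  if (is.null(ws) || !identical(ws$dims, as.integer(dims)))
    ws <- srcnn_workspace(sp, dims)
  nvox <- prod(dims)
  wts <- model$weights
  W1 <- matrix(wts[[1L]]$W, ncol = ch[1L])
  W2 <- matrix(wts[[2L]]$W, ncol = ch[2L])
  W3 <- matrix(wts[[3L]]$W, ncol = 1L)

  x <- matrix(as.numeric(source), ncol = 1L)
  im2col_fill(x, ws$dims, k[1L], ws$P1)
  A1 <- pmax(ws$P1 %*% W1 + rep(wts[[1L]]$b, each = nvox), 0)
  im2col_fill(A1, ws$dims, k[2L], ws$P2)
  A2 <- pmax(ws$P2 %*% W2 + rep(wts[[2L]]$b, each = nvox), 0)
  im2col_fill(A2, ws$dims, k[3L], ws$P3)
  f <- ws$P3 %*% W3 + wts[[3L]]$b

  w <- sp$residual_weight
  out <- (1 - w) * as.numeric(source) + w * as.numeric(f)
  err <- out - as.numeric(target)
  loss <- mean(err^2)

  dZ3 <- matrix((2 * w / nvox) * err, ncol = 1L)
  dW3 <- crossprod(ws$P3, dZ3)
  db3 <- sum(dZ3)
  im2col_fill(dZ3, ws$dims, k[3L], ws$Pd3)
  dZ2 <- (ws$Pd3 %*% flipped_wmat(wts[[3L]]$W)) * (A2 > 0)
  dW2 <- crossprod(ws$P2, dZ2)
  db2 <- colSums(dZ2)
  im2col_fill(dZ2, ws$dims, k[2L], ws$Pd2)
  dZ1 <- (ws$Pd2 %*% flipped_wmat(wts[[2L]]$W)) * (A1 > 0)
  dW1 <- crossprod(ws$P1, dZ1)
  db1 <- colSums(dZ1)

  grads <- list(list(W = dW1, b = db1), list(W = dW2, b = db2),
                list(W = dW3, b = db3))
  for (l in 1:3) dim(grads[[l]]$W) <- dim(wts[[l]]$W)
  list(loss = loss, grads = grads, output = array(out, dims))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS container holding the full `"srcnn"` object
#' (weights, architecture spec, iteration count and training log), so a
#' restored model is immediately usable for prediction or further training.
#'
#' @param model an `"srcnn"` object.
#' @param path file path for the checkpoint.
#' @return `write_srcnn()` returns `model` invisibly; `read_srcnn()`
#'   returns the restored `"srcnn"` object.
#' @export
write_srcnn <- function(model, path) {
  stopifnot(inherits(model, "srcnn"))
  saveRDS(model, path)
  invisible(model)
}

#' @rdname write_srcnn
#' @export
read_srcnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "srcnn"))
    dwisr_stop("file does not contain an srcnn checkpoint", "io")
  model
}

#' @export
print.srcnn <- function(x, ...) {
  sp <- x$spec
  cat("<srcnn> 3-D super-resolution network\n")
  cat(sprintf("  layers: %s (kernel edges), %s (channels), ReLU between\n",
              paste(sp$kernel_edges, collapse = "/"),
              paste(sp$channels, collapse = "/")))
  cat(sprintf("  residual weight: %g   parameters: %d\n",
              sp$residual_weight, n_parameters(x)))
  if (x$iterations == 0L) cat("  untrained (0 iterations)\n")
  else cat(sprintf("  trained for %d iterations; final loss %.4g\n",
                   x$iterations, utils::tail(x$log$loss, 1L)))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$weights,
             function(l) length(l$W) + length(l$b), 0))
}

#' @export
coef.srcnn <- function(object, ...) {
  object$weights
}

#' @export
summary.srcnn <- function(object, ...) {
  out <- list(spec = object$spec, iterations = object$iterations,
              n_parameters = n_parameters(object),
              checkpoints = vapply(object$checkpoints, `[[`, 0L,
                                   "iteration"))
  if (!is.null(object$log)) {
    out$loss_initial <- object$log$loss[1L]
    out$loss_final <- utils::tail(object$log$loss, 1L)
    out$subject_loss <- subject_loss(object$log)
  }
  class(out) <- "summary.srcnn"
  out
}

#' @export
print.summary.srcnn <- function(x, ...) {
  cat("3-D SRCNN:", x$n_parameters, "parameters,",
      x$iterations, "training iterations\n")
  if (!is.null(x$loss_initial))
    cat(sprintf("  loss: %.5g (first iteration) -> %.5g (last)\n",
                x$loss_initial, x$loss_final))
  if (length(x$checkpoints))
    cat("  checkpoints at iterations:",
        paste(x$checkpoints, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.srcnn <- function(x, log = "y", ...) {
  if (is.null(x$log) || !nrow(x$log))
    dwisr_stop("model has no training log to plot", "usage")
  plot(x$log$iteration, x$log$loss, type = "l", log = log,
       xlab = "iteration", ylab = "MSE loss",
       main = "Training loss", ...)
  invisible(x)
}
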