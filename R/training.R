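#' Training hyperparameters
#'
#' Controls the AdaGrad/MSE training loop.  The optimizer updates each
#' parameter with its accumulated squared gradient,
#' \deqn{a \leftarrow a + g^2, \quad
#'       \theta \leftarrow \theta - \eta\, g / \sqrt{a + \epsilon},}
#' which adapts the effective learning rate to the gradient history.
#' Training streams one pair at a time (batch size is fixed at 1), and the
#' loss is the mean (not sum) of squared voxel errors so volumes of
#' different sizes are comparable.
#'
#' @param learning_rate positive step size (default 5e-4; larger rates make
#'   the evaluation indices oscillate around the optimum late in training).
#' @param optimizer optimizer name; only `"adagrad"` is supported.
#' @param batch_size fixed at 1; any other value is a configuration error.
#' @param epochs number of passes over the training pairs.
#' @param checkpoint_interval snapshot the weights every this many
#'   iterations (a final snapshot is always taken).
#' @param loss loss name; only `"mse"` is supported.
#' @param epsilon AdaGrad stabilizer added inside the square root.
#' @param seed integer seed for the per-epoch shuffling of pair order.
#' @return An object of class `"training_control"`.
#' @export
training_control <- function(learning_rate = 5e-4, optimizer = "adagrad",
                             batch_size = 1L, epochs = 10L,
                             checkpoint_interval = 5000L, loss = "mse",
                             epsilon = 1e-8, seed = 1L) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  if (!identical(optimizer, "adagrad"))
    dwisr_stop("only the AdaGrad optimizer is supported", "config")
  if (!identical(as.integer(batch_size), 1L))
    dwisr_stop("`batch_size` is fixed at 1", "config")
  if (!identical(loss, "mse"))
    dwisr_stop("only the MSE loss is supported", "config")
  epochs <- as.integer(epochs)
  checkpoint_interval <- as.integer(checkpoint_interval)
  if (epochs < 1L) dwisr_stop("`epochs` must be >= 1", "config")
  if (checkpoint_interval < 1L)
    dwisr_stop("`checkpoint_interval` must be >= 1", "config")
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 batch_size = 1L, epochs = epochs,
                 checkpoint_interval = checkpoint_interval, loss = loss,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "training_control")
}

#' One AdaGrad update
#'
#' Applies the per-parameter AdaGrad rule to a parameter array: the
#' accumulator gains the squared gradient and the step is
#' `lr * g / sqrt(acc + eps)`.
#'
#' @param par numeric vector/array of parameters.
#' @param grad gradient of the loss w.r.t. `par` (same shape).
#' @param acc accumulated squared gradients (same shape; start at 0).
#' @param lr learning rate.
#' @param eps stabilizer (default 1e-8).
#' @return List with updated `par` and `acc`.
#' @export
adagrad_step <- function(par, grad, acc, lr, eps = 1e-8) {
  acc <- acc + grad^2
  list(par = par - lr * grad / sqrt(acc + eps), acc = acc)
}

#' Build interpolated/target training pairs from a DWI volume
#'
#' For every gradient entry the high-resolution grid (zero-padded to
#' dimensions divisible by the resampling factor) becomes the target; the
#' source is the target degraded by block-average downsampling, restored by
#' interpolation, and range-renormalized against the target.  Source and
#' target therefore have identical dimensions, and a constant target
#' survives the cycle unchanged.
#'
#' With `rescale = TRUE` (default) all grids are divided by the volume-wide
#' intensity maximum first, so training operates on intensities in
#' `[0, 1]` regardless of scanner units; the range renormalization applied
#' at prediction time restores the output scale.
#'
#' @param vol a [dwi_volume()].
#' @param spec a [resample_spec()].
#' @param rescale divide by the global intensity maximum before pairing.
#' @param subject optional subject label attached to every pair (used for
#'   per-subject loss aggregation).
#' @return A list of class `"dwi_pairs"`; each element has `source`,
#'   `target`, `bval` and `subject`.
#' @export
build_pairs <- function(vol, spec = resample_spec(), rescale = TRUE,
                        subject = NULL) {
  stopifnot(inherits(vol, "dwi_volume"), inherits(spec, "resample_spec"))
  f <- spec$factor
  data <- vol$data
  if (isTRUE(rescale)) {
    mx <- max(data)
    if (mx > 0) data <- data / mx
  }
  pairs <- lapply(seq_len(dim(data)[4L]), function(i) {
    target <- data[, , , i, drop = FALSE]
    dim(target) <- dim(data)[1:3]
    target <- pad_to_multiple(target, f)
    source <- interpolate_up(downsample(target, f), f, spec$method)
    if (spec$renormalize && max(target) > min(target))
      source <- normalize_range(source, target)
    list(source = source, target = target, bval = vol$bvals[i],
         subject = subject %||% 1L)
  })
  structure(pairs, class = "dwi_pairs")
}

# canonical three-group scheme over the acquisition shells
.group_defs <- list(b0_b1000 = c(0, 1000), b1500 = 1500, b2000 = 2000)

group_label_for_bval <- function(bval, tol = 100) {
  for (lab in names(.group_defs))
    if (any(abs(.group_defs[[lab]] - bval) <= tol)) return(lab)
  dwisr_stop(sprintf(
    "b-value %g does not belong to any configured shell (0, 1000, 1500, 2000)",
    bval), "config")
}

#' Split training pairs into the three b-value groups
#'
#' A separate model is trained per diffusion-weighting strength so that no
#' single model must absorb the contrast differences between shells.  The
#' unweighted b = 0 images (one per subject) are merged into the b = 1000
#' group; b = 1500 and b = 2000 each form their own group.  Exactly three
#' groups are always returned (possibly with zero pairs); a b-value outside
#' the configured shells is a configuration error naming the value.
#'
#' @param pairs a `"dwi_pairs"` list (or plain list of pairs).
#' @param tol tolerance in s/mm^2 for matching a pair's b-value to a shell.
#' @return A named list of three objects of class `"bvalue_group"`, each
#'   with `label`, `bvalues` (member shells) and `pairs`.
#' @export
group_by_bvalue <- function(pairs, tol = 100) {
  labels <- vapply(pairs, function(p) group_label_for_bval(p$bval, tol), "")
  out <- lapply(names(.group_defs), function(lab) {
    structure(list(label = lab, bvalues = .group_defs[[lab]],
                   pairs = structure(pairs[labels == lab],
                                     class = "dwi_pairs")),
              class = "bvalue_group")
  })
  names(out) <- names(.group_defs)
  out
}

as_pair_list <- function(pairs) {
  if (inherits(pairs, "bvalue_group")) pairs <- pairs$pairs
  if (!length(pairs))
    dwisr_stop("no training pairs supplied", "usage")
  pairs
}

#' Fit the 3-D super-resolution network
#'
#' Trains the three-layer residual network on interpolated/target pairs by
#' streaming one pair per iteration (batch size 1) through the AdaGrad/MSE
#' loop.  Pair order is shuffled once per epoch under the control seed, the
#' loss is recorded at every iteration, and weight snapshots are taken
#' every `checkpoint_interval` iterations (plus a final one).  Identical
#' data, spec and control give bit-identical fits.
#'
#' @param pairs a `"dwi_pairs"` list or a `"bvalue_group"` from
#'   [group_by_bvalue()]; must be non-empty.
#' @param spec an [srcnn_spec()] describing the architecture.
#' @param control a [training_control()].
#' @param model optional `"srcnn"` object to continue training from
#'   (defaults to a fresh [init_srcnn()] of `spec`).
#' @return An object of class `"srcnn"`; see [init_srcnn()] for the weight
#'   layout.  Additional elements: `log` (data frame with `iteration`,
#'   `epoch`, `subject`, `bval`, `loss`), `checkpoints` (list of
#'   `list(iteration, weights)`), `control` and `group` (label, when fitted
#'   on a `"bvalue_group"`).  Supports `print()`, `summary()`, `coef()`,
#'   `predict()` and `plot()`.
#' @examples
#' \donttest{
#' spec <- phantom_spec(grid_shape = c(6, 6, 6),
#'                      gradients = icosahedral_gradients(shells = 1000))
#' vol <- generate_phantom(spec)
#' pairs <- build_pairs(vol)
#' fit <- fit_srcnn(pairs, srcnn_spec(kernel_edges = c(3, 3, 3),
#'                                    channels = c(4, 4, 1)),
#'                  training_control(epochs = 2))
#' print(fit)
#' }
#' @export
fit_srcnn <- function(pairs, spec = srcnn_spec(),
                      control = training_control(), model = NULL) {
  group_label <- if (inherits(pairs, "bvalue_group")) pairs$label else NA
  plist <- as_pair_list(pairs)
  stopifnot(inherits(control, "training_control"))
  model <- model %||% init_srcnn(spec)
  stopifnot(inherits(model, "srcnn"))

  acc <- lapply(model$weights, function(l)
    list(W = array(0, dim(l$W)), b = numeric(length(l$b))))
  lr <- control$learning_rate
  eps <- control$epsilon

  n <- length(plist)
  total <- control$epochs * n
  log_iter <- integer(total); log_epoch <- integer(total)
  log_subj <- vector("list", total); log_bval <- numeric(total)
  log_loss <- numeric(total)
  iter <- model$iterations
  checkpoints <- model$checkpoints
  row <- 0L

  ws <- srcnn_workspace(model$spec, dim(plist[[1L]]$source))
  orders <- with_seed(control$seed,
                      lapply(seq_len(control$epochs),
                             function(e) sample.int(n)))
  for (epoch in seq_len(control$epochs)) {
    for (j in orders[[epoch]]) {
      p <- plist[[j]]
      lg <- srcnn_loss_grad(model, p$source, p$target, ws)
      if (!is.finite(lg$loss))
        dwisr_stop(sprintf(
          "training diverged: non-finite loss at iteration %d", iter + 1L),
          "divergence")
      for (l in 1:3) {
        sW <- adagrad_step(model$weights[[l]]$W, lg$grads[[l]]$W,
                           acc[[l]]$W, lr, eps)
        model$weights[[l]]$W <- sW$par
        acc[[l]]$W <- sW$acc
        sb <- adagrad_step(model$weights[[l]]$b, lg$grads[[l]]$b,
                           acc[[l]]$b, lr, eps)
        model$weights[[l]]$b <- sb$par
        acc[[l]]$b <- sb$acc
      }
      iter <- iter + 1L
      row <- row + 1L
      log_iter[row] <- iter; log_epoch[row] <- epoch
      log_subj[[row]] <- p$subject; log_bval[row] <- p$bval
      log_loss[row] <- lg$loss
      if (iter %% control$checkpoint_interval == 0L)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(iteration = iter, weights = model$weights)
    }
  }
  if (!length(checkpoints) ||
      checkpoints[[length(checkpoints)]]$iteration != iter)
    checkpoints[[length(checkpoints) + 1L]] <-
      list(iteration = iter, weights = model$weights)

  log <- data.frame(iteration = log_iter[seq_len(row)],
                    epoch = log_epoch[seq_len(row)],
                    subject = unlist(log_subj[seq_len(row)]),
                    bval = log_bval[seq_len(row)],
                    loss = log_loss[seq_len(row)])
  model$log <- rbind(model$log, log)
  model$iterations <- iter
  model$checkpoints <- checkpoints
  model$control <- control
  model$group <- group_label
  model
}

#' Per-subject aggregated training loss
#'
#' The loss is logged at every iteration; this aggregates it to one value
#' per (epoch, subject): the mean of that subject's iteration losses, i.e.
#' the loss recorded each time one subject's data has been trained.
#'
#' @param log the `log` data frame of a fitted `"srcnn"`.
#' @return Data frame with columns `epoch`, `subject`, `loss`.
#' @export
subject_loss <- function(log) {
  out <- aggregate(loss ~ epoch + subject, data = log, FUN = mean)
  out[order(out$epoch, out$subject), , drop = FALSE]
}

#' Super-resolve a volume with a fitted network
#'
#' Applies the full restoration path to a low-resolution 3-D grid:
#' interpolate up by the resampling factor, scale into the training
#' intensity range, run the network forward, and renormalize the result
#' onto the interpolated image's intensity range (the only range available
#' at prediction time, standing in for the unknown original).
#'
#' Three renormalization modes are provided.  The default, `"clamp"`,
#' trusts the intensity calibration the network learned under the shared
#' training scale and only clamps the thin negative ringing halo that a
#' convolution stack produces (MRI magnitudes are nonnegative).  `"range"`
#' is the literal two-point map of [normalize_range()] onto the
#' interpolated image's range; it makes an untrained (zero-weight) model
#' reproduce the interpolated image exactly, but for a trained model it
#' re-imposes the interpolated image's intensity distribution, whose upper
#' tail is systematically attenuated by the smoothing the network was
#' trained to undo, and its min/max anchors are single-voxel extremes
#' (undershoot/overshoot outliers) -- both measurably degrade PSNR and
#' structural similarity.  `"none"` returns the raw network output on the
#' input intensity scale.
#'
#' @param object a fitted (or initialized) `"srcnn"` object.
#' @param newdata low-resolution 3-D array, or an already interpolated
#'   array when `interpolated = TRUE`.
#' @param spec a [resample_spec()] giving factor and kernel.
#' @param interpolated set to `TRUE` when `newdata` has already been
#'   upsampled.
#' @param scale intensity scale that maps the input onto the training
#'   intensity convention of [build_pairs()] (the volume-wide maximum of
#'   the subject's data); defaults to the maximum of the interpolated
#'   input, the prediction-time stand-in.  [predict_dwi()] passes the
#'   maximum over the whole interpolated 4-D volume.
#' @param renormalize renormalization mode: `"clamp"` (default),
#'   `"range"` or `"none"`.
#' @param ... unused.
#' @return 3-D array with `spec$factor`-times the input dimensions.
#' @export
predict.srcnn <- function(object, newdata, spec = resample_spec(),
                          interpolated = FALSE, scale = NULL,
                          renormalize = c("clamp", "range", "none"), ...) {
  if (!is.array(newdata) || length(dim(newdata)) != 3L)
    dwisr_stop("`newdata` must be a 3-D array", "shape")
  renormalize <- match.arg(renormalize)
  interp <- if (interpolated) newdata
            else interpolate_up(newdata, spec$factor, spec$method)
  s <- scale %||% max(interp)
  if (!is.finite(s) || s <= 0) s <- 1
  y <- srcnn_forward(object, interp / s)
  switch(renormalize,
    clamp = pmax(y, 0) * s,
    range = {
      if (max(interp) > min(interp)) normalize_range(y, interp)
      else array(interp[1L], dim(interp))
    },
    none = y * s)
}

#' Select the best checkpoint by the normalized three-index product
#'
#' Checkpoints are compared on held-out metrics by multiplying three
#' indices: PSNR normalized to `[0, 1]` by dividing every checkpoint's
#' average PSNR by the best average PSNR, times average SSIM, times average
#' cosine similarity.  The checkpoint with the largest product wins; ties
#' go to the earlier checkpoint.
#'
#' @param metrics data frame with one row per checkpoint and columns
#'   `psnr`, `ssim`, `cosine` (checkpoint averages), plus optionally
#'   `checkpoint` (identifier; defaults to the row number).
#' @return The identifier of the selected checkpoint.  The product scores
#'   are attached as `attr(, "scores")`.
#' @seealso [product_score()]
#' @export
select_best_checkpoint <- function(metrics) {
  metrics <- as.data.frame(metrics)
  if (!nrow(metrics))
    dwisr_stop("no checkpoint metrics supplied", "usage")
  scores <- product_score(metrics)
  best <- which.max(scores)  # first maximum: earlier checkpoint wins ties
  id <- if ("checkpoint" %in% names(metrics)) metrics$checkpoint[best]
        else best
  structure(id, scores = scores)
}
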