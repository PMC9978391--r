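#' Degrade/restore resampling specification
#'
#' Parameters of the resolution-degradation cycle used to build training
#' pairs: integer downsampling factor, the interpolation kernel used to
#' restore the original grid, and whether restored grids are renormalized
#' to the reference intensity range afterwards.
#'
#' @param factor positive integer resampling factor (default 3, i.e. a 1/3
#'   resolution reduction and x3 restoration).
#' @param method interpolation kernel: `"tricubic"` (Keys cubic, the
#'   conventional bicubic baseline extended to 3-D), `"trilinear"` or
#'   `"nearest"`.
#' @param renormalize logical; apply [normalize_range()] after every
#'   resolution change.
#' @return An object of class `"resample_spec"`.
#' @export
resample_spec <- function(factor = 3L,
                          method = c("tricubic", "trilinear", "nearest"),
                          renormalize = TRUE) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    dwisr_stop("`factor` must be a positive integer", "config")
  if (!is.character(method))
    dwisr_stop("`method` must be an interpolation method name", "config")
  method <- method[1L]
  if (!method %in% c("tricubic", "trilinear", "nearest"))
    dwisr_stop(paste0("unknown interpolation method: ", method), "config")
  structure(list(factor = as.integer(factor), method = method,
                 renormalize = isTRUE(renormalize)),
            class = "resample_spec")
}

block_mean_axis1 <- function(a, f) {
  d <- dim(a)
  out <- colMeans(matrix(a, nrow = f))
  array(out, c(d[1L] / f, d[2L], d[3L]))
}

#' Downsample a 3-D grid by block averaging
#'
#' Reduces each dimension by an integer factor; every output voxel is the
#' arithmetic mean of its `factor^3` source block.  Block averaging (rather
#' than strided decimation) is anti-aliased and maps constant volumes to
#' themselves exactly.
#'
#' @param vol 3-D numeric array whose dimensions are all divisible by
#'   `factor`.
#' @param factor positive integer.
#' @return 3-D array of dimension `dim(vol) / factor`.
#' @seealso [interpolate_up()]
#' @export
downsample <- function(vol, factor = 3L) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    dwisr_stop("`vol` must be a 3-D array", "shape")
  factor <- as.integer(factor)
  if (factor < 1L) dwisr_stop("`factor` must be >= 1", "config")
  if (any(dim(vol) %% factor != 0L))
    dwisr_stop(sprintf(
      "dimensions (%s) are not divisible by factor %d; pad first",
      paste(dim(vol), collapse = ", "), factor), "shape")
  if (factor == 1L) return(vol)
  for (i in 1:3) {
    vol <- block_mean_axis1(vol, factor)
    vol <- aperm(vol, c(2L, 3L, 1L))
  }
  vol
}

# 1-D interpolation operator (n_in*factor x n_in) under voxel-center
# alignment: output sample i (0-based) sits at input coordinate
# (i + 0.5)/factor - 0.5.  Out-of-range taps are clamped to the border
# (edge replication), which keeps kernel weights a partition of unity.
interp_matrix <- function(n_in, factor, method) {
  n_out <- n_in * factor
  pos <- (seq_len(n_out) - 0.5) / factor - 0.5
  B <- matrix(0, n_out, n_in)
  clamp <- function(i) pmin(pmax(i, 0L), n_in - 1L)
  if (method == "nearest") {
    idx <- clamp(as.integer(floor(pos + 0.5)))
    B[cbind(seq_len(n_out), idx + 1L)] <- 1
  } else if (method == "trilinear") {
    i0 <- floor(pos)
    t <- pos - i0
    for (o in 0:1) {
      w <- if (o == 0) 1 - t else t
      idx <- clamp(as.integer(i0) + o)
      for (r in seq_len(n_out)) B[r, idx[r] + 1L] <- B[r, idx[r] + 1L] + w[r]
    }
  } else {  # tricubic: Keys kernel with a = -1/2
    a <- -0.5
    keys <- function(s) {
      s <- abs(s)
      ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
             ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
    }
    i0 <- floor(pos)
    t <- pos - i0
    for (o in -1:2) {
      w <- keys(t - o)
      idx <- clamp(as.integer(i0) + o)
      for (r in seq_len(n_out)) B[r, idx[r] + 1L] <- B[r, idx[r] + 1L] + w[r]
    }
  }
  B
}

apply_axis1 <- function(a, B) {
  d <- dim(a)
  array(B %*% matrix(a, nrow = d[1L]), c(nrow(B), d[2L], d[3L]))
}

#' Upsample a 3-D grid by separable interpolation
#'
#' Restores a downsampled grid to `factor` times its size along each axis
#' using nearest-neighbor, trilinear or tricubic (Keys) interpolation,
#' applied separably with voxel-center alignment and edge replication at
#' the borders.  Under this alignment, for factor 3 every third output
#' sample coincides with a source lattice site and reproduces its value
#' (for the interpolating linear/cubic kernels).
#'
#' @param vol 3-D numeric array.
#' @param factor positive integer upsampling factor.
#' @param method `"tricubic"`, `"trilinear"` or `"nearest"`.
#' @return 3-D array of dimension `dim(vol) * factor`.
#' @export
interpolate_up <- function(vol, factor = 3L, method = "tricubic") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    dwisr_stop("`vol` must be a 3-D array", "shape")
  factor <- as.integer(factor)
  if (factor < 1L) dwisr_stop("`factor` must be >= 1", "config")
  if (!is.character(method) || length(method) != 1L ||
      !method %in% c("tricubic", "trilinear", "nearest"))
    dwisr_stop(paste0("unknown interpolation method: ", method), "config")
  if (factor == 1L) return(vol)
  for (i in 1:3) {
    B <- interp_matrix(dim(vol)[1L], factor, method)
    vol <- apply_axis1(vol, B)
    vol <- aperm(vol, c(2L, 3L, 1L))
  }
  vol
}

#' Linearly map a grid onto a reference intensity range
#'
#' Applies the affine map that sends the minimum and maximum of `vol` onto
#' the minimum and maximum of `reference`; the output extremes match the
#' reference extremes bit-exactly.  Used after every resolution change so
#' that restored images share the original intensity range.
#'
#' @param vol 3-D numeric array to rescale.
#' @param reference numeric array supplying the target range; must have
#'   `max > min`.
#' @return Array like `vol` spanning exactly the reference range.  If `vol`
#'   is constant the map is degenerate: a constant grid at the reference
#'   minimum is returned with a warning.
#' @export
normalize_range <- function(vol, reference) {
  if (!is.numeric(vol) || !is.numeric(reference))
    dwisr_stop("inputs must be numeric", "shape")
  rmin <- min(reference); rmax <- max(reference)
  if (!is.finite(rmin) || !is.finite(rmax) || rmax <= rmin)
    dwisr_stop("`reference` must have max > min", "domain")
  vmin <- min(vol); vmax <- max(vol)
  if (vmax == vmin) {
    warning("`vol` is constant; returning the reference minimum")
    out <- vol
    out[] <- rmin
    return(out)
  }
  out <- rmin + (vol - vmin) * ((rmax - rmin) / (vmax - vmin))
  out[vol == vmin] <- rmin
  out[vol == vmax] <- rmax
  out
}

#' Pad a 3-D grid with zeros to dimensions divisible by a factor
#'
#' Zero padding at the high end of each axis; zeros are background in
#' brain DWI so padded voxels behave like surrounding air.
#'
#' @param vol 3-D numeric array.
#' @param factor positive integer.
#' @return The padded array (unchanged if already divisible).
#' @export
pad_to_multiple <- function(vol, factor = 3L) {
  d <- dim(vol)
  target <- as.integer(ceiling(d / factor) * factor)
  if (all(target == d)) return(vol)
  out <- array(0, target)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
  out
}
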