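#' Diffusion-weighted volume container
#'
#' Bundles a 4-D diffusion-weighted intensity grid with its gradient table.
#' The fourth array axis always indexes gradient entries (one per acquired
#' diffusion direction); a 3-D array is promoted to 4-D with a single entry.
#' b-vectors are stored in the image coordinate frame as given; no
#' reorientation by the affine is attempted.
#'
#' Validation enforces the container's invariants: the gradient table must
#' match the fourth axis, all intensities must be finite, and every b-vector
#' with a positive b-value must be a unit vector.  Vectors whose norm
#' deviates from 1 by at most `1e-3` (text-file rounding) are silently
#' renormalized; larger deviations are only accepted as the zero vector on a
#' b = 0 entry.
#'
#' @param data numeric 3-D or 4-D array of intensities (x, y, z, gradient).
#' @param bvals numeric vector of b-values in s/mm^2, one per gradient entry.
#' @param bvecs numeric 3 x n matrix of gradient directions (columns), or an
#'   n x 3 matrix which is transposed.
#' @param voxel_size positive numeric length-3 vector, voxel edges in mm.
#' @param affine optional 4 x 4 spatial transform; identity when omitted.
#' @return An object of class `"dwi_volume"`: a list with elements `data`,
#'   `bvals`, `bvecs` (3 x n), `voxel_size` and `affine`.
#' @examples
#' vol <- dwi_volume(array(1, c(3, 3, 3)), bvals = 0,
#'                   bvecs = matrix(0, 3, 1))
#' n_gradients(vol)
#' @export
dwi_volume <- function(data, bvals, bvecs, voxel_size = c(1, 1, 1),
                       affine = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    dwisr_stop("`data` must be a 3-D or 4-D array", "data")
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  data <- array(as.double(data), dim(data))  # drop any foreign attributes
  if (any(dim(data)[1:3] < 1L))
    dwisr_stop("all spatial dimensions must be >= 1", "data")
  if (!all(is.finite(data)))
    dwisr_stop("volume contains non-finite intensities", "data")

  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    dwisr_stop("`bvecs` must have 3 components per direction", "metadata")
  n <- dim(data)[4L]
  if (length(bvals) != n || ncol(bvecs) != n)
    dwisr_stop(sprintf(
      "gradient table mismatch: %d volumes but %d b-values and %d b-vectors",
      n, length(bvals), ncol(bvecs)), "metadata")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    dwisr_stop("b-values must be finite and nonnegative", "metadata")

  nrm <- sqrt(colSums(bvecs^2))
  fix <- abs(nrm - 1) <= 1e-3 & nrm > 0
  bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")
  bad <- !fix & !(bvals == 0 & nrm == 0)
  if (any(bad))
    dwisr_stop(sprintf(
      "b-vector %d has norm %.4f: only unit vectors (or zero at b = 0) are valid",
      which(bad)[1L], nrm[which(bad)[1L]]), "metadata")

  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    dwisr_stop("`voxel_size` must be 3 positive lengths in mm", "metadata")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    dwisr_stop("`affine` must be a 4 x 4 matrix", "metadata")

  structure(list(data = data, bvals = bvals, bvecs = bvecs,
                 voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' Number of gradient entries in a DWI volume
#' @param vol a [dwi_volume()].
#' @return Integer count of gradient entries (4th-axis length).
#' @export
n_gradients <- function(vol) {
  stopifnot(inherits(vol, "dwi_volume"))
  dim(vol$data)[4L]
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  shells <- sort(unique(round(x$bvals)))
  cat("<dwi_volume> ", paste(d[1:3], collapse = " x "),
      " voxels, ", d[4L], " gradient entries\n", sep = "")
  cat("  voxel size: ", paste(format(x$voxel_size), collapse = " x "),
      " mm\n", sep = "")
  cat("  b-values:   ", paste(shells, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Extract one gradient entry as a 3-D grid
#' @param vol a [dwi_volume()].
#' @param i gradient index.
#' @return 3-D numeric array.
#' @export
dwi_grid <- function(vol, i) {
  stopifnot(inherits(vol, "dwi_volume"))
  g <- vol$data[, , , i, drop = FALSE]
  dim(g) <- dim(vol$data)[1:3]
  g
}
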