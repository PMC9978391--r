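#' Read a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' Loads a 3-D or 4-D NIfTI image together with its companion gradient
#' table in the FSL dialect: a `bval` text file holding one row of
#' b-values and a `bvec` file holding three rows (x, y, z components).
#' The result is validated: the gradient table must match the image's
#' fourth axis and all voxels must be finite.
#'
#' @param image_path path to a `.nii` or `.nii.gz` file.
#' @param bval_path path to the whitespace-separated b-value table.
#' @param bvec_path path to the whitespace-separated b-vector table.
#' @return A validated [dwi_volume()].
#' @seealso [write_dwi()]
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p))
      dwisr_stop(paste0("cannot read file: ", p), "io")
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) dwisr_stop(
                    paste0("failed to parse NIfTI file: ", conditionMessage(e)),
                    "io"))
  data <- as.array(img)
  if (!(length(dim(data)) %in% c(3L, 4L)))
    dwisr_stop("image must be 3-D or 4-D", "data")
  vx <- RNifti::pixdim(img)
  if (length(vx) < 3L || any(!is.finite(vx[1:3])) || any(vx[1:3] <= 0))
    vx <- c(1, 1, 1)
  bvals <- tryCatch(scan(bval_path, quiet = TRUE),
                    error = function(e) dwisr_stop(
                      paste0("failed to read bval table: ",
                             conditionMessage(e)), "io"))
  raw <- tryCatch(scan(bvec_path, quiet = TRUE),
                  error = function(e) dwisr_stop(
                    paste0("failed to read bvec table: ",
                           conditionMessage(e)), "io"))
  if (length(raw) %% 3L != 0L)
    dwisr_stop("bvec table length is not a multiple of 3", "metadata")
  # FSL layout: first row all x components, then y, then z.
  bvecs <- matrix(raw, nrow = 3L, byrow = TRUE)
  if (length(bvals) != ncol(bvecs))
    dwisr_stop(sprintf("bval table has %d entries but bvec table has %d",
                       length(bvals), ncol(bvecs)), "metadata")
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  dwi_volume(data, bvals = bvals, bvecs = bvecs,
             voxel_size = as.numeric(vx[1:3]), affine = aff)
}

#' Write a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' Stores the volume as 32-bit floating-point NIfTI with the voxel size in
#' the header, plus FSL-dialect gradient tables: one row of b-values and
#' three rows of b-vector components.  `read_dwi()` reconstructs the
#' dataset up to the 32-bit storage precision.
#'
#' @param vol a [dwi_volume()].
#' @param image_path,bval_path,bvec_path output paths.
#' @return Invisibly, `vol`.
#' @export
write_dwi <- function(vol, image_path, bval_path, bvec_path) {
  stopifnot(inherits(vol, "dwi_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size, 1)
  tryCatch({
    RNifti::writeNifti(img, image_path, datatype = "float")
    writeLines(paste(format(vol$bvals, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), bval_path)
    writeLines(apply(vol$bvecs, 1L, function(r)
      paste(format(r, digits = 15, trim = TRUE), collapse = " ")),
      bvec_path)
  }, error = function(e)
    dwisr_stop(paste0("failed to write DWI dataset: ", conditionMessage(e)),
               "io"),
  warning = function(w)
    dwisr_stop(paste0("failed to write DWI dataset: ", conditionMessage(w)),
               "io"))
  invisible(vol)
}
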