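#' Generalized q-sampling reconstruction parameters
#'
#' The spin-distribution function (SDF) is estimated model-free from
#' multi-shell DWI by projecting each gradient's signal onto a set of unit
#' directions through a sinc kernel whose argument scales with the
#' diffusion sampling length \eqn{\sqrt{6 D b}}.  With the default
#' free-water diffusivity `D = 3.0e-3` mm^2/s the per-gradient length is
#' \eqn{\sqrt{0.018\, b}}; `sampling_length_ratio` (the conventional
#' sigma, default 1.25) scales it.
#'
#' @param sampling_length_ratio positive scale of the sampling length.
#' @param diffusivity reference diffusivity D in mm^2/s.
#' @param tessellation_level icosahedron subdivision level for the
#'   direction set (level 3 gives 321 hemisphere directions).
#' @return An object of class `"gqi_spec"`.
#' @export
gqi_spec <- function(sampling_length_ratio = 1.25, diffusivity = 3.0e-3,
                     tessellation_level = 3L) {
  stopifnot_scalar_number(sampling_length_ratio, "sampling_length_ratio",
                          positive = TRUE)
  stopifnot_scalar_number(diffusivity, "diffusivity", positive = TRUE)
  tessellation_level <- as.integer(tessellation_level)
  if (tessellation_level < 1L)
    dwisr_stop("`tessellation_level` must be >= 1", "config")
  structure(list(sampling_length_ratio = sampling_length_ratio,
                 diffusivity = diffusivity,
                 tessellation_level = tessellation_level),
            class = "gqi_spec")
}

#' Tessellated hemisphere of unit directions
#'
#' Subdivides the icosahedron `level` times (edge midpoints pushed onto
#' the sphere), then keeps one representative per antipodal vertex pair;
#' diffusion is symmetric under direction reversal, so ODFs only need one
#' hemisphere.  Neighbor adjacency among the retained directions (vertices
#' sharing a mesh edge, with antipodes identified) supports local-maximum
#' peak search.
#'
#' @param level number of subdivisions (>= 1); level 1 keeps 21
#'   directions, level 3 keeps 321.
#' @return An object of class `"sphere_tessellation"`: list with
#'   `vertices` (n x 3 matrix of unit vectors), `adjacency` (list of
#'   integer neighbor vectors) and `n`.
#' @export
tessellate_sphere <- function(level = 3L) {
  level <- as.integer(level)
  if (level < 1L) dwisr_stop("`level` must be >= 1", "config")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(level)) {
    mid <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(V)
    newV <- vector("list", 0L)
    getmid <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      m <- V[i, ] + V[j, ]
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      id <- nv + length(newV)
      assign(key, id, envir = mid)
      id
    }
    nF <- matrix(0L, 4L * nrow(F), 3L)
    for (r in seq_len(nrow(F))) {
      a <- F[r, 1L]; b <- F[r, 2L]; cc <- F[r, 3L]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nF[4L * r - 3L, ] <- c(a, ab, ca)
      nF[4L * r - 2L, ] <- c(b, bc, ab)
      nF[4L * r - 1L, ] <- c(cc, ca, bc)
      nF[4L * r, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- nF
  }

  # one representative per antipodal pair
  tol <- 1e-9
  keep <- V[, 3L] > tol |
    (abs(V[, 3L]) <= tol & V[, 2L] > tol) |
    (abs(V[, 3L]) <= tol & abs(V[, 2L]) <= tol & V[, 1L] > 0)
  rep_idx <- integer(nrow(V))
  kept <- which(keep)
  rep_idx[kept] <- seq_along(kept)
  Vk <- V[kept, , drop = FALSE]
  other <- which(!keep)
  # map each dropped vertex to its antipodal representative
  dots <- (-V[other, , drop = FALSE]) %*% t(Vk)
  rep_idx[other] <- max.col(dots)

  adj <- vector("list", length(kept))
  edges <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  e1 <- rep_idx[edges[, 1L]]
  e2 <- rep_idx[edges[, 2L]]
  ok <- e1 != e2
  e1 <- e1[ok]; e2 <- e2[ok]
  for (i in seq_along(kept)) adj[[i]] <- integer(0L)
  pair <- split(c(e2, e1), c(e1, e2))
  for (nm in names(pair)) adj[[as.integer(nm)]] <- sort(unique(pair[[nm]]))

  structure(list(vertices = Vk, adjacency = adj, n = nrow(Vk)),
            class = "sphere_tessellation")
}

#' @export
print.sphere_tessellation <- function(x, ...) {
  cat("<sphere_tessellation>", x$n, "hemisphere directions,",
      "mean degree", round(mean(lengths(x$adjacency)), 2), "\n")
  invisible(x)
}

#' Reconstruct the per-voxel spin-distribution function
#'
#' Model-free generalized q-sampling estimate: for every voxel v and unit
#' direction \eqn{\hat u},
#' \deqn{\psi_v(\hat u) = \sum_i S_{v,i}\,
#'   \mathrm{sinc}\!\left(\sigma \sqrt{6 D b_i}\, (\hat g_i \cdot \hat u)\right)}
#' with `sinc(t) = sin(t)/t`, `sinc(0) = 1`.  The kernel is even, so the
#' SDF is symmetric under direction reversal and the hemisphere
#' tessellation suffices.  b = 0 entries contribute a constant offset
#' (their kernel is 1 in every direction).
#'
#' @param dwi a [dwi_volume()].
#' @param spec a [gqi_spec()].
#' @param sphere a [tessellate_sphere()] result; defaults to the spec's
#'   tessellation level.
#' @return An object of class `"sdf_field"`: list with `psi` (nvox x
#'   ndirections matrix, voxels in column-major spatial order), `dims`
#'   (spatial dimensions), `sphere` and `spec`.
#' @export
reconstruct_sdf <- function(dwi, spec = gqi_spec(), sphere = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(spec, "gqi_spec"))
  if (n_gradients(dwi) < 1L)
    dwisr_stop("gradient table is empty", "usage")
  sphere <- sphere %||% tessellate_sphere(spec$tessellation_level)
  d <- dim(dwi$data)
  S <- matrix(dwi$data, nrow = prod(d[1:3]), ncol = d[4L])
  len <- spec$sampling_length_ratio * sqrt(6 * spec$diffusivity * dwi$bvals)
  # (ngrad x ndir) kernel matrix
  arg <- (t(dwi$bvecs) %*% t(sphere$vertices)) * len
  K <- ifelse(arg == 0, 1, sin(arg) / ifelse(arg == 0, 1, arg))
  structure(list(psi = S %*% K, dims = d[1:3], sphere = sphere,
                 spec = spec), class = "sdf_field")
}

#' Local maxima of one voxel's SDF
#'
#' A peak is a tessellation direction whose SDF value strictly exceeds the
#' values of all adjacent directions; peaks indicate fiber orientations.
#' A constant SDF has no peaks.
#'
#' @param psi numeric vector of SDF samples over the tessellation
#'   directions.
#' @param sphere the [tessellate_sphere()] the SDF was sampled on.
#' @return Data frame sorted by decreasing `value` with columns `index`,
#'   `value`, `x`, `y`, `z` (peak direction components).
#' @export
find_peaks <- function(psi, sphere) {
  stopifnot(inherits(sphere, "sphere_tessellation"))
  if (length(psi) != sphere$n)
    dwisr_stop("`psi` length does not match the tessellation", "shape")
  is_peak <- vapply(seq_len(sphere$n), function(i)
    all(psi[i] > psi[sphere$adjacency[[i]]]), TRUE)
  idx <- which(is_peak)
  idx <- idx[order(psi[idx], decreasing = TRUE)]
  data.frame(index = idx, value = psi[idx],
             x = sphere$vertices[idx, 1L],
             y = sphere$vertices[idx, 2L],
             z = sphere$vertices[idx, 3L])
}

# Vectorized top-peak value for every voxel: a direction is a peak where
# psi strictly exceeds the maximum over its neighbors.
top_peak_values <- function(psi, sphere) {
  nvox <- nrow(psi)
  best <- rep(-Inf, nvox)
  for (i in seq_len(sphere$n)) {
    nb <- sphere$adjacency[[i]]
    nbmax <- Reduce(pmax, lapply(nb, function(j) psi[, j]))
    cand <- psi[, i] > nbmax
    if (any(cand))
      best[cand] <- pmax(best[cand], psi[cand, i])
  }
  best
}

#' GFA, QA, NQA and ISO index maps from an SDF field
#'
#' Scalar summaries of each voxel's spin-distribution function:
#' \itemize{
#'   \item GFA (generalized fractional anisotropy): std/rms of the SDF,
#'     \eqn{\sqrt{n \sum (\psi - \bar\psi)^2} / \sqrt{(n-1) \sum \psi^2}},
#'     0 for a flat SDF and 1 for a one-hot SDF;
#'   \item ISO: the isotropic background, `min(psi)`, large in free-water
#'     regions such as the ventricles;
#'   \item QA (quantitative anisotropy): SDF value at the top peak minus
#'     ISO (0 where the SDF has no peak), the spin population diffusing
#'     along the dominant fiber orientation;
#'   \item NQA: QA divided by the maximum QA over the masked voxels, so
#'     the map is scaled to `[0, 1]` per subject.
#' }
#' Negative SDF samples (possible through the sinc kernel's side lobes)
#' are clamped to zero first, since the SDF estimates a nonnegative spin
#' density; this also bounds GFA by 1.
#'
#' @param sdf an [reconstruct_sdf()] result.
#' @param mask optional logical 3-D array; maps are zero outside it.
#' @return An object of class `"index_maps"`: list of 3-D arrays `gfa`,
#'   `qa`, `nqa`, `iso`.
#' @export
compute_index_maps <- function(sdf, mask = NULL) {
  stopifnot(inherits(sdf, "sdf_field"))
  psi <- pmax(sdf$psi, 0)
  nvox <- nrow(psi)
  n <- ncol(psi)
  mask_vec <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  if (length(mask_vec) != nvox)
    dwisr_stop("`mask` does not match the SDF grid", "shape")

  mu <- rowMeans(psi)
  ss <- rowSums(psi^2)
  num <- sqrt(n * pmax(ss - n * mu^2, 0))
  den <- sqrt((n - 1) * ss)
  gfa <- ifelse(den > 0, num / den, 0)
  iso <- Reduce(pmin, lapply(seq_len(n), function(j) psi[, j]))
  top <- top_peak_values(psi, sdf$sphere)
  qa <- ifelse(is.finite(top), pmax(top - iso, 0), 0)

  gfa[!mask_vec] <- 0; iso[!mask_vec] <- 0; qa[!mask_vec] <- 0
  if (all(ss[mask_vec] == 0))
    warning("SDF is zero everywhere in the mask; index maps are zero")
  qmax <- max(qa[mask_vec], 0)
  nqa <- if (qmax > 0) qa / qmax else qa * 0

  shape <- function(v) array(v, sdf$dims)
  structure(list(gfa = shape(gfa), qa = shape(qa), nqa = shape(nqa),
                 iso = shape(iso)), class = "index_maps")
}

#' @export
print.index_maps <- function(x, ...) {
  cat("<index_maps>", paste(dim(x$gfa), collapse = " x "), "voxels\n")
  for (nm in c("gfa", "qa", "nqa", "iso"))
    cat(sprintf("  %-4s range [%.4g, %.4g]\n", toupper(nm),
                min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Write index maps as NIfTI files
#'
#' @param maps an [compute_index_maps()] result.
#' @param prefix output path prefix; files `<prefix>gfa.nii.gz` etc. are
#'   written.
#' @param voxel_size voxel edges in mm for the NIfTI headers.
#' @return Invisibly, the vector of written paths.
#' @export
write_index_maps <- function(maps, prefix, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(maps, "index_maps"))
  paths <- character(0)
  for (nm in c("gfa", "qa", "nqa", "iso")) {
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- c(voxel_size, 1)
    p <- paste0(prefix, nm, ".nii.gz")
    RNifti::writeNifti(img, p, datatype = "float")
    paths <- c(paths, p)
  }
  invisible(paths)
}
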