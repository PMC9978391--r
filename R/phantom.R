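#' Axially symmetric diffusion tensor compartment
#'
#' One fiber population inside a voxel, modelled as a cylindrically
#' symmetric Gaussian diffusion tensor: diffusivity `axial` along the
#' fiber axis and `radial` perpendicular to it.
#'
#' @param direction length-3 vector giving the fiber axis (normalized).
#' @param axial axial diffusivity in mm^2/s; must satisfy
#'   `axial >= radial > 0`.
#' @param radial radial diffusivity in mm^2/s.
#' @param fraction volume fraction in `[0, 1]`.
#' @return An object of class `"tensor_compartment"`.
#' @examples
#' tensor_compartment(c(1, 0, 0), axial = 1.7e-3, radial = 0.3e-3)
#' @export
tensor_compartment <- function(direction, axial = 1.7e-3, radial = 0.3e-3,
                               fraction = 1) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L || !all(is.finite(direction)) ||
      sum(direction^2) == 0)
    dwisr_stop("`direction` must be a nonzero 3-vector", "domain")
  direction <- direction / sqrt(sum(direction^2))
  stopifnot_scalar_number(axial, "axial", positive = TRUE)
  stopifnot_scalar_number(radial, "radial", positive = TRUE)
  if (axial < radial)
    dwisr_stop("`axial` diffusivity must be >= `radial`", "domain")
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction < 0 || fraction > 1)
    dwisr_stop("`fraction` must lie in [0, 1]", "domain")
  structure(list(direction = direction, axial = axial, radial = radial,
                 fraction = fraction), class = "tensor_compartment")
}

check_compartments <- function(compartments) {
  if (inherits(compartments, "tensor_compartment"))
    compartments <- list(compartments)
  if (!length(compartments) ||
      !all(vapply(compartments, inherits, TRUE, "tensor_compartment")))
    dwisr_stop("`compartments` must be tensor_compartment objects", "domain")
  f <- sum(vapply(compartments, `[[`, 0, "fraction"))
  if (abs(f - 1) > 1e-9)
    dwisr_stop(sprintf("volume fractions must sum to 1 (got %.12f)", f),
               "domain")
  compartments
}

#' Noise-free multi-tensor DWI signal for one voxel
#'
#' Evaluates the standard multi-tensor forward model
#' \deqn{S = S_0 \sum_k f_k \exp(-b\, \hat g^T D_k \hat g)}
#' with each \eqn{D_k} the axially symmetric tensor of compartment k, so
#' the exponent reduces to
#' \eqn{b\,[\lambda_r + (\lambda_a - \lambda_r)(\hat g \cdot \mu_k)^2]}.
#'
#' @param compartments a `tensor_compartment` or list of them; volume
#'   fractions must sum to 1.
#' @param s0 baseline (b = 0) intensity.
#' @param bval b-value in s/mm^2 (scalar or vector).
#' @param bvec unit gradient direction(s): length-3 vector or 3 x n matrix;
#'   the zero vector is accepted for b = 0 entries.
#' @return Numeric vector of signal intensities, one per gradient.
#' @examples
#' fib <- tensor_compartment(c(1, 0, 0))
#' simulate_voxel_signal(fib, s0 = 1, bval = 1000, bvec = c(1, 0, 0))
#' @export
simulate_voxel_signal <- function(compartments, s0, bval, bvec) {
  compartments <- check_compartments(compartments)
  bval <- as.numeric(bval)
  if (any(!is.finite(bval)) || any(bval < 0))
    dwisr_stop("b-values must be nonnegative", "domain")
  bvec <- if (is.matrix(bvec)) bvec else matrix(as.numeric(bvec), nrow = 3L)
  if (nrow(bvec) != 3L || ncol(bvec) != length(bval))
    dwisr_stop("`bvec` must supply one 3-vector per b-value", "domain")
  sig <- numeric(length(bval))
  for (cm in compartments) {
    dot2 <- as.numeric(crossprod(cm$direction, bvec))^2
    adc <- cm$radial + (cm$axial - cm$radial) * dot2
    sig <- sig + cm$fraction * exp(-bval * adc)
  }
  s0 * sig
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude-MRI noise model: each voxel value s becomes
#' \eqn{\sqrt{(s + n_1)^2 + n_2^2}} with independent zero-mean Gaussian
#' \eqn{n_1, n_2} of standard deviation `sigma`.  Output is nonnegative and
#' deterministic for a given seed; the caller's RNG state is untouched.
#'
#' @param signal numeric array of noise-free intensities.
#' @param sigma Rician scale (Gaussian SD); `sigma = 0` returns the input.
#' @param seed integer RNG seed.
#' @return Array of the same shape with Rician-distributed magnitudes.
#' @export
add_rician_noise <- function(signal, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    dwisr_stop("`sigma` must be a single nonnegative number", "domain")
  if (sigma == 0) return(signal)
  n <- length(signal)
  noisy <- with_seed(seed, {
    n1 <- rnorm(n, sd = sigma)
    n2 <- rnorm(n, sd = sigma)
    sqrt((as.numeric(signal) + n1)^2 + n2^2)
  })
  if (is.array(signal)) dim(noisy) <- dim(signal)
  noisy
}

#' Icosahedral gradient table
#'
#' Multi-shell gradient scheme used by the default phantom: the six
#' antipodally unique vertices of the icosahedron repeated on each
#' requested shell, preceded by `n_b0` unweighted entries.  With the
#' default three shells this yields 19 entries.
#'
#' @param shells b-values (s/mm^2) of the diffusion-weighted shells.
#' @param n_b0 number of b = 0 entries.
#' @return List with `bvals` (vector) and `bvecs` (3 x n matrix).
#' @export
icosahedral_gradients <- function(shells = c(1000, 1500, 2000), n_b0 = 1L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(1, phi, 0), c(-1, phi, 0),
             c(0, 1, phi), c(0, -1, phi),
             c(phi, 0, 1), c(phi, 0, -1))
  v <- v / sqrt(rowSums(v^2))
  bvals <- c(rep(0, n_b0), rep(shells, each = nrow(v)))
  bvecs <- cbind(matrix(0, 3L, n_b0),
                 t(v)[, rep(seq_len(nrow(v)), times = length(shells))])
  list(bvals = bvals, bvecs = bvecs)
}

#' Dense multi-shell gradient table from a sphere tessellation
#'
#' Gradient scheme using the hemisphere directions of a subdivided
#' icosahedron on every shell (level 1 gives 21 directions per shell).
#' Crossing-fiber geometry is only resolvable with reasonably dense
#' q-space sampling, so use this scheme (rather than the 6-direction
#' [icosahedral_gradients()]) when the phantom feeds GQI reconstruction.
#'
#' @param level icosahedron subdivision level passed to
#'   [tessellate_sphere()].
#' @param shells b-values (s/mm^2) of the diffusion-weighted shells.
#' @param n_b0 number of b = 0 entries.
#' @return List with `bvals` and `bvecs` as in [icosahedral_gradients()].
#' @export
tessellated_gradients <- function(level = 1L, shells = c(1000, 1500, 2000),
                                  n_b0 = 1L) {
  dirs <- t(tessellate_sphere(level)$vertices)
  nd <- ncol(dirs)
  list(bvals = c(rep(0, n_b0), rep(shells, each = nd)),
       bvecs = cbind(matrix(0, 3L, n_b0),
                     dirs[, rep(seq_len(nd), times = length(shells))]))
}

#' Specification of a synthetic multi-shell DWI phantom
#'
#' Describes a digital phantom with known fiber geometry: anisotropic
#' bundles (including a crossing region), an isotropic CSF-like region, a
#' zero background, and Rician noise.  Region masks are predicates over
#' voxel-center coordinates normalized to `[0, 1]^3`; overlaps resolve by
#' priority CSF > bundles in listed order > background, so a crossing
#' region is expressed as its own bundle definition (listed first) holding
#' two compartments.
#'
#' The default geometry is two orthogonal straight bundles (along x and y)
#' crossing at the volume center of a lower axial slab, plus an ellipsoidal
#' CSF region in the upper slab so that the fiber and free-water
#' compartments occupy disjoint voxels.
#'
#' @param grid_shape three positive integers, each divisible by 3 (so the
#'   factor-3 degrade/restore cycle is exact).
#' @param voxel_size voxel edges in mm.
#' @param gradients list with `bvals`/`bvecs` as from
#'   [icosahedral_gradients()].
#' @param s0 baseline intensity (arbitrary scanner units).
#' @param bundles list of bundle definitions, each a list with elements
#'   `name`, `mask` (function of normalized x, y, z returning logical) and
#'   `compartments` (list of [tensor_compartment()]).
#' @param csf list with elements `mask` and `diffusivity` (mm^2/s) for the
#'   isotropic free-water region.
#' @param noise_sigma Rician scale, >= 0; default 2% of `s0`.
#' @param seed integer RNG seed for the noise draw.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 12L),
                         voxel_size = c(2, 2, 2),
                         gradients = icosahedral_gradients(),
                         s0 = 100,
                         bundles = default_bundles(),
                         csf = default_csf(),
                         noise_sigma = 0.02 * s0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    dwisr_stop("`grid_shape` must be 3 positive integers", "config")
  if (any(grid_shape %% 3L != 0L))
    dwisr_stop("each grid dimension must be divisible by 3", "config")
  stopifnot_scalar_number(s0, "s0", positive = TRUE)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    dwisr_stop("`noise_sigma` must be >= 0", "domain")
  for (b in bundles) check_compartments(b$compartments)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 bvals = gradients$bvals, bvecs = gradients$bvecs,
                 s0 = s0, bundles = bundles, csf = csf,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param axial,radial fiber diffusivities in mm^2/s (adult white-matter
#'   literature values by default).
#' @export
default_bundles <- function(axial = 1.7e-3, radial = 0.3e-3) {
  in_x_slab <- function(x, y, z) abs(y - 0.5) <= 0.15 & abs(z - 1/3) <= 0.15
  in_y_slab <- function(x, y, z) abs(x - 0.5) <= 0.15 & abs(z - 1/3) <= 0.15
  fx <- tensor_compartment(c(1, 0, 0), axial, radial, fraction = 1)
  fy <- tensor_compartment(c(0, 1, 0), axial, radial, fraction = 1)
  fx2 <- tensor_compartment(c(1, 0, 0), axial, radial, fraction = 0.5)
  fy2 <- tensor_compartment(c(0, 1, 0), axial, radial, fraction = 0.5)
  list(
    list(name = "crossing",
         mask = function(x, y, z) in_x_slab(x, y, z) & in_y_slab(x, y, z),
         compartments = list(fx2, fy2)),
    list(name = "bundle_x", mask = in_x_slab, compartments = list(fx)),
    list(name = "bundle_y", mask = in_y_slab, compartments = list(fy)))
}

#' @rdname phantom_spec
#' @param diffusivity isotropic free-water diffusivity in mm^2/s.
#' @param s0_scale baseline-intensity multiplier of the CSF region relative
#'   to `s0`.  Diffusion acquisitions are heavily T2-weighted (echo times
#'   around 100 ms), which makes long-T2 free water several times brighter
#'   than white matter at b = 0; 4 approximates the ratio
#'   exp(-TE/T2_CSF) / exp(-TE/T2_WM) at TE = 115 ms.
#' @export
default_csf <- function(diffusivity = 3.0e-3, s0_scale = 4) {
  list(name = "csf",
       mask = function(x, y, z)
         ((x - 0.5) / 0.22)^2 + ((y - 0.5) / 0.22)^2 +
           ((z - 0.78) / 0.16)^2 <= 1,
       diffusivity = diffusivity,
       s0_scale = s0_scale)
}

#' Generate a synthetic DWI phantom volume
#'
#' Evaluates the multi-tensor forward model over the phantom geometry and
#' applies Rician noise.  Voxels in a bundle region use its compartments,
#' the CSF region uses a single isotropic compartment, and the background
#' is zero before noise.  Identical specs (including seed) give
#' bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A [dwi_volume()].  The region label of every voxel is attached
#'   as `attr(vol, "regions")`, a named list of logical 3-D masks
#'   (`csf`, one per bundle, plus `fiber` = union of bundles and
#'   `background`), and the generating spec as `attr(vol, "phantom_spec")`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  nvox <- prod(d)
  cx <- (seq_len(d[1]) - 0.5) / d[1]
  cy <- (seq_len(d[2]) - 0.5) / d[2]
  cz <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  ngrad <- length(spec$bvals)
  sig <- matrix(0, nvox, ngrad)
  masks <- list()

  # lowest priority first; later (higher-priority) writes win
  region_id <- integer(nvox)
  defs <- list()
  for (i in rev(seq_along(spec$bundles))) {
    b <- spec$bundles[[i]]
    defs[[length(defs) + 1L]] <- list(
      name = b$name %||% paste0("bundle_", i),
      mask = b$mask(X, Y, Z),
      compartments = b$compartments)
  }
  iso <- tensor_compartment(c(0, 0, 1), spec$csf$diffusivity,
                            spec$csf$diffusivity, fraction = 1)
  defs[[length(defs) + 1L]] <- list(name = spec$csf$name %||% "csf",
                                    mask = spec$csf$mask(X, Y, Z),
                                    compartments = list(iso),
                                    s0_scale = spec$csf$s0_scale %||% 1)
  for (i in seq_along(defs)) region_id[defs[[i]]$mask] <- i

  for (i in seq_along(defs)) {
    vox <- region_id == i
    if (!any(vox)) next
    profile <- simulate_voxel_signal(defs[[i]]$compartments,
                                     spec$s0 * (defs[[i]]$s0_scale %||% 1),
                                     spec$bvals, spec$bvecs)
    sig[vox, ] <- rep(profile, each = sum(vox))
    masks[[defs[[i]]$name]] <- array(vox, d)
  }
  masks$background <- array(region_id == 0L, d)
  bundle_names <- setdiff(names(masks), c("csf", "background"))
  masks$fiber <- if (length(bundle_names))
    array(Reduce(`|`, masks[bundle_names]), d) else array(FALSE, d)

  data <- array(sig, c(d, ngrad))
  data <- add_rician_noise(data, spec$noise_sigma, spec$seed)
  vol <- dwi_volume(data, bvals = spec$bvals, bvecs = spec$bvecs,
                    voxel_size = spec$voxel_size)
  attr(vol, "regions") <- masks
  attr(vol, "phantom_spec") <- spec
  vol
}
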