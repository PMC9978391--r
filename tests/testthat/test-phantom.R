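test_that("multi-tensor voxel signal matches closed forms", {
  fib <- tensor_compartment(c(1, 0, 0), axial = 1.7e-3, radial = 0.3e-3)
  # b = 0 returns s0 regardless of compartments
  expect_equal(simulate_voxel_signal(fib, 100, 0, c(0, 0, 0)), 100)
  # single compartment along x, gradient along x: s0 * exp(-b * axial)
  expect_equal(simulate_voxel_signal(fib, 1, 1000, c(1, 0, 0)), exp(-1.7))
  # gradient perpendicular: s0 * exp(-b * radial)
  expect_equal(simulate_voxel_signal(fib, 1, 1000, c(0, 0, 1)), exp(-0.3))
  # equal-fraction mixture is the mean of the single-compartment signals
  a <- tensor_compartment(c(1, 0, 0), fraction = 0.5)
  b <- tensor_compartment(c(0, 1, 0), fraction = 0.5)
  g <- c(1, 2, 3) / sqrt(14)
  mix <- simulate_voxel_signal(list(a, b), 50, 1500, g)
  s1 <- simulate_voxel_signal(tensor_compartment(c(1, 0, 0)), 50, 1500, g)
  s2 <- simulate_voxel_signal(tensor_compartment(c(0, 1, 0)), 50, 1500, g)
  expect_equal(mix, (s1 + s2) / 2)
})

test_that("compartment validation enforces the tensor model's constraints", {
  expect_error(tensor_compartment(c(1, 0, 0), axial = 1e-3, radial = 2e-3),
               class = "dwisr_domain_error")
  expect_error(simulate_voxel_signal(tensor_compartment(c(1, 0, 0)), 1,
                                     -100, c(1, 0, 0)),
               class = "dwisr_domain_error")
  # fractions must sum to 1
  bad <- list(tensor_compartment(c(1, 0, 0), fraction = 0.5),
              tensor_compartment(c(0, 1, 0), fraction = 0.4))
  expect_error(simulate_voxel_signal(bad, 1, 0, c(0, 0, 0)),
               class = "dwisr_domain_error")
})

test_that("Rician noise is nonnegative, seeded, and has the analytic mean", {
  s <- array(100, c(40, 50, 50))
  expect_identical(add_rician_noise(s, 0, 1), s)
  n1 <- add_rician_noise(s, 5, 42)
  n2 <- add_rician_noise(s, 5, 42)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
  expect_false(identical(n1, add_rician_noise(s, 5, 43)))
  expect_error(add_rician_noise(s, -1), class = "dwisr_domain_error")
  # high-SNR Rician mean: E approx s + sigma^2/(2 s) = 100.005 at sigma = 1
  draws <- add_rician_noise(array(100, c(100, 100, 10)), 1, 7)
  expect_lt(abs(mean(draws) - 100.005), 0.05)
})

test_that("phantom generation is deterministic and shaped by its gradient table", {
  spec <- tiny_phantom(seed = 7, noise_sigma = 2)
  v1 <- generate_phantom(spec)
  v2 <- generate_phantom(spec)
  expect_identical(v1$data, v2$data)
  expect_equal(dim(v1$data)[4], length(spec$bvals))
  expect_error(phantom_spec(grid_shape = c(10, 9, 9)),
               class = "dwisr_config_error")
})

test_that("noiseless phantom signals are positive, bounded by s0, monotone in b", {
  vol <- generate_phantom(tiny_phantom())
  regions <- attr(vol, "regions")
  tissue <- regions$fiber | regions$csf
  sig <- matrix(vol$data, ncol = n_gradients(vol))[tissue, ]
  expect_true(all(sig > 0))
  # fiber voxels never exceed s0; CSF never exceeds its T2-scaled baseline
  fib_sig <- matrix(vol$data, ncol = n_gradients(vol))[regions$fiber, ]
  expect_true(all(fib_sig <= 100 + 1e-12))
  expect_true(all(sig <= 4 * 100 + 1e-12))
  # decay is monotone in b for a fixed direction
  g <- icosahedral_gradients()
  dir1 <- g$bvecs[, 2]  # first diffusion direction, present on all shells
  idx <- which(vapply(seq_along(g$bvals), function(i)
    g$bvals[i] > 0 && all(abs(g$bvecs[, i] - dir1) < 1e-12), TRUE))
  bs <- g$bvals[idx]
  expect_true(all(diff(bs) > 0))
  for (v in sample(which(tissue), 5))
    expect_true(all(diff(sig[which(tissue) == v, idx][order(bs)]) < 0))
})

test_that("parallel signal is weaker than perpendicular in a single bundle", {
  fib <- tensor_compartment(c(1, 0, 0))
  par_sig <- simulate_voxel_signal(fib, 100, 1000, c(1, 0, 0))
  perp_sig <- simulate_voxel_signal(fib, 100, 1000, c(0, 1, 0))
  expect_lt(par_sig, perp_sig)
})

test_that("crossing voxels attenuate within the crossing plane", {
  cross <- list(tensor_compartment(c(1, 0, 0), fraction = 0.5),
                tensor_compartment(c(0, 1, 0), fraction = 0.5))
  dirs <- tessellate_sphere(2)$vertices   # dense direction grid
  sig <- simulate_voxel_signal(cross, 1, rep(2000, nrow(dirs)), t(dirs))
  s_at <- function(u) simulate_voxel_signal(cross, 1, 2000, u)
  # both bundle axes attenuate more than the common perpendicular ...
  expect_lt(s_at(c(1, 0, 0)), s_at(c(0, 0, 1)))
  expect_lt(s_at(c(0, 1, 0)), s_at(c(0, 0, 1)))
  # ... and the signal maximum over the sphere is perpendicular to the plane
  expect_lt(angle_deg(dirs[which.max(sig), ], c(0, 0, 1)), 5)
  # the global minimum lies in the crossing plane (both tensors attenuate)
  expect_lt(abs(dirs[which.min(sig), 3]), 0.3)
})
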