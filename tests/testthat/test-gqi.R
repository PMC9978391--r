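sph3 <- tessellate_sphere(3)

test_that("the tessellated hemisphere has the expected structure", {
  sph1 <- tessellate_sphere(1)
  expect_equal(sph1$n, 21L)   # 42-vertex icosphere, one per antipodal pair
  expect_equal(sph3$n, 321L)  # 642-vertex icosphere
  for (sph in list(sph1, sph3)) {
    expect_equal(sqrt(rowSums(sph$vertices^2)), rep(1, sph$n),
                 tolerance = 1e-12)
    # no identical or antipodal duplicates
    d <- abs(sph$vertices %*% t(sph$vertices))
    diag(d) <- 0
    expect_lt(max(d), 1 - 1e-9)
    # adjacency is symmetric and non-empty
    for (i in seq_len(sph$n)) {
      expect_gt(length(sph$adjacency[[i]]), 0)
      for (j in sph$adjacency[[i]])
        expect_true(i %in% sph$adjacency[[j]])
    }
  }
})

test_that("b = 0 only data give a direction-independent SDF", {
  vol <- dwi_volume(array(7, c(2, 2, 2, 3)), bvals = c(0, 0, 0),
                    bvecs = matrix(0, 3, 3))
  sdf <- reconstruct_sdf(vol, gqi_spec(), sph3)
  # sinc(0) = 1 for every entry: psi is the plain signal sum everywhere
  expect_equal(sdf$psi, matrix(21, 8, sph3$n))
})

test_that("an isotropic voxel yields a nearly flat SDF", {
  g <- tessellated_gradients(level = 1)
  iso <- tensor_compartment(c(0, 0, 1), 3e-3, 3e-3)
  sdf <- reconstruct_sdf(voxel_volume(iso, g), gqi_spec(), sph3)
  psi <- sdf$psi[1, ]
  expect_lt((max(psi) - min(psi)) / mean(psi), 0.05)
})

test_that("single-fiber and crossing-fiber peaks recover the true directions", {
  g <- tessellated_gradients(level = 1)
  # single fiber, deliberately off-axis
  u <- c(2, 1, 0.5) / sqrt(5.25)
  sdf <- reconstruct_sdf(voxel_volume(tensor_compartment(u), g),
                         gqi_spec(), sph3)
  pk <- find_peaks(sdf$psi[1, ], sph3)
  expect_gt(nrow(pk), 0)
  expect_lt(angle_deg(unlist(pk[1, c("x", "y", "z")]), u), 5)
  # 90-degree crossing along x and y
  cross <- list(tensor_compartment(c(1, 0, 0), fraction = 0.5),
                tensor_compartment(c(0, 1, 0), fraction = 0.5))
  sdf2 <- reconstruct_sdf(voxel_volume(cross, g), gqi_spec(), sph3)
  pk2 <- find_peaks(sdf2$psi[1, ], sph3)
  expect_gte(nrow(pk2), 2)
  lead <- as.matrix(pk2[1:2, c("x", "y", "z")])
  ax <- apply(lead, 1, angle_deg, v = c(1, 0, 0))
  ay <- apply(lead, 1, angle_deg, v = c(0, 1, 0))
  expect_lt(min(ax), 10); expect_lt(min(ay), 10)
  expect_gt(max(ax), 45)  # the two peaks are distinct directions
})

test_that("peak finding handles flat and single-maximum profiles", {
  flat <- rep(2, sph3$n)
  expect_equal(nrow(find_peaks(flat, sph3)), 0L)
  onehot <- rep(0, sph3$n); onehot[17] <- 1
  pk <- find_peaks(onehot, sph3)
  expect_equal(pk$index[1], 17L)
})

test_that("index maps take their analytic values on degenerate SDFs", {
  mk_sdf <- function(psi_matrix, dims) structure(
    list(psi = psi_matrix, dims = dims, sphere = sph3, spec = gqi_spec()),
    class = "sdf_field")
  n <- sph3$n
  # constant SDF: GFA 0, ISO c, QA 0
  sdf_c <- mk_sdf(matrix(3, 1, n), c(1, 1, 1))
  maps <- compute_index_maps(sdf_c)
  expect_equal(as.numeric(maps$gfa), 0)
  expect_equal(as.numeric(maps$iso), 3)
  expect_equal(as.numeric(maps$qa), 0)
  # one-hot SDF: GFA exactly 1
  psi1 <- matrix(0, 1, n); psi1[1, 42] <- 5
  maps1 <- compute_index_maps(mk_sdf(psi1, c(1, 1, 1)))
  expect_equal(as.numeric(maps1$gfa), 1)
  expect_equal(as.numeric(maps1$qa), 5)   # top peak minus zero ISO
  expect_equal(as.numeric(maps1$nqa), 1)  # self-normalization
  # all-zero SDF warns and yields zero maps
  expect_warning(maps0 <- compute_index_maps(mk_sdf(matrix(0, 2, n),
                                                    c(2, 1, 1))))
  expect_true(all(maps0$gfa == 0 & maps0$iso == 0))
})

test_that("SDF linearity: GFA/NQA scale-invariant, ISO/QA linear in the signal", {
  g <- tessellated_gradients(level = 1)
  fib <- tensor_compartment(c(0, 1, 1))
  v1 <- voxel_volume(fib, g, s0 = 100)
  v2 <- voxel_volume(fib, g, s0 = 300)
  s1 <- reconstruct_sdf(v1, gqi_spec(), sph3)
  s2 <- reconstruct_sdf(v2, gqi_spec(), sph3)
  expect_equal(s2$psi, 3 * s1$psi, tolerance = 1e-12)
  m1 <- compute_index_maps(s1); m2 <- compute_index_maps(s2)
  expect_equal(m2$gfa, m1$gfa, tolerance = 1e-12)
  expect_equal(m2$nqa, m1$nqa, tolerance = 1e-12)
  expect_equal(m2$iso, 3 * m1$iso, tolerance = 1e-12)
  expect_equal(m2$qa, 3 * m1$qa, tolerance = 1e-12)
})

test_that("phantom index maps separate fiber from free water", {
  spec <- tiny_phantom(grid = c(12, 12, 6),
                       gradients = tessellated_gradients(level = 1),
                       noise_sigma = 0)
  vol <- generate_phantom(spec)
  regions <- attr(vol, "regions")
  maps <- compute_index_maps(reconstruct_sdf(vol, gqi_spec(), sph3))
  expect_gt(mean(maps$gfa[regions$fiber]), mean(maps$gfa[regions$csf]))
  expect_gt(mean(maps$iso[regions$csf]), mean(maps$iso[regions$fiber]))
  expect_true(all(maps$gfa >= 0 & maps$gfa <= 1))
  expect_true(all(maps$nqa >= 0 & maps$nqa <= 1))
  expect_true(all(maps$iso >= 0) && all(maps$qa >= 0))
})

test_that("index maps can be written as NIfTI", {
  n <- sph3$n
  psi <- matrix(runif(8 * n), 8, n)
  sdf <- structure(list(psi = psi, dims = c(2, 2, 2), sphere = sph3,
                        spec = gqi_spec()), class = "sdf_field")
  maps <- compute_index_maps(sdf)
  td <- withr::local_tempdir()
  paths <- write_index_maps(maps, file.path(td, "sub1_"), c(1.1, 1.1, 1.3))
  expect_true(all(file.exists(paths)))
  gfa_back <- RNifti::readNifti(paths[1])
  expect_equal(array(as.numeric(gfa_back), c(2, 2, 2)), maps$gfa,
               tolerance = 1e-6)
})
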