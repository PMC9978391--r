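# Small deterministic fixtures shared across test files.

rand_grid <- function(d, seed = 1) {
  set.seed(seed)
  array(runif(prod(d)), d)
}

# tiny architecture so unit tests stay fast; same code paths as default
tiny_spec <- function(seed = 1, init_scale = 0.05) {
  srcnn_spec(kernel_edges = c(3, 3, 3), channels = c(3, 2, 1),
             init_scale = init_scale, seed = seed)
}

tiny_phantom <- function(seed = 1, grid = c(9, 9, 6),
                         gradients = icosahedral_gradients(),
                         noise_sigma = 0) {
  phantom_spec(grid_shape = grid, gradients = gradients,
               noise_sigma = noise_sigma, seed = seed)
}

# single-voxel DWI volume from explicit compartments, for GQI tests
voxel_volume <- function(compartments, gradients, s0 = 100) {
  sig <- simulate_voxel_signal(compartments, s0, gradients$bvals,
                               gradients$bvecs)
  dwi_volume(array(sig, c(1, 1, 1, length(sig))), gradients$bvals,
             gradients$bvecs)
}

angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

# independent nested-loop "same"-padding cross-correlation oracle
conv3d_oracle <- function(channels_in, W, b) {
  k <- dim(W)[1]; cc <- (k - 1) / 2; d <- dim(channels_in[[1]])
  lapply(seq_len(dim(W)[5]), function(co) {
    out <- array(b[co], d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      s <- 0
      for (ci in seq_along(channels_in))
        for (dx in 1:k) for (dy in 1:k) for (dz in 1:k) {
          xi <- x + dx - 1 - cc; yi <- y + dy - 1 - cc; zi <- z + dz - 1 - cc
          if (xi >= 1 && xi <= d[1] && yi >= 1 && yi <= d[2] &&
              zi >= 1 && zi <= d[3])
            s <- s + W[dx, dy, dz, ci, co] * channels_in[[ci]][xi, yi, zi]
        }
      out[x, y, z] <- out[x, y, z] + s
    }
    out
  })
}

srcnn_oracle <- function(model, x) {
  relu <- function(l) lapply(l, pmax, 0)
  w <- model$spec$residual_weight
  a1 <- relu(conv3d_oracle(list(x), model$weights[[1]]$W,
                           model$weights[[1]]$b))
  a2 <- relu(conv3d_oracle(a1, model$weights[[2]]$W, model$weights[[2]]$b))
  a3 <- conv3d_oracle(a2, model$weights[[3]]$W, model$weights[[3]]$b)
  (1 - w) * x + w * a3[[1]]
}
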