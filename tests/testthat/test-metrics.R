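# independent single-pass oracles, coded directly from the definitions
mse_oracle <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}
ssim_oracle <- function(x, y, C1, C2, C3) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  vx <- sum((x - mx)^2) / length(x); vy <- sum((y - my)^2) / length(y)
  sxy <- sum((x - mx) * (y - my)) / length(x)
  ((2 * mx * my + C1) / (mx^2 + my^2 + C1)) *
    ((2 * sqrt(vx) * sqrt(vy) + C2) / (vx + vy + C2)) *
    ((sxy + C3) / (sqrt(vx) * sqrt(vy) + C3))
}

test_that("mse, psnr, ssim and cosine match brute-force oracles on random pairs", {
  set.seed(314)
  p8 <- ssim_params(bit_depth = 8)
  for (i in 1:20) {
    x <- rand_grid(c(8, 8, 8), seed = i) * 255
    y <- rand_grid(c(8, 8, 8), seed = 1000 + i) * 255
    m <- mse_oracle(as.numeric(x), as.numeric(y))
    expect_equal(mse(x, y), m, tolerance = 1e-12)
    expect_equal(psnr(x, y, imax = 255), 10 * log10(255^2 / m),
                 tolerance = 1e-12)
    expect_equal(ssim(x, y, p8),
                 ssim_oracle(x, y, 6.5025, 58.5225, 29.26125),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(x, y),
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
  }
})

test_that("identity and degenerate cases take their exact values", {
  x <- rand_grid(c(6, 6, 6)) * 50
  expect_identical(mse(x, x), 0)
  expect_identical(psnr(x, x), Inf)
  expect_equal(ssim(x, x), 1)
  expect_equal(cosine_similarity(x, x), 1)
  z <- array(0, c(4, 4, 4))
  expect_equal(ssim(z, z), 1)  # all factors collapse to C/C
  expect_warning(cz <- cosine_similarity(z, z))
  expect_equal(cz, 1)
  # disjoint support is orthogonal
  a <- z; a[1:8] <- 1
  b <- z; b[9:16] <- 1
  expect_equal(cosine_similarity(a, b), 0)
  # scale invariance of cosine
  expect_equal(cosine_similarity(x, 2 * x), 1)
  expect_error(mse(x, rand_grid(c(5, 5, 5))), class = "dwisr_shape_error")
})

test_that("psnr evaluates the dB formula and validates its dynamic range", {
  x <- array(0, c(3, 3, 3))
  # MSE = Imax^2 gives exactly 0 dB
  expect_equal(psnr(x, x + 7, imax = 7), 0)
  # Imax = 1, MSE = 0.5 -> 10 log10(2)
  a <- array(c(0, 1), c(2, 1, 1)); b <- array(0, c(2, 1, 1))
  expect_equal(psnr(a, b, imax = 1), 10 * log10(2), tolerance = 1e-12)
  expect_error(psnr(x, x + 1, imax = 0), class = "dwisr_domain_error")
})

test_that("ssim is symmetric, psnr is not, and ssim is scale-invariant with L", {
  x <- rand_grid(c(7, 7, 7), 21) * 10
  y <- rand_grid(c(7, 7, 7), 22) * 90 + 5
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
  expect_false(isTRUE(all.equal(psnr(x, y), psnr(y, x))))
  # rescaling both images and the dynamic range together leaves SSIM fixed
  s1 <- ssim(x, y, ssim_params(bit_depth = log2(max(x, y) + 1)))
  s2 <- ssim(3 * x, 3 * y, ssim_params(bit_depth = log2(3 * max(x, y) + 1)))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("intensity histograms conserve counts with half-open bins", {
  x <- rand_grid(c(9, 9, 9), 4)
  h <- intensity_histogram(x, bins = 16, range = c(0, 1))
  expect_equal(sum(h), length(x))
  # constant grid: one non-zero bin
  hc <- intensity_histogram(array(5, c(3, 3, 3)), bins = 8, range = c(0, 10))
  expect_equal(sum(hc > 0), 1L)
  # half-open [lo, hi) bins, last closed: 0.5 falls in the upper bin
  hb <- intensity_histogram(array(c(0, 0.5, 1), c(3, 1, 1)), bins = 2,
                            range = c(0, 1))
  expect_equal(as.integer(hb), c(1L, 2L))
  expect_error(intensity_histogram(x, bins = 4, range = c(1, 0)),
               class = "dwisr_usage_error")
})

test_that("summaries report Average/Std/Max/Min and drop infinite PSNR", {
  x <- rand_grid(c(5, 5, 5), 1); y <- rand_grid(c(5, 5, 5), 2)
  reps <- list(metric_report(x, y), metric_report(y, x),
               metric_report(x, x))
  expect_warning(s <- summarize_metrics(reps))
  expect_equal(rownames(s), c("Average", "Std", "Max", "Min"))
  finite_psnr <- c(psnr(x, y), psnr(y, x))
  expect_equal(s["Average", "psnr"], mean(finite_psnr))
  expect_equal(s["Max", "ssim"], 1)
  expect_true(all(s["Min", ] <= s["Average", ] & s["Average", ] <= s["Max", ]))
})

test_that("product scores normalize PSNR by the best checkpoint average", {
  m <- data.frame(psnr = c(20, 40), ssim = c(1, 1), cosine = c(1, 1))
  expect_equal(product_score(m), c(0.5, 1.0))
  # single checkpoint: score = 1 * ssim * cosine
  expect_equal(product_score(data.frame(psnr = 33, ssim = 0.9,
                                        cosine = 0.8)), 0.72)
  # best checkpoint's PSNR factor is exactly 1
  m2 <- data.frame(psnr = c(31, 35, 33), ssim = c(0.9, 0.92, 0.91),
                   cosine = c(0.99, 0.98, 0.97))
  expect_equal(product_score(m2)[2], 0.92 * 0.98)
  expect_error(product_score(data.frame(psnr = Inf, ssim = 1, cosine = 1)),
               class = "dwisr_usage_error")
})

test_that("checkpoint selection takes the argmax and breaks ties earlier", {
  m <- data.frame(checkpoint = c(5000, 10000, 15000),
                  psnr = c(30, 31, 30.5), ssim = c(0.90, 0.95, 0.93),
                  cosine = c(1, 1, 1))
  expect_equal(as.numeric(select_best_checkpoint(m)), 10000)
  tie <- data.frame(checkpoint = c(1, 2), psnr = c(30, 30),
                    ssim = c(0.9, 0.9), cosine = c(1, 1))
  expect_equal(as.numeric(select_best_checkpoint(tie)), 1)
  single <- data.frame(checkpoint = 7, psnr = 25, ssim = 0.8, cosine = 0.9)
  expect_equal(as.numeric(select_best_checkpoint(single)), 7)
  expect_error(select_best_checkpoint(data.frame()),
               class = "dwisr_usage_error")
})
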