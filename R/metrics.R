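#' Mean squared error between two grids
#'
#' @param x,y numeric arrays of identical dimensions.
#' @return Mean of squared voxel differences.
#' @export
mse <- function(x, y) {
  check_same_dims(x, y)
  mean((as.numeric(x) - as.numeric(y))^2)
}

check_same_dims <- function(x, y) {
  dx <- dim(x) %||% length(x)
  dy <- dim(y) %||% length(y)
  if (!identical(dx, dy))
    dwisr_stop(sprintf("dimension mismatch: (%s) vs (%s)",
                       paste(dx, collapse = ", "),
                       paste(dy, collapse = ", ")), "shape")
  invisible(TRUE)
}

#' Peak signal-to-noise ratio in dB
#'
#' \deqn{\mathrm{PSNR} = 10 \log_{10}(I_{max}^2 / \mathrm{MSE})}
#' where \eqn{I_{max}} is the dynamic range of the reference.  For
#' floating-point DWI no bit depth applies, so `"auto"` uses the reference
#' maximum.  Identical inputs have zero MSE; `Inf` is returned as a
#' sentinel (summaries exclude it with a warning).
#'
#' @param x grid under evaluation.
#' @param y reference grid (carries the dynamic range, so PSNR is not
#'   symmetric in its arguments).
#' @param imax dynamic range, or `"auto"` for `max(y)`.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, imax = "auto") {
  check_same_dims(x, y)
  if (identical(imax, "auto")) imax <- max(y)
  if (!is.numeric(imax) || length(imax) != 1L || !is.finite(imax) ||
      imax <= 0)
    dwisr_stop("`imax` must be a positive number (or \"auto\")", "domain")
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(imax^2 / m)
}

#' Parameters of the structural similarity index
#'
#' Stabilizing constants of the SSIM: with dynamic range L,
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and `C3 = C2 / 2`.  For integer
#' images L is `2^bit_depth - 1` (e.g. 255 at 8 bits); for floating-point
#' data `bit_depth = "auto"` derives L from the data at evaluation time.
#'
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure terms (all 1 by default).
#' @param bit_depth integer bit depth, or `"auto"`.
#' @return An object of class `"ssim_params"`.
#' @export
ssim_params <- function(alpha = 1, beta = 1, gamma = 1, bit_depth = "auto") {
  if (!identical(bit_depth, "auto")) {
    stopifnot_scalar_number(bit_depth, "bit_depth", positive = TRUE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 bit_depth = bit_depth), class = "ssim_params")
}

ssim_constants <- function(params, x, y) {
  L <- if (identical(params$bit_depth, "auto")) {
    m <- max(max(x), max(y))
    if (m <= 0) 1 else m           # identical zero grids: any L > 0 works
  } else 2^params$bit_depth - 1
  list(L = L, C1 = (0.01 * L)^2, C2 = (0.03 * L)^2, C3 = (0.03 * L)^2 / 2)
}

#' Global structural similarity index
#'
#' Whole-volume (single-window) SSIM: the product of luminance, contrast
#' and structure terms computed from global means, standard deviations and
#' covariance,
#' \deqn{l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2 + \mu_y^2 + C_1},\quad
#'       c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2 + \sigma_y^2 + C_2},\quad
#'       s = \frac{\sigma_{xy} + C_3}{\sigma_x\sigma_y + C_3},}
#' returned as \eqn{l^\alpha c^\beta s^\gamma}.  Variances use the
#' population (1/N) convention for bit-reproducibility.  A sliding-window
#' mean variant is available via `windowed = TRUE` for comparison.
#'
#' @param x,y numeric arrays of identical dimensions.
#' @param params an [ssim_params()].
#' @param windowed if `TRUE`, average local SSIM over cubic windows of
#'   edge `window` instead of using global statistics.
#' @param window window edge length for the windowed variant.
#' @return SSIM value in `[-1, 1]`; exactly 1 for identical inputs.
#' @export
ssim <- function(x, y, params = ssim_params(), windowed = FALSE,
                 window = 8L) {
  check_same_dims(x, y)
  cst <- ssim_constants(params, x, y)
  if (!windowed) return(ssim_global(x, y, params, cst))
  d <- dim(x) %||% length(x)
  if (length(d) != 3L)
    dwisr_stop("windowed SSIM requires 3-D input", "shape")
  vals <- c()
  starts <- function(n) unique(pmin(seq(1L, n, by = window), n - min(window, n) + 1L))
  for (i in starts(d[1])) for (j in starts(d[2])) for (k in starts(d[3])) {
    ii <- i:min(i + window - 1L, d[1])
    jj <- j:min(j + window - 1L, d[2])
    kk <- k:min(k + window - 1L, d[3])
    vals <- c(vals, ssim_global(x[ii, jj, kk], y[ii, jj, kk], params, cst))
  }
  mean(vals)
}

ssim_global <- function(x, y, params, cst) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)   # population variance
  sxy <- mean((x - mx) * (y - my))
  sx <- sqrt(vx); sy <- sqrt(vy)
  l <- (2 * mx * my + cst$C1) / (mx^2 + my^2 + cst$C1)
  cc <- (2 * sx * sy + cst$C2) / (vx + vy + cst$C2)
  s <- (sxy + cst$C3) / (sx * sy + cst$C3)
  l^params$alpha * cc^params$beta * s^params$gamma
}

#' Cosine similarity between two grids
#'
#' Inner product of the flattened voxel vectors divided by the product of
#' their Euclidean norms; 1 for proportional signals, 0 for signals with
#' disjoint support.  Two all-zero grids are identical: 1 is returned with
#' a warning (the ratio itself is undefined).
#'
#' @param x,y numeric arrays of identical dimensions.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  check_same_dims(x, y)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 && ny == 0) {
    warning("both grids are all-zero; cosine similarity undefined, returning 1")
    return(1)
  }
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Intensity histogram over a shared range
#'
#' Bin counts of voxel intensities over `bins` equal-width bins spanning
#' `range`; bins are half-open `[lo, hi)` with the last bin closed, and
#' values outside the range land in the first/last bin so the counts
#' always sum to the voxel count.  Using the same range for every compared
#' image makes the histogram shapes directly comparable.
#'
#' @param x numeric array.
#' @param bins number of bins (>= 1).
#' @param range length-2 numeric, `lo < hi`.
#' @return Integer vector of counts with the bin midpoints as
#'   `attr(, "mids")` and edges as `attr(, "breaks")`.
#' @export
intensity_histogram <- function(x, bins = 64L, range = base::range(x)) {
  bins <- as.integer(bins)
  if (bins < 1L) dwisr_stop("`bins` must be >= 1", "usage")
  if (length(range) != 2L || range[2L] <= range[1L])
    dwisr_stop("`range` must be an increasing pair", "usage")
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  idx <- findInterval(as.numeric(x), breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  structure(counts, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
            breaks = breaks)
}

#' Full image-quality report for one volume pair
#'
#' @param x reconstructed grid; `y` reference grid.
#' @param y reference grid.
#' @param params an [ssim_params()].
#' @param imax PSNR dynamic range (`"auto"` = reference maximum).
#' @return A list of class `"metric_report"` with `psnr`, `ssim`,
#'   `cosine`, `mse` and `imax`.
#' @export
metric_report <- function(x, y, params = ssim_params(), imax = "auto") {
  structure(list(psnr = psnr(x, y, imax), ssim = ssim(x, y, params),
                 cosine = cosine_similarity(x, y), mse = mse(x, y),
                 imax = if (identical(imax, "auto")) max(y) else imax),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | SSIM %.4f | cosine %.4f | MSE %.4g\n",
              x$psnr, x$ssim, x$cosine, x$mse))
  invisible(x)
}

#' Average/Std/Max/Min summary over a set of metric reports
#'
#' Aggregates per-image reports into the standard four-row summary.
#' Infinite PSNR sentinels (identical image pairs) are excluded from the
#' PSNR statistics with a warning.
#'
#' @param reports list of [metric_report()] objects.
#' @return Data frame with rows Average, Std, Max, Min and columns `psnr`,
#'   `ssim`, `cosine`.
#' @export
summarize_metrics <- function(reports) {
  if (!length(reports)) dwisr_stop("no reports supplied", "usage")
  get <- function(f) vapply(reports, `[[`, 0, f)
  p <- get("psnr")
  if (any(!is.finite(p))) {
    warning(sprintf("%d infinite PSNR value(s) excluded from the summary",
                    sum(!is.finite(p))))
    p <- p[is.finite(p)]
  }
  if (!length(p))
    dwisr_stop("all PSNR values are infinite", "usage")
  block <- function(v) c(Average = mean(v),
                         Std = stats::sd(v),
                         Max = max(v), Min = min(v))
  out <- data.frame(psnr = block(p), ssim = block(get("ssim")),
                    cosine = block(get("cosine")))
  if (length(reports) == 1L) out["Std", ] <- 0
  out
}

#' Normalized three-index product score per checkpoint
#'
#' Because the peaks of PSNR, SSIM and cosine similarity occur at
#' different checkpoints, a single selection criterion multiplies the
#' three: PSNR is first normalized to `[0, 1]` by dividing every
#' checkpoint's average PSNR by the best checkpoint average, so the best
#' checkpoint's PSNR factor is exactly 1.
#'
#' @param metrics data frame (or list coercible to one) with columns
#'   `psnr`, `ssim`, `cosine`, one row per checkpoint.
#' @return Numeric vector of product scores, one per checkpoint.
#' @export
product_score <- function(metrics) {
  metrics <- as.data.frame(metrics)
  for (f in c("psnr", "ssim", "cosine"))
    if (!f %in% names(metrics))
      dwisr_stop(paste0("`metrics` must contain a `", f, "` column"),
                 "usage")
  p <- metrics$psnr
  fin <- is.finite(p)
  if (!any(fin))
    dwisr_stop("all checkpoint PSNR averages are infinite", "usage")
  best <- max(p[fin])
  pn <- ifelse(fin, p / best, 1)  # infinite PSNR cannot be beaten
  pn * metrics$ssim * metrics$cosine
}
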