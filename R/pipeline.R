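#' Configuration of an end-to-end super-resolution experiment
#'
#' Bundles every stage's parameters: phantom cohort generation, the
#' degrade/restore cycle, network architecture, training, and GQI
#' reconstruction.  The experiment is a pure function of this
#' configuration (including the seed), so identical configurations give
#' bit-identical report bundles.
#'
#' @param n_subjects number of phantom subjects in the cohort.
#' @param phantom a [phantom_spec()] used as the per-subject template
#'   (each subject gets its own noise seed derived from `seed`).
#' @param resample a [resample_spec()].
#' @param srcnn an [srcnn_spec()].
#' @param training a [training_control()].
#' @param gqi a [gqi_spec()].
#' @param ssim an [ssim_params()].
#' @param test_ratio approximate train:test ratio as a single number
#'   (11 means 11:1); at least one subject is always held out.
#' @param histogram_bins bins of the shared-range intensity histograms.
#' @param output_dir optional directory; when set, predicted volumes,
#'   metric JSON, the training logs and index maps are written there.
#' @param seed master integer seed for cohort generation, the split and
#'   training.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(n_subjects = 12L,
                       phantom = phantom_spec(),
                       resample = resample_spec(),
                       srcnn = srcnn_spec(),
                       training = training_control(),
                       gqi = gqi_spec(),
                       ssim = ssim_params(),
                       test_ratio = 11,
                       histogram_bins = 50L,
                       output_dir = NULL,
                       seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L)
    dwisr_stop("`n_subjects` must be >= 2 (need a held-out subject)",
               "config")
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(resample, "resample_spec"),
            inherits(srcnn, "srcnn_spec"),
            inherits(training, "training_control"),
            inherits(gqi, "gqi_spec"))
  structure(list(n_subjects = n_subjects, phantom = phantom,
                 resample = resample, srcnn = srcnn, training = training,
                 gqi = gqi, ssim = ssim, test_ratio = test_ratio,
                 histogram_bins = as.integer(histogram_bins),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Super-resolve a DWI volume with per-shell models
#'
#' Routes every gradient entry to the model trained on its b-value group
#' (b = 0 entries use the b0/b1000 model), applies the restoration path of
#' [predict.srcnn()], and assembles the super-resolved 4-D volume.  The
#' output voxel size is the input voxel size divided by the resampling
#' factor.
#'
#' @param models named list of fitted `"srcnn"` objects with names among
#'   `"b0_b1000"`, `"b1500"`, `"b2000"`.
#' @param lr_vol low-resolution [dwi_volume()].
#' @param spec a [resample_spec()].
#' @return A [dwi_volume()] with `spec$factor`-times the spatial
#'   dimensions.
#' @export
predict_dwi <- function(models, lr_vol, spec = resample_spec()) {
  stopifnot(inherits(lr_vol, "dwi_volume"), inherits(spec, "resample_spec"))
  n <- n_gradients(lr_vol)
  labels <- vapply(lr_vol$bvals, group_label_for_bval, "")
  missing <- setdiff(unique(labels), names(models))
  if (length(missing))
    dwisr_stop(paste0(
      "no model supplied for b-value group(s): ",
      paste(missing, collapse = ", ")), "usage")

  interp <- lapply(seq_len(n), function(i)
    interpolate_up(dwi_grid(lr_vol, i), spec$factor, spec$method))
  scale <- max(vapply(interp, max, 0))  # shared training-intensity scale
  out <- array(0, c(dim(interp[[1L]]), n))
  for (i in seq_len(n))
    out[, , , i] <- predict(models[[labels[i]]], interp[[i]], spec,
                            interpolated = TRUE, scale = scale)
  dwi_volume(out, bvals = lr_vol$bvals, bvecs = lr_vol$bvecs,
             voxel_size = lr_vol$voxel_size / spec$factor,
             affine = lr_vol$affine)
}

phantom_with_seed <- function(template, seed) {
  template$seed <- as.integer(seed)
  template
}

checkpoint_model <- function(model, checkpoint) {
  model$weights <- checkpoint$weights
  model$iterations <- checkpoint$iteration
  model
}

# Metrics of one model state on a set of held-out pairs: forward pass on
# the interpolated source, renormalized onto the source range, compared
# against the high-resolution target.
evaluate_on_pairs <- function(model, pairs, ssim_par) {
  reports <- lapply(pairs, function(p) {
    pred <- predict(model, p$source, interpolated = TRUE, scale = 1)
    metric_report(pred, p$target, params = ssim_par)
  })
  summarize_metrics(reports)
}

#' Run the full super-resolution experiment on a phantom cohort
#'
#' Reproduces the complete workflow on synthetic data: generate a cohort
#' of phantom subjects, hold out test subject(s) (train:test about
#' `test_ratio`:1, split at subject level so no gradient of a test subject
#' leaks into training), build degrade/interpolate training pairs, train
#' one network per b-value group, select each group's best checkpoint by
#' the normalized PSNR x SSIM x cosine product on the held-out pairs,
#' super-resolve the held-out subject, and compare against the
#' interpolation baseline with image metrics, shared-range histograms and
#' GQI index maps.
#'
#' @param config a [run_config()].
#' @return A list of class `"sr_experiment"` with elements:
#' \describe{
#'   \item{split}{train/test subject indices.}
#'   \item{models}{named list of fitted `"srcnn"` objects (best
#'     checkpoint weights installed).}
#'   \item{selection}{per-group checkpoint metrics and the selected
#'     iteration.}
#'   \item{losses}{per-group initial and final training loss.}
#'   \item{metrics}{per-gradient reports and Average/Std/Max/Min
#'     summaries for the SRCNN prediction and the interpolation baseline.}
#'   \item{histograms}{shared-range intensity histograms of target,
#'     baseline and prediction.}
#'   \item{gqi}{index maps for target/baseline/prediction, their metric
#'     summaries, and fiber-vs-CSF GFA / ISO contrasts.}
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  subjects <- lapply(seq_len(config$n_subjects), function(s)
    generate_phantom(phantom_with_seed(config$phantom, seed * 100L + s)))

  n_test <- max(1L, round(config$n_subjects / (config$test_ratio + 1)))
  test_ids <- sort(with_seed(seed,
                             sample.int(config$n_subjects, n_test)))
  train_ids <- setdiff(seq_len(config$n_subjects), test_ids)

  train_pairs <- structure(unlist(lapply(train_ids, function(s)
    build_pairs(subjects[[s]], config$resample, subject = s)),
    recursive = FALSE), class = "dwi_pairs")
  test_pairs <- structure(unlist(lapply(test_ids, function(s)
    build_pairs(subjects[[s]], config$resample, subject = s)),
    recursive = FALSE), class = "dwi_pairs")

  groups <- group_by_bvalue(train_pairs)
  test_groups <- group_by_bvalue(test_pairs)

  models <- list()
  selection <- list()
  losses <- list()
  for (g in names(groups)) {
    if (!length(groups[[g]]$pairs)) {
      warning(sprintf("no training data for group %s; model not trained", g))
      next
    }
    spec_g <- config$srcnn
    spec_g$seed <- config$srcnn$seed + match(g, names(groups))
    ctrl_g <- config$training
    ctrl_g$seed <- config$training$seed + match(g, names(groups))
    fit <- fit_srcnn(groups[[g]], spec = spec_g, control = ctrl_g)

    ck_metrics <- do.call(rbind, lapply(fit$checkpoints, function(ck) {
      sm <- evaluate_on_pairs(checkpoint_model(fit, ck),
                              test_groups[[g]]$pairs, config$ssim)
      data.frame(checkpoint = ck$iteration, psnr = sm["Average", "psnr"],
                 ssim = sm["Average", "ssim"],
                 cosine = sm["Average", "cosine"])
    }))
    best <- select_best_checkpoint(ck_metrics)
    ck <- fit$checkpoints[[which(ck_metrics$checkpoint == as.numeric(best))]]
    models[[g]] <- checkpoint_model(fit, ck)
    selection[[g]] <- list(metrics = ck_metrics,
                           scores = attr(best, "scores"),
                           selected = ck$iteration)
    losses[[g]] <- list(initial = fit$log$loss[1L],
                        final = utils::tail(fit$log$loss, 1L))
  }

  # held-out evaluation against the acquired high-resolution volumes
  test_vol <- subjects[[test_ids[1L]]]
  f <- config$resample$factor
  hr <- test_vol$data
  nlist <- seq_len(dim(hr)[4L])
  lr_data <- array(0, c(dim(hr)[1:3] / f, dim(hr)[4L]))
  for (i in nlist) lr_data[, , , i] <- downsample(dwi_grid(test_vol, i), f)
  lr_vol <- dwi_volume(lr_data, bvals = test_vol$bvals,
                       bvecs = test_vol$bvecs,
                       voxel_size = test_vol$voxel_size * f)

  baseline_data <- array(0, dim(hr))
  for (i in nlist)
    baseline_data[, , , i] <- interpolate_up(dwi_grid(lr_vol, i), f,
                                             config$resample$method)
  baseline_vol <- dwi_volume(baseline_data, bvals = test_vol$bvals,
                             bvecs = test_vol$bvecs,
                             voxel_size = test_vol$voxel_size)
  pred_vol <- predict_dwi(models, lr_vol, config$resample)

  report_set <- function(vol) lapply(nlist, function(i)
    metric_report(dwi_grid(vol, i), dwi_grid(test_vol, i),
                  params = config$ssim))
  baseline_reports <- report_set(baseline_vol)
  srcnn_reports <- report_set(pred_vol)
  metrics <- list(
    baseline = list(reports = baseline_reports,
                    summary = summarize_metrics(baseline_reports)),
    srcnn = list(reports = srcnn_reports,
                 summary = summarize_metrics(srcnn_reports)))

  rng <- c(0, max(hr))
  histograms <- list(
    target = intensity_histogram(hr, config$histogram_bins, rng),
    baseline = intensity_histogram(baseline_vol$data,
                                   config$histogram_bins, rng),
    srcnn = intensity_histogram(pred_vol$data, config$histogram_bins, rng))

  regions <- attr(test_vol, "regions")
  gqi_maps <- lapply(list(target = test_vol, baseline = baseline_vol,
                          srcnn = pred_vol), function(v)
    compute_index_maps(reconstruct_sdf(v, config$gqi)))
  contrast <- function(maps) list(
    gfa_fiber = mean(maps$gfa[regions$fiber]),
    gfa_csf = mean(maps$gfa[regions$csf]),
    iso_fiber = mean(maps$iso[regions$fiber]),
    iso_csf = mean(maps$iso[regions$csf]))
  map_metrics <- lapply(c(baseline = "baseline", srcnn = "srcnn"),
                        function(w) {
    reps <- lapply(c("gfa", "nqa", "iso"), function(m)
      metric_report(gqi_maps[[w]][[m]], gqi_maps$target[[m]],
                    params = config$ssim))
    names(reps) <- c("gfa", "nqa", "iso")
    reps
  })

  result <- structure(list(
    config = config,
    split = list(train = train_ids, test = test_ids),
    models = models,
    selection = selection,
    losses = losses,
    volumes = list(low_res = lr_vol, baseline = baseline_vol,
                   srcnn = pred_vol, target = test_vol),
    metrics = metrics,
    histograms = histograms,
    gqi = list(maps = gqi_maps,
               contrasts = lapply(gqi_maps, contrast),
               map_metrics = map_metrics)),
    class = "sr_experiment")

  if (!is.null(config$output_dir)) write_experiment(result)
  result
}

#' @export
print.sr_experiment <- function(x, ...) {
  cat("<sr_experiment> ", length(x$split$train), " training / ",
      length(x$split$test), " test subject(s)\n", sep = "")
  for (g in names(x$models))
    cat(sprintf("  %s: %d iterations, checkpoint %d selected, loss %.3g -> %.3g\n",
                g, x$models[[g]]$iterations + 0L, x$selection[[g]]$selected,
                x$losses[[g]]$initial, x$losses[[g]]$final))
  b <- x$metrics$baseline$summary["Average", ]
  s <- x$metrics$srcnn$summary["Average", ]
  cat(sprintf("  held-out mean PSNR: %.2f dB (interp) vs %.2f dB (SRCNN)\n",
              b$psnr, s$psnr))
  cat(sprintf("  held-out mean SSIM: %.4f (interp) vs %.4f (SRCNN)\n",
              b$ssim, s$ssim))
  invisible(x)
}

write_experiment <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- result$volumes$target$voxel_size
  for (nm in names(result$volumes))
    write_dwi(result$volumes[[nm]],
              file.path(dir, paste0(nm, ".nii.gz")),
              file.path(dir, paste0(nm, ".bval")),
              file.path(dir, paste0(nm, ".bvec")))
  for (nm in names(result$gqi$maps))
    write_index_maps(result$gqi$maps[[nm]],
                     file.path(dir, paste0(nm, "_")), vx)
  for (g in names(result$models)) {
    write_srcnn(result$models[[g]], file.path(dir, paste0(g, ".rds")))
    utils::write.csv(result$models[[g]]$log,
                     file.path(dir, paste0(g, "_log.csv")),
                     row.names = FALSE)
  }
  report <- list(
    split = result$split,
    selection = lapply(result$selection, function(s)
      list(selected = s$selected, metrics = s$metrics,
           scores = s$scores)),
    losses = result$losses,
    metrics = list(baseline = result$metrics$baseline$summary,
                   srcnn = result$metrics$srcnn$summary),
    histograms = lapply(result$histograms, as.integer),
    gqi_contrasts = result$gqi$contrasts)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
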