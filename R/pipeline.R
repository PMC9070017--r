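#' Default pipeline configuration
#'
#' All analysis parameters in one nested list, set to the calibration
#' analysis defaults: 1-45 Hz order-8 Butterworth band-pass with 60 Hz
#' notch, downsampling to 150 Hz, pooled occipitoparietal channel,
#' 2.5 s time-frequency epochs with -600..-100 ms baseline and
#' 300..800 ms response windows, -200..+800 ms ERP epochs, artifact
#' rejection off (mirroring the primary analyses), and repeated
#' stratified 80/20 cross-validation for the classifiers.  The list
#' round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   replaced wholesale).
#' @return A list of class `rsvp_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    schedule = list(rate_hz = 1, n_trials = 100, seq_len = 10),
    sim = unclass(sim_params()),
    filter = list(low = 1, high = 45, notch = 60, order = 8),
    resample_fs = 150,
    pool = posterior_channels(),
    tf_window = c(-1250, 1250),
    baseline_window = c(-600, -100),
    response_window = c(300, 800),
    erp_window = c(-200, 800),
    erp_baseline = c(-200, 0),
    classifier_filter = list(low = 2, high = 45),
    classifier_window = c(0, 500),
    artifact_reject = FALSE,
    sources = c("POOL", "Pz"),
    classify = list(run = TRUE,
                    models = c("logreg_l2", "svc", "tangent_space",
                               "uniform_random"),
                    rda_kde = TRUE,
                    cv = unclass(cv_spec()),
                    tune = FALSE, grid_step_ms = 50),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "rsvp_config")
}

#' Write / read a pipeline configuration
#'
#' @param config An `rsvp_config` list.
#' @param path JSON file path.
#' @return `path` (writer) or the restored `rsvp_config` (reader).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}

#' Run the full calibration analysis pipeline
#'
#' Executes simulate (or ingest) -> filter/downsample/pool -> optional
#' artifact rejection -> spectrum and IAF -> wavelet scaleogram,
#' Z-transform and alpha attenuation -> ERP summary -> classifiers, and
#' optionally writes every stage's outputs under `out_dir` (events CSV,
#' spectrum CSV, IAF JSON, per-epoch alpha CSV, attenuation JSON, ERP
#' summary CSV, classifier JSON, rejection CSV, and a run manifest).
#'
#' @param config An `rsvp_config` list.
#' @param recording Optional pre-loaded `rsvp_recording` (with events);
#'   when `NULL` a recording is simulated from `config$schedule` and
#'   `config$sim`.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return A list of class `rsvp_report` with elements `iaf`, `spectrum`,
#'   `alpha` (per source), `erp` (per source), `classifiers`,
#'   `rejection`, `config`, `summary` (flat named list of headline
#'   numbers).
#' @export
run_pipeline <- function(config = default_config(), recording = NULL,
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "simulate"
  res <- try({
    if (is.null(recording)) {
      say("simulating %d trials at %g Hz",
          config$schedule$n_trials, config$schedule$rate_hz)
      sched <- make_schedule(config$schedule$rate_hz,
                             config$schedule$n_trials,
                             config$schedule$seq_len, config$seed)
      sp <- config$sim
      sp$seed <- config$seed          # the run seed covers the simulation
      recording <- synthesize_recording(sched, do.call(sim_params, sp))
    }
    if (!nrow(recording$events)) stop("recording contains no events")

    stage <- "preprocess"
    say("filtering %g-%g Hz + %g Hz notch, resampling to %g Hz",
        config$filter$low, config$filter$high, config$filter$notch,
        config$resample_fs)
    filt <- bandpass_notch(recording, config$filter$low, config$filter$high,
                           config$filter$notch, config$filter$order)
    ds <- resample_recording(filt, config$resample_fs)
    pooled <- pool_channels(ds, config$pool)
    tf_epochs <- epoch_recording(pooled, config$tf_window)

    stage <- "artifact"
    rejection <- NULL
    if (isTRUE(config$artifact_reject)) {
      rejection <- flag_epochs(tf_epochs,
                               channels = setdiff(tf_epochs$channels, "POOL"))
      say("artifact rejection kept %d/%d epochs",
          sum(rejection$keep_mask), length(rejection$keep_mask))
      tf_epochs <- subset_epochs(tf_epochs, rejection$keep_mask)
    }

    stage <- "spectral"
    spectrum <- amplitude_spectrum(tf_epochs, "POOL")
    iaf <- estimate_iaf(spectrum, config$schedule$rate_hz)
    say("IAF: %.1f Hz (%s)", iaf$iaf_hz, iaf$method)

    stage <- "tf_alpha"
    layer_idx <- select_iaf_layer(layer_freqs(), iaf$iaf_hz)
    alpha <- list()
    for (src in config$sources) {
      sc <- cwt_scaleogram(tf_epochs, channels = src, layers = layer_idx)
      z <- ztransform(sc, config$baseline_window)
      alpha[[src]] <- alpha_activity(z, 1, config$response_window, src)
      say("%s attenuation %.3f (p = %.3g)", src, alpha[[src]]$attenuation,
          alpha[[src]]$mwu_p)
    }

    stage <- "erp"
    erp_epochs <- epoch_recording(pooled, config$erp_window)
    if (!is.null(rejection)) {
      keep_ev <- tf_epochs$events$sample
      erp_epochs <- subset_epochs(erp_epochs,
                                  erp_epochs$events$sample %in% keep_ev)
    }
    erp <- lapply(stats::setNames(nm = config$sources), function(src)
      erp_summary(erp_epochs, src, config$erp_baseline))

    stage <- "classify"
    classifiers <- list()
    tuned <- NULL
    if (isTRUE(config$classify$run)) {
      cv <- do.call(cv_spec, config$classify$cv)
      sc4 <- cwt_scaleogram(tf_epochs, channels = config$pool,
                            layers = layer_idx)
      z4 <- ztransform(sc4, config$baseline_window)
      feats <- extract_alpha_features(z4, 1, config$response_window,
                                      config$pool)
      for (m in config$classify$models) {
        classifiers[[m]] <- train_eval(feats, m, cv, config$seed)
        say("%s: %.3f", m, classifiers[[m]]$mean_balanced_acc)
      }
      if (isTRUE(config$classify$tune)) {
        tuned <- tune_windows(tf_epochs, iaf$iaf_hz,
                              config$classify$grid_step_ms,
                              cv = cv, seed = config$seed,
                              channels = config$pool)
      }
      if (isTRUE(config$classify$rda_kde)) {
        erp_filt <- bandpass_notch(recording, config$classifier_filter$low,
                                   config$classifier_filter$high, NULL,
                                   config$filter$order)
        erp_ds <- resample_recording(erp_filt, config$resample_fs)
        cls_epochs <- epoch_recording(erp_ds, config$classifier_window)
        classifiers[["rda_kde"]] <- rda_kde_eval(cls_epochs, cv, config$seed)
        say("rda_kde: %.3f", classifiers[["rda_kde"]]$mean_balanced_acc)
      }
    }

    summary <- c(
      list(rate_hz = config$schedule$rate_hz, n_epochs = length(tf_epochs$labels),
           iaf_hz = iaf$iaf_hz, iaf_method = iaf$method),
      stats::setNames(lapply(alpha, `[[`, "attenuation"),
                      paste0("attenuation_", names(alpha))),
      stats::setNames(lapply(alpha, `[[`, "mwu_p"),
                      paste0("mwu_p_", names(alpha))),
      if (length(classifiers))
        stats::setNames(lapply(classifiers, `[[`, "mean_balanced_acc"),
                        paste0("bal_acc_", names(classifiers)))
    )
    structure(list(iaf = iaf, spectrum = spectrum, alpha = alpha, erp = erp,
                   classifiers = classifiers, tuned = tuned,
                   rejection = rejection, epochs = tf_epochs,
                   config = config, summary = summary),
              class = "rsvp_report")
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(res, "condition")$message))
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' Write a pipeline report bundle to disk
#'
#' @param report An `rsvp_report` from [run_pipeline()].
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  j <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)
  utils::write.csv(data.frame(freq = report$spectrum$freqs,
                              amp = report$spectrum$amp),
                   file.path(out_dir, "spectrum.csv"), row.names = FALSE)
  j(report$iaf[c("iaf_hz", "method", "excluded_freqs")], "iaf.json")
  per <- do.call(rbind, lapply(names(report$alpha), function(src)
    cbind(source = src, report$alpha[[src]]$per_epoch)))
  utils::write.csv(per, file.path(out_dir, "alpha_per_epoch.csv"),
                   row.names = FALSE)
  j(lapply(report$alpha, function(a)
    list(attenuation = a$attenuation, mwu_p = a$mwu_p,
         class_medians = as.list(a$class_medians))), "attenuation.json")
  erp_tab <- do.call(rbind, lapply(names(report$erp), function(src) {
    s <- report$erp[[src]]
    data.frame(source = src,
               component = rep(c("n200", "p300"), times = 3),
               measure = rep(c("latency_ms", "amp_target", "amp_nontarget"),
                             each = 2),
               value = c(s$latencies, s$amplitudes[, "target"],
                         s$amplitudes[, "nontarget"]))
  }))
  utils::write.csv(erp_tab, file.path(out_dir, "erp_summary.csv"),
                   row.names = FALSE)
  if (length(report$classifiers))
    j(lapply(report$classifiers, function(r)
      r[c("model_id", "per_split_balanced_acc", "mean_balanced_acc",
          "seed")]), "classifier_results.json")
  if (!is.null(report$rejection))
    utils::write.csv(report$rejection$table,
                     file.path(out_dir, "rejection.csv"), row.names = FALSE)
  j(report$summary, "summary.json")
  j(unclass(report$config), "manifest.json")
  invisible(out_dir)
}

#' @export
print.rsvp_report <- function(x, ...) {
  cat("RSVP pipeline report\n")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}
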