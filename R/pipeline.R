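#' Pipeline configuration
#'
#' Bundles the stage configurations of the full analysis chain
#' (resample, denoise, envelope, cycle estimation, cropping, features, PCA,
#' ensemble) with one master seed from which all stage seeds derive.
#'
#' @param preprocess a [preprocess_config()].
#' @param denoise apply wavelet denoising (default TRUE).
#' @param envelope named list overriding [scalogram_config()] arguments.
#' @param bpm_range cycle-length search range in BPM.
#' @param n_cycles cycles per segment (default 5).
#' @param delta_frac envelope peak threshold as a fraction of the segment
#'   envelope maximum.
#' @param pca_retain retained variance fraction; `NULL` disables PCA.
#' @param pca_standardize standardize features before PCA.
#' @param n_networks,threshold,hidden_units,retrains,holdout_fraction,maxit
#'   ensemble settings (see [train_bagging()]).
#' @param master_seed single integer seed for the whole run.
#' @return list of class `pcg_config`.
#' @export
pcg_config <- function(preprocess = preprocess_config(), denoise = TRUE,
                       envelope = list(), bpm_range = c(48, 240),
                       n_cycles = 5L, delta_frac = 0.25,
                       pca_retain = 0.9, pca_standardize = TRUE,
                       n_networks = 5L, threshold = 0.15,
                       hidden_units = 10L, retrains = 30L,
                       holdout_fraction = 0.2, maxit = 200L,
                       master_seed = 1L) {
  structure(list(preprocess = preprocess, denoise = denoise,
                 envelope = envelope, bpm_range = bpm_range,
                 n_cycles = as.integer(n_cycles), delta_frac = delta_frac,
                 pca_retain = pca_retain, pca_standardize = pca_standardize,
                 n_networks = as.integer(n_networks), threshold = threshold,
                 hidden_units = as.integer(hidden_units),
                 retrains = as.integer(retrains),
                 holdout_fraction = holdout_fraction, maxit = as.integer(maxit),
                 master_seed = as.integer(master_seed)),
            class = "pcg_config")
}

#' Analyze one record up to the feature vector
#'
#' Runs resample, optional denoise, envelope detection, autocorrelation,
#' cycle-length estimation, five-cycle cropping and feature extraction.
#' Stage failures are re-raised with the stage name prefixed.
#'
#' @param record a [heart_sound_record()].
#' @param config a [pcg_config()].
#' @param keep_intermediate also return the envelope, autocorrelation and
#'   segment.
#' @return list with `features` (35-vector), `bpm`, `cycle_length`,
#'   `low_confidence`, and optionally the intermediates.
#' @export
analyze_record <- function(record, config = pcg_config(),
                           keep_intermediate = FALSE) {
  stopifnot(inherits(record, "heart_sound_record"),
            inherits(config, "pcg_config"))
  rec <- .stage("resample",
                resample_record(record, config$preprocess$target_fs))
  if (isTRUE(config$denoise))
    rec <- .stage("denoise", denoise_record(rec, config$preprocess))
  env_args <- utils::modifyList(list(fs = rec$fs), config$envelope)
  env <- .stage("envelope",
                compute_envelope(rec, do.call(scalogram_config, env_args)))
  acf_e <- .stage("autocorrelation", autocorrelate(env))
  est <- .stage("cycle-estimate",
                estimate_cycle_length(acf_e, bpm_range = config$bpm_range))
  seg <- .stage("crop", crop_segment(rec, env, est, n_cycles = config$n_cycles))
  feats <- .stage("features",
                  extract_features(seg, delta_frac = config$delta_frac))
  out <- list(features = feats, bpm = est$bpm,
              cycle_length = est$lag_samples,
              low_confidence = est$low_confidence)
  if (keep_intermediate)
    out <- c(out, list(envelope = env, acf = acf_e, segment = seg))
  out
}

#' Build a feature matrix from a list of records
#'
#' @param records list of [heart_sound_record()].
#' @param config a [pcg_config()].
#' @return list: `x` (n x 35 matrix), `bpm` (vector), `labels` (vector,
#'   `NA` where unknown).
#' @export
extract_feature_matrix <- function(records, config = pcg_config()) {
  res <- lapply(records, analyze_record, config = config)
  list(x = do.call(rbind, lapply(res, `[[`, "features")),
       bpm = vapply(res, `[[`, 0, "bpm"),
       labels = vapply(records, function(r)
         if (is.na(r$label)) NA_real_ else as.numeric(r$label), 0))
}

#' Train the full screening model
#'
#' Extracts features from labelled records, optionally balances classes by
#' minority oversampling, fits the PCA reduction and trains the bagged
#' ensemble. The returned model classifies new records via [run_pipeline()].
#'
#' @param records list of labelled [heart_sound_record()].
#' @param config a [pcg_config()].
#' @param oversample balance classes before training.
#' @return object of class `pcg_model`: `pca`, `ensemble`, `config`.
#' @export
train_pipeline <- function(records, config = pcg_config(), oversample = TRUE) {
  fm <- extract_feature_matrix(records, config)
  if (anyNA(fm$labels)) stop("all training records need labels", call. = FALSE)
  x <- fm$x; y <- fm$labels
  if (oversample) {
    oi <- oversample_minority(y, seed = .derive_seed(config$master_seed, 11L))
    x <- x[oi, , drop = FALSE]; y <- y[oi]
  }
  pca <- NULL
  if (!is.null(config$pca_retain)) {
    pca <- fit_pca(x, retain = config$pca_retain,
                   standardize = config$pca_standardize)
    x <- predict(pca, x)
  }
  ens <- train_bagging(x, y, n_networks = config$n_networks,
                       threshold = config$threshold,
                       hidden_units = config$hidden_units,
                       retrains = config$retrains,
                       holdout_fraction = config$holdout_fraction,
                       maxit = config$maxit,
                       seed = .derive_seed(config$master_seed, 12L))
  structure(list(pca = pca, ensemble = ens, config = config),
            class = "pcg_model")
}

#' Classify a heart-sound record
#'
#' Runs the complete chain -- resample, denoise, envelope, autocorrelation,
#' cycle estimate, five-cycle crop, 35-element features, PCA projection,
#' ensemble vote -- and reports the class label with the estimated heart
#' rate.
#'
#' @param record a [heart_sound_record()].
#' @param model a `pcg_model` from [train_pipeline()].
#' @param config configuration; defaults to the model's.
#' @return list: `label` (0 normal / 1 abnormal), `bpm`, `abnormal_rate`
#'   (TRUE when the estimated BPM sits on the search boundary), `votes`,
#'   `outputs`, `features`.
#' @export
run_pipeline <- function(record, model, config = model$config) {
  stopifnot(inherits(model, "pcg_model"))
  an <- analyze_record(record, config)
  z <- if (!is.null(model$pca)) predict(model$pca, an$features) else an$features
  pr <- .stage("classify", predict(model$ensemble, z))
  list(label = pr$label[1], bpm = an$bpm, abnormal_rate = an$low_confidence,
       votes = drop(pr$votes), outputs = drop(pr$outputs),
       features = an$features)
}

#' @export
print.pcg_model <- function(x, ...) {
  cat("<pcg_model>\n")
  if (!is.null(x$pca)) print(x$pca)
  print(x$ensemble)
  invisible(x)
}
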