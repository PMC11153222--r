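#' Full pipeline configuration
#'
#' One nested list holding every tunable of the pipeline with its default:
#' channel selection, band-pass filter, sliding window, STFT, architecture
#' choice, training, detector and synthetic-data settings. Round-trips
#' through YAML unchanged.
#'
#' @param seed root seed; stage seeds are derived from it.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    channels = default_channels(),
    filter = list(order = 6, band = c(1, 60)),
    window = list(window_s = 1.35, overlap_s = 1.0),
    stft = list(win_len = 2, hop = 1, nfft = 128, band = c(20, 60),
                floor_db = -120),
    architecture = list(name = "default", width = 8),
    train = list(learning_rate = 0.01, epochs = 30, val_fraction = 0.2,
                 val_frequency = 50, batch_size = 32, momentum = 0.9,
                 class_weighting = FALSE, train_stride = 1),
    detector = list(pre_tolerance_s = 0, smoothing_k = 1,
                    min_overlap_frac = 0.5),
    synthetic = list(fs = 256, n_channels = 6, duration_s = 480,
                     onef_exponent = 1, alpha_uv = 10, sigma_uv = 15,
                     n_subjects = 3,
                     seizures = list(onset_s = c(70, 210, 350),
                                     duration_s = c(35, 35, 35),
                                     band_boost_db = c(20, 20, 20)))),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' @param path YAML (or JSON) file.
#' @return `read_pipeline_config`: a `pipeline_config` (fields missing from
#'   the file keep their defaults); `write_pipeline_config`: `path`,
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_pipeline_config()
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_in(base[[nm]], new[[nm]])
      } else new[[nm]]
    }
    base
  }
  out <- merge_in(unclass(cfg), raw)
  class(out) <- "pipeline_config"
  out
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# concrete parameter objects from the config
config_objects <- function(cfg, fs = cfg$synthetic$fs) {
  list(
    fspec = filter_spec(cfg$filter$order, unlist(cfg$filter$band), fs),
    wcfg = window_config(cfg$window$window_s, cfg$window$overlap_s, fs),
    stft = stft_params(cfg$stft$win_len, cfg$stft$hop, cfg$stft$nfft, fs,
                       unlist(cfg$stft$band), cfg$stft$floor_db),
    arch = if (identical(cfg$architecture$name, "default")) {
      default_architecture()
    } else {
      reduced_architecture(cfg$architecture$width)
    },
    tcfg = train_config(cfg$train$learning_rate, cfg$train$epochs,
                        cfg$train$val_fraction, cfg$train$val_frequency,
                        cfg$train$batch_size, cfg$train$momentum,
                        seed = cfg$seed + 17L,
                        class_weighting = cfg$train$class_weighting))
}

#' Synthetic-data settings of a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @return the corresponding [synth_config()] (seed derived from the
#'   pipeline's root seed).
#' @export
config_synth <- function(cfg) {
  sz <- cfg$synthetic$seizures
  synth_config(fs = cfg$synthetic$fs, n_channels = cfg$synthetic$n_channels,
               duration_s = cfg$synthetic$duration_s,
               onef_exponent = cfg$synthetic$onef_exponent,
               alpha_uv = cfg$synthetic$alpha_uv,
               sigma_uv = cfg$synthetic$sigma_uv,
               seizures = as.data.frame(sz), seed = cfg$seed + 100L)
}

#' Train on a set of subjects and evaluate detection on others
#'
#' The core experiment: band-pass filter all recordings, build peri-ictal
#' training epochs from the training subjects, train the CNN, then stream
#' the detector over each test subject's full recording and score events
#' and windows.
#'
#' @param dataset named list of `list(recording, annotation)` per subject
#'   (e.g. from [generate_dataset()]).
#' @param train_subjects,test_subjects subject names.
#' @param cfg a `pipeline_config`.
#' @param verbose print progress.
#' @return list with `model`, `per_case` (one row per test subject),
#'   `decisions` (named list).
#' @export
run_split <- function(dataset, train_subjects, test_subjects,
                      cfg = default_pipeline_config(), verbose = FALSE) {
  fs <- dataset[[1]]$recording$fs
  ob <- config_objects(cfg, fs)
  recs <- lapply(dataset[train_subjects], `[[`, "recording")
  anns <- lapply(dataset[train_subjects], `[[`, "annotation")
  ts <- make_training_set(recs, anns, ob$wcfg, ob$stft, fspec = ob$fspec,
                          train_stride = cfg$train$train_stride,
                          min_overlap_frac = cfg$detector$min_overlap_frac)
  if (verbose) {
    message(sprintf("training on %d epochs (%d seizure-active)",
                    length(ts$labels), sum(ts$labels == "seizure-active")))
  }
  model <- build_model(ob$arch, seed = cfg$seed)
  model <- train_model(model, ts$epochs, ts$labels, ob$tcfg,
                       verbose = verbose)
  per_case <- list()
  decisions <- list()
  for (s in test_subjects) {
    dec <- stream_detect(model, dataset[[s]]$recording, ob$wcfg, ob$stft,
                         fspec = ob$fspec)
    decisions[[s]] <- dec
    per_case[[s]] <- evaluate_case(dec, dataset[[s]]$annotation, case = s,
                                   pre_tolerance_s =
                                     cfg$detector$pre_tolerance_s,
                                   smoothing_k = cfg$detector$smoothing_k,
                                   min_overlap_frac =
                                     cfg$detector$min_overlap_frac)
  }
  list(model = model, per_case = do.call(rbind, per_case),
       decisions = decisions)
}

#' Leave-one-subject-out experiment
#'
#' Runs [run_split()] once per fold and pools the per-fold test rows.
#'
#' @param dataset named list of `list(recording, annotation)` per subject.
#' @param cfg a `pipeline_config`.
#' @param verbose print progress.
#' @return list with `report` (an `eval_report`), `folds` (per-fold
#'   results without models).
#' @export
run_loso <- function(dataset, cfg = default_pipeline_config(),
                     verbose = FALSE) {
  folds <- loso_folds(names(dataset))
  rows <- list()
  fold_out <- list()
  for (f in folds) {
    if (verbose) message("fold: test subject ", f$test)
    r <- run_split(dataset, f$train, f$test, cfg, verbose = verbose)
    rows[[f$test]] <- r$per_case
    fold_out[[f$test]] <- list(per_case = r$per_case,
                               decisions = r$decisions)
  }
  list(report = aggregate_cases(do.call(rbind, rows)), folds = fold_out)
}
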