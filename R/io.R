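# Persistence: HDF5 containers for trial sets, feature sequences and model
# checkpoints (rhdf5), CSV/JSON for ratings and cross-validation reports,
# and a YAML pipeline configuration whose seeds fully determine a run.

#' Write a trial set to HDF5
#'
#' Layout: datasets `/data` (trials x channels x samples), `/ratings`
#' (trials x 2), optional `/truth/A` and `/truth/sources`, plus `fs` and
#' `channel_names` attributes on `/data`. Ratings can additionally be
#' exported to CSV with [write_ratings_csv()].
#'
#' @param ts A [trialset()].
#' @param path Output `.h5` path (overwritten).
#' @param with_sources Also store the ground-truth source panel when present.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(ts, path, with_sources = TRUE) {
  if (!inherits(ts, "trialset")) stop_arg("`ts` must be a trialset")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ts$data, path, "data")
  rhdf5::h5write(ts$ratings, path, "ratings")
  if (!is.null(ts$truth)) {
    rhdf5::h5createGroup(path, "truth")
    rhdf5::h5write(ts$truth$A, path, "truth/A")
    rhdf5::h5write(ts$truth$noise_sd, path, "truth/noise_sd")
    if (with_sources && !is.null(ts$truth$sources)) {
      rhdf5::h5write(ts$truth$sources$sources, path, "truth/sources")
    }
  }
  h5_write_attr(path, "data", "fs", ts$fs)
  h5_write_attr(path, "data", "channel_names", ts$channel_names)
  rhdf5::h5closeAll()
  invisible(path)
}

h5_write_attr <- function(path, dataset, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, dataset)
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, did, name)
}

#' Read a trial set from HDF5
#'
#' Validates the layout written by [save_trialset()]: a missing dataset or
#' attribute raises a format error naming the field, and an `expect_shape`
#' of `c(trials, channels)` is checked against the file.
#'
#' @param path Input `.h5` path.
#' @param expect_shape Optional `c(trials, channels)` to validate against.
#' @return A [trialset()].
#' @export
load_trialset <- function(path, expect_shape = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  content <- rhdf5::h5ls(path)
  have <- paste0(ifelse(content$group == "/", "/", paste0(content$group, "/")),
                 content$name)
  for (need in c("/data", "/ratings")) {
    if (!need %in% have) stop_format("missing dataset '", need, "' in ", path)
  }
  data <- rhdf5::h5read(path, "data")
  ratings <- rhdf5::h5read(path, "ratings")
  attrs <- rhdf5::h5readAttributes(path, "data")
  if (is.null(attrs$fs)) stop_format("missing attribute 'fs' on /data in ", path)
  channel_names <- attrs$channel_names
  truth <- NULL
  if ("/truth/A" %in% have) {
    truth <- list(A = rhdf5::h5read(path, "truth/A"),
                  noise_sd = as.numeric(rhdf5::h5read(path, "truth/noise_sd")))
    if ("/truth/sources" %in% have) {
      truth$sources <- structure(
        list(sources = rhdf5::h5read(path, "truth/sources"),
             fs = as.numeric(attrs$fs)),
        class = "source_panel")
    }
  }
  if (!is.null(expect_shape)) {
    d <- dim(data)
    if (d[1] != expect_shape[1] || d[2] != expect_shape[2]) {
      stop_format("shape mismatch: file has ", d[1], " trials x ", d[2],
                  " channels, expected ", expect_shape[1], " x ",
                  expect_shape[2])
    }
  }
  trialset(data, ratings, fs = as.numeric(attrs$fs),
           channel_names = as.character(channel_names), truth = truth)
}

#' Export ratings to CSV
#'
#' @param ts A [trialset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ts, path) {
  if (!inherits(ts, "trialset")) stop_arg("`ts` must be a trialset")
  df <- data.frame(trial = seq_len(nrow(ts$ratings)), ts$ratings)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature set to HDF5
#'
#' Datasets `/features` (trials x frames x features) and attributes with the
#' feature names and framing parameters.
#'
#' @param fset A `feature_set`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
save_features <- function(fset, path) {
  if (!inherits(fset, "feature_set")) stop_arg("`fset` must be a feature_set")
  d <- dim(fset$sequences[[1]])
  arr <- array(0, dim = c(length(fset$sequences), d[1], d[2]))
  for (k in seq_along(fset$sequences)) arr[k, , ] <- fset$sequences[[k]]
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "features")
  h5_write_attr(path, "features", "feature_names", fset$feature_names)
  h5_write_attr(path, "features", "kind", fset$kind)
  h5_write_attr(path, "features", "fs", fset$fs)
  h5_write_attr(path, "features", "window_s", fset$spec$window_s)
  h5_write_attr(path, "features", "step_s", fset$spec$step_s)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a feature set from HDF5
#'
#' @param path Input `.h5` path written by [save_features()].
#' @return A `feature_set`.
#' @export
load_features <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  arr <- rhdf5::h5read(path, "features")
  at <- rhdf5::h5readAttributes(path, "features")
  seqs <- lapply(seq_len(dim(arr)[1]), function(k) {
    m <- arr[k, , ]
    colnames(m) <- as.character(at$feature_names)
    m
  })
  structure(list(sequences = seqs,
                 feature_names = as.character(at$feature_names),
                 fs = as.numeric(at$fs),
                 spec = frame_spec(as.numeric(at$window_s),
                                   as.numeric(at$step_s)),
                 kind = as.character(at$kind)),
            class = "feature_set")
}

#' Checkpoint an autoencoder or classifier to HDF5
#'
#' Autoencoders store `/W1,/b1,...` plus the scaling vectors; classifiers
#' store the gate matrix, FC and output layers plus the architecture
#' attributes needed to rebuild the object.
#'
#' @param model An `sae_model` or `lstm_classifier`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (inherits(model, "sae_model")) {
    for (l in seq_along(model$W)) {
      rhdf5::h5write(model$W[[l]], path, paste0("W", l))
      rhdf5::h5write(model$b[[l]], path, paste0("b", l))
    }
    rhdf5::h5write(model$center, path, "center")
    rhdf5::h5write(model$scale, path, "scale")
    rhdf5::h5write(model$widths, path, "widths")
    rhdf5::h5write(as.integer(isTRUE(model$trained)), path, "trained")
    rhdf5::h5write("sae", path, "kind")
  } else if (inherits(model, "lstm_classifier")) {
    rhdf5::h5write(model$Wg, path, "Wg")
    rhdf5::h5write(model$bg, path, "bg")
    rhdf5::h5write(model$Wfc, path, "Wfc")
    rhdf5::h5write(model$bfc, path, "bfc")
    rhdf5::h5write(model$Wout, path, "Wout")
    rhdf5::h5write(model$bout, path, "bout")
    rhdf5::h5write(model$center, path, "center")
    rhdf5::h5write(model$scale, path, "scale")
    sp <- model$spec
    rhdf5::h5write(c(sp$input_dim, sp$seq_len, sp$lstm_hidden, sp$fc_units,
                     sp$output_units), path, "widths")
    rhdf5::h5write(c(sp$dropout_lstm, sp$dropout_fc), path, "dropout")
    rhdf5::h5write(as.integer(isTRUE(model$trained)), path, "trained")
    rhdf5::h5write("lstm", path, "kind")
  } else {
    stop_arg("`model` must be an sae_model or lstm_classifier")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Restore a checkpointed model
#'
#' @param path `.h5` path written by [save_checkpoint()].
#' @return The restored `sae_model` or `lstm_classifier`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  kind <- as.character(rhdf5::h5read(path, "kind"))
  if (kind == "sae") {
    widths <- as.integer(rhdf5::h5read(path, "widths"))
    nl <- length(widths) - 1L
    W <- lapply(seq_len(nl), function(l) {
      m <- rhdf5::h5read(path, paste0("W", l))
      matrix(m, widths[l + 1L], widths[l])
    })
    b <- lapply(seq_len(nl), function(l) as.numeric(rhdf5::h5read(path, paste0("b", l))))
    m <- sae_model(W, b, center = as.numeric(rhdf5::h5read(path, "center")),
                   scale = as.numeric(rhdf5::h5read(path, "scale")),
                   trained = as.integer(rhdf5::h5read(path, "trained")) == 1L)
    m
  } else if (kind == "lstm") {
    w <- as.integer(rhdf5::h5read(path, "widths"))
    dr <- as.numeric(rhdf5::h5read(path, "dropout"))
    sp <- classifier_spec(w[1], w[2], w[3], w[4], w[5], dr[1], dr[2])
    model <- lstm_init(sp, seed = 1)
    model$Wg <- matrix(rhdf5::h5read(path, "Wg"), w[1] + w[3], 4L * w[3])
    model$bg <- as.numeric(rhdf5::h5read(path, "bg"))
    model$Wfc <- matrix(rhdf5::h5read(path, "Wfc"), w[2] * w[3], w[4])
    model$bfc <- as.numeric(rhdf5::h5read(path, "bfc"))
    model$Wout <- matrix(rhdf5::h5read(path, "Wout"), w[4], w[5])
    model$bout <- as.numeric(rhdf5::h5read(path, "bout"))
    model$center <- as.numeric(rhdf5::h5read(path, "center"))
    model$scale <- as.numeric(rhdf5::h5read(path, "scale"))
    model$trained <- as.integer(rhdf5::h5read(path, "trained")) == 1L
    model
  } else {
    stop_format("unknown checkpoint kind '", kind, "' in ", path)
  }
}

#' Persist a cross-validation report
#'
#' Writes a JSON report (arm, counts, per-fold accuracies, mean accuracy,
#' any comparison p-values) and a CSV of the fold table next to it.
#'
#' @param report A `cv_report`.
#' @param path Output `.json` path; the CSV replaces the extension.
#' @param comparisons Optional tibble of paired-test results to embed.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path, comparisons = NULL) {
  if (!inherits(report, "cv_report")) stop_arg("`report` must be a cv_report")
  if (!nrow(report$folds)) stop_arg("report contains no folds")
  payload <- list(arm = as.list(report$arm), dimension = report$dimension,
                  k = report$k, seed = report$seed,
                  n_total = report$n_total, n_kept = report$n_kept,
                  n_balanced = report$n_balanced,
                  folds = report$folds,
                  mean_accuracy = report$mean_accuracy)
  if (!is.null(comparisons)) payload$comparisons <- comparisons
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_format("cannot write report to ", path)
  write.csv(report$folds, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' Reload a JSON cross-validation report
#'
#' @param path `.json` path written by [save_report()].
#' @return A `cv_report`.
#' @export
load_report <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(folds = as_tibble(p$folds),
                 mean_accuracy = p$mean_accuracy,
                 arm = unlist(p$arm), dimension = p$dimension,
                 k = p$k, seed = p$seed, n_total = p$n_total,
                 n_kept = p$n_kept, n_balanced = p$n_balanced),
            class = "cv_report")
}

#' Pipeline configuration
#'
#' One plain-text (YAML-compatible) configuration fully determines a run:
#' sampling rate, framing, architecture widths, labeling thresholds, folds
#' and seeds.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sampling_rate = 128, window_s = 1, overlap_fraction = 0.5,
    n_trials = 40, n_channels = 32, n_sources = 12, duration_s = 63,
    sae_layers = c(32, 64, 12), lstm_hidden = 125, fc_units = 125,
    dropout = 0.2,
    bands = c("theta", "alpha", "beta", "gamma"),
    label_high_threshold = 5.5, label_low_threshold = 4.5,
    n_folds = 10, effect_size = 3, rating_noise_sd = 0.5, noise_sd = 0,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_arg("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1) {
    stop_arg("overlap_fraction must lie in [0, 1)")
  }
  if (cfg$label_low_threshold > cfg$label_high_threshold) {
    stop_arg("label_low_threshold must not exceed label_high_threshold")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of config fields; omitted fields keep defaults.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_format("config must be a YAML mapping")
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "pipeline_config")) stop_arg("`cfg` must be a pipeline_config")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_frame_spec <- function(cfg) {
  frame_spec(window_s = cfg$window_s,
             step_s = cfg$window_s * (1 - cfg$overlap_fraction))
}
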