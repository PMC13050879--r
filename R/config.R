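# Layered run configuration: built-in defaults < config file < overrides.

default_run_config <- function() {
  list(
    data = list(bundle = NULL, channels = NULL),
    preprocess = list(band_low = 0.5, band_high = 30, filter_order = 4,
                      crop_start = NULL, crop_end = NULL),
    augment = list(n_segments = 8, noise_sigma = 0.2, multiplier = 1),
    model = list(F1 = 16, F2 = 32, pool1 = 75, pool2 = 3, dropout = 0.3,
                 cbam_reduction = 8, classifier_hidden = 0,
                 spatial_mode = "depthwise"),
    sat = list(n_heads = 4, n_layers = 6, window = 4, stride = 1,
               top_k = "auto", ffn_expansion = 0, dropout = 0.3),
    train = list(test_fraction = 0.2, val_fraction_of_train = 0.2,
                 n_repeats = 5, batch_size = 32, max_epochs = 100,
                 lr = 0.001),
    simulate = list(n_trials_per_class = 72, n_classes = 2,
                    channels = "c3czc4_3", fs = 250, duration = 4,
                    snr = 1, erd_depth = 1, noise_exponent = 1),
    seed = 1,
    out = "runs")
}

merge_config <- function(base, upd, path = "") {
  for (key in names(upd)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(upd[[key]]))
        stop("config key ", full, " must be a section", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], upd[[key]], full)
    } else {
      base[[key]] <- coerce_like(base[[key]], upd[[key]], full)
    }
  }
  base
}

coerce_like <- function(old, new, key) {
  if (is.null(old)) return(new)
  if (identical(key, "sat.top_k")) return(new)  # "auto" or integer
  if (is.numeric(old)) {
    val <- suppressWarnings(as.numeric(new))
    if (anyNA(val)) stop("config key ", key, " must be numeric", call. = FALSE)
    return(val)
  }
  if (is.logical(old)) {
    val <- as.logical(new)
    if (anyNA(val)) stop("config key ", key, " must be logical", call. = FALSE)
    return(val)
  }
  as.character(new)
}

#' Resolve a layered run configuration
#'
#' Applies, in order of increasing precedence: built-in defaults, an
#' optional YAML config file, and `key=value` command-line overrides with
#' dotted section paths (e.g. `sat.n_heads=8`). Unknown keys and values of
#' the wrong type are rejected by name, and cross-field invariants (head
#' divisibility, band ordering, fractions) are validated.
#'
#' @param file optional YAML file path.
#' @param overrides character vector of `section.key=value` strings.
#' @return the resolved configuration (nested named list).
#' @export
resolve_config <- function(file = NULL, overrides = character()) {
  cfg <- default_run_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    loaded <- yaml::read_yaml(file)
    if (length(loaded)) cfg <- merge_config(cfg, loaded)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("override must be key=value: ", ov, call. = FALSE)
    path <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    upd <- kv[2L]
    for (p in rev(path)) upd <- stats::setNames(list(upd), p)
    cfg <- merge_config(cfg, upd)
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$model$F2 %% cfg$sat$n_heads != 0)
    stop(sprintf("model.F2 (%d) must be divisible by sat.n_heads (%d)",
                 cfg$model$F2, cfg$sat$n_heads), call. = FALSE)
  if (cfg$preprocess$band_low >= cfg$preprocess$band_high)
    stop("preprocess: band_low must be below band_high", call. = FALSE)
  with(cfg$train, {
    if (test_fraction <= 0 || test_fraction >= 1 ||
        val_fraction_of_train <= 0 || val_fraction_of_train >= 1)
      stop("train fractions must lie in (0, 1)", call. = FALSE)
  })
  invisible(cfg)
}

# model_config from the nested run config plus data geometry
config_to_model <- function(cfg, C, T, n_classes, fs) {
  m <- cfg$model
  s <- cfg$sat
  model_config(C = C, T = T, n_classes = n_classes, fs = fs,
               F1 = m$F1, F2 = m$F2, pool1 = m$pool1, pool2 = m$pool2,
               dropout = m$dropout, cbam_reduction = m$cbam_reduction,
               classifier_hidden = m$classifier_hidden,
               spatial_mode = m$spatial_mode,
               sat = sat_config(d_model = m$F2, n_heads = s$n_heads,
                                n_layers = s$n_layers, window = s$window,
                                stride = s$stride, top_k = s$top_k,
                                ffn_expansion = s$ffn_expansion,
                                dropout = s$dropout))
}

# ---- model checkpoints -----------------------------------------------------

#' Save a fitted decoder to a checkpoint directory
#'
#' Weights and batch-norm statistics go to little-endian float64 binaries;
#' the architecture configuration and format version go to a JSON snapshot,
#' so a checkpoint is self-describing.
#'
#' @param model a fitted `mi_decoder`.
#' @param path checkpoint directory to create.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mi_decoder"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  snap <- list(format_version = 1L,
               config = cfg[c("C", "T", "fs", "n_classes", "F1", "F2",
                              "temporal_kernels", "pool1", "pae_kernels",
                              "pool2", "dropout", "cbam_reduction",
                              "classifier_hidden", "spatial_mode")],
               sat = unclass(cfg$sat), best_epoch = model$best_epoch,
               n_parameters = model$n_parameters, seed = model$seed)
  jsonlite::write_json(snap, file.path(path, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "params.f64"), "wb")
  writeBin(flatten_params(model$params), con, size = 8L, endian = "little")
  close(con)
  con <- file(file.path(path, "state.f64"), "wb")
  writeBin(flatten_params(model$state), con, size = 8L, endian = "little")
  close(con)
  utils::write.csv(model$history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load a decoder checkpoint
#'
#' @param path directory written by [save_checkpoint()].
#' @return a `mi_decoder` (without training history beyond the stored log).
#' @export
load_checkpoint <- function(path) {
  snap <- jsonlite::read_json(file.path(path, "checkpoint.json"),
                              simplifyVector = TRUE)
  cc <- snap$config
  cfg <- model_config(C = cc$C, T = cc$T, n_classes = cc$n_classes,
                      fs = cc$fs, F1 = cc$F1, F2 = cc$F2,
                      temporal_kernels = cc$temporal_kernels,
                      pool1 = cc$pool1, pae_kernels = cc$pae_kernels,
                      pool2 = cc$pool2, dropout = cc$dropout,
                      cbam_reduction = cc$cbam_reduction,
                      classifier_hidden = cc$classifier_hidden,
                      spatial_mode = cc$spatial_mode,
                      sat = do.call(sat_config, as.list(snap$sat)))
  skel <- init_params(cfg, seed = 1)
  sskel <- init_state(cfg)
  con <- file(file.path(path, "params.f64"), "rb")
  theta <- readBin(con, "double", n = length(flatten_params(skel)),
                   size = 8L, endian = "little")
  close(con)
  con <- file(file.path(path, "state.f64"), "rb")
  sv <- readBin(con, "double", n = length(flatten_params(sskel)),
                size = 8L, endian = "little")
  close(con)
  hist_file <- file.path(path, "history.csv")
  structure(
    list(params = unflatten_params(theta, skel),
         state = unflatten_params(sv, sskel), config = cfg,
         history = if (file.exists(hist_file)) utils::read.csv(hist_file)
                   else NULL,
         best_epoch = snap$best_epoch, classes = seq_len(cfg$n_classes) - 1L,
         n_parameters = snap$n_parameters, seed = snap$seed),
    class = "mi_decoder")
}

# ---- pipeline runner -------------------------------------------------------

#' Run one pipeline stage
#'
#' Dispatches the named stage with a resolved configuration, writing its
#' artifacts plus a config snapshot (`config_snapshot.yaml`) and a
#' structured JSON report into the output directory, so every run directory
#' is self-describing. Deterministic given `cfg$seed`. Input files are
#' never mutated.
#'
#' @param cmd one of `"simulate"`, `"preprocess"`, `"augment"`, `"train"`,
#'   `"eval"`, `"count-params"`.
#' @param cfg a configuration from [resolve_config()].
#' @param data path to an input bundle (stages after `simulate`).
#' @param checkpoint path to a model checkpoint (for `eval`).
#' @param out output directory (defaults to `cfg$out`).
#' @return stage result, invisibly (bundle path, `eval_report`, or count).
#' @export
run_pipeline <- function(cmd = c("simulate", "preprocess", "augment",
                                 "train", "eval", "count-params"),
                         cfg = resolve_config(), data = NULL,
                         checkpoint = NULL, out = NULL) {
  cmd <- match.arg(cmd)
  out <- out %||% cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config_snapshot.yaml"))
  report <- list(command = cmd, seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("mieeg")))

  need_data <- function() {
    if (is.null(data)) stop(cmd, " requires --data <bundle>", call. = FALSE)
    read_epochs(data)
  }

  result <- switch(
    cmd,
    "simulate" = {
      s <- cfg$simulate
      spec <- mi_synth_spec(n_trials_per_class = s$n_trials_per_class,
                            n_classes = s$n_classes, channels = s$channels,
                            fs = s$fs, duration = s$duration, snr = s$snr,
                            erd_depth = s$erd_depth,
                            noise_exponent = s$noise_exponent,
                            seed = derive_seed(cfg$seed, "simulate"))
      x <- simulate_mi_eeg(spec)
      bp <- file.path(out, "bundle")
      write_epochs(x, bp)
      report$n_trials <- n_trials(x)
      bp
    },
    "preprocess" = {
      x <- need_data()
      p <- cfg$preprocess
      x <- bandpass_epochs(x, p$band_low, p$band_high, p$filter_order)
      if (!is.null(p$crop_start) && !is.null(p$crop_end))
        x <- crop_epochs(x, p$crop_start, p$crop_end)
      x <- zscore_epochs(x)
      bp <- file.path(out, "bundle")
      write_epochs(x, bp)
      bp
    },
    "augment" = {
      x <- need_data()
      a <- cfg$augment
      x <- build_augmented_train_set(x, n_segments = a$n_segments,
                                     noise_sigma = a$noise_sigma,
                                     multiplier = a$multiplier,
                                     seed = derive_seed(cfg$seed, "augment"))
      bp <- file.path(out, "bundle")
      write_epochs(x, bp)
      bp
    },
    "train" = {
      x <- need_data()
      mcfg <- config_to_model(cfg, n_channels(x), n_samples(x),
                              n_classes(x), x$fs)
      proto <- train_protocol(
        test_fraction = cfg$train$test_fraction,
        val_fraction_of_train = cfg$train$val_fraction_of_train,
        n_repeats = cfg$train$n_repeats,
        batch_size = cfg$train$batch_size,
        max_epochs = cfg$train$max_epochs, lr = cfg$train$lr,
        augment = cfg$augment, seed = derive_seed(cfg$seed, "protocol"))
      rep_ <- run_protocol(x, proto, mcfg, verbose = TRUE)
      report$accuracy <- rep_$accuracy
      report$kappa <- rep_$kappa
      report$per_repeat <- rep_$per_repeat
      report$confusion <- rep_$confusion
      rep_
    },
    "eval" = {
      if (is.null(checkpoint))
        stop("eval requires --checkpoint <dir>", call. = FALSE)
      model <- load_checkpoint(checkpoint)
      x <- need_data()
      if (model$config$C != n_channels(x))
        stop(sprintf("checkpoint expects %d channels, bundle has %d",
                     model$config$C, n_channels(x)), call. = FALSE)
      rep_ <- evaluate(model, x)
      report$accuracy <- rep_$accuracy
      report$kappa <- rep_$kappa
      report$confusion <- rep_$confusion
      rep_
    },
    "count-params" = {
      mcfg <- config_to_model(cfg, C = 22L, T = 1000L, n_classes = 4L,
                              fs = 250)
      total <- count_parameters(mcfg)
      report$total <- as.integer(total)
      report$breakdown <- as.list(attr(total, "breakdown"))
      total
    })

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
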