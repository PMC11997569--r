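#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages. Unknown keys are rejected by
#' [run_pipeline()]'s schema check before any stage runs. Stored as JSON for
#' file-based configuration (see [read_pipeline_config()]).
#'
#' Sections: `io` (input CSV paths or `"simulate"`; `scale` one of `"none"`,
#' `"per_subject"` — per-subject min-max is appropriate for real multi-class
#' recordings but erases class structure in single-class-per-subject
#' synthetic streams), `simulate`, `preprocess`, `split`, `augment`,
#' `features`, `balance`, `model`, `train`.
#'
#' @param seed global seed; every stage derives its own child seed from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    run_dir = NULL,
    io = list(input = "simulate", scale = "none"),
    simulate = list(n_per_class = 10L, session_lengths_s = c(330, 330),
                    inter_session_gap_s = 1800),
    preprocess = list(delta = 900, window_s = 60, overlap = 0.5,
                      completeness = 0.95),
    split = list(fraction = 0.8, by = "window"),
    augment = list(enabled = TRUE, sigma = 0.02, copies = 1L),
    features = list(n_subframes = 12L, n_bins = 64L, hrv = TRUE),
    balance = list(enabled = TRUE, k = 5L),
    model = list(variant = "full", n_blocks = 3L, filters = c(32L, 64L, 128L),
                 kernel = 3L, pool = 2L, dropout = 0.3, fc_m = 128L,
                 fc_n = 64L, n_classes = 3L),
    train = list(eta = 1e-3, lambda = 1e-4, epochs = 30L, batch_size = 64L,
                 patience = 10L)
  )
}

.merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stopf("unknown config key '%s%s'", path, nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]],
                                  paste0(path, nm, "."))
    else base[nm] <- list(user[[nm]])  # keeps NULL values as present keys
  }
  base
}

#' Read and validate a JSON pipeline configuration file
#'
#' @param path JSON file with any subset of the keys of
#'   [default_pipeline_config()]; unknown keys are an error.
#' @return A complete validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  .merge_config(default_pipeline_config(), user)
}

#' Stratified train/evaluation split of a window list
#'
#' Per class, `round(fraction * n_class)` windows are drawn (seeded) into the
#' training split, keeping both splits' class proportions within one window
#' of exact. The splits are disjoint, their union is the input, and they
#' carry a `split` attribute (`"train"` / `"eval"`) consumed by the
#' augmentation leakage guard.
#'
#' @param windows list of labelled `window` objects.
#' @param fraction training fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return List with `train` and `eval` window lists.
#' @export
split_stratified <- function(windows, fraction = 0.8, seed = 1L) {
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0,1)")
  labs <- vapply(windows, function(w) as.integer(w$label), integer(1))
  counts <- table(labs)
  assert_that(all(counts >= 2), "every class needs >= 2 windows to split")
  train_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (cl in names(counts)) {
      idx <- which(labs == as.integer(cl))
      n_tr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  tr <- windows[train_idx]
  ev <- windows[-train_idx]
  attr(tr, "split") <- "train"
  attr(ev, "split") <- "eval"
  list(train = tr, eval = ev)
}

#' Stratified split by subject
#'
#' Leakage-safe alternative: whole subjects are assigned to one split, so
#' overlapping windows from one session can never straddle the boundary.
#' Proportions are approximate at small subject counts.
#'
#' @inheritParams split_stratified
#' @return List with `train` and `eval` window lists.
#' @export
split_by_subject <- function(windows, fraction = 0.8, seed = 1L) {
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0,1)")
  subj <- vapply(windows, function(w) as.character(w$subject), character(1))
  labs <- vapply(windows, function(w) as.integer(w$label), integer(1))
  slab <- vapply(split(labs, subj), function(v) v[1], integer(1))
  train_subj <- character(0)
  with_seed(derive_seed(seed, "split_subject"), {
    for (cl in unique(slab)) {
      s <- names(slab)[slab == cl]
      n_tr <- max(1L, min(length(s) - 1L, round(fraction * length(s))))
      train_subj <- c(train_subj, sample(s, n_tr))
    }
  })
  tr <- windows[subj %in% train_subj]
  ev <- windows[!subj %in% train_subj]
  attr(tr, "split") <- "train"
  attr(ev, "split") <- "eval"
  list(train = tr, eval = ev)
}

.assert_no_synthetic <- function(windows, where) {
  synth <- vapply(windows, function(w) isTRUE(w$synthetic), logical(1))
  assert_that(!any(synth), "synthetic window leaked into the %s split", where)
}

.stage <- function(log, name, ...) {
  msg <- sprintf("[%s] %s", name, sprintf(...))
  if (log) message(msg)
  msg
}

#' Run the full pipeline
#'
#' Stage order: simulate (or read) -> optional per-subject min-max scaling ->
#' session segmentation -> windowing -> stratified 80/20 split (by window by
#' default; `split$by = "subject"` for the leakage-safe alternative) ->
#' jitter augmentation (training split only) -> dual-domain feature
#' extraction -> standardization (fitted on training rows) -> SMOTE
#' (training split only) -> model training with early stopping ->
#' evaluation. Provenance flags are audited so no augmented or SMOTE row can
#' reach the evaluation split. A manifest (config, seed, config hash, stage
#' counts) sufficient to reproduce the run bit-for-bit is returned and, when
#' `run_dir` is set, written alongside the report.
#'
#' @param config a configuration list, see [default_pipeline_config()].
#' @param streams optional list of [recording_stream()]s; overrides `io$input`.
#' @param verbose log stage progress via `message()`.
#' @return List with `model`, `report`, `manifest`, `history`, `train_ds`,
#'   `eval_ds` and `run_dir` (or `NULL`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), streams = NULL,
                         verbose = FALSE) {
  config <- .merge_config(default_pipeline_config(), config)
  seed <- config$seed
  logl <- character(0)
  log1 <- function(name, ...) logl <<- c(logl, .stage(verbose, name, ...))

  # -- acquire streams --------------------------------------------------------
  if (is.null(streams)) {
    if (identical(config$io$input, "simulate")) {
      spec <- synth_spec(
        session_lengths_s = config$simulate$session_lengths_s,
        inter_session_gap_s = config$simulate$inter_session_gap_s,
        seed = derive_seed(seed, "simulate"))
      streams <- generate_dataset(spec, separability_design(),
                                  n_per_class = config$simulate$n_per_class)
      log1("simulate", "%d streams", length(streams))
    } else {
      streams <- list()
      for (p in config$io$input) {
        st <- read_wide_csv(p, delta = config$preprocess$delta)
        streams <- c(streams, if (inherits(st, "recording_stream")) list(st)
                              else st)
      }
      log1("read", "%d streams from %d file(s)", length(streams),
           length(config$io$input))
    }
  }

  if (identical(config$io$scale, "per_subject")) {
    streams <- lapply(streams, minmax_scale)
    log1("scale", "per-subject min-max applied")
  }

  # -- segment and window -----------------------------------------------------
  windows <- windows_from_streams(
    streams, delta = config$preprocess$delta,
    length_s = config$preprocess$window_s,
    overlap = config$preprocess$overlap,
    completeness_fraction = config$preprocess$completeness)
  assert_that(length(windows) > 0, "no windows survived preprocessing")
  log1("window", "%d windows", length(windows))

  sp <- if (identical(config$split$by, "subject"))
    split_by_subject(windows, config$split$fraction, seed)
  else split_stratified(windows, config$split$fraction, seed)
  .assert_no_synthetic(sp$eval, "evaluation")
  log1("split", "train %d / eval %d", length(sp$train), length(sp$eval))

  # -- augment (train only) ---------------------------------------------------
  train_windows <- sp$train
  if (isTRUE(config$augment$enabled)) {
    train_windows <- augment_training_set(
      train_windows,
      augment_spec(sigma = config$augment$sigma,
                   n_jitter_copies = config$augment$copies,
                   seed = derive_seed(seed, "augment")))
    log1("augment", "%d -> %d training windows", length(sp$train),
         length(train_windows))
  }

  # -- features ---------------------------------------------------------------
  fcfg <- feature_config(n_subframes = config$features$n_subframes,
                         n_bins = config$features$n_bins,
                         hrv = config$features$hrv)
  train_ds <- build_feature_dataset(train_windows, fcfg)
  eval_ds <- build_feature_dataset(sp$eval, fcfg)
  train_ds <- standardize_features(train_ds, seq_along(train_ds$y))
  eval_ds <- apply_feature_scaler(eval_ds, train_ds$scaler)
  assert_that(!any(eval_ds$synthetic), "synthetic row in evaluation features")
  log1("features", "X_t %s, X_f %s",
       paste(dim(train_ds$X_t), collapse = "x"),
       paste(dim(train_ds$X_f), collapse = "x"))

  # -- SMOTE (train only) -----------------------------------------------------
  if (isTRUE(config$balance$enabled)) {
    n0 <- length(train_ds$y)
    train_ds <- smote_dataset(train_ds, smote_spec(
      k = config$balance$k, seed = derive_seed(seed, "smote")))
    log1("balance", "%d -> %d rows after SMOTE", n0, length(train_ds$y))
  }

  # -- train ------------------------------------------------------------------
  mcfg <- model_config(n_blocks = config$model$n_blocks,
                       filters = config$model$filters,
                       kernel = config$model$kernel, pool = config$model$pool,
                       dropout = config$model$dropout,
                       fc_m = config$model$fc_m, fc_n = config$model$fc_n,
                       n_classes = config$model$n_classes)
  model <- build_model(mcfg, input_shape_of(train_ds),
                       variant = config$model$variant,
                       seed = derive_seed(seed, "model"))
  tc <- train_config(eta = config$train$eta, lambda = config$train$lambda,
                     epochs = config$train$epochs,
                     batch_size = config$train$batch_size,
                     patience = config$train$patience,
                     seed = derive_seed(seed, "train"))
  model <- train_model(model, train_ds, eval_ds, tc)
  log1("train", "%d epochs run (best %d)", nrow(model$history),
       model$best_epoch)

  # -- evaluate ---------------------------------------------------------------
  report <- evaluate_model(model, eval_ds)
  log1("evaluate", "accuracy %.4f macro-F1 %.4f", report$accuracy,
       report$macro["f1"])

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(config = config, seed = seed,
                   config_hash = sprintf("fnv1a32:%08x", as.integer(fnv1a32(cfg_json) %% 2^31)),
                   counts = list(streams = length(streams),
                                 windows = length(windows),
                                 train_rows = length(train_ds$y),
                                 eval_rows = length(eval_ds$y)),
                   package_version = as.character(utils::packageVersion("wearstress")))

  run_dir <- config$run_dir
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    jsonlite::write_json(report_as_list(report),
                         file.path(run_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(report), file.path(run_dir, "report.txt"))
    utils::write.csv(model$history, file.path(run_dir, "history.csv"),
                     row.names = FALSE)
    writeLines(logl, file.path(run_dir, "stages.log"))
  }

  list(model = model, report = report, manifest = manifest,
       history = model$history, train_ds = train_ds, eval_ds = eval_ds,
       run_dir = run_dir)
}

#' Run the ablation comparison (full / no_freq / no_time)
#'
#' Builds the data once from `config`, then trains the three architecture
#' variants on identical splits and features, returning their reports and a
#' comparison table.
#'
#' @param config a pipeline configuration list.
#' @param verbose log stage progress.
#' @return List with `reports` (per variant), `comparison` (data frame of
#'   accuracy and macro F1) and `datasets`.
#' @export
run_ablation <- function(config = default_pipeline_config(), verbose = FALSE) {
  config <- .merge_config(default_pipeline_config(), config)
  base <- config
  base$model$variant <- "full"
  first <- run_pipeline(base, verbose = verbose)
  reports <- list(full = first$report)
  models <- list(full = first$model)
  for (variant in c("no_freq", "no_time")) {
    mcfg <- model_config(n_blocks = config$model$n_blocks,
                         filters = config$model$filters,
                         kernel = config$model$kernel,
                         pool = config$model$pool,
                         dropout = config$model$dropout,
                         fc_m = config$model$fc_m, fc_n = config$model$fc_n,
                         n_classes = config$model$n_classes)
    m <- build_model(mcfg, input_shape_of(first$train_ds), variant = variant,
                     seed = derive_seed(config$seed, "model"))
    tc <- train_config(eta = config$train$eta, lambda = config$train$lambda,
                       epochs = config$train$epochs,
                       batch_size = config$train$batch_size,
                       patience = config$train$patience,
                       seed = derive_seed(config$seed, "train"))
    m <- train_model(m, first$train_ds, first$eval_ds, tc)
    reports[[variant]] <- evaluate_model(m, first$eval_ds)
    models[[variant]] <- m
  }
  comparison <- data.frame(
    variant = names(reports),
    accuracy = vapply(reports, `[[`, 0, "accuracy"),
    macro_f1 = vapply(reports, function(r) unname(r$macro["f1"]), 0),
    row.names = NULL)
  list(reports = reports, models = models, comparison = comparison,
       datasets = list(train = first$train_ds, eval = first$eval_ds))
}
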