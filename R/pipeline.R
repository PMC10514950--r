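# End-to-end orchestration: data -> 4 base models per task -> ensemble ->
# evaluation report and overlays.

#' Pipeline configuration
#'
#' @param data either a directory in the package disk format, or a list
#'   `list(synthetic = synthetic_config(...), n_train =, n_test =)` to
#'   generate data on the fly.
#' @param specs list of [model_spec()]s (default: the four selected base
#'   models).  The published pipeline initializes encoders from ImageNet;
#'   here the default is `"scratch"` because pretrained weights must be
#'   supplied locally (see [build_model()]).
#' @param train_cyto,train_nuc [train_config()]s per task.
#' @param ensemble an [ensemble_config()] (M is set to `length(specs)`).
#' @param eval an [eval_config()].
#' @param out_dir output root.
#' @param split_ratio,seed train/validation split ratio and global seed.
#' @param n_overlays number of qualitative overlay images to export.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data, specs = base_model_specs(),
                            train_cyto = train_config("cytoplasm"),
                            train_nuc = train_config("nucleus"),
                            ensemble = ensemble_config(M = length(specs)),
                            eval = eval_config(),
                            out_dir = tempfile("cytoseg_run_"),
                            split_ratio = 0.9, seed = 1L,
                            n_overlays = 3L) {
  if (!length(specs)) stop("at least one model spec required")
  structure(list(data = data, specs = specs, train_cyto = train_cyto,
                 train_nuc = train_nuc, ensemble = ensemble, eval = eval,
                 out_dir = out_dir, split_ratio = split_ratio,
                 seed = as.integer(seed), n_overlays = as.integer(n_overlays)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL            # hash the scientific config, not the path
  saveRDS(rapply(cfg, unclass, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full segmentation pipeline
#'
#' Per task (cytoplasm, nucleus): train every base-model spec (with
#' `n_runs` repeats and selection by validation loss), predict probability
#' maps on the held-out test set, average them, threshold at the ensemble
#' cut-off, and evaluate micro-averaged Dice/sensitivity/specificity with
#' bootstrap confidence intervals plus a paired bootstrap comparison of
#' the ensemble against the best single model.  All artifacts are written
#' under `config$out_dir` and listed in the returned manifest.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- data ----
  samples <- stage("data", {
    if (is.character(config$data)) {
      train <- load_dataset(file.path(config$data, "train"))
      test <- load_dataset(file.path(config$data, "test"))
      list(train = train, test = test)
    } else {
      sc <- config$data$synthetic
      train_dir <- file.path(out, "data", "train")
      test_dir <- file.path(out, "data", "test")
      generate_dataset(sc, config$data$n_train, train_dir)
      sc_test <- sc
      sc_test$seed <- sc$seed + 104729L   # disjoint stream for the test set
      generate_dataset(sc_test, config$data$n_test, test_dir)
      files <- c(files, list.files(train_dir, full.names = TRUE),
                 list.files(test_dir, full.names = TRUE))
      list(train = load_dataset(train_dir), test = load_dataset(test_dir))
    }
  })
  ids <- vapply(samples$train, `[[`, character(1), "id")
  split <- split_train_val(ids, config$split_ratio, config$seed)
  tr <- samples$train[ids %in% split$train]
  va <- samples$train[ids %in% split$val]

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_train = length(tr), n_val = length(va),
                   n_test = length(samples$test), tasks = list())

  for (task in c("cytoplasm", "nucleus")) {
    tcfg <- if (task == "cytoplasm") config$train_cyto else config$train_nuc
    ckpt_dir <- file.path(out, "checkpoints")
    dir.create(ckpt_dir, showWarnings = FALSE)
    maps_by_model <- list()
    metrics_by_model <- list()
    val_losses <- numeric()
    truths <- lapply(samples$test, task_mask, task = task)

    for (spec in config$specs) {
      nm <- spec_name(spec)
      if (verbose) message(sprintf("[%s] training %s", task, nm))
      run <- stage(paste0("train:", task, ":", nm), {
        cfg <- tcfg
        cfg$seed <- tcfg$seed + config$seed
        train_model_runs(spec, cfg, tr, va, verbose = verbose)
      })
      ck <- file.path(ckpt_dir, paste0(task, "_", nm, ".rds"))
      saveRDS(list(spec = spec, params = run$model$params,
                   state = run$model$state, history = run$history), ck)
      files <- c(files, ck)
      hist_file <- file.path(ckpt_dir, paste0(task, "_", nm, "_history.csv"))
      utils::write.csv(run$history, hist_file, row.names = FALSE)
      files <- c(files, hist_file)
      val_losses[nm] <- min(run$history$val_loss)
      maps <- stage(paste0("predict:", task, ":", nm), {
        predict(run$model, lapply(samples$test, `[[`, "image"), task = task)
      })
      maps_by_model[[nm]] <- maps
      preds <- lapply(maps, threshold_map, threshold = config$ensemble$threshold)
      metrics_by_model[[nm]] <- evaluate_micro(preds, truths)$metrics
    }

    ens_cfg <- config$ensemble
    ens_cfg$M <- length(maps_by_model)
    if (ens_cfg$method == "weighted" && is.null(ens_cfg$weights)) {
      ens_cfg$weights <- weights_from_val_losses(val_losses)
    }
    ens_maps <- lapply(seq_along(samples$test), function(i) {
      average_probabilities(lapply(maps_by_model, `[[`, i), ens_cfg)
    })
    ens_preds <- lapply(ens_maps, threshold_map,
                        threshold = ens_cfg$threshold)
    ens_eval <- evaluate_micro(ens_preds, truths)
    cis <- lapply(stats::setNames(nm = c("dice", "sensitivity", "specificity")),
                  function(k) bootstrap_ci(ens_eval$counts, k, config$eval))

    best_nm <- names(metrics_by_model)[which.max(
      vapply(metrics_by_model, `[[`, numeric(1), "dice"))]
    best_preds <- lapply(maps_by_model[[best_nm]], threshold_map,
                         threshold = ens_cfg$threshold)
    pv <- paired_bootstrap_test(ens_preds, best_preds, truths,
                                metric = "dice", config = config$eval)

    report <- summarize_report(metrics_by_model, ens_eval$metrics,
                               cis = cis,
                               pvals = c(dice_vs_best = pv$p_value))
    rep_file <- file.path(out, paste0("report_", task, ".json"))
    jsonlite::write_json(list(
      task = task,
      per_model = metrics_by_model,
      average = as.list(report$table["Average value", ]),
      ensemble = ens_eval$metrics,
      ci = cis,
      p_value_dice_vs_best = pv$p_value,
      best_single = best_nm), rep_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, rep_file)
    csv_file <- file.path(out, paste0("report_", task, ".csv"))
    utils::write.csv(report$table, csv_file)
    files <- c(files, csv_file)

    manifest$tasks[[task]] <- list(
      report = rep_file, checkpoint_dir = ckpt_dir,
      ensemble_dice = ens_eval$metrics$dice,
      member_mean_dice = mean(vapply(metrics_by_model, `[[`, numeric(1),
                                     "dice")),
      p_value_dice_vs_best = pv$p_value)

    manifest$tasks[[task]]$ensemble_preds <- ens_preds
  }

  # qualitative overlays from the stored per-task ensemble predictions
  if (config$n_overlays > 0) {
    ov_dir <- file.path(out, "overlays")
    dir.create(ov_dir, showWarnings = FALSE)
    k <- min(config$n_overlays, length(samples$test))
    for (i in seq_len(k)) {
      ov <- render_overlay(samples$test[[i]],
                           manifest$tasks$cytoplasm$ensemble_preds[[i]],
                           manifest$tasks$nucleus$ensemble_preds[[i]])
      f <- file.path(ov_dir, paste0(samples$test[[i]]$id, "_overlay.png"))
      write_image_file(ov, f)
      files <- c(files, f)
    }
  }
  manifest$tasks$cytoplasm$ensemble_preds <- NULL
  manifest$tasks$nucleus$ensemble_preds <- NULL

  mf <- file.path(out, "manifest.json")
  manifest$files <- sort(unique(c(files, mf)))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
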