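#' Run one end-to-end experiment
#'
#' Generates the task's dataset, trains the matching network, evaluates it and
#' (optionally) writes a metrics report plus, for detector tasks, a 3D
#' reconstruction of the first test sample. Idempotent under a fixed seed.
#'
#' @param name one of `"depth"`, `"deblur"`, `"nonoverlap"`,
#'   `"overlap_single"`, `"overlap_dual"`, `"overlap_resnet"`, `"dynamics"`.
#' @param config experiment configuration; `default_config(fast = TRUE)` is
#'   the desk-scale profile.
#' @param seed root seed for data generation and training.
#' @param output_dir if non-NULL, write `report.json`, metric CSVs and any
#'   reconstructions there.
#' @return A report list with the task's metrics, the fitted model, the
#'   config hash and the seed.
#' @export
run_experiment <- function(name = c("depth", "deblur", "nonoverlap",
                                    "overlap_single", "overlap_dual",
                                    "overlap_resnet", "dynamics"),
                           config = default_config(), seed = 1,
                           output_dir = NULL) {
  name <- rlang::arg_match(name)
  ds <- config$dataset
  tr <- config$train
  task <- switch(name, depth = "depth", deblur = "deblur",
                 nonoverlap = "depthmap", "detector")
  pick <- function(x) {
    if (length(x) > 1 && !is.null(names(x))) unname(x[[task]] %||% x[[1]])
    else unname(x[[1]])
  }
  cfg <- train_config(epochs = pick(tr$epochs), batch_size = tr$batch_size,
                      learning_rate = pick(tr$learning_rate),
                      seed = child_seed(seed, 1))
  n_det <- ds$n_train_detector %||% ds$n_train
  report <- switch(name,
    depth = {
      d <- build_depth_dataset(ds$n_train, ds$n_test, seed, config)
      model <- train_depth_classifier(d$train, cfg)
      pred <- predict(model, d$test)
      truth <- vapply(d$test$samples, `[[`, numeric(1), "depth_class")
      m <- depth_metrics(pred$depth_class, truth)
      list(metrics = list(accuracy = m$accuracy,
                          max_error_um = m$max_error_um,
                          n_test = ds$n_test),
           model = model)
    },
    deblur = {
      d <- build_deblur_dataset(ds$n_train, seed, config)
      test <- build_deblur_dataset(ds$n_test, child_seed(seed, 500000L), config)
      model <- train_deblur_net(d, cfg)
      pred <- predict(model, test)
      err <- vapply(seq_along(pred), function(i)
        mean_normalized_deviation(pred[[i]],
                                  normalize_view(test$samples[[i]]$target)),
        numeric(1))
      list(metrics = list(mean_error = mean(err), sd_error = stats::sd(err),
                          n_test = ds$n_test),
           model = model)
    },
    nonoverlap = {
      d <- build_nonoverlap_dataset(ds$n_train, seed, config)
      test <- build_nonoverlap_dataset(ds$n_test, child_seed(seed, 500000L),
                                       config)
      model <- train_depth_mapper(d, cfg)
      pred <- predict(model, test)
      err <- vapply(seq_along(pred), function(i)
        mean(abs(pred[[i]] - test$samples[[i]]$depth_map)), numeric(1))
      list(metrics = list(mean_error = mean(err), sd_error = stats::sd(err),
                          n_test = ds$n_test),
           model = model)
    },
    dynamics = {
      train <- build_overlap_dataset(n_det, dual = TRUE, seed = seed,
                                     config = config)
      seqs <- build_moving_cluster_set(ds$n_sequences,
                                       child_seed(seed, 500000L), config)
      model <- train_detector(train, resnet_detector_spec(2, 4), cfg)
      steps <- unlist(lapply(seqs$samples, `[[`, "steps"), recursive = FALSE)
      pred <- predict(model, steps)
      ss <- average_step_metrics(pred, steps)
      roc <- roc_curve(unlist(pred, recursive = FALSE),
                       unlist(lapply(steps, `[[`, "label_planes"),
                              recursive = FALSE))
      list(metrics = list(sensitivity = ss$sensitivity,
                          specificity = ss$specificity,
                          per_layer = ss$per_layer, auc = roc$auc,
                          n_sequences = ds$n_sequences),
           model = model, roc = roc)
    },
    { # overlap_single / overlap_dual / overlap_resnet
      dual <- name != "overlap_single"
      train <- build_overlap_dataset(n_det, dual = dual, seed = seed,
                                     config = config)
      test <- build_overlap_dataset(ds$n_test, dual = dual,
                                    seed = child_seed(seed, 500000L),
                                    config = config)
      spec <- if (name == "overlap_resnet") resnet_detector_spec(2, 4)
        else encoder_decoder_spec(if (dual) 2 else 1, 4)
      model <- train_detector(train, spec, cfg)
      pred <- predict(model, test)
      layer_err <- detector_layer_errors(pred, test$samples)
      ss <- average_step_metrics(pred, test$samples)
      roc <- roc_curve(unlist(pred, recursive = FALSE),
                       unlist(lapply(test$samples, `[[`, "label_planes"),
                              recursive = FALSE))
      rec <- reconstruct_3d(pred[[1]], test$samples[[1]]$depths_um,
                            sensor_geometry(config$optics$separation_um))
      list(metrics = list(layer_error_rates = layer_err,
                          mean_error = mean(layer_err),
                          middle_layer_error = mean(layer_err[2:3]),
                          sensitivity = ss$sensitivity,
                          specificity = ss$specificity,
                          auc = roc$auc, n_test = ds$n_test),
           model = model, roc = roc, reconstruction = rec)
    })
  report$name <- name
  report$seed <- seed
  report$config_hash <- config_hash(config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(c(list(name = name, seed = seed,
                                config_hash = report$config_hash),
                           report$metrics),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy(report$model),
                     file.path(output_dir, "training_log.csv"),
                     row.names = FALSE)
    if (!is.null(report$roc))
      utils::write.csv(report$roc$points, file.path(output_dir, "roc.csv"),
                       row.names = FALSE)
    if (!is.null(report$reconstruction))
      write_reconstruction(report$reconstruction,
                           file.path(output_dir, "reconstruction"))
    write_config(config, file.path(output_dir, "config_snapshot.yaml"))
  }
  report
}

# Mean over samples of per-sample sensitivity/specificity (per-layer table
# averaged the same way).
average_step_metrics <- function(pred, samples) {
  per <- lapply(seq_along(samples), function(i)
    suppressWarnings(
      sensitivity_specificity(pred[[i]], samples[[i]]$label_planes))$per_layer)
  all <- dplyr::bind_rows(per)
  per_layer <- dplyr::summarise(
    dplyr::group_by(all, .data$layer),
    error_rate = mean(.data$error_rate),
    sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    specificity = mean(.data$specificity, na.rm = TRUE), .groups = "drop")
  list(per_layer = per_layer,
       sensitivity = mean(per_layer$sensitivity),
       specificity = mean(per_layer$specificity))
}
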