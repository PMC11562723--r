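# The end-to-end workflow over a workspace directory. Each stage reads its
# inputs from, and writes its artifacts to, the workspace, so the CLI
# subcommands compose to exactly what run_pipeline() produces. Trained
# forests are deliberately not serialized (no binary artifacts): the train
# and predict stages re-fit deterministically from the written training
# table and the configured seeds.

field_path <- function(dir, var, hour) {
  file.path(dir, "fields", sprintf("%s_h%03d.csv", var, hour))
}

write_hour_fields <- function(dir, var, fields) {
  for (f in fields) if (!is.null(f)) write_field(f, field_path(dir, var, f$hour))
}

read_hour_fields <- function(dir, var, n_hours, grid = NULL,
                             allow_missing = FALSE) {
  out <- vector("list", n_hours)
  for (t in seq_len(n_hours)) {
    p <- field_path(dir, var, t - 1L)
    if (!file.exists(p)) {
      if (allow_missing) next
      stopf("missing field file '%s'", p)
    }
    out[[t]] <- read_field(p, grid)
  }
  out
}

log_line <- function(dir, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...),
      file = file.path(dir, "run_log.txt"), append = TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Pipeline stages over a workspace directory
#'
#' Each stage is an exported building block of [run_pipeline()]:
#' `pipeline_simulate` writes the synthetic scene (masked satellite AOD,
#' background AOD, meteorology, observations); `pipeline_gapfill` fills the
#' satellite gaps per hour; `pipeline_features` builds and writes the
#' training table; `pipeline_train` SMOTE-augments it, fits the pooled
#' forest and writes the OOB report; `pipeline_validate` runs the
#' configured cross-validations; `pipeline_predict` re-fits the forest
#' deterministically and writes gap-free hourly surfaces.
#'
#' @param config A [pipeline_config()].
#' @param dir Workspace directory (created if needed).
#' @return Each stage returns its main artifact invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
pipeline_simulate <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(dir, "fields"), recursive = TRUE, showWarnings = FALSE)
  scene <- simulate_scene(config$scene)
  write_hour_fields(dir, "sat_aod", scene$satellite_aod)
  write_hour_fields(dir, "bg_aod", scene$truth$background_aod)
  for (v in names(scene$truth$met))
    write_hour_fields(dir, v, scene$truth$met[[v]])
  write_observations(scene$observations, file.path(dir, "observations.csv"))
  n_masked <- vapply(scene$satellite_aod,
                     function(f) sum(is.na(f$values)), 1L)
  log_line(dir, "simulate: seed %d, grid %dx%d, %d hours",
           config$scene$seed, config$scene$n_rows, config$scene$n_cols,
           config$scene$n_hours)
  log_line(dir, "simulate: theoretical_r2 %.6f (noise sd %.6g)",
           scene$truth$theoretical_r2, scene$truth$noise_sd)
  log_line(dir, "simulate: masked cells per hour: %s",
           paste(n_masked, collapse = " "))
  log_line(dir, "simulate: %d observation rows (%d REF, %d LC sites)",
           nrow(scene$observations), config$scene$n_reference_sites,
           config$scene$n_lowcost_sites)
  invisible(scene)
}

#' @rdname pipeline_stages
#' @export
pipeline_gapfill <- function(config, dir) {
  nh <- config$scene$n_hours
  sat <- read_hour_fields(dir, "sat_aod", nh)
  grid <- sat[[1L]]$grid
  bg <- read_hour_fields(dir, "bg_aod", nh, grid)
  met <- lapply(MET_VARIABLES, function(v) read_hour_fields(dir, v, nh, grid))
  names(met) <- MET_VARIABLES
  gf <- gapfill_scene(sat, bg, met, config$gapfill_forest)
  write_hour_fields(dir, "filled_aod", gf$filled)
  rep <- list(oob_r2 = gf$oob_r2, oob_rmse = gf$oob_rmse,
              mean_oob_r2 = mean(gf$oob_r2, na.rm = TRUE),
              mean_oob_rmse = mean(gf$oob_rmse, na.rm = TRUE),
              n_skipped = gf$n_skipped, seed = config$gapfill_forest$seed)
  jsonlite::write_json(rep, file.path(dir, "gapfill_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(dir, "gapfill: mean OOB R2 %.4f, RMSE %.4g, %d hour(s) skipped",
           rep$mean_oob_r2, rep$mean_oob_rmse, gf$n_skipped)
  invisible(gf)
}

#' @rdname pipeline_stages
#' @export
pipeline_features <- function(config, dir) {
  nh <- config$scene$n_hours
  filled <- read_hour_fields(dir, "filled_aod", nh, allow_missing = TRUE)
  grid <- filled[[which(!vapply(filled, is.null, TRUE))[1L]]]$grid
  met <- lapply(MET_VARIABLES, function(v) read_hour_fields(dir, v, nh, grid))
  names(met) <- MET_VARIABLES
  obs <- read_observations(file.path(dir, "observations.csv"))
  tab <- build_pm25_table(filled, met, obs, default_feature_spec(),
                          wavelet_order = config$wavelet$order,
                          extension_mode = config$wavelet$extension_mode)
  data.table::fwrite(tab, file.path(dir, "table.csv"))
  log_line(dir, "features: %d rows (%d REF, %d LC), %d predictors",
           nrow(tab), sum(tab$source == "REF"), sum(tab$source == "LC"),
           length(predictor_names(tab, "pm25")))
  invisible(tab)
}

read_table <- function(dir) {
  p <- file.path(dir, "table.csv")
  if (!file.exists(p)) stopf("missing training table '%s'", p)
  as.data.frame(data.table::fread(p, colClasses = list(
    character = c("monitor_id", "source"), logical = "synthetic")))
}

augment_and_train <- function(config, tab) {
  flags <- identify_minority(tab, config$smote$minority_threshold)
  n_before <- nrow(tab)
  if (sum(flags) > config$smote$k_neighbors &&
      mean(flags) < config$smote$target_minority_fraction)
    tab <- smote(tab, flags, config$smote)
  model <- train_pm25(tab, config$pm25_forest)
  list(model = model, table = tab, n_synthetic = nrow(tab) - n_before)
}

#' @rdname pipeline_stages
#' @export
pipeline_train <- function(config, dir) {
  tab <- read_table(dir)
  tr <- augment_and_train(config, tab)
  oob <- oob_report(tr$model, tr$table)
  rep <- list(oob_r2 = oob$r2, oob_rmse = oob$rmse, n = oob$n,
              n_synthetic = tr$n_synthetic,
              importance = as.list(tr$model$importance),
              seed = config$pm25_forest$seed)
  jsonlite::write_json(rep, file.path(dir, "oob_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(dir, "train: %d real + %d synthetic rows, OOB R2 %.4f, RMSE %.4f",
           nrow(tab), tr$n_synthetic, oob$r2, oob$rmse)
  invisible(tr$model)
}

#' @rdname pipeline_stages
#' @export
pipeline_validate <- function(config, dir) {
  tab <- read_table(dir)
  tab <- tab[!tab$synthetic, , drop = FALSE]
  out <- list(k = config$cv$k, seed = config$seed)
  if ("random" %in% config$cv$schemes) {
    cvr <- kfold_cv(tab, config$cv$k, config$pm25_forest, config$smote,
                    seed = config$seed)
    out$random <- list(r2 = cvr$r2, rmse = cvr$rmse, fold_n = cvr$fold_n,
                       fold_mse = cvr$fold_mse)
  }
  if ("spatial" %in% config$cv$schemes) {
    cvs <- spatial_kfold_cv(tab, config$cv$k, config$pm25_forest,
                            config$smote, seed = config$seed)
    out$spatial <- list(r2 = cvs$r2, rmse = cvs$rmse, fold_n = cvs$fold_n,
                        fold_mse = cvs$fold_mse)
  }
  jsonlite::write_json(out, file.path(dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(out$random))
    log_line(dir, "validate: random %d-fold R2 %.4f RMSE %.4f",
             config$cv$k, out$random$r2, out$random$rmse)
  if (!is.null(out$spatial))
    log_line(dir, "validate: spatial %d-fold R2 %.4f RMSE %.4f",
             config$cv$k, out$spatial$r2, out$spatial$rmse)
  invisible(out)
}

#' @rdname pipeline_stages
#' @export
pipeline_predict <- function(config, dir) {
  nh <- config$scene$n_hours
  tab <- read_table(dir)
  tr <- augment_and_train(config, tab) # deterministic re-fit
  filled <- read_hour_fields(dir, "filled_aod", nh, allow_missing = TRUE)
  avail <- which(!vapply(filled, is.null, TRUE))
  grid <- filled[[avail[1L]]]$grid
  met <- lapply(MET_VARIABLES, function(v) read_hour_fields(dir, v, nh, grid))
  names(met) <- MET_VARIABLES
  spec <- default_feature_spec()
  surfaces <- vector("list", nh)
  for (t in avail) {
    surf <- predict_surface(tr$model, filled[[t]], met_at_hour(met, t), spec,
                            wavelet_order = config$wavelet$order,
                            extension_mode = config$wavelet$extension_mode)
    if (anyNA(surf$values))
      stopf("predicted surface for hour %d has missing cells", t - 1L)
    surfaces[[t]] <- surf
  }
  write_hour_fields(dir, "surface", surfaces)
  log_line(dir, "predict: %d gap-free surfaces written", length(avail))
  invisible(surfaces)
}

#' Run the full pipeline
#'
#' Simulate -> gap-fill -> features -> train -> validate -> predict, over a
#' workspace directory. Any stage failure aborts with the stage name and
#' cause. Reruns with the same config produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param dir Workspace directory.
#' @return Invisibly, a list with the CV report, OOB report and gap-fill
#'   summary (parsed from the written JSON artifacts).
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(dir, "run_log.txt"))
  write_pipeline_config(config, file.path(dir, "config.json"))
  log_line(dir, "pmwave %s on R %s; master seed %d",
           as.character(utils::packageVersion("pmwave")),
           paste(R.version$major, R.version$minor, sep = "."), config$seed)
  run_stage("simulate", pipeline_simulate(config, dir))
  run_stage("gapfill", pipeline_gapfill(config, dir))
  run_stage("features", pipeline_features(config, dir))
  run_stage("train", pipeline_train(config, dir))
  run_stage("validate", pipeline_validate(config, dir))
  run_stage("predict", pipeline_predict(config, dir))
  invisible(list(
    cv = jsonlite::fromJSON(file.path(dir, "cv_report.json")),
    oob = jsonlite::fromJSON(file.path(dir, "oob_report.json")),
    gapfill = jsonlite::fromJSON(file.path(dir, "gapfill_report.json"))))
}
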