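# The pooled PM2.5 model: one forest over all hours, trained on merged
# monitor observations with wavelet + raw features, rendering gap-free
# hourly concentration surfaces.

#' Build the pooled PM2.5 training table
#'
#' For every hour, merges the monitor records onto grid cells
#' ([merge_observations()]; reference monitors take precedence, co-located
#' records are averaged) and reads the feature matrix at the occupied cells.
#'
#' @param filled_aod Per-hour list of gap-free AOD [field()]s (`NULL`
#'   entries, e.g. hours skipped by gap filling, are omitted).
#' @param met Named list (variable -> per-hour list) of met [field()]s.
#' @param observations Monitor records (`site_id`, `source`, `x`, `y`,
#'   `hour`, `pm25`).
#' @param spec A [feature_spec()].
#' @param wavelet_order,extension_mode Passed to [assemble_features()].
#' @return Training table: meta columns (`cell`, `row`, `col`, `hour`,
#'   `monitor_id`, `source`, `synthetic = FALSE`), target `pm25`, and one
#'   column per feature.
#' @export
build_pm25_table <- function(filled_aod, met, observations,
                             spec = default_feature_spec(),
                             wavelet_order = 5L,
                             extension_mode = "symmetric") {
  hours_avail <- which(!vapply(filled_aod, is.null, TRUE))
  if (length(hours_avail) == 0L) stopf("no gap-free AOD fields supplied")
  out <- vector("list", length(hours_avail))
  for (i in seq_along(hours_avail)) {
    t <- hours_avail[i]
    fld <- filled_aod[[t]]
    merged <- merge_observations(observations, fld$grid, hour = fld$hour)
    if (nrow(merged) == 0L) next
    feats <- assemble_features(fld, met_at_hour(met, t), spec,
                               cells = merged$cell,
                               wavelet_order = wavelet_order,
                               extension_mode = extension_mode)
    out[[i]] <- cbind(
      data.frame(cell = merged$cell, row = merged$row, col = merged$col,
                 hour = fld$hour, monitor_id = merged$monitor_id,
                 source = merged$source, synthetic = FALSE,
                 pm25 = merged$pm25, stringsAsFactors = FALSE),
      as.data.frame(feats))
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stopf("no merged observations fall on the supplied hours")
  rownames(out) <- NULL
  out
}

#' Train the pooled PM2.5 forest
#'
#' @param table Training table (post-SMOTE) with at least 100 rows.
#' @param config A [forest_config()].
#' @return A `fitted_forest`.
#' @export
train_pm25 <- function(table, config = forest_config()) {
  if (nrow(table) < 100L)
    stopf("PM2.5 training needs at least 100 rows, got %d", nrow(table))
  fit_forest(table, target = "pm25", config = config)
}

#' Predict a gap-free PM2.5 surface for one hour
#'
#' Assembles the model's features for every grid cell and predicts; the
#' output has no missing cells and, by the averaging nature of the tree
#' ensemble, stays within the training-target range.
#'
#' @param model A `fitted_forest` from [train_pm25()].
#' @param filled_aod Gap-free AOD [field()] for the hour.
#' @param met Named list of met [field()]s for the hour.
#' @param spec The [feature_spec()] the model was trained with.
#' @param wavelet_order,extension_mode Passed to [assemble_features()].
#' @return A [field()] of predicted PM2.5 (ug/m3) with no missing cells.
#' @export
predict_surface <- function(model, filled_aod, met, spec,
                            wavelet_order = 5L,
                            extension_mode = "symmetric") {
  stopifnot(inherits(model, "fitted_forest"))
  cols <- feature_columns(spec)
  if (!identical(sort(cols), sort(model$predictors)))
    stopf("feature spec (%d features) does not match the model's predictors (%d)",
          length(cols), length(model$predictors))
  feats <- assemble_features(filled_aod, met, spec,
                             wavelet_order = wavelet_order,
                             extension_mode = extension_mode)
  pred <- predict(model, as.data.frame(feats))
  field(filled_aod$grid, pred, variable = "pm25_pred",
        hour = filled_aod$hour)
}
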