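# Per-hour AOD gap filling: a random forest learns observed satellite
# retrievals from the background-model AOD and meteorology at the same
# cells, then predicts the masked cells. Observed retrievals are never
# altered.

#' Build the gap-filling training table for one hour
#'
#' One row per cell with an observed satellite retrieval; predictors are the
#' background-model AOD plus all meteorological variables at that cell, the
#' target is the observed AOD. Rows with a missing predictor are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param satellite_aod Satellite AOD [field()] with gaps.
#' @param background_aod Gap-free background-model AOD [field()].
#' @param met Named list of gap-free meteorological [field()]s.
#' @return Data frame with meta columns `cell`, `row`, `col`, `hour`, target
#'   column `aod`, and predictors `bg_aod` + the met variable names.
#'   Attribute `n_dropped` counts rows lost to missing predictors.
#' @export
build_gapfill_table <- function(satellite_aod, background_aod, met) {
  stopifnot(inherits(satellite_aod, "field"), inherits(background_aod, "field"))
  grid <- satellite_aod$grid
  for (f in c(list(background_aod), met))
    if (!grid_equal(f$grid, grid))
      stopf("field '%s' grid %s does not match the satellite grid %s",
            f$variable, grid_desc(f$grid), grid_desc(grid))
  sat <- as.vector(t(satellite_aod$values))
  obs <- which(!is.na(sat))
  if (length(obs) == 0L)
    stopf("hour %d has zero observed satellite cells; the hour is unfillable",
          satellite_aod$hour)
  tab <- data.frame(cell = obs - 1L,
                    row = (obs - 1L) %/% grid$n_cols,
                    col = (obs - 1L) %% grid$n_cols,
                    hour = satellite_aod$hour,
                    aod = sat[obs])
  tab$bg_aod <- as.vector(t(background_aod$values))[obs]
  for (v in names(met)) tab[[v]] <- as.vector(t(met[[v]]$values))[obs]
  keep <- stats::complete.cases(tab)
  dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- dropped
  tab
}

#' Train the per-hour gap-filling forest
#'
#' @param table A [build_gapfill_table()] result with at least 50 rows.
#' @param config A [forest_config()]; the default widens the leaves
#'   (`min_leaf = 30`) so the forest averages retrieval noise out of its
#'   predictions instead of fitting it.
#' @return A `fitted_forest` with per-row OOB predictions and permutation
#'   importances. A constant target is fitted but flagged
#'   (`constant_target = TRUE`; OOB R2 is then undefined).
#' @export
train_gapfill <- function(table, config = forest_config(min_leaf = 30L)) {
  if (nrow(table) < 50L)
    stopf("gap-filling needs at least 50 observed cells, got %d", nrow(table))
  fit_forest(table, target = "aod", config = config)
}

#' Fill the gaps of a satellite AOD field
#'
#' Observed cells keep their retrievals bit for bit; missing cells receive
#' forest predictions from the background AOD and meteorology.
#'
#' @param model A `fitted_forest` from [train_gapfill()].
#' @param satellite_aod Satellite AOD [field()] with gaps.
#' @param background_aod,met Predictor fields on the same grid.
#' @return A gap-free [field()].
#' @export
fill_gaps <- function(model, satellite_aod, background_aod, met) {
  stopifnot(inherits(model, "fitted_forest"))
  expected <- c("bg_aod", names(met))
  if (!identical(model$predictors, expected))
    stopf("predictor mismatch: model was trained on (%s) but inputs provide (%s)",
          paste(model$predictors, collapse = ", "),
          paste(expected, collapse = ", "))
  grid <- satellite_aod$grid
  sat <- as.vector(t(satellite_aod$values))
  gaps <- which(is.na(sat))
  if (length(gaps) == 0L) return(satellite_aod)
  newdata <- data.frame(bg_aod = as.vector(t(background_aod$values))[gaps])
  for (v in names(met)) newdata[[v]] <- as.vector(t(met[[v]]$values))[gaps]
  sat[gaps] <- predict(model, newdata)
  field(grid, sat, variable = satellite_aod$variable, hour = satellite_aod$hour)
}

#' Gap-fill every hour of a scene
#'
#' Trains one forest per hour and fills that hour's field. Hours with zero
#' observed retrievals are skipped (their output stays `NULL`) and counted.
#'
#' @param satellite_aod Per-hour list of masked AOD [field()]s.
#' @param background_aod Per-hour list of background AOD [field()]s.
#' @param met Named list (variable -> per-hour list) of met [field()]s.
#' @param config A [forest_config()]; the per-hour fit seed is
#'   `config$seed + hour`.
#' @return List with `filled` (per-hour list of gap-free fields, `NULL` for
#'   skipped hours), `oob_r2`, `oob_rmse` (per-hour vectors), and
#'   `n_skipped`.
#' @export
gapfill_scene <- function(satellite_aod, background_aod, met,
                          config = forest_config(min_leaf = 30L)) {
  nh <- length(satellite_aod)
  filled <- vector("list", nh)
  oob_r2 <- rep(NA_real_, nh)
  oob_rmse <- rep(NA_real_, nh)
  skipped <- 0L
  for (t in seq_len(nh)) {
    sat <- satellite_aod[[t]]
    if (all(is.na(sat$values))) {
      skipped <- skipped + 1L
      next
    }
    met_t <- met_at_hour(met, t)
    tab <- build_gapfill_table(sat, background_aod[[t]], met_t)
    mod <- train_gapfill(tab, config = forest_config(
      n_trees = config$n_trees, m_try = config$m_try,
      min_leaf = config$min_leaf, seed = config$seed + t))
    ok <- is.finite(mod$oob)
    if (!mod$constant_target && any(ok)) {
      oob_r2[t] <- r2_score(tab$aod[ok], mod$oob[ok])
      oob_rmse[t] <- rmse(tab$aod[ok], mod$oob[ok])
    }
    filled[[t]] <- fill_gaps(mod, sat, background_aod[[t]], met_t)
  }
  list(filled = filled, oob_r2 = oob_r2, oob_rmse = oob_rmse,
       n_skipped = skipped)
}
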