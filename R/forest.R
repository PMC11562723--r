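# Random-forest infrastructure shared by the gap-filling and PM2.5 stages.
# Forests are bagged regression trees fitted with ranger; every fit is
# seeded and single-threaded, so identical inputs give identical ensembles.

#' Random-forest configuration
#'
#' Hyperparameters shared by the per-hour AOD gap-filling models and the
#' pooled PM2.5 model: 500 trees and 4 candidate variables per split.
#'
#' @param n_trees Number of trees (>= 1).
#' @param m_try Candidate predictors per split; capped at the number of
#'   predictors at fit time.
#' @param min_leaf Minimal terminal node size.
#' @param seed Integer seed for the ensemble.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, m_try = 4L, min_leaf = 5L,
                          seed = 1L) {
  if (!is_count(n_trees)) stopf("n_trees must be a positive integer")
  if (!is_count(m_try)) stopf("m_try must be a positive integer")
  if (!is_count(min_leaf)) stopf("min_leaf must be a positive integer")
  structure(list(n_trees = as.integer(n_trees), m_try = as.integer(m_try),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "forest_config")
}

#' @export
print.forest_config <- function(x, ...) {
  cat(sprintf("<forest_config> %d trees, mtry %d, min leaf %d, seed %d\n",
              x$n_trees, x$m_try, x$min_leaf, x$seed))
  invisible(x)
}

# reserved (non-predictor) column names of training tables
TABLE_META <- c("cell", "row", "col", "hour", "monitor_id", "source",
                "synthetic", "site_id", "x_obs", "y_obs")

#' Predictor column names of a training table
#' @param table Training-table data frame.
#' @param target Target column name.
#' @return Character vector of predictor column names, in table order.
#' @export
predictor_names <- function(table, target) {
  setdiff(names(table), c(TABLE_META, target))
}

fit_forest <- function(table, target, config, seed = NULL) {
  stopifnot(inherits(config, "forest_config"))
  preds <- predictor_names(table, target)
  if (length(preds) == 0L) stopf("training table has no predictor columns")
  if (config$m_try > length(preds))
    stopf("m_try = %d exceeds the %d available predictors",
          config$m_try, length(preds))
  y <- table[[target]]
  if (anyNA(y)) stopf("target '%s' contains missing values", target)
  x <- table[preds]
  if (anyNA(x)) stopf("predictors contain missing values; drop those rows first")
  constant <- isTRUE(var(y) == 0)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = config$m_try,
    min.node.size = config$min_leaf,
    importance = "permutation",
    seed = seed %||% config$seed,
    num.threads = 1L,
    oob.error = TRUE)
  structure(list(fit = fit, predictors = preds, target = target,
                 oob = fit$predictions,
                 importance = fit$variable.importance,
                 target_range = range(y),
                 constant_target = constant,
                 n = nrow(table)),
            class = "fitted_forest")
}

#' @export
print.fitted_forest <- function(x, ...) {
  cat(sprintf("<fitted_forest> target '%s', %d rows, %d predictors, %d trees%s\n",
              x$target, x$n, length(x$predictors), x$fit$num.trees,
              if (x$constant_target) " [constant target: OOB R2 undefined]" else ""))
  invisible(x)
}

#' Predict with a fitted forest
#' @param object A `fitted_forest`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fitted_forest <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stopf("newdata is missing predictor column(s): %s",
          paste(miss, collapse = ", "))
  predict(object$fit, data = newdata[object$predictors],
          num.threads = 1L)$predictions
}
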