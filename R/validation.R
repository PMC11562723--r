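# Model evaluation: coefficient-of-determination R2 and RMSE, pooled over
# out-of-bag predictions, random k-fold CV, and leave-monitors-out spatial
# CV. SMOTE rows may train folds but never enter a metric.

#' Coefficient of determination and root-mean-square error
#'
#' `r2_score` is `1 - SSres / SStot` (the coefficient of determination, not
#' a squared correlation); it is `NA` when the observations are constant.
#'
#' @param obs,pred Numeric vectors of equal length (>= 2).
#' @return A single number.
#' @export
r2_score <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) < 2L)
    stopf("obs and pred must have equal length >= 2")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) {
    warning("constant observations: R2 is undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((obs - pred)^2) / sst
}

#' @rdname r2_score
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) < 1L)
    stopf("obs and pred must have equal, positive length")
  sqrt(mean((obs - pred)^2))
}

new_cv_report <- function(scheme, k, fold_of_row, obs, pred, fold_monitors = NULL) {
  stopifnot(length(obs) == length(pred), length(fold_of_row) == length(obs))
  per_fold <- lapply(seq_len(k), function(f) {
    i <- fold_of_row == f
    list(n = sum(i), mse = if (any(i)) mean((obs[i] - pred[i])^2) else NA_real_)
  })
  structure(list(
    scheme = scheme, k = k,
    fold_of_row = fold_of_row,
    fold_monitors = fold_monitors,
    r2 = r2_score(obs, pred),
    rmse = rmse(obs, pred),
    fold_n = vapply(per_fold, `[[`, 1, "n"),
    fold_mse = vapply(per_fold, `[[`, 1, "mse"),
    obs = obs, pred = pred),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s %d-fold: pooled R2 = %.3f, RMSE = %.3f (n = %d)\n",
              x$scheme, x$k, x$r2, x$rmse, length(x$obs)))
  invisible(x)
}

check_cv_table <- function(table, target) {
  if (!is.null(table$synthetic) && any(table$synthetic))
    stopf("cross-validation input must contain only real rows; SMOTE is applied inside each fold")
  if (is.null(table[[target]])) stopf("table has no target column '%s'", target)
}

fit_fold <- function(train, test, target, config, smote_cfg, fold) {
  if (!is.null(smote_cfg)) {
    flags <- identify_minority(train, smote_cfg$minority_threshold, target)
    m <- sum(flags)
    if (m > smote_cfg$k_neighbors &&
        m / nrow(train) < smote_cfg$target_minority_fraction) {
      cfg_f <- smote_cfg
      cfg_f$seed <- smote_cfg$seed + fold
      train <- smote(train, flags, cfg_f, target)
    }
  }
  cfg <- config
  cfg$seed <- config$seed + fold
  mod <- fit_forest(train, target, cfg)
  predict(mod, test)
}

#' Random k-fold cross-validation
#'
#' Rows are partitioned into `k` near-equal folds at random; for each fold
#' the remaining rows (optionally SMOTE-augmented inside the fold) train a
#' forest that predicts the held-out rows. Pooled R2 and RMSE are computed
#' over the concatenation of all test-fold predictions.
#'
#' @param table Real-only training table.
#' @param k Number of folds (>= 2).
#' @param config A [forest_config()]; fold fits use `config$seed + fold`.
#' @param smote_cfg Optional [smote_config()] applied to the training rows
#'   of each fold (never to test rows).
#' @param seed Integer seed for the partition.
#' @param target Target column (default `"pm25"`).
#' @return A `cv_report`.
#' @export
kfold_cv <- function(table, k = 10L, config = forest_config(),
                     smote_cfg = NULL, seed = 1L, target = "pm25") {
  check_cv_table(table, target)
  n <- nrow(table)
  if (!is_count(k, min = 2L)) stopf("k must be an integer >= 2")
  if (n < k) stopf("table has %d rows, fewer than k = %d", n, k)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- fold == f
    pred[te] <- fit_fold(table[!te, , drop = FALSE],
                         table[te, , drop = FALSE],
                         target, config, smote_cfg, f)
  }
  new_cv_report("random", k, fold, table[[target]], pred)
}

#' Leave-monitors-out spatial cross-validation
#'
#' Partitions monitors (not rows) into `k` roughly equal groups; all rows of
#' a monitor share its group's role, so test locations are never seen in
#' training. Pooled metrics as in [kfold_cv()].
#'
#' @inheritParams kfold_cv
#' @return A `cv_report` with `fold_monitors`, the monitor partition.
#' @export
spatial_kfold_cv <- function(table, k = 10L, config = forest_config(),
                             smote_cfg = NULL, seed = 1L, target = "pm25") {
  check_cv_table(table, target)
  if (is.null(table$monitor_id)) stopf("table has no monitor_id column")
  if (!is_count(k, min = 2L)) stopf("k must be an integer >= 2")
  monitors <- sort(unique(as.character(table$monitor_id)))
  if (length(monitors) < k)
    stopf("only %d distinct monitors for k = %d folds", length(monitors), k)
  grp <- withr::with_seed(seed, {
    perm <- sample(monitors)
    stats::setNames(rep_len(seq_len(k), length(monitors)), perm)
  })
  fold <- unname(grp[as.character(table$monitor_id)])
  pred <- numeric(nrow(table))
  for (f in seq_len(k)) {
    te <- fold == f
    pred[te] <- fit_fold(table[!te, , drop = FALSE],
                         table[te, , drop = FALSE],
                         target, config, smote_cfg, f)
  }
  fold_monitors <- split(names(grp), unname(grp))
  new_cv_report("spatial", k, fold, table[[target]], pred, fold_monitors)
}

#' Out-of-bag metrics of a fitted forest
#'
#' Computes R2 and RMSE over the model's out-of-bag predictions, restricted
#' to rows with a defined OOB value; synthetic (SMOTE) rows are excluded
#' from the metric.
#'
#' @param model A `fitted_forest`.
#' @param table The table the model was trained on (row-aligned).
#' @return List with `r2`, `rmse`, `n` (rows entering the metric), and
#'   `n_excluded_synthetic`.
#' @export
oob_report <- function(model, table) {
  stopifnot(inherits(model, "fitted_forest"))
  if (nrow(table) != model$n)
    stopf("table has %d rows but the model was trained on %d",
          nrow(table), model$n)
  real <- if (is.null(table$synthetic)) rep(TRUE, nrow(table)) else
    !table$synthetic
  ok <- real & is.finite(model$oob)
  if (!any(ok)) stopf("no rows with defined OOB predictions")
  obs <- table[[model$target]][ok]
  if (model$constant_target)
    return(list(r2 = NA_real_, rmse = rmse(obs, model$oob[ok]), n = sum(ok),
                n_excluded_synthetic = sum(!real)))
  list(r2 = r2_score(obs, model$oob[ok]),
       rmse = rmse(obs, model$oob[ok]),
       n = sum(ok),
       n_excluded_synthetic = sum(!real))
}
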