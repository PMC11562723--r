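# Synthetic minority oversampling for regression targets: interpolated
# synthetic rows between high-concentration observations and their nearest
# high-concentration neighbors in standardized predictor space.

#' SMOTE configuration
#'
#' @param minority_threshold Concentration (ug/m3) at or above which a row
#'   belongs to the minority class; default 35 (a standard regulatory daily
#'   benchmark).
#' @param k_neighbors Number of nearest minority neighbors used for
#'   interpolation (default 5).
#' @param target_minority_fraction Minority fraction the augmented table
#'   should reach, in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(minority_threshold = 35, k_neighbors = 5L,
                         target_minority_fraction = 0.2, seed = 1L) {
  if (!is_count(k_neighbors)) stopf("k_neighbors must be a positive integer")
  if (!is_number(target_minority_fraction) ||
      target_minority_fraction <= 0 || target_minority_fraction >= 1)
    stopf("target_minority_fraction must lie in (0, 1)")
  structure(list(minority_threshold = minority_threshold,
                 k_neighbors = as.integer(k_neighbors),
                 target_minority_fraction = target_minority_fraction,
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Flag minority (high-concentration) rows
#'
#' @param table Training table with the target column.
#' @param threshold Concentration threshold.
#' @param target Target column name (default `"pm25"`).
#' @return Logical vector, `TRUE` where `target >= threshold`.
#' @export
identify_minority <- function(table, threshold, target = "pm25") {
  if (nrow(table) == 0L) stopf("table is empty")
  table[[target]] >= threshold
}

#' Synthetic minority oversampling of a training table
#'
#' Each synthetic row is `seed_row + u * (neighbor - seed_row)` with
#' `u ~ Uniform(0, 1)`, applied jointly to all predictors and the target;
#' the neighbor is drawn among the `k` nearest minority rows in z-scored
#' predictor space. Rows are synthesized until the minority fraction reaches
#' `target_minority_fraction`; original rows are untouched and keep
#' `synthetic = FALSE`.
#'
#' @param table Training table (no synthetic rows).
#' @param flags Logical minority flags, as from [identify_minority()].
#' @param config A [smote_config()].
#' @param target Target column name (default `"pm25"`).
#' @return The table with synthetic rows appended (`synthetic = TRUE`).
#' @export
smote <- function(table, flags, config = smote_config(), target = "pm25") {
  stopifnot(inherits(config, "smote_config"))
  n <- nrow(table)
  if (length(flags) != n) stopf("flags length %d != table rows %d",
                                length(flags), n)
  if (is.null(table$synthetic)) table$synthetic <- FALSE
  m <- sum(flags)
  k <- config$k_neighbors
  if (m <= k)
    stopf("SMOTE needs more minority rows (%d) than k_neighbors (%d)", m, k)
  f <- config$target_minority_fraction
  n_syn <- ceiling((f * n - m) / (1 - f))
  if (n_syn <= 0) return(table)
  preds <- predictor_names(table, target)
  num_cols <- c(preds, target)
  mino <- table[flags, , drop = FALSE]
  x <- as.matrix(mino[preds])
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sg, "/")
  d2 <- as.matrix(dist(z))^2
  diag(d2) <- Inf
  ord <- apply(d2, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  withr::with_seed(config$seed, {
    base_rep <- n_syn %/% m
    extra <- n_syn %% m
    seed_idx <- c(rep(seq_len(m), base_rep),
                  if (extra > 0) sample(m, extra) else integer())
    nb_pick <- nn[cbind(seed_idx, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
  })
  syn <- mino[seed_idx, , drop = FALSE]
  a <- as.matrix(mino[seed_idx, num_cols, drop = FALSE])
  b <- as.matrix(mino[nb_pick, num_cols, drop = FALSE])
  syn[num_cols] <- a + u * (b - a)
  syn$synthetic <- TRUE
  out <- rbind(table, syn)
  rownames(out) <- NULL
  out
}
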