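# Feature assembly: wavelet multiresolution components and raw values of
# the gridded predictors, read off at monitor cells (or all cells).

#' Feature specification
#'
#' Maps each variable to the components entering the model: `"raw"` (the
#' undecomposed field), `"l<J>"` (the level-`J` smooth approximation) and/or
#' `"h<j>"` (detail components, `j = 1..J`). Cell-center coordinates can be
#' appended as two extra predictors.
#'
#' @param components Named list, variable -> character vector of component
#'   tokens.
#' @param J Decomposition level the tokens refer to.
#' @param include_coordinates Append planar cell-center `x`, `y`?
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(components, J = 5L, include_coordinates = TRUE) {
  if (!is_count(J)) stopf("J must be a positive integer")
  J <- as.integer(J)
  if (!is.list(components) || is.null(names(components)) ||
      any(names(components) == ""))
    stopf("components must be a named list (variable -> tokens)")
  valid <- c("raw", sprintf("l%d", J), sprintf("h%d", seq_len(J)))
  for (v in names(components)) {
    bad <- setdiff(components[[v]], valid)
    if (length(bad))
      stopf("invalid component token(s) for '%s' at J = %d: %s",
            v, J, paste(bad, collapse = ", "))
    if (length(components[[v]]) == 0L)
      stopf("variable '%s' selects no components", v)
  }
  if (length(unlist(components)) == 0L && !include_coordinates)
    stopf("feature spec selects no features")
  structure(list(components = components, J = J,
                 include_coordinates = isTRUE(include_coordinates)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> J = %d, %d predictors%s\n", x$J,
              length(feature_columns(x)),
              if (x$include_coordinates) " (incl. coordinates)" else ""))
  for (v in names(x$components))
    cat(sprintf("  %-10s %s\n", v, paste(x$components[[v]], collapse = ", ")))
  invisible(x)
}

#' Default feature specification
#'
#' The final 20-predictor selection: all six level-5 components of AOD;
#' only the smooth `l5` of longwave flux, u-wind, surface pressure,
#' boundary-layer height and specific humidity; `h1`, `h3`, `l5` of upward
#' shortwave flux; raw 2 m temperature, v-wind, downward shortwave flux and
#' relative humidity; plus the two cell-center coordinates.
#'
#' @return A [feature_spec()] with `J = 5`.
#' @export
default_feature_spec <- function() {
  feature_spec(list(
    aod = c("l5", "h1", "h2", "h3", "h4", "h5"),
    lw_flux = "l5", u_wind = "l5", sfc_pres = "l5", pblh = "l5",
    sp_hum = "l5",
    sw_up = c("h1", "h3", "l5"),
    temp_2m = "raw", v_wind = "raw", sw_down = "raw", rel_hum = "raw"),
    J = 5L, include_coordinates = TRUE)
}

#' Raw-only feature specification over the same variables
#'
#' Ablation counterpart of a spec: every variable enters undecomposed.
#' @param spec A [feature_spec()] to mirror.
#' @return A [feature_spec()] selecting `"raw"` for each variable of `spec`.
#' @export
raw_feature_spec <- function(spec = default_feature_spec()) {
  comps <- lapply(spec$components, function(x) "raw")
  feature_spec(comps, J = spec$J,
               include_coordinates = spec$include_coordinates)
}

component_order <- function(J) c("raw", sprintf("l%d", J),
                                 sprintf("h%d", seq_len(J)))

#' Predictor column names of a feature spec, in canonical order
#' @param spec A [feature_spec()].
#' @return Character vector `<variable>_<component>` (plus `x`, `y`).
#' @export
feature_columns <- function(spec) {
  ord <- component_order(spec$J)
  cols <- unlist(lapply(names(spec$components), function(v) {
    sel <- intersect(ord, spec$components[[v]])
    paste(v, sel, sep = "_")
  }))
  if (spec$include_coordinates) cols <- c(cols, "x", "y")
  cols
}

#' Assemble the predictor matrix for a set of cells
#'
#' Decomposes each variable that contributes wavelet components once (per
#' call) over the row-major flattened field and reads the selected
#' components plus raw values at the requested cells. The column order is
#' fixed by [feature_columns()] and identical across calls.
#'
#' @param filled_aod Gap-free AOD [field()].
#' @param met Named list of gap-free meteorological [field()]s.
#' @param spec A [feature_spec()].
#' @param cells Integer vector of 0-based row-major cell indices, or `NULL`
#'   for all cells.
#' @param wavelet_order Daubechies order for the decomposition (default 5).
#' @param extension_mode Boundary extension, see [dwt_decompose()].
#' @return Numeric matrix, one row per requested cell, columns per
#'   [feature_columns()].
#' @export
assemble_features <- function(filled_aod, met, spec, cells = NULL,
                              wavelet_order = 5L,
                              extension_mode = "symmetric") {
  stopifnot(inherits(spec, "feature_spec"))
  fields <- c(list(aod = filled_aod), met)
  missing_vars <- setdiff(names(spec$components), names(fields))
  if (length(missing_vars))
    stopf("no field supplied for selected variable(s): %s",
          paste(missing_vars, collapse = ", "))
  grid <- filled_aod$grid
  idx <- if (is.null(cells)) seq_len(n_cells(grid)) else as.integer(cells) + 1L
  if (any(idx < 1L | idx > n_cells(grid)))
    stopf("cell indices out of range 0..%d", n_cells(grid) - 1L)
  filters <- daubechies_filters(wavelet_order)
  cols <- feature_columns(spec)
  out <- matrix(NA_real_, length(idx), length(cols),
                dimnames = list(NULL, cols))
  for (v in names(spec$components)) {
    fld <- fields[[v]]
    if (!grid_equal(fld$grid, grid))
      stopf("field '%s' grid %s does not match %s", v,
            grid_desc(fld$grid), grid_desc(grid))
    sel <- spec$components[[v]]
    sig <- NULL
    if (any(sel != "raw")) {
      mra <- mra_components(field_to_signal(fld), filters, spec$J,
                            extension_mode)
      for (comp in sel) {
        if (comp == "raw") next
        vals <- if (comp == sprintf("l%d", spec$J)) mra$approx else
          mra$details[[as.integer(sub("^h", "", comp))]]
        out[, paste(v, comp, sep = "_")] <- vals[idx]
      }
    }
    if ("raw" %in% sel)
      out[, paste(v, "raw", sep = "_")] <- field_to_signal(fld)[idx]
  }
  if (spec$include_coordinates) {
    ctr <- cell_centers(grid)
    out[, "x"] <- ctr$x[idx]
    out[, "y"] <- ctr$y[idx]
  }
  out
}

#' Prune a feature spec by forest importance
#'
#' Drops components whose share of total permutation importance falls below
#' `epsilon`. The last remaining feature is never dropped; coordinates are
#' dropped only if both fall below the cut.
#'
#' @param model A `fitted_forest` trained on the features of `spec`.
#' @param spec The [feature_spec()] the model was trained on.
#' @param epsilon Fraction of total importance below which a feature is
#'   pruned (default 0.005).
#' @return A pruned [feature_spec()].
#' @export
prune_by_importance <- function(model, spec, epsilon = 0.005) {
  stopifnot(inherits(model, "fitted_forest"), inherits(spec, "feature_spec"))
  cols <- feature_columns(spec)
  if (!all(cols %in% names(model$importance)))
    stopf("model importances do not cover the feature specification's columns")
  imp <- pmax(model$importance[cols], 0)
  share <- imp / sum(imp)
  if (epsilon > 0 && all(share < epsilon))
    stopf("all %d features fall below epsilon = %g; nothing would remain",
          length(share), epsilon)
  keep <- names(share)[share >= epsilon]
  if (length(keep) == 0L) keep <- names(which.max(share))
  comps <- list()
  for (v in names(spec$components)) {
    sel <- spec$components[[v]]
    kept <- sel[paste(v, sel, sep = "_") %in% keep]
    if (length(kept)) comps[[v]] <- kept
  }
  coords <- spec$include_coordinates && any(c("x", "y") %in% keep)
  if (length(comps) == 0L && !coords) {
    # keep the single best feature's variable
    best <- names(which.max(share))
    if (best %in% c("x", "y")) coords <- TRUE else {
      v <- sub("_(raw|l[0-9]+|h[0-9]+)$", "", best)
      comps[[v]] <- sub("^.*_", "", best)
    }
  }
  feature_spec(comps, J = spec$J, include_coordinates = coords)
}
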