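# Plain-text formats: gridded fields as a one-line JSON header plus a
# row,col,value CSV body (shortest-roundtrip doubles, so write-then-read is
# bitwise lossless); observations as CSV; configuration and reports as JSON.

FIELD_MAGIC <- "#pmwave-field "

grid_to_list <- function(grid) unclass(grid)

grid_from_list <- function(x) {
  grid_spec(as.numeric(x$origin_x), as.numeric(x$origin_y),
            as.numeric(x$cell_size), x$n_rows, x$n_cols)
}

#' Write / read a gridded field
#'
#' The file holds one header line (`#pmwave-field ` followed by a JSON
#' object with the grid, variable and hour) and a `row,col,value` body with
#' one line per non-degenerate cell; missing cells are written as empty
#' values. Values round-trip bit for bit.
#'
#' @param f A [field()].
#' @param path Output file path.
#' @return `write_field` returns `path` invisibly.
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "field"))
  meta <- list(grid = grid_to_list(f$grid), variable = f$variable,
               hour = f$hour)
  con <- file(path, "w")
  writeLines(paste0(FIELD_MAGIC,
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  close(con)
  ctr <- cell_centers(f$grid)
  vals <- as.vector(t(f$values))
  # 17 significant digits guarantee a bit-exact double round trip
  dt <- data.table::data.table(
    row = ctr$row, col = ctr$col,
    value = ifelse(is.na(vals), "", sprintf("%.17g", vals)))
  data.table::fwrite(dt, path, append = TRUE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param grid Optional [grid_spec()] the file must match; a mismatch is an
#'   error naming both grids.
#' @return `read_field` returns the [field()].
#' @export
read_field <- function(path, grid = NULL) {
  if (!file.exists(path)) stopf("no such field file: %s", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, FIELD_MAGIC))
    stopf("'%s' is not a pmwave field file (missing header)", path)
  meta <- jsonlite::fromJSON(substring(header, nchar(FIELD_MAGIC) + 1L))
  g <- grid_from_list(meta$grid)
  if (!is.null(grid) && !grid_equal(g, grid))
    stopf("grid mismatch: file '%s' has %s but %s was expected",
          path, grid_desc(g), grid_desc(grid))
  dt <- data.table::fread(path, skip = 1L, header = FALSE,
                          col.names = c("row", "col", "value"),
                          colClasses = list(integer = 1:2, double = 3L))
  vals <- rep(NA_real_, n_cells(g))
  vals[dt$row * g$n_cols + dt$col + 1L] <- dt$value
  field(g, vals, variable = meta$variable, hour = meta$hour)
}

#' Write / read monitor observations
#' @param observations Data frame (`site_id`, `source`, `x`, `y`, `hour`,
#'   `pm25`).
#' @param path CSV path.
#' @export
write_observations <- function(observations, path) {
  data.table::fwrite(observations, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    character = c("site_id", "source"))))
}

# --- pipeline configuration --------------------------------------------

PIPELINE_KEYS <- c("scene", "wavelet", "gapfill_forest", "pm25_forest",
                   "smote", "cv", "seed")

#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic scene, the wavelet
#' choice (Daubechies order, level `J`, extension mode), one
#' [forest_config()] per forest stage, the [smote_config()], and the CV
#' plan. Serializes to JSON; unknown keys are rejected on read.
#'
#' @param scene A [scene_config()].
#' @param wavelet List with `order` (Daubechies order, default 5), `J`
#'   (default 5) and `extension_mode` (default `"symmetric"`).
#' @param gapfill_forest,pm25_forest [forest_config()]s per stage.
#' @param smote A [smote_config()].
#' @param cv List with `k` (default 10) and `schemes` (subset of
#'   `c("random", "spatial")`).
#' @param seed Master seed; stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(),
                            wavelet = list(order = 5L, J = 5L,
                                           extension_mode = "symmetric"),
                            gapfill_forest = forest_config(),
                            pm25_forest = forest_config(),
                            smote = smote_config(),
                            cv = list(k = 10L,
                                      schemes = c("random", "spatial")),
                            seed = 1L) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(gapfill_forest, "forest_config"),
            inherits(pm25_forest, "forest_config"),
            inherits(smote, "smote_config"))
  wavelet$order <- wavelet$order %||% 5L
  wavelet$J <- wavelet$J %||% 5L
  wavelet$extension_mode <- check_mode(wavelet$extension_mode %||% "symmetric")
  daubechies_filters(wavelet$order)
  cv$k <- cv$k %||% 10L
  cv$schemes <- cv$schemes %||% c("random", "spatial")
  if (!all(cv$schemes %in% c("random", "spatial")))
    stopf("cv schemes must be a subset of 'random', 'spatial'")
  if (!is_count(seed, min = 0L)) stopf("seed must be a non-negative integer")
  structure(list(scene = scene, wavelet = wavelet,
                 gapfill_forest = gapfill_forest, pm25_forest = pm25_forest,
                 smote = smote, cv = cv, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- lapply(unclass(config), function(el)
    if (is.object(el)) unclass(el) else el)
  # keep coefficient names: jsonlite drops names of atomic vectors
  x$scene$response_params <- as.list(x$scene$response_params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), PIPELINE_KEYS)
  if (length(unknown))
    stopf("unknown pipeline config key(s): %s", paste(unknown, collapse = ", "))
  sc <- x$scene
  rp <- unlist(sc$response_params)
  scene <- scene_config(
    n_rows = sc$n_rows, n_cols = sc$n_cols, cell_size = sc$cell_size,
    n_hours = sc$n_hours, n_reference_sites = sc$n_reference_sites,
    n_lowcost_sites = sc$n_lowcost_sites, gap_fraction = sc$gap_fraction,
    blob_scale = sc$blob_scale, noise_sd = sc$noise_sd,
    target_r2 = sc$target_r2, sensor_bias_sd = sc$sensor_bias_sd,
    obs_noise_sd = sc$obs_noise_sd, met_smooth_sigma = sc$met_smooth_sigma,
    aod_smooth_sigma = sc$aod_smooth_sigma, coarse_factor = sc$coarse_factor,
    response_params = rp, seed = sc$seed)
  fc <- function(y) forest_config(y$n_trees, y$m_try, y$min_leaf, y$seed)
  sm <- x$smote
  pipeline_config(
    scene = scene, wavelet = x$wavelet,
    gapfill_forest = fc(x$gapfill_forest), pm25_forest = fc(x$pm25_forest),
    smote = smote_config(sm$minority_threshold, sm$k_neighbors,
                         sm$target_minority_fraction, sm$seed),
    cv = x$cv, seed = x$seed)
}
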