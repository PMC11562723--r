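#' Modeling grid specification
#'
#' A regular planar grid of square cells. Cells are indexed row-major from 0:
#' cell `(row, col)` has linear index `row * n_cols + col`, and its center sits
#' at `origin + (index + 0.5) * cell_size` in each axis (`x` along columns, `y`
#' along rows). Coordinates are planar (km by convention); no geodesy.
#'
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner.
#' @param cell_size Cell edge length (> 0); 1 km nominal.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, 1, 100, 100)
#' nearest_cell(g, c(7.5, 3.5)) # center of cell (3, 7)
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 1,
                      n_rows = 1L, n_cols = 1L) {
  if (!is_number(origin_x) || !is_number(origin_y))
    stopf("grid origin must be finite numbers")
  if (!is_number(cell_size) || cell_size <= 0)
    stopf("cell_size must be a positive number, got %s", format(cell_size))
  if (!is_count(n_rows) || !is_count(n_cols))
    stopf("n_rows and n_cols must be positive integers")
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count `n_rows * n_cols`.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

grid_desc <- function(g) {
  sprintf("[%dx%d, cell %g, origin (%g, %g)]",
          g$n_rows, g$n_cols, g$cell_size, g$origin_x, g$origin_y)
}

#' Cell-center coordinates in row-major order
#'
#' @param grid A [grid_spec()].
#' @return A data.frame with columns `row`, `col` (0-based), `x`, `y`, one row
#'   per cell in row-major order (row 0 first).
#' @export
cell_centers <- function(grid) {
  row <- rep(0:(grid$n_rows - 1L), each = grid$n_cols)
  col <- rep(0:(grid$n_cols - 1L), times = grid$n_rows)
  data.frame(row = row, col = col,
             x = grid$origin_x + (col + 0.5) * grid$cell_size,
             y = grid$origin_y + (row + 0.5) * grid$cell_size)
}

#' Gridded field for one variable at one hour
#'
#' A `field` couples a [grid_spec()] with a value for every cell plus an
#' explicit missing mask. Values are stored as an `n_rows x n_cols` matrix
#' (`values[row + 1, col + 1]` for the 0-based cell `(row, col)`); missing
#' cells are `NA`.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`, or a vector of
#'   length `n_rows * n_cols` in row-major cell order.
#' @param variable Variable name.
#' @param hour Integer hour index (0-based within the scene).
#' @return An object of class `field`.
#' @export
field <- function(grid, values, variable = "value", hour = 0L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(values)) {
    if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
      stopf("field values are %dx%d but grid %s expects %dx%d",
            nrow(values), ncol(values), grid_desc(grid),
            grid$n_rows, grid$n_cols)
  } else {
    if (length(values) != n_cells(grid))
      stopf("field vector has length %d but grid has %d cells",
            length(values), n_cells(grid))
    values <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols,
                     byrow = TRUE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, variable = as.character(variable),
                 hour = as.integer(hour), values = values),
            class = "field")
}

#' @export
print.field <- function(x, ...) {
  cat(sprintf("<field> '%s' hour %d on %s, %d/%d missing\n",
              x$variable, x$hour, grid_desc(x$grid),
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Missing mask of a field
#' @param f A [field()].
#' @return Logical matrix, `TRUE` where the cell value is missing.
#' @export
field_missing <- function(f) is.na(f$values)

#' Nearest grid cell to a point
#'
#' Returns the cell whose center minimizes Euclidean distance to the point.
#' Ties (a point equidistant between centers) resolve to the
#' lexicographically smallest `(row, col)`. Points are accepted up to half a
#' cell beyond the grid edge and clamped to the boundary cell.
#'
#' @param grid A [grid_spec()].
#' @param point Numeric `c(x, y)`, or a two-column matrix of points.
#' @return Integer vector `c(row, col)` (0-based), or an `n x 2` matrix for
#'   matrix input.
#' @export
nearest_cell <- function(grid, point) {
  pt <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  gx <- (pt[, 1L] - grid$origin_x) / grid$cell_size # continuous col + 0.5
  gy <- (pt[, 2L] - grid$origin_y) / grid$cell_size
  bad <- gx < -0.5 | gx > grid$n_cols + 0.5 | gy < -0.5 | gy > grid$n_rows + 0.5
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("point (%g, %g) lies outside the grid extent %s",
          pt[i, 1L], pt[i, 2L], grid_desc(grid))
  }
  # continuous row coordinate of the point is gy - 0.5; nearest integer with
  # ties to the smaller index is ceiling(. - 0.5)
  row <- pmin(pmax(ceiling(gy - 1), 0L), grid$n_rows - 1L)
  col <- pmin(pmax(ceiling(gx - 1), 0L), grid$n_cols - 1L)
  out <- cbind(row = as.integer(row), col = as.integer(col))
  if (!is.matrix(point)) out[1L, ] else out
}

#' Linear (row-major, 0-based) index of cells
#' @param grid A [grid_spec()].
#' @param row,col 0-based cell indices.
#' @return 0-based linear cell index `row * n_cols + col`.
#' @export
cell_index <- function(grid, row, col) as.integer(row) * grid$n_cols + as.integer(col)

#' Average timestamped samples within one clock hour
#'
#' @param times Timestamps (`POSIXct` or numeric seconds); all must fall in
#'   the same clock hour.
#' @param values Numeric samples, `NA` allowed.
#' @return Arithmetic mean of the non-missing samples, or `NA` if none.
#' @export
hourly_average <- function(times, values) {
  if (length(times) != length(values))
    stopf("times and values differ in length (%d vs %d)",
          length(times), length(values))
  secs <- as.numeric(times)
  hrs <- unique(floor(secs / 3600))
  if (length(hrs) > 1L)
    stopf("samples span %d distinct clock hours; hourly_average needs one",
          length(hrs))
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Bilinear interpolation stencil
#'
#' Four corner values on an axis-aligned rectangle plus a target point inside
#' it. `s11` sits at `(w1, v1)`, `s21` at `(w2, v1)`, `s12` at `(w1, v2)`,
#' `s22` at `(w2, v2)`.
#'
#' @param s11,s12,s21,s22 Corner values.
#' @param w1,w2,v1,v2 Corner coordinates with `w1 < w2`, `v1 < v2`.
#' @param w,v Target coordinates, `w` in `[w1, w2]`, `v` in `[v1, v2]`.
#' @return An object of class `bilinear_stencil`.
#' @export
bilinear_stencil <- function(s11, s12, s21, s22, w1, w2, v1, v2, w, v) {
  if (!(w1 < w2) || !(v1 < v2))
    stopf("degenerate stencil rectangle: need w1 < w2 and v1 < v2 (got w [%g, %g], v [%g, %g])",
          w1, w2, v1, v2)
  if (w < w1 || w > w2 || v < v1 || v > v2)
    stopf("target (%g, %g) outside stencil rectangle [%g, %g] x [%g, %g]",
          w, v, w1, w2, v1, v2)
  structure(list(s11 = s11, s12 = s12, s21 = s21, s22 = s22,
                 w1 = w1, w2 = w2, v1 = v1, v2 = v2, w = w, v = v),
            class = "bilinear_stencil")
}

#' Evaluate a bilinear stencil
#'
#' Standard tensor-product bilinear interpolation: linear in `w` along both
#' `v`-edges, then linear in `v`. Exact on fields of the form
#' `a + b*w + c*v + d*w*v`.
#'
#' @param stencil A [bilinear_stencil()].
#' @return Interpolated value at the stencil's target point.
#' @export
bilinear_interpolate <- function(stencil) {
  stopifnot(inherits(stencil, "bilinear_stencil"))
  s <- stencil
  dw <- s$w2 - s$w1
  dv <- s$v2 - s$v1
  (s$s11 * (s$w2 - s$w) * (s$v2 - s$v) +
   s$s21 * (s$w - s$w1) * (s$v2 - s$v) +
   s$s12 * (s$w2 - s$w) * (s$v - s$v1) +
   s$s22 * (s$w - s$w1) * (s$v - s$v1)) / (dw * dv)
}

#' Bilinear regridding of a coarse field onto a target grid
#'
#' Every target cell center is interpolated from the 2x2 stencil of enclosing
#' coarse cell centers. Target centers outside the span of coarse centers are
#' clamped to the outermost stencil (edge extrapolation is linear within the
#' clamped stencil). A missing coarse corner makes the affected target cells
#' missing.
#'
#' @param coarse A [field()] on a coarse grid.
#' @param target A [grid_spec()] for the output resolution.
#' @return A [field()] on `target`.
#' @export
regrid_bilinear <- function(coarse, target) {
  stopifnot(inherits(coarse, "field"), inherits(target, "grid_spec"))
  cg <- coarse$grid
  if (cg$n_rows < 2L || cg$n_cols < 2L)
    stopf("coarse grid %s is too small for a bilinear stencil", grid_desc(cg))
  ctr <- cell_centers(target)
  # continuous coarse-cell coordinates of target centers (0-based cell units)
  gx <- (ctr$x - cg$origin_x) / cg$cell_size - 0.5
  gy <- (ctr$y - cg$origin_y) / cg$cell_size - 0.5
  if (all(gx < -1 | gx > cg$n_cols) || all(gy < -1 | gy > cg$n_rows))
    stopf("target grid %s does not overlap coarse grid %s",
          grid_desc(target), grid_desc(cg))
  c1 <- pmin(pmax(floor(gx), 0), cg$n_cols - 2L)
  r1 <- pmin(pmax(floor(gy), 0), cg$n_rows - 2L)
  fw <- gx - c1
  fv <- gy - r1
  vals <- coarse$values
  s11 <- vals[cbind(r1 + 1L, c1 + 1L)]
  s21 <- vals[cbind(r1 + 1L, c1 + 2L)]
  s12 <- vals[cbind(r1 + 2L, c1 + 1L)]
  s22 <- vals[cbind(r1 + 2L, c1 + 2L)]
  out <- s11 * (1 - fw) * (1 - fv) + s21 * fw * (1 - fv) +
    s12 * (1 - fw) * fv + s22 * fw * fv
  field(target, out, variable = coarse$variable, hour = coarse$hour)
}

#' Inverse-distance-weighted downscaling
#'
#' Each target cell value is the IDW mean over the `k` nearest non-missing
#' coarse cell centers, with weights `d^(-power)`. A target center coinciding
#' with a source center returns that source value exactly.
#'
#' @param coarse A [field()] with at least `k` non-missing cells.
#' @param target A [grid_spec()].
#' @param power Positive distance exponent (default 2).
#' @param k Number of neighbors (default 4).
#' @return A [field()] on `target` with no missing cells.
#' @export
idw_downscale <- function(coarse, target, power = 2, k = 4L) {
  stopifnot(inherits(coarse, "field"), inherits(target, "grid_spec"))
  if (!is_number(power) || power <= 0) stopf("power must be > 0")
  if (!is_count(k)) stopf("k must be a positive integer")
  src <- cell_centers(coarse$grid)
  z <- as.vector(t(coarse$values)) # row-major
  keep <- !is.na(z)
  if (!any(keep)) stopf("idw_downscale: coarse field has no non-missing cells")
  if (sum(keep) < k)
    stopf("idw_downscale: only %d non-missing source cells for k = %d",
          sum(keep), k)
  sx <- src$x[keep]; sy <- src$y[keep]; sz <- z[keep]
  tgt <- cell_centers(target)
  out <- numeric(nrow(tgt))
  eps <- 1e-9 * coarse$grid$cell_size
  for (i in seq_len(nrow(tgt))) {
    d2 <- (sx - tgt$x[i])^2 + (sy - tgt$y[i])^2
    nn <- order(d2)[seq_len(k)]
    d <- sqrt(d2[nn])
    if (d[1L] < eps) {
      out[i] <- sz[nn[1L]]
    } else {
      w <- d^(-power)
      out[i] <- sum(w * sz[nn]) / sum(w)
    }
  }
  field(target, out, variable = coarse$variable, hour = coarse$hour)
}

#' Merge monitor observations onto grid cells
#'
#' Records are assigned to their nearest grid cell. Within a cell,
#' reference-grade records (`source == "REF"`) take absolute precedence:
#' if any are present their mean is used and low-cost (`"LC"`) records are
#' discarded; otherwise the mean of the low-cost records is used. The result
#' has one value per occupied cell.
#'
#' @param records Data frame with columns `site_id`, `source` (`"REF"` or
#'   `"LC"`), `x`, `y`, `hour`, `pm25`.
#' @param grid A [grid_spec()].
#' @param hour Hour to select from `records`.
#' @return Data frame with one row per occupied cell: `cell` (0-based linear
#'   index), `row`, `col`, `monitor_id` (lexicographically first contributing
#'   site), `source`, `pm25`.
#' @export
merge_observations <- function(records, grid, hour) {
  need <- c("site_id", "source", "x", "y", "hour", "pm25")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records are missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(records$source %in% c("REF", "LC")))
    stopf("record source must be 'REF' or 'LC'")
  rec <- records[records$hour == hour & !is.na(records$pm25), , drop = FALSE]
  if (nrow(rec) == 0L)
    return(data.frame(cell = integer(), row = integer(), col = integer(),
                      monitor_id = character(), source = character(),
                      pm25 = numeric()))
  rc <- tryCatch(nearest_cell(grid, cbind(rec$x, rec$y)), error = function(e) e)
  if (inherits(rc, "error")) {
    # re-run one by one to report the offending record id
    for (i in seq_len(nrow(rec))) {
      ok <- tryCatch({nearest_cell(grid, c(rec$x[i], rec$y[i])); TRUE},
                     error = function(e) FALSE)
      if (!ok)
        stopf("record '%s' at (%g, %g) lies outside the grid extent %s",
              rec$site_id[i], rec$x[i], rec$y[i], grid_desc(grid))
    }
    stop(rc)
  }
  cell <- cell_index(grid, rc[, 1L], rc[, 2L])
  out <- lapply(split(seq_len(nrow(rec)), cell), function(idx) {
    sub <- rec[idx, , drop = FALSE]
    use <- if (any(sub$source == "REF")) sub[sub$source == "REF", , drop = FALSE] else sub
    data.frame(cell = cell[idx[1L]],
               monitor_id = min(as.character(use$site_id)),
               source = use$source[1L],
               pm25 = mean(use$pm25),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$row <- out$cell %/% grid$n_cols
  out$col <- out$cell %% grid$n_cols
  out[order(out$cell), c("cell", "row", "col", "monitor_id", "source", "pm25")]
}
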