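test_that("nearest_cell returns the center cell and honors the tie rule", {
  g <- grid_spec(0, 0, 1, 10, 12)
  expect_equal(nearest_cell(g, c(7.5, 3.5)), c(row = 3L, col = 7L))
  # boundary between cols 3 and 4: lexicographically smaller wins
  expect_equal(nearest_cell(g, c(4.0, 2.5)), c(row = 2L, col = 3L))
  expect_equal(nearest_cell(g, c(2.5, 6.0)), c(row = 5L, col = 2L))
  expect_error(nearest_cell(g, c(-2, 5)), "outside")
})

test_that("nearest_cell agrees with exhaustive search over all centers", {
  g <- grid_spec(-3, 2, 0.7, 9, 11)
  ctr <- cell_centers(g)
  set.seed(99)
  pts <- cbind(runif(1000, -3, -3 + 11 * 0.7), runif(1000, 2, 2 + 9 * 0.7))
  rc <- nearest_cell(g, pts)
  for (i in seq_len(200)) { # spot-check a deterministic subset
    d2 <- (ctr$x - pts[i, 1])^2 + (ctr$y - pts[i, 2])^2
    best <- which(d2 == min(d2))[1] # ties: first in row-major order
    expect_equal(unname(rc[i, ]), c(ctr$row[best], ctr$col[best]))
  }
})

test_that("hourly_average averages the available samples of one clock hour", {
  t0 <- as.POSIXct("2020-08-22 14:00:00", tz = "UTC")
  expect_equal(hourly_average(t0 + 300 * (0:11), 0:11), 5.5)
  expect_equal(hourly_average(t0 + c(0, 600, 1200), c(0.2, NA, 0.4)), 0.3)
  expect_true(is.na(hourly_average(t0 + c(0, 60), c(NA, NA))))
  expect_error(hourly_average(t0 + c(0, 3600), c(1, 2)), "distinct clock hours")
})

test_that("bilinear interpolation is exact on bilinear fields", {
  s <- bilinear_stencil(5, 5, 5, 5, 0, 1, 0, 1, 0.3, 0.8)
  expect_equal(bilinear_interpolate(s), 5)
  s <- bilinear_stencil(3, 7, 4, 9, 0, 2, 0, 2, 0, 0)
  expect_equal(bilinear_interpolate(s), 3) # corner (w1, v1) -> S11
  # f = w + 2v on the unit square
  s <- bilinear_stencil(0, 2, 1, 3, 0, 1, 0, 1, 0.25, 0.5)
  expect_equal(bilinear_interpolate(s), 1.25)
  # exact on a + bw + cv + dwv at random targets
  set.seed(2)
  for (i in 1:20) {
    co <- rnorm(4)
    fn <- function(w, v) co[1] + co[2] * w + co[3] * v + co[4] * w * v
    w <- runif(1, 1, 3); v <- runif(1, -1, 2)
    s <- bilinear_stencil(fn(1, -1), fn(1, 2), fn(3, -1), fn(3, 2),
                          1, 3, -1, 2, w, v)
    expect_equal(bilinear_interpolate(s), fn(w, v), tolerance = 1e-12)
  }
  expect_error(bilinear_stencil(1, 2, 3, 4, 1, 1, 0, 1, 1, 0.5), "degenerate")
})

test_that("bilinear regridding reproduces constants and planes and matches stencils", {
  cg <- grid_spec(0, 0, 5, 6, 7)
  tg <- grid_spec(2, 2, 1, 22, 28)
  expect_equal(regrid_bilinear(field(cg, matrix(4.2, 6, 7)), tg)$values,
               matrix(4.2, 22, 28))
  ctr <- cell_centers(cg)
  plane <- 1.5 + 0.3 * ctr$x - 0.7 * ctr$y
  out <- regrid_bilinear(field(cg, plane), tg)
  tctr <- cell_centers(tg)
  expect_equal(as.vector(t(out$values)), 1.5 + 0.3 * tctr$x - 0.7 * tctr$y,
               tolerance = 1e-12)
  # random field: equality with explicit per-cell stencil evaluation
  set.seed(31)
  cf <- field(cg, rnorm(42))
  out <- regrid_bilinear(cf, tg)
  cc <- cell_centers(cg)
  vals <- as.vector(t(cf$values))
  for (i in seq(1, nrow(tctr), by = 37)) {
    gx <- (tctr$x[i] - cg$origin_x) / cg$cell_size - 0.5
    gy <- (tctr$y[i] - cg$origin_y) / cg$cell_size - 0.5
    c1 <- min(max(floor(gx), 0), cg$n_cols - 2)
    r1 <- min(max(floor(gy), 0), cg$n_rows - 2)
    at <- function(r, c) vals[r * cg$n_cols + c + 1]
    s <- bilinear_stencil(at(r1, c1), at(r1 + 1, c1), at(r1, c1 + 1),
                          at(r1 + 1, c1 + 1),
                          c1, c1 + 1, r1, r1 + 1, gx, gy)
    expect_equal(out$values[tctr$row[i] + 1, tctr$col[i] + 1],
                 bilinear_interpolate(s), tolerance = 1e-12)
  }
  # convex-combination property: no new extrema
  expect_gte(min(out$values), min(cf$values))
  expect_lte(max(out$values), max(cf$values))
})

test_that("IDW downscaling matches brute force and returns exact values at sources", {
  cg <- grid_spec(0, 0, 4, 5, 5)
  set.seed(13)
  cf <- field(cg, rnorm(25, 10, 2))
  # a target grid whose first center coincides with a coarse center
  tg <- grid_spec(1.5, 1.5, 1, 8, 8)
  out <- idw_downscale(cf, tg, power = 2, k = 4)
  expect_equal(out$values[1, 1], cf$values[1, 1]) # coincident center, d = 0
  ctr <- cell_centers(cg)
  tctr <- cell_centers(tg)
  vals <- as.vector(t(cf$values))
  for (i in seq(1, 64, by = 7)) {
    expect_equal(as.vector(t(out$values))[i],
                 naive_idw(tctr$x[i], tctr$y[i], ctr$x, ctr$y, vals, 2, 4),
                 tolerance = 1e-12)
  }
  # two equidistant sources average
  cg2 <- grid_spec(0, 0, 2, 1, 2)
  cf2 <- field(cg2, c(2, 4))
  tg2 <- grid_spec(1.5, 0.5, 1, 1, 1) # center (2,1), equidistant from both
  expect_equal(idw_downscale(cf2, tg2, k = 2)$values[1, 1], 3)
  # convexity
  expect_gte(min(out$values), min(cf$values))
  expect_lte(max(out$values), max(cf$values))
  # missing handling
  cf$values[2, 2] <- NA
  expect_silent(idw_downscale(cf, tg))
  expect_error(idw_downscale(field(cg, matrix(NA_real_, 5, 5)), tg), "non-missing")
})

test_that("observation merging enforces reference precedence and averaging", {
  g <- grid_spec(0, 0, 1, 10, 10)
  rec <- data.frame(
    site_id = c("A1", "P1", "P2", "P3", "A2", "A3"),
    source = c("REF", "LC", "LC", "LC", "REF", "REF"),
    x = c(2.5, 2.6, 5.5, 5.4, 8.5, 8.6),
    y = c(2.5, 2.4, 5.5, 5.6, 8.5, 8.4),
    hour = 0L, pm25 = c(10, 20, 8, 12, 10, 14))
  out <- merge_observations(rec, g, 0L)
  expect_equal(nrow(out), 3L)
  # cell with REF + LC -> REF value only
  c1 <- out[out$row == 2 & out$col == 2, ]
  expect_equal(c1$pm25, 10); expect_equal(c1$source, "REF")
  # cell with two LC -> mean, tag LC
  c2 <- out[out$row == 5 & out$col == 5, ]
  expect_equal(c2$pm25, 10); expect_equal(c2$source, "LC")
  # cell with two REF -> mean, tag REF
  c3 <- out[out$row == 8 & out$col == 8, ]
  expect_equal(c3$pm25, 12); expect_equal(c3$source, "REF")
  # outside record is reported by id
  rec2 <- rbind(rec, data.frame(site_id = "BAD", source = "LC",
                                x = 40, y = 2, hour = 0L, pm25 = 5))
  expect_error(merge_observations(rec2, g, 0L), "BAD")
})
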