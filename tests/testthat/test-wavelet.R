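test_that("Daubechies filters satisfy orthonormality, QMF and moment conditions", {
  expect_equal(daubechies_filters(1)$lowpass, c(1, 1) / sqrt(2))
  for (p in c(1, 2, 5, 8, 10)) {
    f <- daubechies_filters(p)
    expect_equal(f$L, 2 * p)
    expect_lt(abs(sum(f$lowpass) - sqrt(2)), 1e-10)
    expect_lt(abs(sum(f$lowpass^2) - 1), 1e-10)
    # quadrature mirror relation g[k] = (-1)^k h[L-1-k]
    k <- 0:(f$L - 1)
    expect_equal(f$highpass, (-1)^k * rev(f$lowpass), tolerance = 1e-14)
    # p vanishing moments of the highpass (relative to the moment magnitude,
    # which grows as k^m for high orders)
    for (m in 0:(p - 1))
      expect_lt(abs(sum(k^m * f$highpass)),
                1e-10 * max(1, sum(k^m * abs(f$highpass))))
    # orthogonality of even shifts: sum h[k] h[k+2s] = delta(s)
    for (s in 1:(p - 1)) {
      if (2 * s >= f$L) break
      lag <- sum(f$lowpass[1:(f$L - 2 * s)] * f$lowpass[(2 * s + 1):f$L])
      expect_lt(abs(lag), 1e-10)
      cross <- sum(f$lowpass[1:(f$L - 2 * s)] * f$highpass[(2 * s + 1):f$L])
      expect_lt(abs(cross), 1e-10)
    }
  }
  expect_error(daubechies_filters(11), "unsupported")
  expect_error(daubechies_filters(0), "unsupported")
})

test_that("maximum decomposition level follows floor(log2(n/(L-1)))", {
  expect_identical(max_decomposition_level(8, 2), 3L)
  expect_identical(max_decomposition_level(100, 10), 3L)
  expect_identical(max_decomposition_level(64, daubechies_filters(3)), 3L)
  expect_identical(max_decomposition_level(10, 10), 0L)
  expect_error(max_decomposition_level(9, 10), "shorter")
})

test_that("hand-computed Haar transform of (1,2,3,4) matches", {
  h <- daubechies_filters(1)
  pyr <- dwt_decompose(c(1, 2, 3, 4), h, 1, "periodic")
  expect_equal(pyr$approx, c(3, 7) / sqrt(2))
  expect_equal(abs(pyr$details[[1]]), c(1, 1) / sqrt(2))
  # declared sign convention: g = (-1)^k h[L-1-k] gives negative details here
  expect_equal(pyr$details[[1]], c(-1, -1) / sqrt(2))
})

test_that("constant signals put all energy into the approximation", {
  for (mode in c("symmetric", "periodic")) {
    pyr <- dwt_decompose(rep(2.5, 32), daubechies_filters(1), 1, mode)
    expect_equal(max(abs(pyr$details[[1]])), 0, tolerance = 1e-14)
  }
})

test_that("pyramid equals the naive extend-convolve-downsample oracle", {
  set.seed(42)
  cases <- expand.grid(p = c(1, 2, 5), mode = c("symmetric", "periodic"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]; mode <- cases$mode[i]
    f <- daubechies_filters(p)
    for (rep in 1:3) {
      n <- sample(40:120, 1)
      x <- rnorm(n)
      J <- min(3L, max_decomposition_level(n, f$L))
      pyr <- dwt_decompose(x, f, J, mode)
      ora <- naive_dwt_multilevel(x, f, J, mode)
      expect_equal(pyr$approx, ora$approx, tolerance = 1e-10)
      for (j in seq_len(J))
        expect_equal(pyr$details[[j]], ora$details[[j]], tolerance = 1e-10)
    }
  }
})

test_that("decompose-reconstruct round trip is exact in both modes", {
  set.seed(7)
  for (mode in c("symmetric", "periodic")) {
    for (p in c(1, 3, 5)) {
      f <- daubechies_filters(p)
      for (n in c(37, 64, 200)) {
        if (max_decomposition_level(n, f$L) < 1) next
        x <- rnorm(n)
        J <- max_decomposition_level(n, f$L)
        pyr <- dwt_decompose(x, f, J, mode)
        expect_equal(dwt_reconstruct(pyr), x, tolerance = 1e-10)
      }
    }
  }
})

test_that("multiresolution components are additive to the input", {
  set.seed(11)
  for (mode in c("symmetric", "periodic")) {
    for (p in c(1, 2, 5)) {
      f <- daubechies_filters(p)
      n <- 150
      x <- cumsum(rnorm(n))
      J <- min(4L, max_decomposition_level(n, f$L))
      m <- mra_components(x, f, J, mode)
      recon <- m$approx + Reduce(`+`, m$details)
      expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
      expect_true(all(lengths(m$details) == n))
      expect_length(m$approx, n)
    }
  }
})

test_that("energy is conserved under the periodized transform (Parseval)", {
  set.seed(5)
  for (p in c(1, 2, 5)) {
    f <- daubechies_filters(p)
    x <- rnorm(256)
    J <- max_decomposition_level(256, f$L)
    pyr <- dwt_decompose(x, f, J, "periodic")
    energy <- sum(pyr$approx^2) + sum(unlist(pyr$details)^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-8)
  }
})

test_that("db5 detail components annihilate a cubic polynomial away from boundaries", {
  t <- seq(-1, 1, length.out = 256)
  x <- 2 - t + 3 * t^2 - 0.5 * t^3
  f <- daubechies_filters(5)
  m <- mra_components(x, f, 3, "symmetric")
  # boundary influence reaches about (L-1)(2^J - 1) = 63 samples per side
  interior <- 81:176
  for (j in 1:3)
    expect_lt(max(abs(m$details[[j]][interior])), 1e-6 * max(abs(x)))
})

test_that("Haar splits an alternating signal into the detail band", {
  x <- rep(c(1, -1), 32)
  m <- mra_components(x, daubechies_filters(1), 1, "periodic")
  expect_equal(max(abs(m$approx)), 0, tolerance = 1e-12)
  expect_equal(m$details[[1]], x, tolerance = 1e-12)
})

test_that("MRA bands match the reference wavelet library (frozen fixture)", {
  fx <- read.csv(test_path("fixtures-pywt-mra.csv"), stringsAsFactors = FALSE)
  i <- 1:64
  x <- sin(0.31 * i) + 0.08 * i + cos(1.9 * i)^2
  for (wav in unique(fx$wavelet)) {
    p <- as.integer(sub("db", "", wav))
    f <- daubechies_filters(p)
    for (mode in unique(fx$mode)) {
      sub <- fx[fx$wavelet == wav & fx$mode == mode, ]
      J <- sub$J[1]
      m <- mra_components(x, f, J, mode)
      for (band in unique(sub$band)) {
        ref <- sub[sub$band == band, ]
        ref <- ref[order(ref$idx), "value"]
        got <- if (band == "approx") m$approx else
          m$details[[as.integer(sub("d", "", band))]]
        expect_equal(got, ref, tolerance = 1e-6,
                     label = paste(wav, mode, band))
      }
    }
  }
})

test_that("decomposition rejects missing values and oversized levels", {
  f <- daubechies_filters(2)
  expect_error(dwt_decompose(c(1, NA, 3, 4, 5, 6, 7, 8), f, 1), "missing")
  expect_error(dwt_decompose(rnorm(32), f, 5), "maximum level")
})

test_that("field flattening is row-major and round-trips", {
  g <- grid_spec(0, 0, 1, 2, 3)
  fld <- field(g, matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
  expect_equal(field_to_signal(fld), c(1, 2, 3, 4, 5, 6))
  set.seed(1)
  g2 <- grid_spec(0, 0, 1, 7, 5)
  f2 <- field(g2, rnorm(35))
  expect_equal(signal_to_field(field_to_signal(f2), g2)$values, f2$values)
  f2$values[3, 2] <- NA
  expect_error(field_to_signal(f2), "missing")
  # the full-state grid size pins the maximum db5 level used in practice
  expect_identical(max_decomposition_level(493561, 10), 15L)
})
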