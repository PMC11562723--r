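# Shared helpers: independent oracles and small scene builders.

# Naive single-level DWT written independently of the package's pyramid:
# explicit per-coefficient loops over the extended signal.
naive_dwt_step <- function(x, filters, mode) {
  L <- filters$L
  dec_lo <- rev(filters$lowpass)
  dec_hi <- rev(filters$highpass)
  n <- length(x)
  if (mode == "periodic") {
    xe <- if (n %% 2L) c(x, x[n]) else x
    m <- length(xe)
    nc <- m %/% 2L
    a <- d <- numeric(nc)
    for (k in seq_len(nc)) {
      for (j in seq_len(L)) {
        pos <- (2L * (k - 1L) + 1L - (j - 1L) + L %/% 2L - 1L) %% m + 1L
        a[k] <- a[k] + dec_lo[j] * xe[pos]
        d[k] <- d[k] + dec_hi[j] * xe[pos]
      }
    }
  } else {
    # symmetric half-point extension by L-1 on each side, explicit fold
    reflect <- function(i) {
      j <- (i - 1L) %% (2L * n)
      if (j < n) j + 1L else 2L * n - j
    }
    ext <- vapply((1L - (L - 1L)):(n + L - 1L), reflect, 1L)
    xe <- x[ext]
    nc <- (n + L - 1L) %/% 2L
    a <- d <- numeric(nc)
    for (k in seq_len(nc)) {
      # full-convolution sample at 0-based offset L + 2(k-1)
      for (j in seq_len(L)) {
        pos <- L + 2L * (k - 1L) - (j - 1L) + 1L
        if (pos >= 1L && pos <= length(xe)) {
          a[k] <- a[k] + dec_lo[j] * xe[pos]
          d[k] <- d[k] + dec_hi[j] * xe[pos]
        }
      }
    }
  }
  list(approx = a, detail = d)
}

naive_dwt_multilevel <- function(x, filters, J, mode) {
  a <- x
  details <- vector("list", J)
  for (j in seq_len(J)) {
    st <- naive_dwt_step(a, filters, mode)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details)
}

# brute-force IDW at one point
naive_idw <- function(px, py, sx, sy, sz, power, k) {
  d <- sqrt((sx - px)^2 + (sy - py)^2)
  nn <- order(d)[seq_len(k)]
  if (d[nn[1L]] == 0) return(sz[nn[1L]])
  w <- d[nn]^(-power)
  sum(w * sz[nn]) / sum(w)
}

# a small fully observed scene for cheap tests
tiny_scene <- function(seed = 3L, n_hours = 2L, nr = 24L, nc = 24L,
                       n_ref = 6L, n_lc = 30L, gap = 0.25) {
  simulate_scene(scene_config(
    n_rows = nr, n_cols = nc, n_hours = n_hours,
    n_reference_sites = n_ref, n_lowcost_sites = n_lc,
    gap_fraction = gap, blob_scale = 4, seed = seed))
}

# a quick synthetic regression table with known structure
toy_table <- function(n = 300, seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
    y <- 3 * x1 + sin(2 * pi * x2) + noise * rnorm(n)
    data.frame(monitor_id = sprintf("M%02d", rep(1:25, length.out = n)),
               synthetic = FALSE, pm25 = y, x1 = x1, x2 = x2, x3 = x3)
  })
}
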