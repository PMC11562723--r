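#' Orthonormal Daubechies filter pair
#'
#' Constructs the length `2p` orthonormal scaling (lowpass) and wavelet
#' (highpass) filters of the extremal-phase Daubechies family with `p`
#' vanishing moments by spectral factorization of the Daubechies half-band
#' polynomial. `p = 1` is the Haar pair.
#'
#' Sign convention: the highpass filter is the quadrature mirror
#' `g[k] = (-1)^k * h[L-1-k]` (0-based) of the lowpass `h`. All decomposition
#' and reconstruction routines in the package use this one convention.
#'
#' @param p Number of vanishing moments, integer in 1..10.
#' @return An object of class `wavelet_filters` with elements `family`, `p`,
#'   `L` (filter length `2p`), `lowpass`, `highpass`.
#' @examples
#' daubechies_filters(1)$lowpass # (1, 1)/sqrt(2)
#' f <- daubechies_filters(5)
#' sum(f$lowpass^2) # 1
#' @export
daubechies_filters <- function(p) {
  if (!is_count(p) || p > 10L)
    stopf("unsupported Daubechies order %s (supported: 1..10)", format(p))
  p <- as.integer(p)
  if (p == 1L) {
    h <- c(1, 1) / sqrt(2)
  } else {
    # roots of the binomial half-band polynomial q(y), y = sin^2(w/2)
    k <- 0:(p - 1L)
    qcoef <- choose(p - 1L + k, k)
    yr <- polyroot(qcoef)
    # Newton polish for a couple of digits (polyroot is ~1e-12 here)
    dq <- qcoef[-1L] * seq_len(p - 1L)
    for (it in 1:3) {
      qy <- vapply(yr, function(y) sum(qcoef * y^(0:(p - 1L))), complex(1))
      dy <- vapply(yr, function(y) sum(dq * y^(0:(p - 2L))), complex(1))
      yr <- yr - qy / dy
    }
    # each y-root gives a reciprocal pair in z; keep the root inside the circle
    zr <- vapply(yr, function(y) {
      b <- 2 - 4 * y
      disc <- sqrt(b * b - 4 + 0i)
      z1 <- (b + disc) / 2
      if (Mod(z1) < 1) z1 else (b - disc) / 2
    }, complex(1))
    coef <- 1 + 0i
    for (i in seq_len(p)) coef <- conv_full(coef, c(1, 1) + 0i) # (1 + z)^p
    for (z in zr) coef <- conv_full(coef, c(-z, 1))
    h <- Re(coef)
    h <- h * sqrt(2) / sum(h)
    # extremal phase: orient with the energy center of mass in the front half
    k <- 0:(length(h) - 1L)
    if (sum(k * h^2) > (length(h) - 1) / 2) h <- rev(h)
  }
  L <- length(h)
  g <- (-1)^(0:(L - 1L)) * rev(h)
  structure(list(family = if (p == 1L) "haar" else sprintf("db%d", p),
                 p = p, L = L, lowpass = h, highpass = g),
            class = "wavelet_filters")
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> %s (L = %d, %d vanishing moments)\n",
              x$family, x$L, x$p))
  invisible(x)
}

#' Maximum useful decomposition level
#'
#' The largest level `J` for which every band still holds at least one
#' meaningful coefficient: `floor(log2(n / (L - 1)))` for signal length `n`
#' and filter length `L`.
#'
#' @param n Signal length (`n >= L`).
#' @param L Filter length (or a [wavelet_filters()] object).
#' @return Integer maximum level (0 if no decomposition is meaningful).
#' @examples
#' max_decomposition_level(493561, 10) # 15
#' @export
max_decomposition_level <- function(n, L) {
  if (inherits(L, "wavelet_filters")) L <- L$L
  if (!is_count(n) || !is_count(L, min = 2L))
    stopf("n and L must be positive integers (L >= 2)")
  if (n < L)
    stopf("signal length %d is shorter than the filter length %d", n, L)
  J <- 0L
  lim <- (L - 1) * 2
  while (n >= lim) {
    J <- J + 1L
    lim <- lim * 2
  }
  J
}

# --- boundary extension -------------------------------------------------

# indices into x for positions (1-P)..(n+P) under the chosen extension
ext_indices <- function(n, P, mode) {
  i <- (1L - P):(n + P)
  switch(mode,
    symmetric = { # half-point reflection, edge value repeated
      j <- (i - 1L) %% (2L * n)
      ifelse(j < n, j + 1L, 2L * n - j)
    },
    periodic = ((i - 1L) %% n) + 1L,
    stopf("unknown extension mode '%s'", mode))
}

check_mode <- function(extension_mode) {
  if (!extension_mode %in% c("symmetric", "periodic"))
    stopf("extension_mode must be 'symmetric' or 'periodic', got '%s'",
          extension_mode)
  extension_mode
}

# --- single analysis / synthesis steps ---------------------------------
#
# 'symmetric': extend by L-1 on both sides, full convolution with the
# time-reversed filters, keep every second sample starting at offset L
# (0-based); coefficient length floor((n + L - 1) / 2).
# 'periodic': orthogonal periodized transform; odd-length inputs are padded
# by repeating the last sample. cA[k] = sum_j dec[j] x[(2k + 1 - j + L/2 - 1) mod m].

dwt_step <- function(x, filters, mode) {
  L <- filters$L
  dec_lo <- rev(filters$lowpass)
  dec_hi <- rev(filters$highpass)
  n <- length(x)
  if (mode == "symmetric") {
    xe <- x[ext_indices(n, L - 1L, mode)]
    nc <- (n + L - 1L) %/% 2L
    sel <- seq(L + 1L, by = 2L, length.out = nc)
    list(approx = conv_full(xe, dec_lo)[sel],
         detail = conv_full(xe, dec_hi)[sel],
         n = n)
  } else {
    xe <- if (n %% 2L) c(x, x[n]) else x
    m <- length(xe)
    nc <- m %/% 2L
    sh <- L %/% 2L - 1L
    a <- numeric(nc)
    d <- numeric(nc)
    base <- 2L * (0:(nc - 1L)) + 1L + sh
    for (j in seq_len(L)) {
      idx <- (base - (j - 1L)) %% m + 1L
      a <- a + dec_lo[j] * xe[idx]
      d <- d + dec_hi[j] * xe[idx]
    }
    list(approx = a, detail = d, n = n)
  }
}

idwt_step <- function(approx, detail, filters, mode, n_out) {
  L <- filters$L
  nc <- length(approx)
  stopifnot(length(detail) == nc)
  if (mode == "symmetric") {
    up_a <- numeric(2L * nc); up_a[seq(1L, by = 2L, length.out = nc)] <- approx
    up_d <- numeric(2L * nc); up_d[seq(1L, by = 2L, length.out = nc)] <- detail
    full <- conv_full(up_a, filters$lowpass) + conv_full(up_d, filters$highpass)
    out_len <- 2L * nc - L + 2L
    start <- L - 1L # 1-based: drop L-2 leading samples
    full[start:(start + out_len - 1L)][seq_len(n_out)]
  } else {
    m <- 2L * nc
    dec_lo <- rev(filters$lowpass)
    dec_hi <- rev(filters$highpass)
    sh <- L %/% 2L - 1L
    y <- numeric(m)
    base <- 2L * (0:(nc - 1L)) + 1L + sh
    for (j in seq_len(L)) {
      idx <- (base - (j - 1L)) %% m + 1L
      y[idx] <- y[idx] + dec_lo[j] * approx + dec_hi[j] * detail
    }
    y[seq_len(n_out)]
  }
}

#' Multilevel discrete wavelet decomposition (Mallat pyramid)
#'
#' Repeatedly filters the running approximation with the lowpass/highpass
#' pair after boundary extension and downsamples by two, producing a
#' coefficient pyramid with detail bands at levels `1..J` and one
#' approximation band at level `J`.
#'
#' @param signal Numeric vector without missing values.
#' @param filters A [wavelet_filters()] pair.
#' @param J Decomposition level, `1 <= J <= max_decomposition_level()`.
#' @param extension_mode `"symmetric"` (half-point reflection, the default) or
#'   `"periodic"` (orthogonal periodized transform; satisfies Parseval).
#' @return An object of class `dwt_pyramid`: `approx` (level-`J` approximation
#'   coefficients), `details` (list of detail coefficient vectors, level 1
#'   first), `lengths` (input length at each level), `J`, `filters`,
#'   `extension_mode`, `n`.
#' @export
dwt_decompose <- function(signal, filters, J,
                          extension_mode = c("symmetric", "periodic")) {
  stopifnot(inherits(filters, "wavelet_filters"))
  mode <- match.arg(extension_mode)
  if (anyNA(signal))
    stopf("signal contains %d missing values; decompose only gap-free signals",
          sum(is.na(signal)))
  n <- length(signal)
  maxJ <- max_decomposition_level(n, filters$L)
  if (!is_count(J) || J > maxJ)
    stopf("J = %s exceeds the maximum level %d for length %d with %s",
          format(J), maxJ, n, filters$family)
  J <- as.integer(J)
  a <- as.numeric(signal)
  details <- vector("list", J)
  lengths <- integer(J)
  for (j in seq_len(J)) {
    lengths[j] <- length(a)
    st <- dwt_step(a, filters, mode)
    details[[j]] <- st$detail
    a <- st$approx
  }
  structure(list(approx = a, details = details, lengths = lengths,
                 J = J, filters = filters, extension_mode = mode, n = n),
            class = "dwt_pyramid")
}

#' @export
print.dwt_pyramid <- function(x, ...) {
  cat(sprintf("<dwt_pyramid> %s, J = %d, mode '%s', n = %d; band lengths: %s | %d\n",
              x$filters$family, x$J, x$extension_mode, x$n,
              paste(vapply(x$details, length, 1L), collapse = ", "),
              length(x$approx)))
  invisible(x)
}

#' Reconstruct a signal from a coefficient pyramid
#'
#' Inverts [dwt_decompose()]; with unmodified coefficients the round trip is
#' exact to floating-point precision in both extension modes.
#'
#' @param pyramid A `dwt_pyramid`.
#' @return Numeric vector of length `pyramid$n`.
#' @export
dwt_reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "dwt_pyramid"))
  a <- pyramid$approx
  for (j in rev(seq_len(pyramid$J))) {
    a <- idwt_step(a, pyramid$details[[j]], pyramid$filters,
                   pyramid$extension_mode, pyramid$lengths[j])
  }
  a
}

#' Additive multiresolution components of a signal
#'
#' Decomposes the signal to level `J` and reconstructs each band separately
#' (all other bands zeroed), yielding the smooth approximation `l_J` and
#' detail components `h_1 .. h_J`, each of the input's full length. By
#' linearity of the exact inverse transform, `l_J + h_1 + ... + h_J`
#' reproduces the signal.
#'
#' @inheritParams dwt_decompose
#' @return An object of class `mra_components`: `approx` (`l_J`), `details`
#'   (list `h_1..h_J`), `J`, `filters`, `extension_mode`, `n`.
#' @export
mra_components <- function(signal, filters, J,
                           extension_mode = c("symmetric", "periodic")) {
  mode <- match.arg(extension_mode)
  pyr <- dwt_decompose(signal, filters, J, mode)
  zero <- function(v) lapply(v, function(x) numeric(length(x)))
  approx_only <- pyr
  approx_only$details <- zero(pyr$details)
  out_details <- vector("list", pyr$J)
  for (j in seq_len(pyr$J)) {
    p <- pyr
    p$approx <- numeric(length(pyr$approx))
    p$details <- zero(pyr$details)
    p$details[[j]] <- pyr$details[[j]]
    out_details[[j]] <- dwt_reconstruct(p)
  }
  structure(list(approx = dwt_reconstruct(approx_only), details = out_details,
                 J = pyr$J, filters = filters, extension_mode = mode,
                 n = pyr$n),
            class = "mra_components")
}

#' @export
print.mra_components <- function(x, ...) {
  cat(sprintf("<mra_components> %s, l_%d + h_1..h_%d, n = %d, mode '%s'\n",
              x$filters$family, x$J, x$J, x$n, x$extension_mode))
  invisible(x)
}

#' Flatten a gridded field to a 1-D signal and back
#'
#' Fields are flattened row-major (row 0 first, columns left to right) so a
#' grid of `n_rows * n_cols` cells becomes a signal of that length; wavelet
#' decomposition operates on this 1-D spatial scan. The round trip is the
#' identity.
#'
#' @param f A gap-free [field()].
#' @return `field_to_signal`: numeric vector of length `n_cells(grid)`.
#' @export
field_to_signal <- function(f) {
  stopifnot(inherits(f, "field"))
  if (anyNA(f$values))
    stopf("field '%s' has %d missing cells; decompose only gap-filled fields",
          f$variable, sum(is.na(f$values)))
  as.vector(t(f$values))
}

#' @rdname field_to_signal
#' @param signal Numeric vector of length `n_cells(grid)` in row-major order.
#' @param grid A [grid_spec()].
#' @param variable,hour Metadata for the rebuilt field.
#' @return `signal_to_field`: a [field()].
#' @export
signal_to_field <- function(signal, grid, variable = "value", hour = 0L) {
  field(grid, signal, variable = variable, hour = hour)
}
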