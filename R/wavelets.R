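# Wavelet machinery: periodized db6 DWT/IDWT and a Mexican-hat CWT.
#
# The discrete transform uses circular (periodized) convolution so that the
# transform is exactly orthogonal at every dyadic length: Parseval holds to
# machine precision and inversion is the transpose. Signals whose length is
# not a multiple of 2^level are zero-padded (padding carries no energy).

# Daubechies-6 (12-tap) orthogonal decomposition filters.
DB6_LO <- c(
  -0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
  -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
  -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
  0.7511339080210954, 0.49462389039845306, 0.11154074335010947
)
DB6_HI <- rev(DB6_LO) * rep_len(c(-1, 1), length(DB6_LO))

# Periodize a filter to length n (wrap taps that overhang the circle).
periodize_filter <- function(h, n) {
  out <- numeric(n)
  idx <- ((seq_along(h) - 1) %% n) + 1
  for (i in seq_along(h)) out[idx[i]] <- out[idx[i]] + h[i]
  out
}

# One analysis step: x (even length) -> list(a, d), each length n/2.
# Convention: a[k] = sum_n h[n] x[(2k + L/2 - n) mod N], matching the
# standard periodization phase so coefficients align with wave positions.
dwt_step <- function(x, lo = DB6_LO, hi = DB6_HI) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  half <- length(lo) / 2
  k2 <- seq(0L, n - 2L, by = 2L)
  a <- numeric(n / 2)
  d <- numeric(n / 2)
  for (j in seq_along(lo)) {
    idx <- ((k2 + half - (j - 1L)) %% n) + 1L
    a <- a + lo[j] * x[idx]
    d <- d + hi[j] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis step (transpose of dwt_step): exact inverse by orthogonality.
idwt_step <- function(a, d, lo = DB6_LO, hi = DB6_HI) {
  n <- 2L * length(a)
  half <- length(lo) / 2
  k2 <- seq(0L, n - 2L, by = 2L)
  x <- numeric(n)
  for (j in seq_along(lo)) {
    idx <- ((k2 + half - (j - 1L)) %% n) + 1L
    x[idx] <- x[idx] + lo[j] * a + hi[j] * d
  }
  x
}

#' Multilevel periodized db6 wavelet decomposition
#'
#' Decomposes a signal into approximation and detail coefficient blocks using
#' the orthogonal Daubechies-6 filter pair with circular boundary handling.
#' Inputs whose length is not a multiple of `2^level` are zero-padded at the
#' end before transforming; the original length is stored so [wave_rec()]
#' returns a same-length signal.
#'
#' @param x Numeric signal.
#' @param level Decomposition depth (positive integer).
#' @return List of class `"wavedec"` with elements `a` (coarsest
#'   approximation), `d` (list of detail blocks, coarsest first), `level`,
#'   and `n` (original length). Total coefficient energy equals padded-signal
#'   energy (Parseval).
#' @export
wave_dec <- function(x, level) {
  if (level < 1 || level != round(level)) stop("level must be a positive integer")
  n <- length(x)
  block <- 2^level
  n_pad <- as.integer(ceiling(n / block) * block)
  if (n_pad < 2^level) stop("signal too short for requested level")
  xp <- c(x, numeric(n_pad - n))
  d <- vector("list", level)
  a <- xp
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    a <- st$a
    d[[level - l + 1L]] <- st$d
  }
  structure(list(a = a, d = d, level = level, n = n), class = "wavedec")
}

#' Reconstruct a signal from a db6 decomposition
#'
#' Inverse of [wave_dec()]; coefficient blocks may be modified (e.g.
#' thresholded) before reconstruction.
#'
#' @param dec A `"wavedec"` object.
#' @return Numeric signal of the original length.
#' @export
wave_rec <- function(dec) {
  a <- dec$a
  for (l in seq_len(dec$level)) a <- idwt_step(a, dec$d[[l]])
  a[seq_len(dec$n)]
}

#' Flatten a wavelet decomposition into one coefficient vector
#'
#' Concatenates the approximation block and the detail blocks from coarsest
#' to finest. For a fixed `(level, input length)` the output length is fixed,
#' which makes it usable as a feature vector.
#'
#' @param dec A `"wavedec"` object.
#' @return Numeric vector of coefficients.
#' @export
wave_coefs <- function(dec) c(dec$a, unlist(dec$d, use.names = FALSE))

#' Mexican-hat mother wavelet
#'
#' `psi(x) = 2/(sqrt(3) pi^(1/4)) (1 - x^2) exp(-x^2/2)`, the (normalized)
#' negative second derivative of a Gaussian. Its band-pass character around
#' the QRS frequency range makes it the standard choice for R-wave detection.
#'
#' @param x Numeric evaluation points.
#' @return Numeric vector `psi(x)`.
#' @export
mexican_hat <- function(x) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - x^2) * exp(-x^2 / 2)
}

#' Continuous wavelet transform
#'
#' Computes `W(a, b) = a^(-1/2) * sum_t x[t] psi((t - b) / a)` over all
#' integer translations `b` and the supplied scales, i.e. the CWT with the
#' sample index as the time unit. The transform is linear in the input.
#'
#' @param x Numeric signal.
#' @param scales Positive numeric vector of scale factors `a`.
#' @param wavelet Mother wavelet function (default [mexican_hat()]).
#' @return Numeric matrix with `length(scales)` rows and `length(x)` columns;
#'   row `i` holds the coefficients at scale `scales[i]`.
#' @export
ecg_cwt <- function(x, scales, wavelet = mexican_hat) {
  if (any(scales <= 0)) stop("scales must be positive")
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    half <- ceiling(9 * a)   # psi(9) ~ 2e-16: truncation below machine eps
    kern <- wavelet(seq(-half, half) / a) / sqrt(a)
    # cross-correlation via zero-padded FFT (power-of-2 length for speed)
    m <- length(kern)
    nfft <- stats::nextn(n + m - 1, 2)
    fx <- stats::fft(c(x, numeric(nfft - n)))
    fk <- stats::fft(c(kern, numeric(nfft - m)))
    full <- Re(stats::fft(fx * Conj(fk), inverse = TRUE)) / nfft
    # correlation with the kernel centered at offset `half`: rotate by -half
    out[i, ] <- c(full[seq(nfft - half + 1, nfft)],
                  full[seq_len(nfft - half)])[seq_len(n)]
  }
  out
}
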