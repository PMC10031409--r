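# Independent oracles and small fixture builders, written as plain
# double-loop / direct-summation code so that they share nothing with the
# production FFT paths.

# Direct DFT synthesis of the band-embedded spectrum: real time signal of
# length n_fft from band coefficients s11 sitting at absolute bins
# k0..k0+n-1 (one-sided, with the conjugate image implied).
oracle_band_to_time <- function(s11, freq_hz, n_fft) {
  n <- length(freq_hz)
  df <- (freq_hz[n] - freq_hz[1]) / (n - 1)
  k0 <- round(freq_hz[1] / df)
  x <- numeric(n_fft)
  for (t in seq(0L, n_fft - 1L)) {
    acc <- 0
    for (k in seq_len(n)) {
      acc <- acc + Re(s11[k] * exp(2i * pi * (k0 + k - 1) * t / n_fft))
    }
    x[t + 1L] <- 2 * acc / n_fft
  }
  x
}

# Naive double-loop evaluation of the filter-bank correlation
# C[a, tau] = sum_n x[n] * pref * psi((n - tau)/alpha), psi the truncated
# sinc supported on [0, T-1].
oracle_wavelet_transform <- function(x, T, scales, shifts, norm = "l2") {
  centre <- (T - 1) / 2
  psi <- function(t) {
    out <- numeric(length(t))
    inside <- t >= 0 & t <= (T - 1)
    u <- t[inside] - centre
    v <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
    out[inside] <- v
    out
  }
  C <- matrix(0, length(scales), length(shifts))
  for (a in seq_along(scales)) {
    alpha <- scales[a]
    pref <- if (norm == "l1") 1 / alpha else 1 / sqrt(alpha)
    for (s in seq_along(shifts)) {
      tau <- shifts[s]
      n <- seq_along(x) - 1L
      C[a, s] <- sum(x * pref * psi((n - tau) / alpha))
    }
  }
  C
}

# Random time-signal set on a given geometry.
random_tset <- function(geom, n = 64, seed = 1, dt = 1e-10) {
  set.seed(seed)
  time_signal_set(geom, dt, matrix(rnorm(geom$L * n), geom$L, n))
}

# Random coefficient grid.
random_grid <- function(nscale = 6, nshift = 11, seed = 1, antenna = NA_integer_) {
  set.seed(seed)
  coefficient_grid(matrix(rnorm(nscale * nshift), nscale, nshift),
                   seq_len(nscale), seq(0L, nshift - 1L), antenna)
}

# Nearest antenna (euclidean, to the antenna elements) of a point.
nearest_antenna <- function(geom, q) {
  pts <- mwstroke:::geometry_points(geom)
  which.min((pts$antennas[, 1] - q[1])^2 + (pts$antennas[, 2] - q[2])^2)
}

# Stroke placement used by localization experiments: radial fraction `frac`
# along the bearing of antenna `a`, jittered off the exact bearing so the
# position is generic (a stroke never sits exactly on an antenna ray).
place_stroke <- function(geom, a, jitter = 0, frac = 0.6) {
  th <- geom$angles[a] + jitter * 2 * pi / geom$L
  frac * c(geom$semi_axes[1] * cos(th), geom$semi_axes[2] * sin(th))
}

# Circular antenna distance.
ring_dist <- function(i, j, L) min((i - j) %% L, (j - i) %% L)
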