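# Normalised sinc, sin(pi x)/(pi x) with sinc(0) = 1.
nsinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

#' Truncated-sinc mother wavelet
#'
#' The radiated stepped-frequency signal is rectangular in the frequency
#' domain, hence a sinc pulse in time; the matched mother wavelet is that
#' sinc truncated symmetrically around its main lobe to `T` samples and
#' shifted onto the non-negative index range `0..T-1`, so its peak of 1 sits
#' at the centre sample `(T-1)/2` and its zero crossings fall on the other
#' integer offsets. A plain sinc has a small non-zero mean (it is not an
#' admissible wavelet in the strict sense); the `"zero_mean_sinc"` convention
#' subtracts the sample mean to restore a zero DC response.
#'
#' @param T Odd support length in samples, at least 3 (default 33).
#' @param convention `"plain_sinc"` (default, the truncated sinc exactly) or
#'   `"zero_mean_sinc"`.
#' @return Object of class `mother_wavelet`: list with `T`, `samples`,
#'   `convention`, and `offset` (the mean that was subtracted).
#' @export
#' @examples
#' w <- make_mother_wavelet(9)
#' w$samples  # 1 at the centre, 0 at other integer offsets
make_mother_wavelet <- function(T = 33L, convention = c("plain_sinc", "zero_mean_sinc")) {
  convention <- match.arg(convention)
  T <- as.integer(T)
  if (is.na(T) || T < 3L || T %% 2L == 0L)
    stop("parameter error: wavelet support T must be an odd integer >= 3")
  centre <- (T - 1L) / 2
  samples <- nsinc(seq(0L, T - 1L) - centre)
  offset <- 0
  if (convention == "zero_mean_sinc") {
    offset <- mean(samples)
    samples <- samples - offset
  }
  structure(list(T = T, samples = samples, convention = convention,
                 offset = offset),
            class = "mother_wavelet")
}

#' @export
print.mother_wavelet <- function(x, ...) {
  cat(sprintf("Truncated sinc mother wavelet: T = %d samples, %s\n",
              x$T, x$convention))
  invisible(x)
}

#' Sample a scaled wavelet filter
#'
#' Evaluates the dilated mother wavelet `prefactor * psi(n / alpha)` on the
#' integer grid covering its stretched support `[0, alpha * (T - 1)]`.
#' Non-integer scales are supported by direct evaluation of the continuous
#' truncated sinc (no interpolation of pre-sampled filters). The prefactor
#' is `1/alpha` under the `"l1"` norm and `1/sqrt(alpha)` under `"l2"`.
#'
#' @param w A [make_mother_wavelet()] result.
#' @param alpha Scale, positive.
#' @param norm `"l2"` (default, preserves energy comparability across
#'   scales) or `"l1"`.
#' @return Numeric vector of filter taps; tap `m + 1` is the filter value at
#'   integer time offset `m` from the filter origin.
#' @export
scaled_wavelet <- function(w, alpha, norm = c("l2", "l1")) {
  stopifnot(inherits(w, "mother_wavelet"))
  norm <- match.arg(norm)
  if (!is.finite(alpha) || alpha <= 0)
    stop("parameter error: scale alpha must be > 0")
  centre <- (w$T - 1L) / 2
  n <- seq(0L, floor(alpha * (w$T - 1L) + 1e-9))
  pref <- if (norm == "l1") 1 / alpha else 1 / sqrt(alpha)
  pref * (nsinc(n / alpha - centre) - w$offset)
}

#' Filter-bank configuration
#'
#' Scale and shift grids of the wavelet-matched filter bank. The defaults
#' cover both low- and high-frequency signal content: 64 linear scales from
#' 1 to 64, and one shift per sample of the analysed response (`shifts =
#' NULL`).
#'
#' @param scales Strictly increasing positive scales.
#' @param shifts Integer shift grid (sample offsets, non-negative), or
#'   `NULL` for every sample of the input.
#' @param norm `"l2"` or `"l1"` filter normalisation.
#' @return Object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(scales = seq(1, 64, length.out = 64),
                               shifts = NULL, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  scales <- as.numeric(scales)
  if (length(scales) == 0L || any(!is.finite(scales)) || any(scales <= 0) ||
      is.unsorted(scales, strictly = TRUE))
    stop("parameter error: scales must be strictly increasing and positive")
  if (!is.null(shifts)) {
    shifts <- as.integer(shifts)
    if (length(shifts) == 0L || any(is.na(shifts)))
      stop("parameter error: empty or invalid shift grid")
  }
  structure(list(scales = scales, shifts = shifts, norm = norm),
            class = "filter_bank_config")
}

#' Wavelet coefficient grid of one antenna's target response
#'
#' @param C Real matrix of coefficients, scales in rows, shifts in columns.
#' @param scale_axis,shift_axis Axis values matching the grid shape.
#' @param antenna Antenna id the grid belongs to (optional).
#' @return Object of class `coefficient_grid`.
#' @export
coefficient_grid <- function(C, scale_axis, shift_axis, antenna = NA_integer_) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (nrow(C) != length(scale_axis) || ncol(C) != length(shift_axis))
    stop("consistency error: grid shape must match the scale/shift axes")
  if (any(!is.finite(C)))
    stop("consistency error: coefficient grid contains non-finite values")
  structure(list(C = C, scale_axis = as.numeric(scale_axis),
                 shift_axis = as.numeric(shift_axis),
                 antenna = as.integer(antenna)),
            class = "coefficient_grid")
}

#' @export
print.coefficient_grid <- function(x, ...) {
  cat(sprintf("Wavelet coefficient grid%s: %d scales x %d shifts\n",
              if (is.na(x$antenna)) "" else sprintf(" (antenna %d)", x$antenna),
              nrow(x$C), ncol(x$C)))
  invisible(x)
}

#' Wavelet transform through the matched-filter bank
#'
#' Correlates a target response with every scaled, shifted copy of the
#' mother wavelet:
#' \deqn{C_{\alpha,\tau} = \sum_n \delta[n] \, \frac{1}{\sqrt{\alpha}}
#'   \psi\!\left(\frac{n - \tau}{\alpha}\right),}
#' (prefactor `1/alpha` under the `"l1"` norm), with the response
#' zero-padded outside its support --- the physical signal is zero before
#' the first echo, so no reflection padding is used. Computed per scale via
#' FFT cross-correlation; numerically identical (to roundoff) to the direct
#' double-loop summation.
#'
#' @param x Numeric vector, one antenna's target response.
#' @param w A [make_mother_wavelet()] result.
#' @param cfg A [filter_bank_config()].
#' @param antenna Antenna id recorded on the output grid.
#' @return A [coefficient_grid()] of shape `length(scales)` x
#'   `length(shifts)`.
#' @export
wavelet_transform <- function(x, w, cfg = filter_bank_config(),
                              antenna = NA_integer_) {
  stopifnot(inherits(w, "mother_wavelet"), inherits(cfg, "filter_bank_config"))
  x <- as.numeric(x)
  nx <- length(x)
  if (nx == 0L) stop("parameter error: empty input signal")
  shifts <- if (is.null(cfg$shifts)) seq(0L, nx - 1L) else cfg$shifts
  if (any(shifts < 0L) || any(shifts > nx - 1L))
    stop("parameter error: shifts must lie within the signal support 0..length(x)-1")

  lh_max <- floor(max(cfg$scales) * (w$T - 1L) + 1e-9) + 1L
  m <- 2L
  while (m < nx + lh_max) m <- m * 2L
  X <- stats::fft(c(x, rep(0, m - nx)))

  C <- matrix(0, length(cfg$scales), length(shifts))
  for (si in seq_along(cfg$scales)) {
    h <- scaled_wavelet(w, cfg$scales[si], norm = cfg$norm)
    H <- stats::fft(c(h, rep(0, m - length(h))))
    r <- Re(stats::fft(Conj(H) * X, inverse = TRUE)) / m
    C[si, ] <- r[shifts + 1L]
  }
  coefficient_grid(C, cfg$scales, shifts, antenna)
}

#' Transform every antenna of a target-response set
#'
#' @param resp A [target_response_set()].
#' @param w A [make_mother_wavelet()] result.
#' @param cfg A [filter_bank_config()].
#' @return List of [coefficient_grid()]s, one per antenna, in antenna order.
#' @export
wavelet_transform_set <- function(resp, w, cfg = filter_bank_config()) {
  stopifnot(inherits(resp, "target_response_set"))
  lapply(seq_len(nrow(resp$responses)), function(i)
    wavelet_transform(resp$responses[i, ], w, cfg, antenna = i))
}
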