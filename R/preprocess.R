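#' Per-antenna real time-domain signals
#'
#' @param geometry An [array_geometry()].
#' @param dt Sample period in seconds, positive.
#' @param samples Real matrix, one row per antenna, equal-length series.
#' @return Object of class `time_signal_set`.
#' @export
time_signal_set <- function(geometry, dt, samples) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.finite(dt) || dt <= 0) stop("parameter error: dt must be > 0")
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) != geometry$L)
    stop("geometry error: one row of samples per antenna required")
  structure(list(geometry = geometry, dt = dt, samples = samples),
            class = "time_signal_set")
}

#' @export
print.time_signal_set <- function(x, ...) {
  cat(sprintf("Time signal set: %d antennas x %d samples, dt = %.4g ns\n",
              nrow(x$samples), ncol(x$samples), 1e9 * x$dt))
  invisible(x)
}

#' Per-antenna target responses after background removal
#'
#' @param source A `time_signal_set` the responses were derived from.
#' @param approach One of `"app1"`, `"app2"`, `"app3"`, `"app4"`, `"app5a"`,
#'   `"app5b"`.
#' @param responses Real matrix of responses, same shape as the source
#'   samples.
#' @param clipped Logical; `TRUE` if negative samples were clipped to zero.
#' @return Object of class `target_response_set`.
#' @export
target_response_set <- function(source, approach, responses, clipped = FALSE) {
  approach <- match.arg(approach, c("app1", "app2", "app3", "app4", "app5a", "app5b"))
  responses <- as.matrix(responses)
  if (!identical(dim(responses), dim(source$samples)))
    stop("consistency error: responses must match the source signal shape")
  structure(list(geometry = source$geometry, dt = source$dt,
                 approach = approach, responses = responses,
                 clipped = isTRUE(clipped)),
            class = "target_response_set")
}

#' @export
print.target_response_set <- function(x, ...) {
  cat(sprintf("Target responses (%s%s): %d antennas x %d samples\n",
              x$approach, if (x$clipped) ", clipped" else "",
              nrow(x$responses), ncol(x$responses)))
  invisible(x)
}

#' Transform frequency-domain sweeps to real time-domain signals
#'
#' Embeds the band-limited reflection coefficients into a full one-sided
#' spectrum at their absolute frequency bins (bins below the band start stay
#' zero), enforces conjugate symmetry, and applies the inverse FFT to obtain
#' a real signal per antenna. The sample period is `1 / (n_fft * df)` where
#' `df` is the sweep's frequency step. By default no window is applied: the
#' radiated stepped-frequency signal has a rectangular band shape, which is
#' exactly what the sinc matched filter downstream is built for.
#'
#' @param s A [sweep_set()].
#' @param n_fft FFT length, or `"auto"` for the smallest power of two that
#'   accommodates twice the highest band bin.
#' @param window `"none"` (default) or `"hann"` taper over the band.
#' @return A [time_signal_set()].
#' @export
to_time_domain <- function(s, n_fft = "auto", window = c("none", "hann")) {
  stopifnot(inherits(s, "sweep_set"))
  window <- match.arg(window)
  freq <- s$freq_hz
  n <- length(freq)
  df <- (freq[n] - freq[1]) / (n - 1)
  k0 <- as.integer(round(freq[1] / df))
  kmax <- k0 + n - 1L
  if (identical(n_fft, "auto")) {
    n_fft <- 2L
    while (n_fft < 2L * (kmax + 1L)) n_fft <- n_fft * 2L
  }
  n_fft <- as.integer(n_fft)
  if (n_fft < 2L * kmax)
    stop("parameter error: n_fft must be at least twice the highest band bin")

  taper <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  } else rep(1, n)

  L <- s$geometry$L
  out <- matrix(0, L, n_fft)
  half <- n_fft %/% 2L
  for (i in seq_len(L)) {
    spec <- complex(length.out = n_fft)
    spec[(k0 + 1L):(kmax + 1L)] <- s$s11[i, ] * taper
    idx <- 2:half
    spec[n_fft + 2L - idx] <- Conj(spec[idx])
    out[i, ] <- Re(stats::fft(spec, inverse = TRUE)) / n_fft
  }
  time_signal_set(s$geometry, dt = 1 / (n_fft * df), samples = out)
}

#' Background removal by healthy-brain reference subtraction (App-1)
#'
#' The ideal reference method: subtract the backscattered signal of the same
#' patient's healthy brain from the stroke-bearing measurement, antenna by
#' antenna. Requires a baseline record, which is rarely available in
#' practice, but isolates the target echo exactly in the noiseless limit.
#'
#' @param target,healthy `time_signal_set`s with identical geometry, sample
#'   period and length.
#' @return A [target_response_set()] with `approach = "app1"`.
#' @export
remove_background_app1 <- function(target, healthy) {
  stopifnot(inherits(target, "time_signal_set"), inherits(healthy, "time_signal_set"))
  if (!identical(dim(target$samples), dim(healthy$samples)) ||
      target$dt != healthy$dt || target$geometry$L != healthy$geometry$L)
    stop("consistency error: target and healthy sets must share geometry, dt and length")
  target_response_set(target, "app1", target$samples - healthy$samples)
}

#' Background removal by adjacent-antenna (rotation) subtraction (App-2)
#'
#' Subtracts the signal of the circularly preceding antenna: the background
#' is nearly common between slightly displaced antenna positions, so their
#' difference suppresses it. Antenna 1 wraps to antenna `L`.
#'
#' @param target A `time_signal_set`.
#' @return A [target_response_set()] with `approach = "app2"`.
#' @export
remove_background_app2 <- function(target) {
  stopifnot(inherits(target, "time_signal_set"))
  L <- target$geometry$L
  prev <- c(L, seq_len(L - 1L))
  target_response_set(target, "app2", target$samples - target$samples[prev, , drop = FALSE])
}

#' Background removal by mirror-antenna subtraction (App-3)
#'
#' Exploits the head's left/right symmetry: the background at antenna `i` is
#' estimated by the signal at the antenna placed symmetrically opposite,
#' `mirror_index(i, L)`. The responses are exactly antisymmetric across the
#' mirror map, `delta_i = -delta_mirror(i)`, so only `L/2` independent series
#' result and the two symmetry-axis antennas get identically zero responses.
#' Optionally the negative samples are clipped to zero afterwards, which
#' breaks the antisymmetry and disjoins the supports of mirrored responses so
#' that all `L` positions carry a usable signal.
#'
#' @param target A `time_signal_set`; the antenna count must be even.
#' @param clip_negative Clip negative samples to zero (default `FALSE`).
#' @return A [target_response_set()] with `approach = "app3"`.
#' @export
remove_background_app3 <- function(target, clip_negative = FALSE) {
  stopifnot(inherits(target, "time_signal_set"))
  L <- target$geometry$L
  m <- mirror_index(seq_len(L), L)
  resp <- target$samples - target$samples[m, , drop = FALSE]
  if (clip_negative) resp <- pmax(resp, 0)
  target_response_set(target, "app3", resp, clipped = clip_negative)
}

#' Background removal by average subtraction (App-4)
#'
#' The background at antenna `i` is estimated as the average of the other
#' backscattered signals: either all antennas (`mode = "all"`, the mean of
#' the whole set including `i`, so that responses are column mean-centred) or
#' the `2k` nearest circular neighbours excluding `i`
#' (`mode = "neighbors"`).
#'
#' @param target A `time_signal_set`.
#' @param mode `"all"` or `"neighbors"`.
#' @param k Neighbour half-width for `mode = "neighbors"`, in `1..L/2-1`.
#' @return A [target_response_set()] with `approach = "app4"`.
#' @export
remove_background_app4 <- function(target, mode = c("all", "neighbors"), k = 1L) {
  stopifnot(inherits(target, "time_signal_set"))
  mode <- match.arg(mode)
  L <- target$geometry$L
  x <- target$samples
  if (mode == "all") {
    bg <- matrix(colMeans(x), L, ncol(x), byrow = TRUE)
  } else {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > L %/% 2L - 1L)
      stop("parameter error: neighbour half-width k must be in 1..L/2-1")
    bg <- matrix(0, L, ncol(x))
    offs <- c(-seq_len(k), seq_len(k))
    for (i in seq_len(L)) {
      j <- ((i - 1L + offs) %% L) + 1L
      bg[i, ] <- colMeans(x[j, , drop = FALSE])
    }
  }
  target_response_set(target, "app4", x - bg)
}

#' Background removal by opposite-antenna averaging (App-5)
#'
#' The novel estimator: the background at antenna `i` is the average of
#' either the adjacent and the two opposite signals (variant `"a"`: antennas
#' `i+1`, `mirror(i)` and `mirror(i+1)`) or the two opposite signals alone
#' (variant `"b"`: `mirror(i)` and `mirror(i+1)`), with circular adjacency.
#' Unlike App-3, the resulting responses are not antisymmetric across the
#' mirror map, so all `L` positions carry independent information.
#'
#' @param target A `time_signal_set`; the antenna count must be even.
#' @param variant `"a"` (three-signal average) or `"b"` (two-signal average).
#' @return A [target_response_set()] with approach `"app5a"` or `"app5b"`.
#' @export
remove_background_app5 <- function(target, variant = c("a", "b")) {
  stopifnot(inherits(target, "time_signal_set"))
  variant <- match.arg(variant)
  L <- target$geometry$L
  x <- target$samples
  nxt <- c(seq_len(L - 1L) + 1L, 1L)
  m <- mirror_index(seq_len(L), L)
  m_nxt <- mirror_index(nxt, L)
  # computed as an average of differences so that identical signals yield an
  # exactly zero response (x - (x+x+x)/3 is not exactly 0 in floating point)
  resp <- if (variant == "a") {
    ((x - x[nxt, , drop = FALSE]) + (x - x[m, , drop = FALSE]) +
       (x - x[m_nxt, , drop = FALSE])) / 3
  } else {
    ((x - x[m, , drop = FALSE]) + (x - x[m_nxt, , drop = FALSE])) / 2
  }
  target_response_set(target, if (variant == "a") "app5a" else "app5b", resp)
}

#' Dispatch a background-removal approach by name
#'
#' Convenience wrapper used by the pipeline and the command line.
#'
#' @param target A `time_signal_set`.
#' @param approach One of `"app1"`, `"app2"`, `"app3"`, `"app4"`, `"app5a"`,
#'   `"app5b"`.
#' @param healthy Healthy-reference `time_signal_set`, required for
#'   `"app1"`.
#' @param clip_negative Passed to [remove_background_app3()].
#' @param app4_mode,app4_k Passed to [remove_background_app4()].
#' @return A [target_response_set()].
#' @export
remove_background <- function(target, approach, healthy = NULL,
                              clip_negative = FALSE,
                              app4_mode = "all", app4_k = 1L) {
  approach <- match.arg(approach, c("app1", "app2", "app3", "app4", "app5a", "app5b"))
  switch(approach,
    app1 = {
      if (is.null(healthy))
        stop("usage error: approach 'app1' requires a healthy reference set")
      remove_background_app1(target, healthy)
    },
    app2 = remove_background_app2(target),
    app3 = remove_background_app3(target, clip_negative = clip_negative),
    app4 = remove_background_app4(target, mode = app4_mode, k = app4_k),
    app5a = remove_background_app5(target, variant = "a"),
    app5b = remove_background_app5(target, variant = "b")
  )
}
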