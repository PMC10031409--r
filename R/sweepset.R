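#' Validate an equidistant frequency grid
#'
#' Checks a vector of frequency samples in Hz: at least two samples, strictly
#' increasing, and equidistant to within a relative tolerance of 1e-6 on the
#' nominal spacing. The internal frequency unit is always Hz.
#'
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return The validated grid, invisibly usable; errors otherwise.
#' @export
validate_frequency_grid <- function(freq_hz) {
  freq_hz <- as.numeric(freq_hz)
  n <- length(freq_hz)
  if (n < 2L || any(!is.finite(freq_hz)))
    stop("format error: frequency grid needs >= 2 finite samples")
  df <- (freq_hz[n] - freq_hz[1]) / (n - 1)
  if (df <= 0) stop("format error: frequency grid must be strictly increasing")
  steps <- diff(freq_hz)
  if (any(abs(steps - df) > 1e-6 * df))
    stop("format error: frequency grid is not equidistant (rel. tol 1e-6)")
  freq_hz
}

#' Per-antenna complex reflection-coefficient sweeps
#'
#' Container for the mono-static S11 measurements of a whole array: one
#' complex reflection-coefficient sweep per antenna, all on a shared
#' equidistant frequency grid. Antenna ids are 1-based and follow the
#' geometry's numbering around the head.
#'
#' @param geometry An [array_geometry()].
#' @param freq_hz Shared frequency grid in Hz, strictly increasing,
#'   equidistant within relative tolerance 1e-6.
#' @param s11 Complex matrix, one row per antenna (`geometry$L` rows),
#'   one column per frequency.
#'
#' @return An object of class `sweep_set` with elements `geometry`,
#'   `freq_hz`, `s11`.
#' @export
sweep_set <- function(geometry, freq_hz, s11) {
  if (!inherits(geometry, "array_geometry"))
    stop("geometry error: 'geometry' must be an array_geometry")
  freq_hz <- validate_frequency_grid(freq_hz)
  s11 <- as.matrix(s11)
  if (!is.complex(s11)) storage.mode(s11) <- "complex"
  if (nrow(s11) != geometry$L)
    stop(sprintf("geometry error: s11 has %d rows but geometry has L = %d antennas",
                 nrow(s11), geometry$L))
  if (ncol(s11) != length(freq_hz))
    stop("grid-mismatch error: s11 columns do not match the frequency grid length")
  if (any(!is.finite(Re(s11))) || any(!is.finite(Im(s11))))
    stop("format error: non-finite reflection coefficients")
  structure(list(geometry = geometry, freq_hz = freq_hz, s11 = s11),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  n <- length(x$freq_hz)
  cat(sprintf("S11 sweep set: %d antennas x %d frequencies, %.3f-%.3f GHz\n",
              x$geometry$L, n, x$freq_hz[1] / 1e9, x$freq_hz[n] / 1e9))
  invisible(x)
}

#' Default measurement band
#'
#' The system's stepped-frequency grid: 401 equidistant points over
#' 1.1--3 GHz.
#'
#' @return Numeric vector of 401 frequencies in Hz.
#' @export
default_band <- function() seq(1.1e9, 3e9, length.out = 401L)
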