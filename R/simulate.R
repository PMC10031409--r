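#' Phantom measurement scenario
#'
#' Parameters of the synthetic head-phantom measurement: an optional stroke
#' (modelled as a point scatterer inside the head ellipse), its echo strength
#' relative to the skull echo, the effective tissue permittivity controlling
#' in-tissue propagation speed, and the clutter/noise levels of the
#' measurement chain. All amplitudes are relative to the unit-amplitude
#' air--skull echo.
#'
#' @param stroke_center Length-2 numeric, stroke coordinates in metres within
#'   the head cross-section, or `NULL` for a healthy brain.
#' @param stroke_reflectivity Echo amplitude of the stroke relative to the
#'   skull echo before tissue attenuation (default 0.05).
#' @param effective_permittivity Homogeneous effective relative permittivity
#'   of the head tissue (default 45); in-tissue speed is
#'   `c / sqrt(effective_permittivity)`.
#' @param clutter_level Relative standard deviation of the smooth, per-antenna
#'   asymmetric clutter (default 0.01).
#' @param noise_level Relative standard deviation of complex white measurement
#'   noise (default 0.005).
#' @param attenuation_length 1/e amplitude decay length in metres of the
#'   in-tissue path (default 0.05).
#' @param seed Integer seed controlling the clutter (and, by derivation,
#'   noise) realizations.
#'
#' @return An object of class `phantom_scenario`.
#' @export
phantom_scenario <- function(stroke_center = NULL,
                             stroke_reflectivity = 0.05,
                             effective_permittivity = 45,
                             clutter_level = 0.01,
                             noise_level = 0.005,
                             attenuation_length = 0.05,
                             seed = 1L) {
  if (!is.null(stroke_center)) {
    stroke_center <- as.numeric(stroke_center)
    if (length(stroke_center) != 2L || any(!is.finite(stroke_center)))
      stop("domain error: stroke_center must be two finite coordinates in metres")
  }
  stopifnot(stroke_reflectivity >= 0, clutter_level >= 0, noise_level >= 0,
            effective_permittivity >= 1, attenuation_length > 0)
  structure(list(stroke_center = stroke_center,
                 stroke_reflectivity = stroke_reflectivity,
                 effective_permittivity = effective_permittivity,
                 clutter_level = clutter_level,
                 noise_level = noise_level,
                 attenuation_length = attenuation_length,
                 seed = as.integer(seed) %% 2147483647L),
            class = "phantom_scenario")
}

#' @export
print.phantom_scenario <- function(x, ...) {
  if (is.null(x$stroke_center)) {
    cat("Phantom scenario: healthy brain")
  } else {
    cat(sprintf("Phantom scenario: stroke at (%.1f, %.1f) mm, reflectivity %.3g",
                1000 * x$stroke_center[1], 1000 * x$stroke_center[2],
                x$stroke_reflectivity))
  }
  cat(sprintf("; clutter %.3g, noise %.3g, seed %d\n",
              x$clutter_level, x$noise_level, x$seed))
  invisible(x)
}

SPEED_OF_LIGHT <- 299792458

# Run expr with a local RNG state so simulation never perturbs the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stroke echo term per antenna: list(delay_s, amplitude).
stroke_echo_params <- function(geom, scenario) {
  pts <- geometry_points(geom)
  q <- scenario$stroke_center
  d_tissue <- sqrt((pts$skin[, 1] - q[1])^2 + (pts$skin[, 2] - q[2])^2)
  v_tissue <- SPEED_OF_LIGHT / sqrt(scenario$effective_permittivity)
  list(
    delay_s = 2 * (geom$standoff / SPEED_OF_LIGHT + d_tissue / v_tissue),
    amplitude = scenario$stroke_reflectivity *
      exp(-d_tissue / scenario$attenuation_length),
    d_tissue = d_tissue
  )
}

# Smooth complex clutter per antenna: low-order random polynomial in the
# normalised frequency, scaled to clutter_level. Asymmetric across antennas.
draw_clutter <- function(L, freq_hz, level, seed) {
  n <- length(freq_hz)
  u <- 2 * (freq_hz - freq_hz[1]) / (freq_hz[n] - freq_hz[1]) - 1
  degree <- 3L
  with_local_seed(seed, {
    vand <- outer(u, 0:degree, "^")
    out <- matrix(0 + 0i, L, n)
    for (i in seq_len(L)) {
      z <- complex(real = stats::rnorm(degree + 1L, sd = sqrt(0.5)),
                   imaginary = stats::rnorm(degree + 1L, sd = sqrt(0.5)))
      out[i, ] <- level * as.vector(vand %*% z) / sqrt(degree + 1L)
    }
    out
  })
}

draw_noise <- function(L, n, level, seed) {
  with_local_seed(seed, {
    matrix(complex(real = stats::rnorm(L * n, sd = sqrt(0.5)),
                   imaginary = stats::rnorm(L * n, sd = sqrt(0.5))),
           L, n) * level
  })
}

#' Simulate a mono-static sweep set for a phantom scenario
#'
#' Point-scatterer signal model of the measurement system. For antenna `i`
#' and frequency `f` the reflection coefficient is
#' \deqn{s_{11}(i,f) = e^{-j 2\pi f \tau_{skull}} +
#'   A_i e^{-j 2\pi f \tau_i} + c_i(f) + n_i(f),}
#' a unit-amplitude air--skull echo delayed by the two-way standoff path
#' (identical for every antenna of the uniform array, hence exactly
#' left/right symmetric), plus --- when a stroke is present --- a weak echo
#' whose delay is the two-way air-plus-tissue path at speed
#' `c/sqrt(effective_permittivity)` and whose amplitude decays exponentially
#' with the in-tissue distance, plus smooth per-antenna clutter and white
#' measurement noise. Identical seeds give bit-identical outputs.
#'
#' @param geom An [array_geometry()].
#' @param scenario A [phantom_scenario()].
#' @param freq_hz Frequency grid in Hz (default [default_band()]).
#' @param noise_seed Seed for the white-noise draw; defaults to a fixed
#'   offset of `scenario$seed`. Exposed so that two measurements can share
#'   their clutter realization (same `scenario$seed`) while having
#'   independent noise, as repeated VNA sweeps of one set-up do.
#' @return A [sweep_set()].
#' @export
#' @examples
#' sc <- phantom_scenario(stroke_center = c(0.03, 0.025), seed = 7)
#' s <- simulate_sweepset(default_geometry(), sc)
#' s
simulate_sweepset <- function(geom, scenario, freq_hz = default_band(),
                              noise_seed = NULL) {
  stopifnot(inherits(geom, "array_geometry"),
            inherits(scenario, "phantom_scenario"))
  freq_hz <- validate_frequency_grid(freq_hz)
  if (!is.null(scenario$stroke_center) &&
      !inside_head(geom, scenario$stroke_center))
    stop("domain error: stroke_center lies outside the head ellipse")
  if (is.null(noise_seed)) noise_seed <- (scenario$seed + 500009L) %% 2147483647L
  L <- geom$L
  n <- length(freq_hz)

  tau_bg <- 2 * geom$standoff / SPEED_OF_LIGHT
  bg_row <- exp(-2i * pi * freq_hz * tau_bg)
  s11 <- matrix(bg_row, L, n, byrow = TRUE)

  if (!is.null(scenario$stroke_center)) {
    echo <- stroke_echo_params(geom, scenario)
    for (i in seq_len(L))
      s11[i, ] <- s11[i, ] +
        echo$amplitude[i] * exp(-2i * pi * freq_hz * echo$delay_s[i])
  }
  if (scenario$clutter_level > 0)
    s11 <- s11 + draw_clutter(L, freq_hz, scenario$clutter_level, scenario$seed)
  if (scenario$noise_level > 0)
    s11 <- s11 + draw_noise(L, n, scenario$noise_level, noise_seed)

  sweep_set(geom, freq_hz, s11)
}

#' Paired healthy/stroke measurement of one patient
#'
#' Generates the input pair that the reference-subtraction approach (App-1)
#' assumes: a healthy-brain baseline sweep and a stroke-bearing sweep of the
#' same head. Both share the seed-derived clutter realization (the set-up is
#' unchanged between visits) but carry independent measurement noise, so the
#' baseline subtraction isolates the stroke echo exactly when
#' `noise_level = 0`.
#'
#' @inheritParams simulate_sweepset
#' @return A list with `sweep_set` elements `healthy` and `target`.
#' @export
paired_scenario <- function(geom, scenario, freq_hz = default_band()) {
  stopifnot(inherits(scenario, "phantom_scenario"))
  if (is.null(scenario$stroke_center))
    stop("usage error: paired_scenario requires a scenario with a stroke")
  healthy_sc <- scenario
  healthy_sc$stroke_center <- NULL
  list(
    healthy = simulate_sweepset(geom, healthy_sc, freq_hz,
                                noise_seed = (scenario$seed + 1000003L) %% 2147483647L),
    target = simulate_sweepset(geom, scenario, freq_hz,
                               noise_seed = (scenario$seed + 2000003L) %% 2147483647L)
  )
}
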