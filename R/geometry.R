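#' Antenna array geometry around a hemi-elliptical head
#'
#' Describes a ring of `L` mono-static antennas uniformly distributed around
#' an elliptical head cross-section, with antenna 1 on the left/right symmetry
#' axis. The geometry carries everything the simulator and the mirror-based
#' background-removal approaches need: antenna bearings, the head semi-axes,
#' and the antenna--skin standoff.
#'
#' Antenna `i` sits at bearing `2*pi*(i-1)/L` measured from the symmetry axis,
#' so the mirror image of antenna `i` with respect to the axis is antenna
#' `L + 2 - i` (see [mirror_index()]). Exactly two antennas are their own
#' mirror: antenna 1 and antenna `L/2 + 1`.
#'
#' @param L Even antenna count, at least 4. Default 16, the measurement
#'   system's array size.
#' @param semi_axes Numeric length-2, head ellipse semi-axes `(a, b)` in
#'   metres. `a` lies along the symmetry axis. Defaults to an adult head
#'   cross-section, 0.09 x 0.07 m.
#' @param standoff Antenna-to-skin distance in metres (default 0.01).
#'
#' @return An object of class `array_geometry`: a list with elements `L`,
#'   `semi_axes`, `angles` (radians, antenna 1 at 0), `standoff`.
#' @seealso [mirror_index()], [default_geometry()]
#' @export
#' @examples
#' g <- array_geometry(L = 8)
#' g$angles
array_geometry <- function(L = 16L, semi_axes = c(0.09, 0.07), standoff = 0.01) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 4L || L %% 2L != 0L)
    stop("geometry error: antenna count L must be an even integer >= 4")
  if (length(semi_axes) != 2L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("geometry error: semi_axes must be two positive lengths in metres")
  if (!is.finite(standoff) || standoff < 0)
    stop("geometry error: standoff must be a non-negative length in metres")
  g <- list(
    L = L,
    semi_axes = as.numeric(semi_axes),
    angles = 2 * pi * (seq_len(L) - 1L) / L,
    standoff = as.numeric(standoff)
  )
  class(g) <- "array_geometry"
  g
}

#' Default 16-antenna measurement geometry
#'
#' The stock geometry of the monitoring system: 16 antennas uniformly
#' distributed around the head, antenna 1 on the symmetry axis.
#'
#' @return An `array_geometry` with `L = 16`.
#' @export
default_geometry <- function() array_geometry(L = 16L)

#' Mirror antenna index across the head symmetry axis
#'
#' Maps antenna `i` to the antenna placed symmetrically opposite with respect
#' to the line dividing the head into left and right halves: `L + 2 - i` for
#' `i >= 2`. The index formula is degenerate at `i = 1` (it would yield 0);
#' antenna 1 lies on the symmetry axis and is its own mirror, as is antenna
#' `L/2 + 1`. The map is an involution.
#'
#' @param i Antenna id(s), 1-based, in `1..L`. Vectorised.
#' @param L Even antenna count.
#' @return Mirror antenna id(s).
#' @export
#' @examples
#' mirror_index(7, 16)  # 11, the antenna opposite the 7th
#' mirror_index(mirror_index(3, 16), 16)  # involution: 3
mirror_index <- function(i, L) {
  L <- as.integer(L)
  if (L < 2L || L %% 2L != 0L) stop("index error: L must be even and >= 2")
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > L))
    stop("index error: antenna id out of range 1..L")
  ifelse(i == 1L, 1L, L + 2L - i)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "Antenna array geometry: L = %d antennas on a %.0f x %.0f mm hemi-ellipse, standoff %.0f mm\n",
    x$L, 2000 * x$semi_axes[1], 2000 * x$semi_axes[2], 1000 * x$standoff))
  invisible(x)
}

# Cartesian antenna and skin-entry coordinates (metres); internal.
# Antennas sit on the ellipse offset outward by the standoff along the
# radial direction of each bearing.
geometry_points <- function(geom) {
  a <- geom$semi_axes[1]; b <- geom$semi_axes[2]
  th <- geom$angles
  skin <- cbind(a * cos(th), b * sin(th))
  rad <- sqrt(cos(th)^2 + sin(th)^2)  # unit; kept for clarity of intent
  antennas <- skin + geom$standoff * cbind(cos(th), sin(th)) / rad
  list(skin = skin, antennas = antennas)
}

# TRUE if point (x, y) lies strictly inside the head ellipse.
inside_head <- function(geom, p) {
  (p[1] / geom$semi_axes[1])^2 + (p[2] / geom$semi_axes[2])^2 < 1
}
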