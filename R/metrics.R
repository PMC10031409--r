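#' Relative wavelet energy (scalogram) of a coefficient grid
#'
#' Normalises the squared wavelet coefficients to a probability distribution
#' over the scale--time plane:
#' \deqn{E_{\tau,\alpha} = \frac{|C_{\alpha,\tau}|^2}
#'   {\sum_\tau \sum_\alpha |C_{\alpha,\tau}|^2}.}
#' A grid with zero total energy (a healthy brain after perfect background
#' removal) yields an all-zero scalogram flagged as degenerate rather than
#' an error.
#'
#' @param C A [coefficient_grid()].
#' @return Matrix of relative energies (rows scales, columns shifts) with
#'   attribute `degenerate` (logical) and summing to 1 when not degenerate.
#' @export
scalogram_rwe <- function(C) {
  stopifnot(inherits(C, "coefficient_grid"))
  e <- C$C^2
  tot <- sum(e)
  if (tot == 0) {
    out <- e
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- e / tot
  attr(out, "degenerate") <- FALSE
  out
}

#' Shannon wavelet entropy along the scale or time axis
#'
#' Measures the unsteadiness of the filtered signal. Two forms are
#' available. `"as_printed"` is the literal wavelet-entropy sum
#' \deqn{\epsilon_\alpha = \sum_\tau |C_{\alpha,\tau}|^2 \log_2
#'   |C_{\alpha,\tau}|^2} (and the transposed sum over scales for the time
#' axis), with the convention `0 * log2(0) = 0` --- this form is
#' scale-dependent: doubling the coefficients changes it.
#' `"normalized_shannon"` first normalises each row (or column) of
#' `|C|^2` to a probability vector `p` and returns `-sum(p * log2(p))`,
#' which is invariant to uniform scaling of `C`; all-zero rows get entropy
#' 0. Either way, a slice with all its energy in one cell scores the
#' minimum, and spread-out energy scores high.
#'
#' @param C A [coefficient_grid()].
#' @param axis `"scale"` (one value per scale, summing over shifts) or
#'   `"time"` (one value per shift, summing over scales).
#' @param form `"as_printed"` (default) or `"normalized_shannon"`.
#' @return Numeric vector of entropies along the requested axis.
#' @export
wavelet_entropy <- function(C, axis = c("scale", "time"),
                            form = c("as_printed", "normalized_shannon")) {
  stopifnot(inherits(C, "coefficient_grid"))
  axis <- match.arg(axis)
  form <- match.arg(form)
  e <- C$C^2
  if (axis == "time") e <- t(e)
  if (form == "as_printed") {
    term <- e * log2(e)
    term[e == 0] <- 0
    return(rowSums(term))
  }
  tot <- rowSums(e)
  out <- numeric(nrow(e))
  nz <- tot > 0
  if (any(nz)) {
    p <- e[nz, , drop = FALSE] / tot[nz]
    term <- p * log2(p)
    term[p == 0] <- 0
    out[nz] <- -rowSums(term)
  }
  out
}

#' Distance between wavelet energy distributions at opposite antennas
#'
#' The detection statistic that discriminates the wavelet energy recorded at
#' two antennas placed symmetrically opposite each other:
#' \deqn{\omega_\alpha^i = \sum_\tau \log_2
#'   \frac{|C_{\alpha,\tau}|_i^2}{|C_{\alpha,\tau}|_{opp}^2}}
#' per scale (`axis = "scale"`), or the transposed sum per shift
#' (`axis = "time"`). Squared coefficients are floored at `epsilon` before
#' the logarithm so that zero cells are well defined; the identity
#' `omega(i, opp) = -omega(opp, i)` then holds exactly, computed as a sum of
#' log differences. A one-sided target pushes the profile of the nearer
#' antenna positive.
#'
#' @param C_i,C_opp [coefficient_grid()]s on identical scale/shift axes.
#' @param axis `"scale"` or `"time"`.
#' @param epsilon Flooring constant for squared coefficients
#'   (default 1e-300).
#' @return Numeric distance vector along the requested axis.
#' @export
energy_distance <- function(C_i, C_opp, axis = c("scale", "time"),
                            epsilon = 1e-300) {
  stopifnot(inherits(C_i, "coefficient_grid"), inherits(C_opp, "coefficient_grid"))
  axis <- match.arg(axis)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("parameter error: epsilon must be > 0")
  if (!isTRUE(all.equal(C_i$scale_axis, C_opp$scale_axis)) ||
      !isTRUE(all.equal(C_i$shift_axis, C_opp$shift_axis)))
    stop("consistency error: coefficient grids must share scale and shift axes")
  d <- log2(pmax(C_i$C^2, epsilon)) - log2(pmax(C_opp$C^2, epsilon))
  if (axis == "time") d <- t(d)
  rowSums(d)
}

#' Per-antenna metrics bundle
#'
#' Assembles the diagnostic quantities of one antenna's coefficient grid:
#' the relative-wavelet-energy scalogram, the Shannon wavelet entropy along
#' the scale and time axes (in the requested form, plus the
#' normalised-Shannon form which the entropy-based ranking uses), and the
#' total wavelet energy.
#'
#' @param C A [coefficient_grid()].
#' @param entropy_form Entropy form stored in `entropy_scale` /
#'   `entropy_time`; see [wavelet_entropy()].
#' @return Object of class `metrics_bundle` with elements `antenna`,
#'   `scale_axis`, `shift_axis`, `rwe`, `degenerate`, `total_energy`,
#'   `entropy_form`, `entropy_scale`, `entropy_time`, `entropy_scale_norm`,
#'   `entropy_time_norm`.
#' @export
compute_bundle <- function(C, entropy_form = c("as_printed", "normalized_shannon")) {
  stopifnot(inherits(C, "coefficient_grid"))
  entropy_form <- match.arg(entropy_form)
  rwe <- scalogram_rwe(C)
  structure(list(
    antenna = C$antenna,
    scale_axis = C$scale_axis,
    shift_axis = C$shift_axis,
    rwe = rwe,
    degenerate = attr(rwe, "degenerate"),
    total_energy = sum(C$C^2),
    entropy_form = entropy_form,
    entropy_scale = wavelet_entropy(C, "scale", entropy_form),
    entropy_time = wavelet_entropy(C, "time", entropy_form),
    entropy_scale_norm = wavelet_entropy(C, "scale", "normalized_shannon"),
    entropy_time_norm = wavelet_entropy(C, "time", "normalized_shannon")
  ), class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("Metrics bundle (antenna %s): total energy %.4g, %d scales x %d shifts\n",
              ifelse(is.na(x$antenna), "?", x$antenna), x$total_energy,
              length(x$scale_axis), length(x$shift_axis)))
  invisible(x)
}

#' Opposite-antenna distance profiles for a whole array
#'
#' Pairs every antenna with its mirror across the head symmetry axis and
#' computes the scale- and time-domain energy distances. Profiles at
#' mirrored antennas are exact negations of each other; the two
#' symmetry-axis antennas are their own mirror and get all-zero profiles.
#'
#' @param grids List of [coefficient_grid()]s, one per antenna in antenna
#'   order (length `geom$L`), sharing axes.
#' @param geom The [array_geometry()].
#' @param epsilon Flooring constant, see [energy_distance()].
#' @return List of `distance_profile` objects (elements `antenna`,
#'   `opposite`, `omega_scale`, `omega_time`, `epsilon`), one per antenna.
#' @export
compute_distances <- function(grids, geom, epsilon = 1e-300) {
  stopifnot(inherits(geom, "array_geometry"))
  if (length(grids) != geom$L)
    stop("consistency error: one coefficient grid per antenna required")
  lapply(seq_len(geom$L), function(i) {
    opp <- mirror_index(i, geom$L)
    if (opp == i) {
      os <- numeric(length(grids[[i]]$scale_axis))
      ot <- numeric(length(grids[[i]]$shift_axis))
    } else {
      os <- energy_distance(grids[[i]], grids[[opp]], "scale", epsilon)
      ot <- energy_distance(grids[[i]], grids[[opp]], "time", epsilon)
    }
    structure(list(antenna = i, opposite = opp, omega_scale = os,
                   omega_time = ot, epsilon = epsilon),
              class = "distance_profile")
  })
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("Distance profile antenna %d vs %d: sum omega_scale %.4g, sum omega_time %.4g\n",
              x$antenna, x$opposite, sum(x$omega_scale), sum(x$omega_time)))
  invisible(x)
}
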