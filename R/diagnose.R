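# Side label of an antenna bearing: antennas strictly between the two
# symmetry-axis elements on the positive-y arc are "left", the others
# "right", axis elements "axis".
antenna_side <- function(i, L) {
  half <- L %/% 2L + 1L
  if (i == 1L || i == half) "axis" else if (i < half) "left" else "right"
}

ranking_object <- function(antenna, score, method, side = "undetermined") {
  structure(list(
    ranked = data.frame(antenna = as.integer(antenna), score = as.numeric(score)),
    method = method, side = side
  ), class = "antenna_ranking")
}

#' @export
print.antenna_ranking <- function(x, n = 5L, ...) {
  cat(sprintf("Antenna ranking by %s (side: %s)\n", x$method, x$side))
  print(utils::head(x$ranked, n), row.names = FALSE)
  invisible(x)
}

#' Rank antennas by opposite-antenna energy distance
#'
#' The closer an antenna is to the target, the larger the distances it
#' records against its mirror in both the scale and time domains. Each
#' antenna is scored by the summed magnitude of its distance profile,
#' `sum(|omega_scale|) + sum(|omega_time|)`. Mirrored antennas tie exactly
#' on that magnitude (the profiles are negations), so ties are resolved by
#' the signed profile sum first --- the antenna whose wavelet energy exceeds
#' its mirror's, i.e. the stroke side --- then by ascending antenna id. The
#' stroke side is inferred from the sign pattern of the top antenna's
#' profile.
#'
#' @param profiles List of `distance_profile`s from [compute_distances()],
#'   one per antenna.
#' @return An `antenna_ranking`: ranked antennas with non-increasing
#'   scores, the method label, and the inferred side (`"left"`, `"right"`,
#'   `"axis"` or `"undetermined"`).
#' @export
rank_by_distance <- function(profiles) {
  L <- length(profiles)
  ids <- vapply(profiles, `[[`, integer(1), "antenna")
  if (!setequal(ids, seq_len(L)))
    stop("consistency error: need one distance profile per antenna 1..L")
  profiles <- profiles[order(ids)]
  score <- vapply(profiles, function(p)
    sum(abs(p$omega_scale)) + sum(abs(p$omega_time)), numeric(1))
  signed <- vapply(profiles, function(p)
    sum(p$omega_scale) + sum(p$omega_time), numeric(1))
  ord <- order(-score, -sign(signed), seq_len(L))
  top <- ord[1]
  side <- if (score[top] == 0) {
    "undetermined"
  } else if (signed[top] > 0) {
    antenna_side(top, L)
  } else if (signed[top] < 0) {
    antenna_side(mirror_index(top, L), L)
  } else if (top == mirror_index(top, L)) "axis" else "undetermined"
  ranking_object(ord, score[ord], "distance", side)
}

#' Rank antennas by total wavelet energy
#'
#' Orders antennas by descending total wavelet energy `sum(|C|^2)`; the
#' strongest residual echo is expected at the antenna nearest the stroke.
#' Ties break by ascending antenna id.
#'
#' @param bundles List of [compute_bundle()] results, one per antenna.
#' @return An `antenna_ranking`.
#' @export
rank_by_energy <- function(bundles) {
  L <- length(bundles)
  ids <- vapply(bundles, `[[`, integer(1), "antenna")
  if (!setequal(ids, seq_len(L)))
    stop("consistency error: need one metrics bundle per antenna 1..L")
  bundles <- bundles[order(ids)]
  score <- vapply(bundles, `[[`, numeric(1), "total_energy")
  ord <- order(-score, seq_len(L))
  ranking_object(ord, score[ord], "energy")
}

#' Rank antennas by normalised scale-domain wavelet entropy
#'
#' Energy concentrated by a nearby target yields low entropy, so antennas
#' are ordered by ascending normalised-Shannon scale entropy. Each antenna
#' is summarised by the minimum of its per-scale entropy vector --- the
#' entropy attained at its best-matched scale. (An unweighted mean would be
#' dominated by scales that hold nothing but the noise floor, whose entropy
#' is near-maximal for every antenna, and would wash out the inverse
#' energy--entropy relationship the ranking exploits.) Scores are reported
#' as evidence values, `max(entropy summary) - entropy summary`, so that
#' they are non-negative and non-increasing down the ranking; identical
#' bundles give uniformly zero evidence. Ties break by ascending antenna
#' id.
#'
#' @param bundles List of [compute_bundle()] results, one per antenna.
#' @return An `antenna_ranking`.
#' @export
rank_by_entropy <- function(bundles) {
  L <- length(bundles)
  ids <- vapply(bundles, `[[`, integer(1), "antenna")
  if (!setequal(ids, seq_len(L)))
    stop("consistency error: need one metrics bundle per antenna 1..L")
  bundles <- bundles[order(ids)]
  ent <- vapply(bundles, function(b) min(b$entropy_scale_norm), numeric(1))
  score <- max(ent) - ent
  ord <- order(-score, seq_len(L))
  ranking_object(ord, score[ord], "entropy")
}

# Score contrast of a ranking: top score relative to the median score.
ranking_contrast <- function(r) {
  top <- r$ranked$score[1]
  med <- stats::median(r$ranked$score)
  if (med > 0) top / med else if (top > 0) Inf else 1
}

#' Detection decision from antenna rankings
#'
#' A stroke is declared when the evidence is concentrated: the top score of
#' a ranking must exceed the median score by the configured contrast ratio
#' (strictly, `top > threshold * median`). With several rankings the
#' decision fires if any of them clears the threshold, and the reported
#' ranking is their Borda-count aggregate (method `"combined"`); with one
#' ranking it is that ranking itself. Uniform scores --- a healthy brain ---
#' give contrast 1 and no detection; an infinite threshold never detects.
#'
#' @param rankings An `antenna_ranking` or list of them.
#' @param threshold Score-contrast ratio (default 2).
#' @param approach Background-removal approach label echoed in the report.
#' @param parameters Named list of run parameters echoed in the report.
#' @return Object of class `diagnosis_report`: `detected`,
#'   `ranked_antennas` (data frame, scores non-increasing), `method`,
#'   `side`, `approach`, `contrasts`, `threshold`, `parameters`.
#' @export
detect <- function(rankings, threshold = 2, approach = NA_character_,
                   parameters = list()) {
  if (inherits(rankings, "antenna_ranking")) rankings <- list(rankings)
  if (length(rankings) == 0L) stop("usage error: at least one ranking required")
  stopifnot(all(vapply(rankings, inherits, logical(1), "antenna_ranking")))
  if (is.na(threshold) || threshold <= 0)
    stop("parameter error: threshold must be positive")

  contrasts <- vapply(rankings, ranking_contrast, numeric(1))
  names(contrasts) <- vapply(rankings, `[[`, character(1), "method")
  detected <- is.finite(threshold) && any(contrasts > threshold)

  if (length(rankings) == 1L) {
    ranked <- rankings[[1]]$ranked
    method <- rankings[[1]]$method
    side <- rankings[[1]]$side
  } else {
    L <- nrow(rankings[[1]]$ranked)
    borda <- numeric(L)
    for (r in rankings)
      borda[r$ranked$antenna] <- borda[r$ranked$antenna] + (L - seq_len(L))
    ord <- order(-borda, seq_len(L))
    ranked <- data.frame(antenna = ord, score = borda[ord])
    method <- "combined"
    sides <- vapply(rankings, `[[`, character(1), "side")
    sides <- sides[sides %in% c("left", "right", "axis")]
    side <- if (length(unique(sides)) == 1L) sides[1] else "undetermined"
  }
  if (!detected) side <- if (identical(side, "axis")) "axis" else "undetermined"

  structure(list(detected = detected, ranked_antennas = ranked,
                 method = method, side = side, approach = approach,
                 contrasts = contrasts, threshold = threshold,
                 parameters = parameters),
            class = "diagnosis_report")
}

#' @export
print.diagnosis_report <- function(x, n = 5L, ...) {
  cat("Microwave stroke diagnosis report\n")
  if (!is.na(x$approach)) cat(sprintf("  background removal: %s\n", x$approach))
  cat(sprintf("  detected: %s (contrast %s vs threshold %.3g)\n",
              if (x$detected) "YES" else "no",
              paste(sprintf("%s=%.3g", names(x$contrasts), x$contrasts),
                    collapse = ", "),
              x$threshold))
  if (x$detected)
    cat(sprintf("  nearest antenna: %d (side: %s)\n",
                x$ranked_antennas$antenna[1], x$side))
  cat(sprintf("  top antennas (%s): %s\n", x$method,
              paste(utils::head(x$ranked_antennas$antenna, n), collapse = ", ")))
  invisible(x)
}
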