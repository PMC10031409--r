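#' Pipeline run configuration
#'
#' Collects every knob of the simulate/analyze/diagnose pipeline in one
#' serialisable object. Defaults reproduce the measurement system's stated
#' set-up (16 antennas, 401 points over 1.1--3 GHz) and the package's
#' declared analysis defaults (sinc wavelet of 33 samples, 64 linear scales,
#' l2 normalisation, literal-form entropy, distance-based ranking, contrast
#' threshold 2).
#'
#' @param geometry An [array_geometry()].
#' @param scenario A [phantom_scenario()] to simulate, or `NULL` when sweeps
#'   are read from files.
#' @param input,healthy_input Optional input paths passed to
#'   [read_sweepset()] (with `input_format`); `healthy_input` is the App-1
#'   baseline.
#' @param input_format `"touchstone"` or `"csv"`.
#' @param approach Background-removal approach, see [remove_background()].
#' @param clip_negative,app4_mode,app4_k Approach options.
#' @param n_fft,window Passed to [to_time_domain()].
#' @param wavelet_T,wavelet_convention Passed to [make_mother_wavelet()].
#' @param scales,norm Passed to [filter_bank_config()].
#' @param entropy_form,epsilon Passed to [compute_bundle()] and
#'   [compute_distances()].
#' @param methods Ranking methods to run: subset of `"distance"`,
#'   `"energy"`, `"entropy"`.
#' @param threshold Detection score-contrast ratio, see [detect()].
#' @param out_dir Directory for persisted artifacts, or `NULL` to keep the
#'   run in memory only.
#' @return Object of class `run_config`.
#' @export
run_config <- function(geometry = default_geometry(),
                       scenario = NULL,
                       input = NULL, healthy_input = NULL,
                       input_format = "csv",
                       approach = "app1",
                       clip_negative = FALSE, app4_mode = "all", app4_k = 1L,
                       n_fft = "auto", window = "none",
                       wavelet_T = 33L, wavelet_convention = "plain_sinc",
                       scales = seq(1, 64, length.out = 64), norm = "l2",
                       entropy_form = "as_printed", epsilon = 1e-300,
                       methods = "distance", threshold = 2,
                       out_dir = NULL) {
  approach <- match.arg(approach, c("app1", "app2", "app3", "app4", "app5a", "app5b"))
  methods <- match.arg(methods, c("distance", "energy", "entropy"),
                       several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full stroke-monitoring pipeline
#'
#' Executes simulate (or read), time-domain transform, background removal,
#' wavelet-matched filtering, metrics, and diagnosis, and returns everything
#' as a `stroke_scan` object. For App-1 with a simulated stroke scenario the
#' healthy baseline comes from [paired_scenario()]; for App-1 with a healthy
#' scenario two independent-noise measurements of the same set-up are
#' simulated. When `cfg$out_dir` is set, the sweeps, target responses,
#' metrics tables/archives, the diagnosis report (JSON) and the config echo
#' are persisted there.
#'
#' @param cfg A [run_config()].
#' @param verbose Log stage timings and parameter echoes to the console.
#' @return Object of class `stroke_scan`: the config, the sweeps, the
#'   target-response set, per-antenna coefficient grids, metrics bundles,
#'   distance profiles, rankings, and the `diagnosis_report`.
#' @export
#' @examples
#' cfg <- run_config(
#'   scenario = phantom_scenario(stroke_center = c(0.03, 0.025), seed = 11),
#'   scales = seq(1, 32, length.out = 32))
#' scan <- run_pipeline(cfg)
#' scan$report$detected
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[3]

  # --- acquire sweeps ------------------------------------------------------
  healthy_sweeps <- NULL
  if (!is.null(cfg$scenario)) {
    stopifnot(inherits(cfg$scenario, "phantom_scenario"))
    if (cfg$approach == "app1") {
      if (is.null(cfg$scenario$stroke_center)) {
        base <- cfg$scenario
        sweeps <- simulate_sweepset(cfg$geometry, base,
          noise_seed = (base$seed + 2000003L) %% 2147483647L)
        healthy_sweeps <- simulate_sweepset(cfg$geometry, base,
          noise_seed = (base$seed + 1000003L) %% 2147483647L)
      } else {
        pair <- paired_scenario(cfg$geometry, cfg$scenario)
        sweeps <- pair$target
        healthy_sweeps <- pair$healthy
      }
    } else {
      sweeps <- simulate_sweepset(cfg$geometry, cfg$scenario)
    }
  } else if (!is.null(cfg$input)) {
    sweeps <- read_sweepset(cfg$input, cfg$input_format, cfg$geometry)
    if (cfg$approach == "app1") {
      if (is.null(cfg$healthy_input))
        stop("usage error: approach 'app1' needs the missing field 'healthy_input'")
      healthy_sweeps <- read_sweepset(cfg$healthy_input, cfg$input_format,
                                      cfg$geometry)
    }
  } else {
    stop("usage error: provide either a scenario or input sweeps")
  }
  say("sweeps ready [%s] (%.2fs)", cfg$approach, proc.time()[3] - t0)

  # --- time domain + background removal -----------------------------------
  tsig <- to_time_domain(sweeps, n_fft = cfg$n_fft, window = cfg$window)
  healthy_tsig <- if (!is.null(healthy_sweeps))
    to_time_domain(healthy_sweeps, n_fft = cfg$n_fft, window = cfg$window)
  resp <- remove_background(tsig, cfg$approach, healthy = healthy_tsig,
                            clip_negative = cfg$clip_negative,
                            app4_mode = cfg$app4_mode, app4_k = cfg$app4_k)
  say("background removed (%s), %d x %d responses (%.2fs)", cfg$approach,
      nrow(resp$responses), ncol(resp$responses), proc.time()[3] - t0)

  # --- wavelet filter bank -------------------------------------------------
  w <- make_mother_wavelet(cfg$wavelet_T, cfg$wavelet_convention)
  bank <- filter_bank_config(scales = cfg$scales, norm = cfg$norm)
  grids <- wavelet_transform_set(resp, w, bank)
  say("filter bank: T=%d (%s), %d scales, %s norm (%.2fs)", w$T, w$convention,
      length(bank$scales), bank$norm, proc.time()[3] - t0)

  # --- metrics + diagnosis -------------------------------------------------
  bundles <- lapply(grids, compute_bundle, entropy_form = cfg$entropy_form)
  distances <- compute_distances(grids, cfg$geometry, epsilon = cfg$epsilon)
  rankings <- lapply(cfg$methods, function(m) switch(m,
    distance = rank_by_distance(distances),
    energy = rank_by_energy(bundles),
    entropy = rank_by_entropy(bundles)))
  params <- list(approach = cfg$approach, wavelet_T = cfg$wavelet_T,
                 wavelet_convention = cfg$wavelet_convention,
                 norm = cfg$norm, entropy_form = cfg$entropy_form,
                 n_scales = length(bank$scales), threshold = cfg$threshold)
  report <- detect(rankings, threshold = cfg$threshold,
                   approach = cfg$approach, parameters = params)
  say("diagnosis: detected=%s, top antenna %d (%.2fs)", report$detected,
      report$ranked_antennas$antenna[1], proc.time()[3] - t0)

  scan <- structure(list(
    config = cfg, sweeps = sweeps, healthy_sweeps = healthy_sweeps,
    time_signals = tsig, responses = resp, grids = grids,
    bundles = bundles, distances = distances, rankings = rankings,
    report = report), class = "stroke_scan")

  if (!is.null(cfg$out_dir)) persist_scan(scan, cfg$out_dir)
  scan
}

# Persist a scan's artifact set under out_dir.
persist_scan <- function(scan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sweepset(scan$sweeps, file.path(out_dir, "sweeps.csv"), "csv")
  if (!is.null(scan$healthy_sweeps))
    write_sweepset(scan$healthy_sweeps, file.path(out_dir, "healthy_sweeps.csv"), "csv")
  write_target_responses(scan$responses, file.path(out_dir, "responses"))
  write_metrics_table(scan$bundles, file.path(out_dir, "metrics.csv"),
                      distances = scan$distances)
  jsonlite::write_json(report_as_list(scan$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- scan$config
  echo <- cfg[!vapply(cfg, is.null, logical(1))]
  echo$geometry <- unclass(echo$geometry)
  if (!is.null(echo$scenario)) echo$scenario <- unclass(echo$scenario)
  jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

report_as_list <- function(r) {
  list(detected = r$detected,
       method = r$method, side = r$side, approach = r$approach,
       threshold = r$threshold,
       contrasts = as.list(r$contrasts),
       ranked_antennas = r$ranked_antennas,
       parameters = r$parameters)
}

#' Persist / re-read target responses as a text artifact
#'
#' Writes the per-antenna response matrix with full precision plus a JSON
#' side-car of the metadata (`approach`, `dt`, `clipped`, antenna count), so
#' the wavelet stage can be re-run from disk with identical results.
#'
#' @param resp A [target_response_set()].
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>_meta.json`.
#' @return The csv path, invisibly.
#' @export
write_target_responses <- function(resp, stem) {
  stopifnot(inherits(resp, "target_response_set"))
  csv <- paste0(stem, ".csv")
  utils::write.table(
    matrix(fmt17(resp$responses), nrow(resp$responses)),
    csv, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(approach = resp$approach, dt = resp$dt, clipped = resp$clipped,
         L = resp$geometry$L),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' @rdname write_target_responses
#' @param stem2 Path stem used when writing.
#' @param geometry The matching [array_geometry()].
#' @export
read_target_responses <- function(stem2, geometry) {
  meta <- jsonlite::read_json(paste0(stem2, "_meta.json"), simplifyVector = TRUE)
  if (meta$L != geometry$L)
    stop("geometry error: archived responses are for a different antenna count")
  mat <- as.matrix(utils::read.table(paste0(stem2, ".csv"), sep = ","))
  dimnames(mat) <- NULL
  src <- time_signal_set(geometry, meta$dt, mat)
  target_response_set(src, meta$approach, mat, clipped = meta$clipped)
}

#' @export
print.stroke_scan <- function(x, ...) {
  cat(sprintf("Stroke scan (%s, %d antennas)\n", x$config$approach,
              x$config$geometry$L))
  print(x$report)
  invisible(x)
}

#' Per-antenna summary of a stroke scan
#'
#' @param object A `stroke_scan`.
#' @param ... Unused.
#' @return Data frame with one row per antenna: total wavelet energy, mean
#'   entropies (stored form and normalised scale form), and the signed and
#'   absolute opposite-antenna distance sums.
#' @export
summary.stroke_scan <- function(object, ...) {
  tab <- data.frame(
    antenna = vapply(object$bundles, `[[`, integer(1), "antenna"),
    total_energy = vapply(object$bundles, `[[`, numeric(1), "total_energy"),
    mean_entropy = vapply(object$bundles, function(b) mean(b$entropy_scale), numeric(1)),
    mean_entropy_norm = vapply(object$bundles, function(b) mean(b$entropy_scale_norm), numeric(1)),
    distance_sum = vapply(object$distances, function(p)
      sum(p$omega_scale) + sum(p$omega_time), numeric(1)),
    distance_abs_sum = vapply(object$distances, function(p)
      sum(abs(p$omega_scale)) + sum(abs(p$omega_time)), numeric(1)))
  tab[order(-tab$distance_abs_sum), ]
}

#' Plot the scalogram of one antenna of a scan
#'
#' Draws the relative-wavelet-energy distribution in the scale--time plane
#' for the requested antenna (default: the top-ranked one), the way the
#' diagnosis is read off visually.
#'
#' @param x A `stroke_scan`.
#' @param antenna Antenna id; default the top-ranked antenna.
#' @param ... Passed to [graphics::image()].
#' @export
plot.stroke_scan <- function(x, antenna = NULL, ...) {
  if (is.null(antenna)) antenna <- x$report$ranked_antennas$antenna[1]
  b <- x$bundles[[antenna]]
  graphics::image(
    x = b$shift_axis * x$responses$dt * 1e9, y = b$scale_axis,
    z = t(b$rwe), col = grDevices::hcl.colors(64, "viridis"),
    xlab = "time shift [ns]", ylab = "scale",
    main = sprintf("RWE scalogram, antenna %d (%s)", antenna,
                   x$config$approach), ...)
  invisible(x)
}
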