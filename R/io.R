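# Full-precision number formatting for text archives: %.17g round-trips
# IEEE doubles exactly.
fmt17 <- function(x) sprintf("%.17g", x)

#' Read a one-port Touchstone (.s1p) file
#'
#' Tolerant single-port reader: `!` comment lines anywhere, an option line
#' `# <unit> S <format> R <ref>` with frequency units HZ/KHZ/MHZ/GHZ and
#' data formats RI (real/imaginary), MA (magnitude/angle in degrees) or DB
#' (dB magnitude/angle in degrees). Frequencies are always converted to Hz.
#'
#' @param path Path to the .s1p file.
#' @return List with `freq_hz` and complex `s11` vectors.
#' @export
read_touchstone_s1p <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  unit_mult <- 1
  fmt <- "RI"
  opt <- grep("^#", lines)
  if (length(opt) > 0) {
    toks <- toupper(strsplit(sub("^#\\s*", "", lines[opt[1]]), "\\s+")[[1]])
    units <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
    u <- toks[toks %in% names(units)]
    if (length(u) > 0) unit_mult <- units[[u[1]]]
    f <- toks[toks %in% c("RI", "MA", "DB")]
    if (length(f) > 0) fmt <- f[1]
    lines <- lines[-opt]
  }
  if (length(lines) == 0) stop("format error: no data rows in Touchstone file")

  rows <- lapply(lines, function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  if (any(vapply(rows, length, integer(1)) < 3L) ||
      any(vapply(rows, function(r) any(is.na(r[1:3])), logical(1))))
    stop("format error: each Touchstone data row needs 'freq v1 v2'")
  mat <- do.call(rbind, lapply(rows, `[`, 1:3))
  s11 <- switch(fmt,
    RI = complex(real = mat[, 2], imaginary = mat[, 3]),
    MA = mat[, 2] * exp(1i * pi * mat[, 3] / 180),
    DB = 10^(mat[, 2] / 20) * exp(1i * pi * mat[, 3] / 180))
  list(freq_hz = mat[, 1] * unit_mult, s11 = s11)
}

#' Write a one-port Touchstone (.s1p) file
#'
#' Always writes the lossless RI data format in Hz with full double
#' precision.
#'
#' @param path Output path.
#' @param freq_hz Frequencies in Hz.
#' @param s11 Complex reflection coefficients.
#' @export
write_touchstone_s1p <- function(path, freq_hz, s11) {
  lines <- c("! mono-static S11 sweep",
             "# HZ S RI R 50",
             paste(fmt17(freq_hz), fmt17(Re(s11)), fmt17(Im(s11))))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("I/O error: cannot write '%s'", path)))
  invisible(path)
}

#' Read an array sweep set from Touchstone or CSV files
#'
#' Two layouts are accepted. `format = "touchstone"`: one .s1p file per
#' antenna, `paths` in antenna order 1..L. `format = "csv"`: one combined
#' table with header columns `antenna, freq_hz, re, im`. All antennas must
#' share an identical equidistant frequency grid and the antenna count must
#' match the geometry.
#'
#' @param paths Character vector of file paths (length L for Touchstone,
#'   length 1 for CSV).
#' @param format `"touchstone"` or `"csv"`.
#' @param geometry The [array_geometry()] the files describe.
#' @return A validated [sweep_set()].
#' @export
read_sweepset <- function(paths, format = c("touchstone", "csv"), geometry) {
  format <- match.arg(format)
  stopifnot(inherits(geometry, "array_geometry"))
  L <- geometry$L
  if (format == "touchstone") {
    if (length(paths) != L)
      stop(sprintf("geometry error: expected %d .s1p files, got %d", L, length(paths)))
    recs <- lapply(paths, read_touchstone_s1p)
    freq <- recs[[1]]$freq_hz
    for (i in seq_along(recs))
      if (length(recs[[i]]$freq_hz) != length(freq) ||
          any(abs(recs[[i]]$freq_hz - freq) > 1e-6 * max(abs(freq))))
        stop(sprintf("grid-mismatch error: antenna %d is not on the shared frequency grid", i))
    s11 <- do.call(rbind, lapply(recs, `[[`, "s11"))
  } else {
    if (length(paths) != 1L)
      stop("usage error: CSV layout is one combined table")
    tab <- utils::read.csv(paths, stringsAsFactors = FALSE)
    need <- c("antenna", "freq_hz", "re", "im")
    if (!all(need %in% names(tab)))
      stop("format error: CSV needs header columns antenna, freq_hz, re, im")
    ids <- sort(unique(tab$antenna))
    if (!identical(as.integer(ids), seq_len(L)))
      stop(sprintf("geometry error: CSV antenna ids must be exactly 1..%d", L))
    sub1 <- tab[tab$antenna == 1L, ]
    freq <- sub1$freq_hz[order(sub1$freq_hz)]
    s11 <- matrix(0 + 0i, L, length(freq))
    for (i in seq_len(L)) {
      sub <- tab[tab$antenna == i, ]
      sub <- sub[order(sub$freq_hz), ]
      if (nrow(sub) != length(freq) ||
          any(abs(sub$freq_hz - freq) > 1e-6 * max(abs(freq))))
        stop(sprintf("grid-mismatch error: antenna %d is not on the shared frequency grid", i))
      s11[i, ] <- complex(real = sub$re, imaginary = sub$im)
    }
  }
  sweep_set(geometry, freq, s11)
}

#' Write an array sweep set to Touchstone or CSV
#'
#' `format = "touchstone"` writes one `antenna_NN.s1p` per antenna into the
#' directory `path` (created if needed); `format = "csv"` writes the
#' combined `(antenna, freq_hz, re, im)` table to the file `path`. Either
#' layout round-trips through [read_sweepset()] within 1e-12 relative.
#'
#' @param s A [sweep_set()].
#' @param path Output directory (Touchstone) or file (CSV).
#' @param format `"touchstone"` or `"csv"`.
#' @return The written path(s), invisibly.
#' @export
write_sweepset <- function(s, path, format = c("touchstone", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "sweep_set"))
  L <- nrow(s$s11)
  if (L == 0L) stop("geometry error: cannot write an empty sweep set")
  if (format == "touchstone") {
    if (!dir.exists(path) &&
        !dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop(sprintf("I/O error: cannot create directory '%s'", path))
    files <- file.path(path, sprintf("antenna_%02d.s1p", seq_len(L)))
    for (i in seq_len(L))
      write_touchstone_s1p(files[i], s$freq_hz, s$s11[i, ])
    return(invisible(files))
  }
  n <- length(s$freq_hz)
  tab <- data.frame(
    antenna = rep(seq_len(L), each = n),
    freq_hz = fmt17(rep(s$freq_hz, L)),
    re = fmt17(as.vector(t(Re(s$s11)))),
    im = fmt17(as.vector(t(Im(s$s11)))))
  tryCatch(utils::write.csv(tab, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop(sprintf("I/O error: cannot write '%s'", path)))
  invisible(path)
}

#' Write the per-antenna metrics summary table and grid archives
#'
#' Produces one summary CSV with a row per antenna (total wavelet energy,
#' the maximum relative-wavelet-energy cell and its scale/shift location,
#' entropy extremes, and --- when distance profiles are supplied ---
#' signed and absolute distance sums), plus a companion archive directory
#' `<path>_arrays/` holding the full relative-energy grids, entropy vectors
#' and axes as full-precision CSV entries that re-read bit-exactly (see
#' [read_metrics_archive()]).
#'
#' @param bundles List of [compute_bundle()] results sharing axes.
#' @param path Output CSV path for the summary table.
#' @param distances Optional list of distance profiles from
#'   [compute_distances()].
#' @return Path of the summary table, invisibly.
#' @export
write_metrics_table <- function(bundles, path, distances = NULL) {
  stopifnot(length(bundles) > 0,
            all(vapply(bundles, inherits, logical(1), "metrics_bundle")))
  ax <- bundles[[1]]
  for (b in bundles)
    if (!identical(b$scale_axis, ax$scale_axis) ||
        !identical(b$shift_axis, ax$shift_axis))
      stop("consistency error: all bundles must share scale/shift axes")

  rows <- lapply(bundles, function(b) {
    pk <- arrayInd(which.max(b$rwe), dim(b$rwe))
    data.frame(
      antenna = b$antenna,
      total_energy = b$total_energy,
      rwe_max = max(b$rwe),
      rwe_max_scale = b$scale_axis[pk[1]],
      rwe_max_shift = b$shift_axis[pk[2]],
      entropy_scale_min = min(b$entropy_scale),
      entropy_scale_max = max(b$entropy_scale),
      entropy_time_min = min(b$entropy_time),
      entropy_time_max = max(b$entropy_time))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(distances)) {
    ids <- vapply(distances, `[[`, integer(1), "antenna")
    distances <- distances[match(tab$antenna, ids)]
    tab$distance_sum <- vapply(distances, function(p)
      sum(p$omega_scale) + sum(p$omega_time), numeric(1))
    tab$distance_abs_sum <- vapply(distances, function(p)
      sum(abs(p$omega_scale)) + sum(abs(p$omega_time)), numeric(1))
  }
  utils::write.csv(tab, path, row.names = FALSE)

  arr_dir <- paste0(sub("\\.csv$", "", path), "_arrays")
  dir.create(arr_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(fmt17(ax$scale_axis), file.path(arr_dir, "scale_axis.csv"))
  writeLines(fmt17(ax$shift_axis), file.path(arr_dir, "shift_axis.csv"))
  for (b in bundles) {
    utils::write.table(
      matrix(fmt17(b$rwe), nrow(b$rwe), ncol(b$rwe)),
      file.path(arr_dir, sprintf("rwe_antenna_%02d.csv", b$antenna)),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(fmt17(b$entropy_scale),
               file.path(arr_dir, sprintf("entropy_scale_antenna_%02d.csv", b$antenna)))
    writeLines(fmt17(b$entropy_time),
               file.path(arr_dir, sprintf("entropy_time_antenna_%02d.csv", b$antenna)))
  }
  invisible(path)
}

#' Re-read a metrics grid archive
#'
#' Reads the companion archive written by [write_metrics_table()] back into
#' memory; values reproduce the written grids bit-exactly.
#'
#' @param path The summary-CSV path that was passed to
#'   [write_metrics_table()].
#' @return List with `scale_axis`, `shift_axis`, and per-antenna `rwe`,
#'   `entropy_scale`, `entropy_time`.
#' @export
read_metrics_archive <- function(path) {
  arr_dir <- paste0(sub("\\.csv$", "", path), "_arrays")
  if (!dir.exists(arr_dir)) stop(sprintf("I/O error: no archive at '%s'", arr_dir))
  scale_axis <- as.numeric(readLines(file.path(arr_dir, "scale_axis.csv")))
  shift_axis <- as.numeric(readLines(file.path(arr_dir, "shift_axis.csv")))
  rwe_files <- sort(list.files(arr_dir, pattern = "^rwe_antenna_", full.names = TRUE))
  ants <- as.integer(sub(".*rwe_antenna_(\\d+)\\.csv$", "\\1", rwe_files))
  out <- list(scale_axis = scale_axis, shift_axis = shift_axis,
              rwe = list(), entropy_scale = list(), entropy_time = list())
  for (k in seq_along(ants)) {
    i <- ants[k]
    out$rwe[[i]] <- as.matrix(utils::read.table(rwe_files[k], sep = ","))
    dimnames(out$rwe[[i]]) <- NULL
    out$entropy_scale[[i]] <- as.numeric(readLines(
      file.path(arr_dir, sprintf("entropy_scale_antenna_%02d.csv", i))))
    out$entropy_time[[i]] <- as.numeric(readLines(
      file.path(arr_dir, sprintf("entropy_time_antenna_%02d.csv", i))))
  }
  out
}
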