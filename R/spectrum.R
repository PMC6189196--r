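#' Construct a Raman spectrum
#'
#' A spectrum couples a strictly increasing wavenumber axis (cm^-1) with CCD
#' counts per channel and acquisition metadata. Raw spectra must have
#' non-negative counts; baseline-subtracted spectra may dip below zero.
#'
#' @param wavenumber numeric vector of channel centres in cm^-1, strictly
#'   increasing, length >= 16.
#' @param counts numeric vector of CCD counts, same length as `wavenumber`.
#' @param integration_time acquisition time in seconds.
#' @param timestamp acquisition timestamp in seconds (experiment clock).
#' @param iteration iteration number at which the spectrum was taken
#'   (0 = not produced by the acquisition controller).
#' @param label free-text label.
#' @param raw logical; if `TRUE` counts are checked to be non-negative.
#' @return an object of class `raman_spectrum`.
#' @export
spectrum <- function(wavenumber, counts, integration_time = 1, timestamp = 0,
                     iteration = 0L, label = "", raw = TRUE) {
  wavenumber <- as.numeric(wavenumber)
  counts <- as.numeric(counts)
  if (length(wavenumber) != length(counts))
    stop("wavenumber and counts must have equal length")
  if (length(wavenumber) < 16L)
    stop("spectrum must have at least 16 channels")
  if (anyNA(wavenumber) || anyNA(counts))
    stop("spectrum contains missing values")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (raw && any(counts < 0))
    stop("raw spectrum has negative counts")
  structure(
    list(wavenumber = wavenumber, counts = counts,
         meta = list(integration_time = integration_time,
                     timestamp = timestamp,
                     iteration = as.integer(iteration),
                     label = label)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf(
    "<raman_spectrum> %d channels, %.1f-%.1f cm-1, t_int %.3g s, iter %d%s\n",
    length(x$wavenumber), rng[1], rng[2], x$meta$integration_time,
    x$meta$iteration,
    if (nzchar(x$meta$label)) paste0(", '", x$meta$label, "'") else ""))
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, counts = x$counts)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

is_spectrum <- function(x) inherits(x, "raman_spectrum")

# rebuild a spectrum keeping metadata; skips the raw-counts check
with_counts <- function(s, counts, wavenumber = s$wavenumber) {
  out <- s
  out$wavenumber <- wavenumber
  out$counts <- counts
  out
}

#' Define an integration band
#'
#' A band names a Raman feature and the window `[center - half_width,
#' center + half_width]` over which its intensity or area is evaluated.
#' The default +/- 15 cm^-1 covers about five channels at 3 cm^-1 spectral
#' resolution.
#'
#' @param name band name, e.g. `"perchlorate"`.
#' @param center band centre in cm^-1.
#' @param half_width half-width of the integration window in cm^-1.
#' @return an object of class `raman_band`.
#' @export
band <- function(name, center, half_width = 15) {
  if (!is.numeric(center) || length(center) != 1L)
    stop("center must be a single number")
  if (!is.numeric(half_width) || half_width <= 0)
    stop("half_width must be > 0")
  structure(list(name = as.character(name), center = center,
                 half_width = half_width), class = "raman_band")
}

#' @export
print.raman_band <- function(x, ...) {
  cat(sprintf("<band '%s'> %.0f +/- %.0f cm-1\n", x$name, x$center,
              x$half_width))
  invisible(x)
}

band_window_idx <- function(s, b) {
  lo <- b$center - b$half_width
  hi <- b$center + b$half_width
  ax <- s$wavenumber
  if (lo < ax[1] || hi > ax[length(ax)])
    stop(sprintf("band '%s' window [%.0f, %.0f] outside spectrum axis [%.0f, %.0f]",
                 b$name, lo, hi, ax[1], ax[length(ax)]))
  which(ax >= lo & ax <= hi)
}

#' Read a spectrum from two-column delimited text
#'
#' The file holds one wavenumber and one counts column, comma or whitespace
#' separated, header optional. A descending axis is re-sorted ascending with
#' counts permuted consistently.
#'
#' @param path file path.
#' @param raw logical, passed to [spectrum()].
#' @param ... further arguments passed to [spectrum()] (metadata).
#' @return a `raman_spectrum`.
#' @export
read_spectrum <- function(path, raw = FALSE, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,;\t ]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  start <- 1L
  if (length(lines)) {
    v1 <- parse_row(lines[1])
    if (length(v1) < 2L || anyNA(v1[1:2])) start <- 2L  # header row
  }
  wn <- cn <- numeric(length(lines) - start + 1L)
  for (i in seq.int(start, length(lines))) {
    vals <- parse_row(lines[i])
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("parse error at line %d of '%s': %s", i, path, lines[i]))
    wn[i - start + 1L] <- vals[1]
    cn[i - start + 1L] <- vals[2]
  }
  o <- order(wn)
  wn <- wn[o]; cn <- cn[o]
  if (anyDuplicated(wn))
    stop("axis not strictly monotone after sorting (duplicate wavenumbers)")
  spectrum(wn, cn, raw = raw, ...)
}

#' Write a spectrum as two-column CSV
#'
#' Values are written with 9 significant digits so a write/read round trip is
#' bit-comparable at that precision.
#'
#' @param s a `raman_spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  lines <- sprintf("%.9g,%.9g", s$wavenumber, s$counts)
  writeLines(c("wavenumber_cm1,counts", lines), path)
  invisible(path)
}

#' Read a spectra matrix CSV
#'
#' Matrix dialect: first column is the shared wavenumber axis, each further
#' column one spectrum. Returns the axis and an n_spectra x n_channels matrix
#' (spectra in rows, as used by the chemometrics functions).
#'
#' @param path file path.
#' @return list with `wavenumber` and `counts` (rows = spectra).
#' @export
read_spectra_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a wavenumber column plus spectra")
  wn <- as.numeric(df[[1]])
  if (anyNA(wn)) stop("non-numeric wavenumber column")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  if (anyNA(m)) stop("non-numeric counts in matrix file")
  o <- order(wn)
  list(wavenumber = wn[o], counts = m[, o, drop = FALSE])
}

#' Write a spectra matrix CSV
#'
#' @param wavenumber shared axis.
#' @param counts n_spectra x n_channels matrix.
#' @param path output path.
#' @export
write_spectra_matrix <- function(wavenumber, counts, path) {
  counts <- rbind(counts)
  stopifnot(length(wavenumber) == ncol(counts))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(counts)))
  df <- data.frame(wavenumber_cm1 = wavenumber, t(counts))
  names(df)[-1] <- ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Preprocessing configuration
#'
#' Bundles the parameters of the standard preprocessing chain. Defaults follow
#' the standard acquisition window of 350-1825 cm^-1; deuterium/alkyne work
#' (C-D 2105, alkyne 2129 cm^-1) needs the extended range 606-2254 cm^-1, set
#' `truncate_lo`/`truncate_hi` accordingly.
#'
#' @param truncate_lo,truncate_hi truncation range in cm^-1.
#' @param whittaker_lambda roughness penalty of the baseline smoother.
#' @param whittaker_p asymmetry weight (0 < p < 1).
#' @param whittaker_iter reweighting passes.
#' @param savgol_window odd window length in channels.
#' @param savgol_order polynomial order, < `savgol_window`.
#' @param spike_z modified z-score threshold of the spike detector.
#' @param normalize logical; area-normalise at the end of the chain (switch
#'   off for sizing spectra).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(truncate_lo = 350, truncate_hi = 1825,
                              whittaker_lambda = 1e5, whittaker_p = 0.001,
                              whittaker_iter = 10,
                              savgol_window = 3, savgol_order = 1,
                              spike_z = 8, normalize = TRUE) {
  if (truncate_lo >= truncate_hi) stop("empty truncation range")
  if (savgol_window %% 2 == 0 || savgol_window <= savgol_order)
    stop("savgol_window must be odd and > savgol_order")
  if (whittaker_p <= 0 || whittaker_p >= 1) stop("whittaker_p must be in (0,1)")
  structure(list(truncate_lo = truncate_lo, truncate_hi = truncate_hi,
                 whittaker_lambda = whittaker_lambda, whittaker_p = whittaker_p,
                 whittaker_iter = whittaker_iter,
                 savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order),
                 spike_z = spike_z, normalize = isTRUE(normalize)),
            class = "preprocess_config")
}

#' Read / write a preprocessing configuration as JSON
#' @param path file path.
#' @rdname preprocess_config_io
#' @export
read_preprocess_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(preprocess_config, x)
}

#' @param cfg a `preprocess_config`.
#' @rdname preprocess_config_io
#' @export
write_preprocess_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
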