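#' Truncate a spectrum to a wavenumber range
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi`; metadata is
#' preserved. The standard analysis range 350-1825 cm^-1 omits the excitation
#' line; the extended range 606-2254 cm^-1 covers the C-D/alkyne region.
#'
#' @param s a `raman_spectrum`.
#' @param lo,hi closed interval bounds in cm^-1, `lo < hi`.
#' @return the truncated `raman_spectrum`.
#' @export
truncate_spectrum <- function(s, lo, hi) {
  stopifnot(is_spectrum(s), lo < hi)
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(keep)) stop("truncation removes all channels")
  with_counts(s, s$counts[keep], s$wavenumber[keep])
}

running_median7 <- function(y) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - 3L):min(n, i + 3L)
    out[i] <- stats::median(y[j])
  }
  out
}

#' Repair cosmic-ray spikes
#'
#' Flags channels whose modified z-score (median/MAD) of the second
#' difference exceeds `z_threshold` and whose counts exceed twice the local
#' 7-channel median (the amplitude guard keeps sharp genuine Raman peaks,
#' which rise only fractionally above their local median, from being
#' repaired), then replaces them by linear interpolation between the nearest
#' unflagged neighbours. Cosmic spikes are one or two channels wide and far
#' sharper than any Raman band, which is what the second-difference
#' statistic keys on.
#'
#' @param s a `raman_spectrum` with >= 5 channels.
#' @param z_threshold modified z-score cut-off (default 8).
#' @return list with `spectrum` (repaired), `repaired` (channel indices) and
#'   `suspect` (`TRUE` when more than 10\% of channels were flagged, which
#'   usually means the flags are real features, not spikes).
#' @export
remove_cosmic_spikes <- function(s, z_threshold = 8) {
  stopifnot(is_spectrum(s), length(s) >= 5L)
  y <- s$counts
  n <- length(y)
  d2 <- c(0, diff(y, differences = 2), 0)  # pad to channel-aligned length
  med <- stats::median(d2)
  mad <- stats::median(abs(d2 - med))
  if (mad == 0) mad <- stats::sd(d2) / 1.4826 + .Machine$double.eps
  z <- 0.6745 * (d2 - med) / mad
  locmed <- running_median7(y)
  amp_guard <- ifelse(locmed > 0, y > 2 * locmed, y > 0)
  flagged <- which(abs(z) > z_threshold & amp_guard)
  suspect <- length(flagged) > 0.1 * n
  if (length(flagged)) {
    keep <- setdiff(seq_len(n), flagged)
    y[flagged] <- stats::approx(s$wavenumber[keep], y[keep],
                                xout = s$wavenumber[flagged], rule = 2)$y
  }
  list(spectrum = with_counts(s, y), repaired = flagged, suspect = suspect)
}

# penalised least squares smooth with per-channel weights w:
# minimise sum w (y - z)^2 + lambda sum (d2 z)^2
whittaker_smooth <- function(y, w, lambda) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n, w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

#' Subtract a fluorescence baseline (asymmetric least squares)
#'
#' Estimates a smooth baseline with the Whittaker smoother (second-difference
#' roughness penalty `lambda`) under asymmetric reweighting: channels above
#' the current baseline get weight `p`, channels below get `1 - p`, so peaks
#' are ignored while the slowly varying fluorescence background is tracked.
#'
#' @param s a `raman_spectrum` (truncated and despiked).
#' @param lambda roughness penalty (default 1e5).
#' @param p asymmetry weight in (0, 1) (default 0.001).
#' @param n_iter reweighting passes (default 10).
#' @return list with `spectrum` (counts minus baseline), `baseline` (numeric
#'   vector) and `converged` (logical: weights stabilised within `n_iter`).
#' @export
subtract_baseline <- function(s, lambda = 1e5, p = 0.001, n_iter = 10) {
  stopifnot(is_spectrum(s), p > 0, p < 1, n_iter >= 1)
  y <- s$counts
  w <- rep(1, length(y))
  z <- y
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    z <- whittaker_smooth(y, w, lambda)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && it > 1L) { converged <- TRUE; break }
    w <- w_new
  }
  out <- with_counts(s, y - z)
  list(spectrum = out, baseline = z, converged = converged)
}

savgol_coef <- function(half, order, at = 0L) {
  x <- seq.int(-half, half)
  V <- outer(x, 0:order, `^`)
  # row of the hat matrix evaluating the fit at offset `at`
  ct <- outer(at, 0:order, `^`)
  as.numeric(ct %*% solve(crossprod(V), t(V)))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. With the default 3-point,
#' first-order filter, interior channels become a 3-point moving average;
#' edge channels are handled by shrinking the window symmetrically (a window
#' of one leaves the channel unchanged).
#'
#' @param s a `raman_spectrum`.
#' @param window odd window length in channels (default 3).
#' @param order polynomial order, < `window` (default 1).
#' @return the smoothed `raman_spectrum`.
#' @export
savgol_smooth <- function(s, window = 3, order = 1) {
  stopifnot(is_spectrum(s))
  if (window %% 2 == 0 || window <= order)
    stop("window must be odd and greater than order")
  y <- s$counts
  n <- length(y)
  h <- (window - 1L) %/% 2L
  out <- y
  interior <- savgol_coef(h, order)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    if (hi == 0L) next
    cf <- if (hi == h) interior else {
      if (2L * hi + 1L <= order) next else savgol_coef(hi, min(order, 2L * hi), 0L)
    }
    out[i] <- sum(cf * y[(i - hi):(i + hi)])
  }
  with_counts(s, out)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Area-under-curve normalisation
#'
#' Divides the counts by the trapezoidal integral of the spectrum over its
#' axis, so the normalised spectrum integrates to one. Area normalisation
#' precedes all compositional chemometrics but is skipped for sizing spectra
#' (the perchlorate ratio carries its own normalisation).
#'
#' @param s a `raman_spectrum`.
#' @return the normalised `raman_spectrum`.
#' @export
auc_normalize <- function(s) {
  stopifnot(is_spectrum(s))
  a <- trapz(s$wavenumber, s$counts)
  if (!is.finite(a) || a <= 0) stop("cannot normalise: non-positive total area")
  with_counts(s, s$counts / a)
}

#' Band intensity and area
#'
#' `band_intensity` is the maximum counts within the band window (peak
#' height); `band_area` the trapezoidal integral over the window.
#'
#' @param s a `raman_spectrum`.
#' @param b a `raman_band` whose window lies inside the axis.
#' @return a scalar.
#' @export
band_intensity <- function(s, b) {
  idx <- band_window_idx(s, b)
  max(s$counts[idx])
}

#' @rdname band_intensity
#' @export
band_area <- function(s, b) {
  idx <- band_window_idx(s, b)
  trapz(s$wavenumber[idx], s$counts[idx])
}

#' Run the full preprocessing chain
#'
#' Truncate, repair cosmic spikes, subtract the asymmetric-least-squares
#' baseline, Savitzky-Golay smooth, and (optionally) area-normalise, in that
#' order.
#'
#' @param s a raw `raman_spectrum`.
#' @param cfg a [preprocess_config()].
#' @return the preprocessed `raman_spectrum`; the repaired channel indices
#'   and the fitted baseline are attached as attributes `repaired` and
#'   `baseline`.
#' @export
preprocess <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  s <- truncate_spectrum(s, cfg$truncate_lo, cfg$truncate_hi)
  ds <- remove_cosmic_spikes(s, cfg$spike_z)
  bl <- subtract_baseline(ds$spectrum, cfg$whittaker_lambda, cfg$whittaker_p,
                          cfg$whittaker_iter)
  out <- savgol_smooth(bl$spectrum, cfg$savgol_window, cfg$savgol_order)
  if (cfg$normalize) out <- auc_normalize(out)
  attr(out, "repaired") <- ds$repaired
  attr(out, "baseline") <- bl$baseline
  out
}
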