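#' Perchlorate ratio of a sizing spectrum
#'
#' `ratio = (A_t - A_p) / A_p`, where `A_t` is the total trapezoidal area of
#' the baseline-subtracted (NOT area-normalised) spectrum and `A_p` the area
#' of the marker band. A trapped particle displaces its volume of marker
#' solution from the confocal volume, so the ratio grows with particle
#' volume: it is zero for pure solution (`A_t = A_p`) and diverges as the
#' marker band vanishes.
#'
#' @param s a baseline-subtracted `raman_spectrum`.
#' @param b the marker [band()] (default perchlorate, 938 +/- 15 cm^-1).
#' @return list of class `perchlorate_ratio` with `ratio`, `a_total`,
#'   `a_band` and `noise_flag` (`TRUE` when the ratio is negative, which can
#'   only be noise).
#' @export
perchlorate_ratio <- function(s, b = band("perchlorate", 938)) {
  a_t <- trapz(s$wavenumber, s$counts)
  a_p <- band_area(s, b)
  if (!is.finite(a_p) || a_p <= 0)
    stop("no marker signal: band area is not positive")
  structure(list(ratio = (a_t - a_p) / a_p, a_total = a_t, a_band = a_p,
                 noise_flag = a_t < a_p),
            class = "perchlorate_ratio")
}

#' Fit the sizing calibration
#'
#' Ordinary least squares of mean perchlorate ratio on log10 particle volume
#' (nm^3, computed as `(pi/6) d^3` from the nominal reference diameters).
#'
#' @param mean_ratios mean ratio per reference size.
#' @param diameters nominal reference diameters in nm (>= 3 distinct).
#' @return list of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `diameters`, `ratios`.
#' @export
fit_calibration <- function(mean_ratios, diameters) {
  if (length(unique(diameters)) < 3L)
    stop("calibration needs at least 3 distinct reference sizes")
  stopifnot(length(mean_ratios) == length(diameters), all(diameters > 0))
  logv <- log10((pi / 6) * diameters^3)
  if (diff(range(logv)) == 0) stop("zero volume spread")
  fit <- stats::lm(mean_ratios ~ logv)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_ratios - mean(mean_ratios))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 diameters = diameters, ratios = mean_ratios),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> ratio = %.4g + %.4g * log10(V[nm^3]), R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Invert a perchlorate ratio to a particle diameter
#'
#' `V = 10^((ratio - intercept)/slope)` (nm^3), `d = (6 V / pi)^(1/3)` (nm).
#' Ratios far outside the calibrated range (beyond half the calibration span
#' on either side) are still inverted but flagged as extrapolations.
#'
#' @param ratio a `perchlorate_ratio`, or a bare numeric ratio.
#' @param fit a `calibration_fit` with positive slope.
#' @return diameter in nm, with attribute `extrapolated`.
#' @export
estimate_size <- function(ratio, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) stop("calibration slope must be positive")
  r <- if (inherits(ratio, "perchlorate_ratio")) ratio$ratio else ratio
  span <- diff(range(fit$ratios))
  guard <- range(fit$ratios) + c(-0.5, 0.5) * span
  v <- 10^((r - fit$intercept) / fit$slope)
  d <- (6 * v / pi)^(1 / 3)
  attr(d, "extrapolated") <- r < guard[1] | r > guard[2]
  d
}

#' Size-distribution statistics
#'
#' Mean, standard deviation (n-1 denominator), polydispersity index
#' `PDI = (s.d. / mean)^2` and a histogram on the supplied bin edges (so
#' simulated size distributions can be binned identically to a reference
#' number distribution).
#'
#' @param diameters per-particle diameters in nm (> 0).
#' @param breaks histogram bin edges; defaults to Sturges on the data range.
#' @return list of class `size_distribution` with `diameters`, `mean`, `sd`,
#'   `pdi`, `histogram` (counts), `breaks`.
#' @export
distribution_stats <- function(diameters, breaks = NULL) {
  if (!length(diameters)) stop("empty size list")
  stopifnot(all(diameters > 0))
  m <- mean(diameters)
  s <- if (length(diameters) > 1L) stats::sd(diameters) else 0
  if (is.null(breaks)) {
    h <- graphics::hist(diameters, plot = FALSE)
  } else {
    h <- graphics::hist(diameters, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
  }
  structure(list(diameters = diameters, mean = m, sd = s, pdi = (s / m)^2,
                 histogram = h$counts, breaks = h$breaks),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> n = %d, mean %.1f nm, s.d. %.1f nm, PDI %.4f\n",
              length(x$diameters), x$mean, x$sd, x$pdi))
  invisible(x)
}

#' Run the full sizing pipeline on a simulated population
#'
#' Convenience wrapper: computes per-trap perchlorate ratios for a
#' population and for reference series, fits the calibration on the per-size
#' mean ratios, and inverts every population ratio to a diameter.
#'
#' @param population result of `simulate_population("sizing", ...)` for the
#'   unknown sample.
#' @param references result of `simulate_population("sizing", ...)` for the
#'   monodisperse reference series (column `diameter` gives the nominal
#'   sizes).
#' @param b marker band.
#' @return list with `fit` (`calibration_fit`), `ratios`, `diameters`
#'   (estimates) and `stats` (`size_distribution`).
#' @export
sizing_pipeline <- function(population, references,
                            b = band("perchlorate", 938)) {
  ref_ratio <- vapply(references$spectra,
                      function(s) perchlorate_ratio(s, b)$ratio, numeric(1))
  by_size <- tapply(ref_ratio, references$truth$diameter, mean)
  fit <- fit_calibration(as.numeric(by_size),
                         as.numeric(names(by_size)))
  ratios <- vapply(population$spectra,
                   function(s) perchlorate_ratio(s, b)$ratio, numeric(1))
  d <- as.numeric(estimate_size(ratios, fit))
  list(fit = fit, ratios = ratios, diameters = d,
       stats = distribution_stats(d))
}
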