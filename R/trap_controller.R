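#' Acquisition configuration
#'
#' Parameters of one automated acquisition run: target number of successful
#' acquisitions `n_a`, the short iteration time used only to test for a
#' trapped particle, the long high-SNR acquisition time, the laser disabling
#' time that lets the particle diffuse away after each attempt, and the
#' iteration cap per attempt cycle (default 10).
#'
#' @param n_a target number of successful acquisitions (>= 1).
#' @param t_iter iteration acquisition time (s).
#' @param t_acq high-SNR acquisition time (s).
#' @param t_off laser disabling time (s).
#' @param max_iterations iterations per attempt cycle before registering the
#'   attempt as unsuccessful.
#' @return an `acquisition_config`.
#' @export
acquisition_config <- function(n_a = 100, t_iter = 1, t_acq = 10, t_off = 0.5,
                               max_iterations = 10) {
  stopifnot(n_a >= 1, t_iter > 0, t_acq > 0, t_off > 0, max_iterations >= 1)
  structure(list(n_a = as.integer(n_a), t_iter = t_iter, t_acq = t_acq,
                 t_off = t_off, max_iterations = as.integer(max_iterations)),
            class = "acquisition_config")
}

#' Virtual instrument handle
#'
#' Wraps the occupancy dynamics ([step_stream()]) and the spectral render
#' ([render_spectrum()]) into a stateful instrument the acquisition
#' controller can drive. `sampler` draws the next arriving particle; the
#' internal clock advances by exactly the acquisition and disabling times.
#'
#' @param config a [stream_config()].
#' @param physics a [trap_physics()].
#' @param sampler function() returning a `particle_spec` for each arrival,
#'   or `NULL` for an empty solution.
#' @param library component library.
#' @return an environment of class `virtual_instrument` with functions
#'   `acquire(t_int)`, `disable(t_off)`, `occupied()`, `particle()`,
#'   `time()`.
#' @export
virtual_instrument <- function(config = stream_config(),
                               physics = trap_physics(),
                               sampler = NULL,
                               library = component_library()) {
  env <- new.env(parent = emptyenv())
  env$state <- new_stream_state()
  if (!is.null(sampler))
    env$state$diameter_hint <- sampler()$diameter
  env$clock <- 0
  env$config <- config
  env$physics <- physics
  acquire <- function(t_int) {
    env$state <- step_stream(env$state, laser_on = TRUE, dt = t_int,
                             physics = physics, sampler = sampler)
    s <- render_spectrum(env$state$particle, fill = env$state$fill,
                         t_int = t_int, config = config, physics = physics,
                         library = library)
    env$clock <- env$clock + t_int
    s$meta$timestamp <- env$clock
    s
  }
  disable <- function(t_off) {
    env$state <- step_stream(env$state, laser_on = FALSE, dt = t_off,
                             physics = physics)
    env$clock <- env$clock + t_off
    invisible(NULL)
  }
  env$acquire <- acquire
  env$disable <- disable
  env$occupied <- function() env$state$occupied
  env$particle <- function() env$state$particle
  env$time <- function() env$clock
  class(env) <- c("virtual_instrument", "environment")
  env
}

#' Calibrate the trap-recognition threshold
#'
#' Mirrors the manual set-up step: an initial particle is trapped and the
#' median height of a characteristic peak over `n_samples` occupied-trap
#' iteration spectra becomes the recognition threshold.
#'
#' @param instrument a [virtual_instrument()].
#' @param b a [band()] marking the characteristic peak.
#' @param n_samples occupied iteration spectra to take the median over.
#' @param t_iter iteration time used for the calibration spectra (s).
#' @param max_attempts bound on acquisitions while waiting for occupancy.
#' @return list of class `trap_threshold` with `band` and `threshold`.
#' @export
calibrate_threshold <- function(instrument, b, n_samples = 11, t_iter = 1,
                                max_attempts = 200) {
  heights <- numeric(0)
  attempts <- 0L
  while (length(heights) < n_samples) {
    s <- instrument$acquire(t_iter)
    attempts <- attempts + 1L
    if (instrument$occupied()) heights <- c(heights, band_intensity(s, b))
    if (attempts >= max_attempts && !length(heights))
      stop("calibration failure: no occupied trap observed")
    if (attempts >= max_attempts + n_samples) break
  }
  if (!length(heights)) stop("calibration failure: no occupied trap observed")
  structure(list(band = b, threshold = stats::median(heights)),
            class = "trap_threshold")
}

#' Run the automated acquisition loop
#'
#' Repeats attempt cycles until `n_a` successes. Within a cycle, up to
#' `max_iterations` short iteration spectra are taken; the first whose band
#' intensity exceeds the threshold (strictly) triggers exactly one high-SNR
#' acquisition and a trap record, after which the laser is disabled for
#' `t_off`. A cycle whose iterations all stay below threshold is logged as
#' unsuccessful and is also followed by the disable. A high-SNR spectrum is
#' never taken without a threshold pass.
#'
#' @param instrument a [virtual_instrument()].
#' @param config an [acquisition_config()].
#' @param threshold a `trap_threshold` from [calibrate_threshold()].
#' @param seed RNG seed for the run.
#' @param max_cycles bound on total attempt cycles (instrument exhaustion);
#'   when hit, the partial log is returned with `truncated = TRUE`.
#' @return list with `log` (data frame, one row per cycle), `spectra` (list
#'   of high-SNR spectra, indexed by `log$spectrum_index`), and `truncated`.
#' @export
run_acquisition <- function(instrument, config, threshold, seed = NULL,
                            max_cycles = 50L * config$n_a) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(threshold, "trap_threshold"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  spectra <- list()
  successes <- 0L
  cycle <- 0L
  while (successes < config$n_a && cycle < max_cycles) {
    cycle <- cycle + 1L
    hit_iter <- NA_integer_
    particle_id <- NA_integer_
    for (it in seq_len(config$max_iterations)) {
      s_it <- instrument$acquire(config$t_iter)
      if (band_intensity(s_it, threshold$band) > threshold$threshold) {
        hit_iter <- it
        break
      }
    }
    if (!is.na(hit_iter)) {
      s_hi <- instrument$acquire(config$t_acq)
      s_hi$meta$iteration <- hit_iter
      if (instrument$occupied()) particle_id <- instrument$particle()$id
      successes <- successes + 1L
      spectra[[successes]] <- s_hi
      rows[[cycle]] <- data.frame(
        trap_index = successes, success = TRUE, iteration_number = hit_iter,
        timestamp_s = instrument$time(), particle_id = particle_id,
        spectrum_index = successes)
    } else {
      rows[[cycle]] <- data.frame(
        trap_index = NA_integer_, success = FALSE,
        iteration_number = config$max_iterations,
        timestamp_s = instrument$time(), particle_id = NA_integer_,
        spectrum_index = NA_integer_)
    }
    instrument$disable(config$t_off)
  }
  log <- do.call(rbind, rows)
  log$t_iter_s <- config$t_iter
  log$t_acq_s <- config$t_acq
  log$t_off_s <- config$t_off
  log$threshold_counts <- threshold$threshold
  log$band_center_cm1 <- threshold$band$center
  list(log = log, spectra = spectra, truncated = successes < config$n_a)
}

#' Iteration-number check of a trapping log
#'
#' The iteration number at which each success occurred verifies the laser
#' disabling time: a pile-up at iteration 1 means the same particle is
#' likely re-trapped before it can diffuse away.
#'
#' @param log trapping-log data frame (needs `success` and
#'   `iteration_number`).
#' @return list with `histogram` (named counts per iteration number),
#'   `fraction_at_1` (`NA` and `undefined = TRUE` for an empty log) and
#'   `n_success`.
#' @export
iteration_check <- function(log) {
  it <- log$iteration_number[isTRUE_vec(log$success)]
  if (!length(it))
    return(list(histogram = integer(0), fraction_at_1 = NA_real_,
                n_success = 0L, undefined = TRUE))
  h <- table(factor(it, levels = seq_len(max(it))))
  list(histogram = h, fraction_at_1 = unname(mean(it == 1L)),
       n_success = length(it), undefined = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Post-hoc threshold filter
#'
#' Re-partitions saved high-SNR spectra against a (possibly stricter)
#' threshold to pick out false-positive traps when the live threshold was
#' set too low. Order is preserved and kept + rejected = input.
#'
#' @param spectra list of `raman_spectrum`.
#' @param b the characteristic [band()].
#' @param new_threshold intensity threshold in counts.
#' @return list with `kept`, `rejected` (lists) and `kept_index`.
#' @export
post_threshold_filter <- function(spectra, b, new_threshold) {
  pass <- vapply(spectra, function(s) band_intensity(s, b) > new_threshold,
                 logical(1))
  list(kept = spectra[pass], rejected = spectra[!pass],
       kept_index = which(pass))
}

#' Read / write a trapping log as JSON-Lines
#'
#' One JSON object per record with keys `trap_index`, `iteration_number`,
#' `timestamp_s`, `t_iter_s`, `t_acq_s`, `t_off_s`, `threshold_counts`,
#' `band_center_cm1`, `spectrum_file`, `post_threshold_pass`.
#'
#' @param log trapping-log data frame.
#' @param path file path.
#' @param spectrum_files optional character vector of per-record spectrum
#'   file names (defaults to `trap_<index>.csv` for successes).
#' @rdname trapping_log_io
#' @export
write_trapping_log <- function(log, path, spectrum_files = NULL) {
  keys <- c("trap_index", "iteration_number", "timestamp_s", "t_iter_s",
            "t_acq_s", "t_off_s", "threshold_counts", "band_center_cm1")
  if (is.null(spectrum_files))
    spectrum_files <- ifelse(isTRUE_vec(log$success),
                             sprintf("trap_%04d.csv", log$trap_index), "")
  if (is.null(log$post_threshold_pass))
    log$post_threshold_pass <- isTRUE_vec(log$success)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- as.list(log[i, intersect(keys, names(log)), drop = FALSE])
    rec$spectrum_file <- spectrum_files[i]
    rec$post_threshold_pass <- log$post_threshold_pass[i]
    rec$success <- isTRUE_vec(log$success)[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname trapping_log_io
#' @export
read_trapping_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
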