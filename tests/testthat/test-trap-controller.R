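# a virtual instrument pre-loaded with a particle and no arrivals: after an
# escape the trap stays empty, which makes retention effects visible
held_instrument <- function(diameter = 200, noise = TRUE, seed = 1) {
  cfg <- stream_config(axis_lo = 350, axis_hi = 1825, seed = seed,
                       spike_prob = 0, shot_noise = noise,
                       read_noise = if (noise) 2 else 0)
  vi <- virtual_instrument(cfg, trap_physics(concentration = NULL))
  vi$state$occupied <- TRUE
  vi$state$particle <- particle_spec(diameter, c(polystyrene = 1), id = 1L)
  vi$state$fill <- 1
  vi$state$next_id <- 2L
  vi
}

# instrument whose solution supplies fresh polystyrene particles with a
# realistic size spread (brightness ~ d^3, so only the brighter half of the
# population clears a median-calibrated threshold)
flowing_instrument <- function(concentration = 1e11, seed = 1,
                               size_sd = 25) {
  cfg <- stream_config(axis_lo = 350, axis_hi = 1825, seed = seed,
                       spike_prob = 0)
  virtual_instrument(cfg, trap_physics(concentration = concentration),
                     sampler = function()
                       particle_spec(max(50, rnorm(1, 200, size_sd)),
                                     c(polystyrene = 1)))
}

ps_band <- band("polystyrene", 1001)

test_that("threshold calibration takes the median occupied peak height", {
  # noiseless instrument with a constant peak height h: threshold = h
  vi <- held_instrument(noise = FALSE)
  th <- calibrate_threshold(vi, ps_band, n_samples = 7)
  s <- held_instrument(noise = FALSE)$acquire(1)
  expect_equal(th$threshold, band_intensity(s, ps_band))

  # with symmetric noise the median approaches the large-sample median
  set.seed(2)
  vi2 <- held_instrument(noise = TRUE)
  th2 <- calibrate_threshold(vi2, ps_band, n_samples = 31)
  set.seed(3)
  vi3 <- held_instrument(noise = TRUE)
  big <- replicate(400, band_intensity(vi3$acquire(1), ps_band))
  expect_lt(abs(th2$threshold - median(big)) / median(big), 0.05)

  # empty solution: calibration failure
  cfg <- stream_config(axis_lo = 350, axis_hi = 1825, seed = 1,
                       spike_prob = 0)
  empty <- virtual_instrument(cfg, trap_physics(concentration = NULL))
  expect_error(calibrate_threshold(empty, ps_band, max_attempts = 10),
               "calibration failure")
})

test_that("acquisition loop records exactly the threshold passes", {
  # always-occupied noiseless instrument: n_a records, all at iteration 1
  set.seed(4)
  vi <- held_instrument(noise = FALSE)
  vi$disable <- function(t_off) invisible(NULL)  # keep the particle held
  th <- structure(list(band = ps_band, threshold = 10),
                  class = "trap_threshold")
  cfg <- acquisition_config(n_a = 8, t_iter = 1, t_acq = 10, t_off = 0.5)
  run <- run_acquisition(vi, cfg, th, seed = 4)
  succ <- run$log[!is.na(run$log$success) & run$log$success, ]
  expect_false(run$truncated)
  expect_equal(nrow(succ), 8)
  expect_true(all(succ$iteration_number == 1))
  expect_length(run$spectra, 8)
  # log completeness: one record per high-SNR spectrum
  expect_equal(sort(succ$spectrum_index), seq_len(8))

  # never-occupied instrument: zero successes, cycles fail at max iterations
  # (threshold sits above the empty-trap background level)
  cfg0 <- stream_config(axis_lo = 350, axis_hi = 1825, seed = 1,
                        spike_prob = 0)
  empty <- virtual_instrument(cfg0, trap_physics(concentration = NULL))
  th_hi <- structure(list(band = ps_band, threshold = 150),
                     class = "trap_threshold")
  run0 <- run_acquisition(empty, acquisition_config(n_a = 2), th_hi,
                          seed = 5, max_cycles = 4)
  expect_true(run0$truncated)
  expect_length(run0$spectra, 0)
  expect_true(all(!run0$log$success))
  expect_true(all(run0$log$iteration_number == 10))
})

test_that("iteration check summarises the trapping log", {
  log <- data.frame(success = rep(TRUE, 4), iteration_number = c(1, 1, 2, 3))
  ic <- iteration_check(log)
  expect_equal(ic$fraction_at_1, 0.5)
  expect_equal(as.integer(ic$histogram), c(2L, 1L, 1L))

  none <- iteration_check(data.frame(success = logical(0),
                                     iteration_number = integer(0)))
  expect_true(none$undefined)
  expect_true(is.na(none$fraction_at_1))
})

test_that("blink-mode disabling re-traps the same particle at iteration 1", {
  # threshold calibrated on a median-size (200 nm) particle; the trapped
  # particle is a brighter one (230 nm, ~1.5x intensity), as only
  # above-threshold particles yield successful traps. 5 ms blink: retention
  # ~0.98, so successes pile up at iteration 1 and re-use the particle.
  set.seed(11)
  vi_cal <- held_instrument(diameter = 200, noise = TRUE)
  th <- calibrate_threshold(vi_cal, ps_band, n_samples = 11)
  vi <- held_instrument(diameter = 230, noise = TRUE)
  run <- run_acquisition(vi, acquisition_config(n_a = 20, t_off = 0.005), th,
                         seed = 12, max_cycles = 40)
  ic <- iteration_check(run$log)
  expect_gt(ic$fraction_at_1, 0.9)
  ids <- run$log$particle_id[!is.na(run$log$particle_id)]
  expect_gt(mean(duplicated(ids)), 0.5)
})

test_that("iteration-1 fraction is non-increasing in disabling time", {
  set.seed(21)
  vi_cal <- held_instrument(diameter = 200, noise = TRUE)
  th <- calibrate_threshold(vi_cal, ps_band, n_samples = 11)
  frac1 <- vapply(c(0.005, 0.1, 0.5), function(t_off) {
    set.seed(22)
    vi <- flowing_instrument(concentration = 1e10, seed = 22)
    vi$state$occupied <- TRUE
    vi$state$particle <- particle_spec(230, c(polystyrene = 1), id = 1L)
    run <- run_acquisition(vi, acquisition_config(n_a = 25, t_off = t_off),
                           th, seed = 23, max_cycles = 300)
    iteration_check(run$log)$fraction_at_1
  }, numeric(1))
  expect_true(all(diff(frac1) <= 0))
  expect_gt(frac1[1], 0.9)
})

test_that("post-hoc threshold filter partitions and preserves order", {
  set.seed(31)
  vi <- held_instrument(seed = 31)  # no arrivals: empties stay empty
  occ <- replicate(18, {
    vi$state$occupied <- TRUE
    vi$state$particle <- particle_spec(200, c(polystyrene = 1), id = 1L)
    vi$state$fill <- 1
    vi$acquire(10)
  }, simplify = FALSE)
  emp <- replicate(2, {
    vi$state$occupied <- FALSE
    vi$state$particle <- NULL
    vi$acquire(10)
  }, simplify = FALSE)
  mixed <- c(occ[1:9], emp[1], occ[10:18], emp[2])
  truth_empty <- c(rep(FALSE, 9), TRUE, rep(FALSE, 9), TRUE)

  all_kept <- post_threshold_filter(mixed, ps_band, 0)
  expect_length(all_kept$kept, 20)
  none_kept <- post_threshold_filter(mixed, ps_band, Inf)
  expect_length(none_kept$rejected, 20)

  # threshold between the empty and occupied populations rejects exactly
  # the empty-trap spectra
  ints <- vapply(mixed, band_intensity, numeric(1), b = ps_band)
  cut <- mean(c(max(ints[truth_empty]), min(ints[!truth_empty])))
  part <- post_threshold_filter(mixed, ps_band, cut)
  expect_equal(part$kept_index, which(!truth_empty))
  expect_length(part$kept, 18)
})

test_that("trapping log round-trips through JSON-Lines", {
  set.seed(41)
  vi <- held_instrument()
  th <- calibrate_threshold(vi, ps_band, n_samples = 5)
  run <- run_acquisition(vi, acquisition_config(n_a = 3, t_off = 0.005), th,
                         seed = 42, max_cycles = 20)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trapping_log(run$log, path)
  back <- read_trapping_log(path)
  expect_equal(nrow(back), nrow(run$log))
  succ <- !is.na(run$log$success) & run$log$success
  expect_equal(back$iteration_number, run$log$iteration_number)
  expect_equal(back$timestamp_s, run$log$timestamp_s)
  expect_equal(back$threshold_counts, rep(th$threshold, nrow(back)))
  expect_equal(back$band_center_cm1, rep(1001, nrow(back)))
  expect_equal(back$spectrum_file[succ],
               sprintf("trap_%04d.csv", run$log$trap_index[succ]))
})
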