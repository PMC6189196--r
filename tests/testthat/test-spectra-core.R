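test_that("spectrum file IO round-trips and validates", {
  nu <- std_axis()
  s <- spectrum(nu, gauss_peak(nu, 938, 8, 100) + 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$wavenumber, s$wavenumber)
  expect_equal(s2$counts, s$counts, tolerance = 1e-9)

  # descending axis input is re-sorted with counts permuted consistently
  writeLines(c("wn,counts", sprintf("%.9g,%.9g", rev(nu), rev(s$counts))),
             path)
  s3 <- read_spectrum(path)
  expect_equal(s3$wavenumber, nu)
  expect_equal(s3$counts, s$counts)

  # non-numeric row names its line
  writeLines(c("wn,counts", "100,1", "NaN, hello", "106,3"), path)
  expect_error(read_spectrum(path), "line 3")

  expect_error(spectrum(nu, c(s$counts[-1], -5)), "negative")
  expect_error(spectrum(rev(nu), s$counts), "increasing")
  expect_error(spectrum(nu[1:4], 1:4), "16 channels")
})

test_that("spectra matrix IO round-trips", {
  nu <- std_axis()
  m <- rbind(gauss_peak(nu, 700, 10, 3), gauss_peak(nu, 1400, 12, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_matrix(nu, m, path)
  back <- read_spectra_matrix(path)
  expect_equal(back$wavenumber, nu)
  expect_equal(unname(back$counts), unname(m), tolerance = 1e-12)
})

test_that("truncation keeps exactly the channels in range", {
  nu <- seq(300, 2000, by = 3)
  s <- spectrum(nu, seq_along(nu))
  tr <- truncate_spectrum(s, 350, 1825)
  expect_true(all(tr$wavenumber >= 350 & tr$wavenumber <= 1825))
  expect_equal(length(tr), sum(nu >= 350 & nu <= 1825))
  expect_equal(tr$meta, s$meta)

  expect_equal(truncate_spectrum(s, 300, 2000)$counts, s$counts)

  ext <- spectrum(seq(606, 2254, 3), rep(1, length(seq(606, 2254, 3))))
  kept <- truncate_spectrum(ext, 606, 2254)
  expect_true(2129 >= min(kept$wavenumber) && 2129 <= max(kept$wavenumber))

  expect_error(truncate_spectrum(s, 5000, 6000), "removes all channels")
})

test_that("cosmic spike repair touches only flagged channels", {
  nu <- std_axis()
  clean <- gauss_peak(nu, 1000, 12, 200) + 50
  spike_at <- 240L
  y <- clean
  y[spike_at] <- y[spike_at] * 100
  out <- remove_cosmic_spikes(spectrum(nu, y))
  expect_equal(out$repaired, spike_at)
  expect_equal(out$spectrum$counts[-spike_at], y[-spike_at])
  expect_lt(abs(out$spectrum$counts[spike_at] - clean[spike_at]),
            0.05 * clean[spike_at] + 1)

  # spike-free input is the identity with zero repairs
  id <- remove_cosmic_spikes(spectrum(nu, clean))
  expect_length(id$repaired, 0)
  expect_equal(id$spectrum$counts, clean)

  # two adjacent spiked channels both repaired to within 5% of ground truth
  y2 <- clean
  y2[300:301] <- y2[300:301] + 30 * max(clean)
  out2 <- remove_cosmic_spikes(spectrum(nu, y2))
  expect_setequal(out2$repaired, c(300L, 301L))
  expect_lt(max(abs(out2$spectrum$counts[300:301] - clean[300:301]) /
                  clean[300:301]), 0.05)
})

test_that("baseline subtraction removes smooth background, keeps peaks", {
  nu <- std_axis()
  # pure linear ramp: residual below 1% of ramp amplitude
  ramp <- 100 + 0.5 * (nu - 350)
  bl <- subtract_baseline(spectrum(nu, ramp))
  expect_lt(max(abs(bl$spectrum$counts)), 0.01 * diff(range(ramp)))

  # narrow peak on a flat offset: offset removed, area preserved within 5%
  peak <- gauss_peak(nu, 938, 8, 200)
  blp <- subtract_baseline(spectrum(nu, peak + 500), lambda = 1e5,
                           p = 0.001, n_iter = 10)
  a_est <- band_area(blp$spectrum, band("p", 938, 30))
  a_true <- trapz_oracle(nu, peak)
  expect_lt(abs(a_est / a_true - 1), 0.05)
  far <- abs(nu - 938) > 100
  expect_lt(max(abs(blp$spectrum$counts[far])), 0.01 * 500)

  # zero spectrum: zero baseline, zero residual
  z <- subtract_baseline(spectrum(nu, rep(0, length(nu))))
  expect_equal(max(abs(z$baseline)), 0)
  expect_equal(max(abs(z$spectrum$counts)), 0)

  # baseline is smoother than the input
  set.seed(7)
  y <- 800 * exp(-(nu - 350) / 1475) + rnorm(length(nu), 0, 4)
  bs <- subtract_baseline(spectrum(nu, pmax(y, 0)))
  expect_lt(sum(diff(bs$baseline, differences = 2)^2),
            sum(diff(y, differences = 2)^2))
  # peak-free input: mean |residual| < 2% of baseline amplitude
  expect_lt(mean(abs(bs$spectrum$counts)), 0.02 * 800)
})

test_that("Savitzky-Golay filter smooths as a local polynomial fit", {
  nu <- std_axis()
  lin <- spectrum(nu, 1 + 0.1 * nu)
  expect_equal(savgol_smooth(lin)$counts, lin$counts, tolerance = 1e-10)

  y <- rep(0, 20); y[10] <- 3
  s <- spectrum(1:20, y)
  expect_equal(savgol_smooth(s)$counts[9:11], c(1, 1, 1))

  expect_error(savgol_smooth(lin, window = 4), "odd")
  expect_error(savgol_smooth(lin, window = 3, order = 3), "odd|order")

  # white-noise s.d. shrinks by ~1/sqrt(3) on interior channels
  set.seed(11)
  sds <- replicate(300, {
    z <- spectrum(nu, rnorm(length(nu)), raw = FALSE)
    sd(savgol_smooth(z)$counts[10:480])
  })
  expect_equal(mean(sds), 1 / sqrt(3), tolerance = 0.02)
})

test_that("area normalisation scales to unit integral", {
  nu <- std_axis()
  s <- spectrum(nu, gauss_peak(nu, 900, 20, 7) + 1)
  n1 <- auc_normalize(s)
  expect_equal(trapz_oracle(n1$wavenumber, n1$counts), 1, tolerance = 1e-9)
  expect_equal(auc_normalize(n1)$counts, n1$counts, tolerance = 1e-12)
  expect_error(auc_normalize(spectrum(nu, rep(0, length(nu)))),
               "cannot normalise")
})

test_that("band intensity and area follow the window geometry", {
  # unit-height triangle of base 2w: intensity 1, area w
  x <- seq(0, 200, by = 2)
  w <- 30
  tri <- pmax(0, 1 - abs(x - 100) / w)
  s <- spectrum(x, tri)
  b <- band("tri", 100, w)
  expect_equal(band_intensity(s, b), 1)
  expect_equal(band_area(s, b), w)

  z <- spectrum(x, rep(0, length(x)))
  expect_equal(band_intensity(z, b), 0)
  expect_equal(band_area(z, b), 0)

  expect_error(band_area(s, band("far", 500, 10)), "far")

  # deuterated lipid shows the C-D band, the plain one does not
  set.seed(3)
  cfg <- stream_config(seed = 3, spike_prob = 0)
  dppc <- render_spectrum(particle_spec(100, c(dppc = 1)), config = cfg,
                          t_int = 10)
  set.seed(3)
  ddppc <- render_spectrum(particle_spec(100, c(d_dppc = 1)), config = cfg,
                           t_int = 10)
  cd <- band("C-D", 2105)
  expect_gt(band_intensity(ddppc, cd), band_intensity(dppc, cd))
})

test_that("full preprocessing chain recovers relative band areas", {
  nu <- std_axis()
  set.seed(21)
  b1 <- band("a", 700, 25); b2 <- band("b", 1400, 25)
  truth <- gauss_peak(nu, 700, 10, 600) + gauss_peak(nu, 1400, 10, 450)
  base <- 300 * exp(-(nu - 350) / 1475) + 40
  y <- rpois(length(nu), truth + base)
  y[123] <- y[123] * 40  # cosmic spike
  s <- spectrum(nu, y)
  out <- preprocess(s, preprocess_config())
  ratio <- band_area(out, b1) / band_area(out, b2)
  truth_s <- spectrum(nu, truth, raw = FALSE)
  true_ratio <- band_area(truth_s, b1) / band_area(truth_s, b2)
  expect_equal(ratio, true_ratio, tolerance = 0.1)
  expect_true(123L %in% attr(out, "repaired"))

  # normalisation preserves band-area ratios exactly
  pos <- spectrum(nu, truth + 10, raw = FALSE)
  n <- auc_normalize(pos)
  expect_equal(band_area(n, b1) / band_area(n, b2),
               band_area(pos, b1) / band_area(pos, b2), tolerance = 1e-12)
})
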