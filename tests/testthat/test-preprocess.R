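test_that("despiking excludes channel outliers and averages survivors", {
  ax <- wavenumber_axis(800, 900)
  n <- length(ax)
  # identical accumulations pass through unchanged
  m <- matrix(rep(sin(seq_len(n) / 5) + 2, 60), nrow = 60, byrow = TRUE)
  st <- spectrum_set(ax, m)
  expect_equal(despike(st)$intensity, m[1, ])

  # a single huge spike is fully excluded
  set.seed(1)
  clean <- sin(seq_len(n) / 5) + 2
  m2 <- matrix(rep(clean, 60), nrow = 60, byrow = TRUE) +
    rnorm(60 * n, sd = 0.01)
  m2[17, 40] <- m2[17, 40] + 1e6
  out <- despike(spectrum_set(ax, m2))
  expect_lt(abs(out$intensity[40] - clean[40]), 0.01)
  expect_match(out$history[length(out$history)], "excluded=")

  # a single accumulation is returned with a warning
  expect_warning(one <- despike(spectrum_set(ax, m2[1, , drop = FALSE])),
                 "single")
  expect_equal(one$intensity, m2[1, ])
})

test_that("despiking at realistic spike rates recovers the clean mean", {
  lib <- fixture_lib
  bone <- generate_bone_spectrum(lib, 1)
  cfg <- sors_config(soft_tissue_weight = 0.4, amide_I_attenuation = 1,
                     spike_rate = 2, spike_height = 50,
                     baseline_scale = 0, noise_sd = 0.05)
  st <- generate_sors_measurement(bone, lib, cfg, seed = 21)
  soft <- lib$components[, "lipid"] + lib$components[, "skin_matrix"]
  truth <- 0.6 * bone$intensity + 0.4 * soft
  out <- despike(st)
  tol <- 3 * 0.05 / sqrt(60)
  expect_gte(mean(abs(out$intensity - truth) <= tol), 0.99)
})

test_that("modified polyfit removes polynomial baselines exactly", {
  ax <- wavenumber_axis()
  u <- 2 * (as.numeric(ax) - 800) / 1000 - 1
  base <- 5 + 3 * u - 2 * u^2 + u^3 + 0.5 * u^4 - 0.25 * u^5
  s <- raman_spectrum(ax, base)
  out <- remove_background(s, order = 5)
  expect_lt(max(abs(out$intensity)), 1e-6 * max(abs(base)))
})

test_that("modified polyfit preserves peaks sitting on baselines", {
  ax <- wavenumber_axis()
  u <- 2 * (as.numeric(ax) - 800) / 1000 - 1
  base <- 10 + 4 * u + 3 * u^2 - u^3
  h <- 2
  peak <- h * exp(-4 * log(2) * (as.numeric(ax) - 1300)^2 / 15^2)
  s <- raman_spectrum(ax, base + peak)
  out <- remove_background(s, order = 5)
  rec_h <- max(out$intensity[ax >= 1290 & ax <= 1310])
  expect_lt(abs(rec_h - h), 0.02 * h)

  # near-idempotence: a second pass changes almost nothing
  out2 <- remove_background(out, order = 5)
  expect_lt(max(abs(out2$intensity - out$intensity)), 0.01 * h)

  # at the spectrum's global minimum the fit passes close to the data, so
  # the corrected value there stays near zero (within 2% of the range)
  i_min <- which.min(base + peak)
  expect_lt(abs(out$intensity[i_min]), 0.02 * max(base + peak))
})

test_that("band normalisation is idempotent, scale-invariant and guarded", {
  lib <- fixture_lib
  s <- generate_bone_spectrum(lib, 1.2)
  w <- band_window(950, 970)
  n1 <- normalize_to_band(s, w)
  expect_equal(max(n1$intensity[s$wavenumber >= 950 & s$wavenumber <= 970]), 1)
  n2 <- normalize_to_band(n1, w)
  expect_equal(n2$intensity, n1$intensity)
  s_scaled <- s; s_scaled$intensity <- 17 * s$intensity
  expect_equal(normalize_to_band(s_scaled, w)$intensity, n1$intensity)

  zero <- raman_spectrum(s$wavenumber, rep(0, length(s$wavenumber)))
  expect_error(normalize_to_band(zero, w), "degenerate")
})

test_that("band intensity measures height by default and area on request", {
  ax <- wavenumber_axis()
  h <- 1.7
  g <- h * exp(-4 * log(2) * (as.numeric(ax) - 1000)^2 / 15^2)
  s <- raman_spectrum(ax, g)
  expect_equal(band_intensity(s, band_window(998, 1002)), h, tolerance = 0.01 * h)
  expect_equal(band_intensity(s, band_window(1700, 1800)), 0)
  # Gaussian integral = h * FWHM * sqrt(pi / (4 log 2))
  area <- band_intensity(s, band_window(900, 1100), type = "area")
  expect_equal(area, h * 15 * sqrt(pi / (4 * log(2))), tolerance = 1e-3)
})

test_that("weak-mineral filtering honours the threshold boundary", {
  ax <- wavenumber_axis()
  mk <- function(nu1) {
    y <- nu1 * exp(-4 * log(2) * (as.numeric(ax) - 961)^2 / 15^2) +
      exp(-4 * log(2) * (as.numeric(ax) - 1299)^2 / 20^2)
    y
  }
  m <- rbind(mk(0.44), mk(0.45), mk(0.46))
  st <- spectrum_set(ax, m, meta = data.frame(subject = c("a", "a", "b")))
  out <- filter_weak_mineral(st)
  expect_equal(nrow(out$intensity), 2)           # 0.45 kept, 0.44 discarded
  expect_equal(band_intensity(out, band_window(959, 963)),
               c(0.45, 0.46), tolerance = 1e-6)
  rep <- attr(out, "filter_report")
  expect_true(all(rep$under_min))                # both subjects < 5 spectra

  # refiltering is a fixed point; empty set passes through
  again <- filter_weak_mineral(out)
  expect_equal(again$intensity, out$intensity)
  empty <- spectrum_set(ax, m[0, , drop = FALSE])
  expect_equal(nrow(filter_weak_mineral(empty)$intensity), 0)
})

test_that("trimming keeps inclusive windows and counts channels", {
  ax <- wavenumber_axis()
  s <- raman_spectrum(ax, seq_along(ax))
  t1 <- trim_region(s, band_window(987, 1540))
  expect_length(t1$intensity, 554)
  expect_true(all(t1$wavenumber >= 987 & t1$wavenumber <= 1540))

  full <- trim_region(s, band_window(800, 1800))
  expect_equal(full$intensity, s$intensity)

  expect_error(trim_region(s, list(band_window(900, 1000),
                                   band_window(950, 1100))), "overlap")
  expect_error(trim_region(s, band_window(1900, 2000)), "outside")
})

test_that("resolution smoothing averages locally and keeps edges", {
  ax <- wavenumber_axis(800, 900)
  y <- rep(c(0, 1), length.out = length(ax))
  s <- smooth_spectra(raman_spectrum(ax, y), 7)
  mid <- 10:90
  expect_true(all(abs(s$intensity[mid] - mean(y)) < 0.08))
  expect_equal(s$intensity[1:3], y[1:3])
  expect_error(smooth_spectra(raman_spectrum(ax, y), 4), "odd")
})
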