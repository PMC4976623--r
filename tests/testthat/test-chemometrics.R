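make_trimmed_cohorts <- function(delta = 5.5, seed = 3, ...) {
  st <- synthesize_excised_study(delta, seed = seed, ...)
  cfg <- pipeline_config("excised")
  st <- remove_background(st)
  st <- normalize_to_band(st, cfg$nu1_window)
  tr <- trim_region(st, cfg$trim)
  normalize_to_band(tr, cfg$carbonate_window)
}

test_that("two-spectrum PCA has one loading along the difference", {
  ax <- wavenumber_axis(1100, 1400)
  set.seed(2)
  a <- rexp(length(ax)); b <- rexp(length(ax))
  st <- spectrum_set(ax, rbind(a, b))
  m <- fit_collagen_pca(st)
  expect_equal(abs(cosine(m$loadings[, 1], a - b)), 1, tolerance = 1e-10)
  sc <- m$scores$collagen_score
  expect_equal(sc[1], -sc[2], tolerance = 1e-8)
})

test_that("full-rank PCA reconstruction reproduces every spectrum", {
  ax <- wavenumber_axis(1000, 1300)
  set.seed(5)
  X <- matrix(rexp(8 * length(ax)), 8)
  m <- fit_collagen_pca(spectrum_set(ax, X))
  rec <- sweep(m$score_matrix %*% t(m$loadings), 2, m$mean_spectrum, `+`)
  expect_lt(max(abs(rec - X)), 1e-10)
  # explained variances sum to the total variance and are non-increasing
  expect_equal(sum(m$explained_variance),
               sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1),
               tolerance = 1e-6)
  expect_true(all(diff(m$explained_variance) <= 1e-10))
  # scores of the training data sum to zero channel-wise
  expect_lt(max(abs(colSums(m$score_matrix))), 1e-8)
})

test_that("scoring matches the brute-force centered projection", {
  ax <- wavenumber_axis(1000, 1300)
  set.seed(6)
  X <- matrix(rexp(6 * length(ax)), 6)
  m <- fit_collagen_pca(spectrum_set(ax, X))
  # mean spectrum scores zero
  expect_equal(collagen_score(m, raman_spectrum(ax, m$mean_spectrum)), 0,
               tolerance = 1e-10)
  # mean + c * loading1 scores c
  expect_equal(collagen_score(m, raman_spectrum(ax, m$mean_spectrum +
                                                  2.5 * m$loadings[, 1])),
               2.5, tolerance = 1e-10)
  # random spectrum: direct inner product
  y <- rexp(length(ax))
  expect_equal(collagen_score(m, raman_spectrum(ax, y)),
               sum((y - m$mean_spectrum) * m$loadings[, 1]),
               tolerance = 1e-12)
  short <- raman_spectrum(wavenumber_axis(1000, 1200), rep(1, 201))
  expect_error(collagen_score(m, short), "axis")
})

test_that("first loading is collagen-oriented and sign-stable", {
  tr <- make_trimmed_cohorts(seed = 9)
  m1 <- fit_collagen_pca(tr)
  m2 <- fit_collagen_pca(tr)
  expect_identical(m1$loadings, m2$loadings)
  ax <- m1$wavenumber
  # largest-magnitude loading channels sit in the collagen bands, not in
  # the carbonate reference window
  top <- ax[order(abs(m1$loadings[, 1]), decreasing = TRUE)[1:30]]
  in_collagen <- (top >= 1200 & top <= 1320) | (top >= 1380 & top <= 1500) |
    (top >= 1580 & top <= 1750)
  expect_gt(mean(in_collagen), 0.8)
  expect_false(any(top >= 1050 & top <= 1090))
  # collagen-positive orientation: control cohort (less mineralised, more
  # collagen per carbonate) scores higher
  agg <- tapply(m1$scores$collagen_score, m1$scores$cohort, mean)
  expect_gt(agg[["control"]], agg[["fractured"]])
})

test_that("per-subject averaging contracts within-subject variance", {
  scores <- data.frame(subject = c("a", "a", "b"), cohort = "c",
                       collagen_score = c(1, 3, 7))
  avg <- average_by_subject(scores)
  expect_equal(avg$collagen_score[avg$subject == "a"], 2)
  expect_equal(avg$collagen_score[avg$subject == "b"], 7)

  tr <- make_trimmed_cohorts(seed = 12)
  m <- fit_collagen_pca(tr)
  avg2 <- average_by_subject(m$scores)
  expect_equal(nrow(avg2), 20)
  pooled_sd <- function(tab) {
    mean(tapply(tab$collagen_score, tab$cohort, sd))
  }
  expect_lt(pooled_sd(avg2), pooled_sd(m$scores))

  bad <- data.frame(subject = "a", cohort = c("x", "y"), collagen_score = 1:2)
  expect_error(average_by_subject(bad), "more than one cohort")
  expect_error(average_by_subject(bad[0, ]), "empty")
})

test_that("group-mean reconstruction obeys its closed forms", {
  tr <- make_trimmed_cohorts(seed = 15)
  m <- fit_collagen_pca(tr)
  # all spectra as one cohort reproduces the global mean (scores centre at 0)
  sc <- m$scores; sc$cohort <- "all"
  rec_all <- reconstruct_group_mean(m, sc, "all")
  expect_equal(rec_all$intensity, m$mean_spectrum, tolerance = 1e-8)
  expect_error(reconstruct_group_mean(m, m$scores, "nope"), "not present")

  # rank-1 two-spectrum case: single-spectrum cohorts are reproduced exactly
  ax <- wavenumber_axis(1000, 1200)
  base <- rexp(length(ax))
  st <- spectrum_set(ax, rbind(base, 2 * base),
                     meta = data.frame(subject = c("p", "q"),
                                       cohort = c("p", "q")))
  m2 <- fit_collagen_pca(st, collagen_window = band_window(1050, 1150))
  rec_p <- reconstruct_group_mean(m2, m2$scores, "p")
  expect_equal(rec_p$intensity, base, tolerance = 1e-8)
})

test_that("percent mineralisation difference inverts known constructions", {
  tr <- make_trimmed_cohorts(seed = 18)
  m <- fit_collagen_pca(tr)
  a <- reconstruct_group_mean(m, m$scores, "fractured")
  expect_equal(percent_mineralization_difference(a, a), 0)

  # scaling the collagen region of b by 1.055 gives +5.5%
  ax <- a$wavenumber
  b <- a
  scale_chan <- ax >= 988 & (ax < 1050 | ax > 1090)
  b$intensity[scale_chan] <- 1.055 * b$intensity[scale_chan]
  expect_equal(percent_mineralization_difference(a, b), 5.5, tolerance = 0.2)

  zero <- raman_spectrum(ax, c(rep(1, sum(ax <= 1090)),
                               rep(0, sum(ax > 1090))))
  zero$intensity[ax >= 988] <- 0
  expect_error(percent_mineralization_difference(zero, a), "zero integrated")
})

test_that("band ratios compose from band intensities", {
  lib <- fixture_lib
  s1 <- generate_bone_spectrum(lib, 1)
  s2 <- generate_bone_spectrum(lib, 2)
  nu1 <- band_window(950, 970); am3 <- band_window(1240, 1260)
  expect_equal(band_ratio(s1, nu1, nu1), 1)
  expect_equal(band_ratio(s2, nu1, am3) / band_ratio(s1, nu1, am3), 2,
               tolerance = 0.02)
  expect_equal(band_ratio(s1, nu1, am3),
               band_intensity(s1, nu1) / band_intensity(s1, am3),
               tolerance = 1e-12)
  flat <- raman_spectrum(lib$wavenumber, rep(0, length(lib$wavenumber)))
  expect_error(band_ratio(flat, nu1, am3), "zero denominator")
})
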