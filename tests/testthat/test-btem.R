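test_that("singular basis matches rank structure and a Gram-matrix oracle", {
  ax <- wavenumber_axis(800, 900)
  n <- length(ax)

  # identical spectra: rank one
  y <- sin(seq_len(n) / 7) + 2
  st <- spectrum_set(ax, matrix(rep(y, 4), nrow = 4, byrow = TRUE))
  b <- compute_basis(st, 2)
  expect_gt(abs(cosine(b$vectors[, 1], y)), 1 - 1e-10)
  expect_lt(b$singular_values[2], 1e-8 * b$singular_values[1])

  # orthogonal rows: singular values are the sorted row norms
  m <- matrix(0, 3, n)
  m[1, 1:30] <- 3; m[2, 31:60] <- 5; m[3, 61:90] <- 4
  norms <- sqrt(rowSums(m^2))
  b2 <- compute_basis(spectrum_set(ax, m), 3)
  expect_equal(b2$singular_values, sort(norms, decreasing = TRUE))

  # random matrix: projection residuals match Gram-matrix eigendecomposition
  set.seed(8)
  X <- matrix(rnorm(10 * n), 10, n)
  b3 <- compute_basis(spectrum_set(ax, X), 5)
  expect_equal(crossprod(b3$vectors), diag(5), tolerance = 1e-8)
  eg <- eigen(X %*% t(X), symmetric = TRUE)
  expect_equal(b3$singular_values, sqrt(eg$values[1:5]), tolerance = 1e-6)
  res_svd <- X - (X %*% b3$vectors) %*% t(b3$vectors)
  U5 <- eg$vectors[, 1:5]
  res_gram <- X - U5 %*% (t(U5) %*% X)
  expect_equal(sum(res_svd^2), sum(res_gram^2), tolerance = 1e-6)

  expect_error(compute_basis(st, 10), "exceeds")
  expect_error(compute_basis(spectrum_set(ax, m[1, , drop = FALSE]), 1), ">= 2")
})

test_that("derivative entropy follows its closed forms and a direct oracle", {
  expect_equal(derivative_entropy(rep(3.7, 50)), 0)

  # symmetric triangle over 2k equal-|slope| intervals: h = log(2k)
  for (k in c(5, 16, 50)) {
    tri <- c(0:k, (k - 1):0)
    expect_equal(derivative_entropy(tri), log(2 * k))
  }

  # direct-summation oracle on random vectors
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(100)
    d <- abs(diff(x))
    p <- d[d > 0] / sum(d)
    h_oracle <- -sum(vapply(p, function(pi) pi * log(pi), 0))
    expect_lt(abs(derivative_entropy(x) - h_oracle), 1e-10)
  }
  expect_error(derivative_entropy(1), "length")
})

test_that("rank-one data are recovered exactly by band-targeted extraction", {
  lib <- fixture_lib
  bone <- generate_bone_spectrum(lib, 1)
  st <- spectrum_set(lib$wavenumber,
                     outer(c(1, 2, 0.5), bone$intensity))
  b <- compute_basis(st, 2)
  res <- btem_extract(b, seed = 1)
  expect_gte(cosine(res$raw_estimate, bone$intensity), 0.999)
  expect_true(res$converged)
})

test_that("extraction fails loudly when the target band has no signal", {
  ax <- wavenumber_axis()
  # a pure Gaussian component at 1600 cm^-1 carries exactly zero intensity
  # hundreds of cm^-1 away, so a 930-945 target cannot be normalised
  lib <- make_component_library(ax, list(
    far = list(band(1600, 15, 1, shape = "gaussian"))))
  set.seed(2)
  m <- outer(runif(5, 0.5, 2), lib$components[, "far"])
  b <- compute_basis(spectrum_set(ax, m), 1)
  expect_error(btem_extract(b, target = band_window(930, 945), seed = 1),
               "target band absent")
})

test_that("BTEM recovers the bone component from 3-component mixtures", {
  mx <- make_mixture_set(n = 10, noise_sd = 0.02, seed = 4)
  sm <- smooth_spectra(mx$set, 7)
  b <- compute_basis(sm, 5)
  res <- btem_extract(b, seed = 4)
  expect_gte(cosine(res$raw_estimate, mx$bone), 0.98)

  # scale invariance: scaling all inputs leaves the estimate unchanged up
  # to simplex-convergence noise in the flat part of the objective valley
  scaled <- sm; scaled$intensity <- 100 * sm$intensity
  res2 <- btem_extract(compute_basis(scaled, 5), seed = 4)
  expect_gt(cosine(res2$raw_estimate, res$raw_estimate), 0.999)

  # basis restriction: estimate lies in the span of the basis
  V <- b$vectors
  x <- res$raw_estimate
  expect_lt(sqrt(sum((x - drop(V %*% crossprod(V, x)))^2)), 1e-8 * sqrt(sum(x^2)))
})

test_that("the best objective is non-increasing in the number of restarts", {
  mx <- make_mixture_set(n = 8, noise_sd = 0.03, seed = 6)
  b <- compute_basis(smooth_spectra(mx$set, 7), 5)
  objs <- vapply(c(0, 4, 8), function(r) {
    btem_extract(b, restarts = r, seed = 5)$objective
  }, 0)
  expect_true(all(diff(objs) <= 1e-9))
})

test_that("per-subject extraction isolates each subject's bone spectrum", {
  lib <- fixture_lib
  set.seed(10)
  soft <- lib$components[, "lipid"] + lib$components[, "skin_matrix"]
  sets <- list()
  ratios <- c(a = 0.9, b = 1.15)
  for (sj in names(ratios)) {
    bone <- generate_bone_spectrum(lib, ratios[[sj]])
    w <- runif(6, 0.3, 0.7)
    m <- t(sapply(w, function(wi) (1 - wi) * bone$intensity + wi * soft +
                    rnorm(length(bone$intensity), sd = 0.01)))
    sets[[sj]] <- spectrum_set(lib$wavenumber, m,
                               meta = data.frame(subject = rep(sj, 6),
                                                 cohort = "c",
                                                 true_ratio = ratios[[sj]]))
  }
  all <- bind_spectra(c(lapply(1:6, function(i) set_spectrum(sets$a, i)),
                        lapply(1:6, function(i) set_spectrum(sets$b, i))))
  out <- btem_per_subject(all, z = 5, seed = 2)
  expect_named(out, c("a", "b"))
  # recovered nu1-normalised carbonate heights preserve the ratio ordering
  carb <- vapply(out, function(r) {
    ax <- r$estimate$wavenumber
    max(r$estimate$intensity[ax >= 1050 & ax <= 1090])
  }, 0)
  expect_gt(carb[["b"]] / carb[["a"]], 1)

  # single-spectrum subject is skipped with a warning
  solo <- bind_spectra(list(set_spectrum(sets$a, 1)))
  solo$meta$subject <- "solo"
  both <- spectrum_set(all$wavenumber, rbind(all$intensity, solo$intensity),
                       meta = rbind(all$meta[c("subject", "cohort", "true_ratio")],
                                    data.frame(subject = "solo", cohort = "c",
                                               true_ratio = 1)))
  expect_warning(out2 <- btem_per_subject(both, z = 5, seed = 2), "single")
  expect_named(out2, c("a", "b"))
})
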