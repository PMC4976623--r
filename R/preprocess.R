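# Spectral preprocessing: cosmic-ray despiking, iterative modified-polyfit
# fluorescence background removal, band normalisation, weak-mineral
# filtering and region trimming. All operations append a machine-readable
# history line to their output.

#' Collapse repeated accumulations into one despiked spectrum
#'
#' Cosmic-ray events hit single channels of single accumulations. Per
#' channel, accumulations whose value exceeds `median + k * MAD` across the
#' stack are excluded and the mean of the surviving values is returned --
#' the outlier comparison of successive spectra that SORS detectors apply
#' on-line.
#'
#' @param set A [spectrum_set()] of >= 2 accumulations on a common axis.
#' @param k MAD multiplier for the exclusion threshold (default 8).
#' @return A [raman_spectrum()]; the history line records how many values
#'   were excluded. A single-accumulation set is returned unchanged with a
#'   warning.
#' @export
despike <- function(set, k = 8) {
  stopifnot(inherits(set, "spectrum_set"))
  m <- set$intensity
  meta1 <- as.list(set$meta[1, setdiff(names(set$meta), "accumulation"),
                            drop = FALSE])
  if (nrow(m) < 2) {
    warning("despike needs >= 2 accumulations; returning the single spectrum")
    s <- raman_spectrum(set$wavenumber, m[1, ], meta = meta1,
                        history = set$history)
    return(add_history(s, "despike", skipped = "single accumulation"))
  }
  med <- col_medians(m)
  madv <- 1.4826 * col_medians(abs(sweep(m, 2, med)))
  thresh <- med + k * madv
  bad <- sweep(m, 2, thresh, `>`)
  keep <- !bad
  out <- colSums(m * keep) / colSums(keep)
  s <- raman_spectrum(set$wavenumber, out, meta = meta1, history = set$history)
  add_history(s, "despike", k = k, n_acc = nrow(m), excluded = sum(bad))
}

# internal: column medians through one radix sort (fast for the wide
# accumulation stacks despiking works on)
col_medians <- function(m) {
  n <- nrow(m)
  srt <- matrix(m[order(col(m), m)], nrow = n)
  if (n %% 2 == 1) srt[(n + 1) / 2, ] else (srt[n / 2, ] + srt[n / 2 + 1, ]) / 2
}

# internal: orthonormal polynomial basis on the axis (scaled to [-1, 1])
poly_basis <- function(axis, order) {
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  qr.Q(qr(outer(u, 0:order, `^`)))
}

#' Remove the broad fluorescence background
#'
#' Iterative modified polyfit: a degree-`order` polynomial is least-squares
#' fitted to the spectrum; points above the fit are replaced by the fit;
#' the loop repeats until the maximum relative change of the fitted
#' baseline drops below `tol` or `max_iter` is reached. Because Raman bands
#' only add to the fluorescence, the clamped refits converge onto the
#' baseline under the bands. The returned spectrum is the input minus the
#' final fit and may contain small negatives.
#'
#' @param s A [raman_spectrum()] or [spectrum_set()] (applied per row).
#' @param order Polynomial degree (default 5, the usual choice for the
#'   800--1800 cm^-1 fingerprint region: tracks broad fluorescence without
#'   biting into the amide I envelope).
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative convergence threshold on the fit (default 1e-4).
#' @return Background-subtracted object of the same class; non-convergence
#'   is flagged in the history, not an error.
#' @export
remove_background <- function(s, order = 5, max_iter = 100, tol = 1e-4) {
  UseMethod("remove_background")
}

# internal: one spectrum against a precomputed orthonormal basis Q
modpolyfit <- function(y, Q, max_iter, tol) {
  work <- y
  fit_prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- drop(Q %*% crossprod(Q, work))
    if (!is.null(fit_prev)) {
      rel <- max(abs(fit - fit_prev)) / max(max(abs(fit)), .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    fit_prev <- fit
    work <- pmin(work, fit)
  }
  list(corrected = y - fit, converged = converged, iterations = it)
}

#' @export
remove_background.raman_spectrum <- function(s, order = 5, max_iter = 100,
                                             tol = 1e-4) {
  if (order < 1 || max_iter < 1 || tol <= 0) {
    stop("order and max_iter must be >= 1 and tol > 0")
  }
  if (length(s$wavenumber) <= order + 1) {
    stop("axis must have more than order + 1 channels")
  }
  Q <- poly_basis(s$wavenumber, order)
  r <- modpolyfit(s$intensity, Q, max_iter, tol)
  s$intensity <- r$corrected
  add_history(s, "remove_background", order = order, iter = r$iterations,
              converged = r$converged)
}

#' @export
remove_background.spectrum_set <- function(s, order = 5, max_iter = 100,
                                           tol = 1e-4) {
  if (length(s$wavenumber) <= order + 1) {
    stop("axis must have more than order + 1 channels")
  }
  Q <- poly_basis(s$wavenumber, order)
  all_conv <- TRUE
  for (i in seq_len(nrow(s$intensity))) {
    r <- modpolyfit(s$intensity[i, ], Q, max_iter, tol)
    s$intensity[i, ] <- r$corrected
    all_conv <- all_conv && r$converged
  }
  s$history <- c(s$history,
                 sprintf("remove_background(order=%d, converged=%s)",
                         order, all_conv))
  s
}

#' Resolution-matched boxcar smoothing
#'
#' Spectra sampled at 1 cm^-1 oversample the ~8 cm^-1 instrument
#' resolution; a moving-average over `window` channels suppresses
#' sub-resolution detector noise without distorting real bands. Edge
#' channels where the window does not fit keep their raw values.
#'
#' @param s A [raman_spectrum()] or [spectrum_set()] (per row).
#' @param window Odd number of channels to average (default 7).
#' @return Smoothed object of the same class.
#' @export
smooth_spectra <- function(s, window = 7) {
  if (window < 1 || window %% 2 != 1) stop("window must be a positive odd count")
  if (window == 1) return(s)
  ker <- rep(1 / window, window)
  sm <- function(y) {
    z <- as.numeric(stats::filter(y, ker, sides = 2))
    z[is.na(z)] <- y[is.na(z)]
    z
  }
  if (inherits(s, "raman_spectrum")) {
    s$intensity <- sm(s$intensity)
    add_history(s, "smooth_spectra", window = window)
  } else if (inherits(s, "spectrum_set")) {
    s$intensity <- t(apply(s$intensity, 1, sm))
    s$history <- c(s$history, sprintf("smooth_spectra(window=%d)", window))
    s
  } else stop("smooth_spectra expects a raman_spectrum or spectrum_set")
}

#' Band intensity within a window
#'
#' "Intensity" of a named band is its peak height: the maximum intensity
#' inside the window (inclusive endpoints). An integrated-area variant is
#' available via `type = "area"` (trapezoidal).
#'
#' @param s A [raman_spectrum()] or [spectrum_set()].
#' @param w A [band_window()].
#' @param type `"height"` (default) or `"area"`.
#' @return Scalar for a spectrum; vector (one value per row) for a set.
#' @export
band_intensity <- function(s, w, type = c("height", "area")) {
  type <- match.arg(type)
  stopifnot(inherits(w, "band_window"))
  ax <- s$wavenumber
  idx <- window_idx(ax, w$lo, w$hi)
  f <- function(y) {
    if (type == "height") max(y[idx]) else pracma::trapz(ax[idx], y[idx])
  }
  if (inherits(s, "raman_spectrum")) f(s$intensity)
  else if (inherits(s, "spectrum_set")) apply(s$intensity, 1, f)
  else stop("band_intensity expects a raman_spectrum or spectrum_set")
}

#' Normalise a spectrum to the peak intensity of a band
#'
#' Divides all intensities by the maximum intensity inside the window, so
#' that the band maximum becomes exactly 1. Idempotent and scale-invariant.
#'
#' @param s A [raman_spectrum()] or [spectrum_set()] (per-row).
#' @param w A [band_window()] (e.g. the phosphate nu1, lipid 1299 or
#'   carbonate window).
#' @return Normalised object of the same class.
#' @export
normalize_to_band <- function(s, w) UseMethod("normalize_to_band")

#' @export
normalize_to_band.raman_spectrum <- function(s, w) {
  stopifnot(inherits(w, "band_window"))
  idx <- window_idx(s$wavenumber, w$lo, w$hi)
  m <- max(s$intensity[idx])
  if (m <= 0) stop(sprintf("degenerate spectrum: max intensity in %g..%g is %g",
                           w$lo, w$hi, m))
  s$intensity <- s$intensity / m
  add_history(s, "normalize_to_band", window = c(w$lo, w$hi))
}

#' @export
normalize_to_band.spectrum_set <- function(s, w) {
  stopifnot(inherits(w, "band_window"))
  idx <- window_idx(s$wavenumber, w$lo, w$hi)
  m <- apply(s$intensity[, idx, drop = FALSE], 1, max)
  if (any(m <= 0)) {
    stop(sprintf("degenerate spectrum (row %d): non-positive max in window",
                 which(m <= 0)[1]))
  }
  s$intensity <- s$intensity / m
  s$history <- c(s$history, sprintf("normalize_to_band(window=%g;%g)", w$lo, w$hi))
  s
}

#' Drop spectra with weak mineral signal
#'
#' On lipid-normalised in vivo spectra the phosphate nu1 band loses its
#' shape and sinks into neighbouring envelopes below an intensity of about
#' 0.45; such spectra carry no usable bone signal. Spectra whose nu1 band
#' intensity is below `threshold` are removed (exactly-at-threshold is
#' kept). Subjects left with fewer than `min_keep` spectra are flagged, not
#' dropped.
#'
#' @param set A lipid-normalised [spectrum_set()].
#' @param threshold Minimum nu1 band intensity (default 0.45).
#' @param min_keep Minimum surviving spectra per subject before flagging
#'   (default 5).
#' @param window nu1 window (default 959--963 cm^-1).
#' @return The surviving subset, with a `filter_report` attribute: a data
#'   frame of per-subject input/surviving counts and an `under_min` flag.
#' @export
filter_weak_mineral <- function(set, threshold = 0.45, min_keep = 5,
                                window = band_window(959, 963)) {
  stopifnot(inherits(set, "spectrum_set"))
  if (nrow(set$intensity) == 0) return(set)
  nu1 <- band_intensity(set, window)
  keep <- nu1 >= threshold
  subj <- if ("subject" %in% names(set$meta)) as.character(set$meta$subject)
          else rep("all", length(keep))
  report <- do.call(rbind, lapply(split(seq_along(keep), subj), function(ii) {
    data.frame(subject = subj[ii[1]], n_in = length(ii),
               n_kept = sum(keep[ii]), stringsAsFactors = FALSE)
  }))
  report$under_min <- report$n_kept < min_keep
  rownames(report) <- NULL
  out <- spectrum_set(set$wavenumber, set$intensity[keep, , drop = FALSE],
                      meta = set$meta[keep, , drop = FALSE],
                      history = c(set$history,
                                  sprintf("filter_weak_mineral(threshold=%g, removed=%d)",
                                          threshold, sum(!keep))))
  attr(out, "filter_report") <- report
  out
}

#' Trim a spectrum to a union of windows
#'
#' Keeps only channels inside the given (non-overlapping, inclusive)
#' windows; used to restrict the analysis to the collagen + carbonate
#' region, and to drop the tissue-absorbed amide I region in vivo.
#'
#' @param s A [raman_spectrum()] or [spectrum_set()].
#' @param keep A [band_window()] or list of them.
#' @return Trimmed object of the same class; the axis keeps only the
#'   retained channels (it may become non-uniform across window gaps).
#' @export
trim_region <- function(s, keep) UseMethod("trim_region")

# internal: union of window indices, checking non-overlap
trim_idx <- function(axis, keep) {
  if (inherits(keep, "band_window")) keep <- list(keep)
  stopifnot(all(vapply(keep, inherits, TRUE, "band_window")))
  o <- order(vapply(keep, `[[`, 0, "lo"))
  keep <- keep[o]
  if (length(keep) > 1) {
    for (i in seq_len(length(keep) - 1)) {
      if (keep[[i]]$hi >= keep[[i + 1]]$lo) stop("keep windows must not overlap")
    }
  }
  idx <- sort(unique(unlist(lapply(keep, function(w)
    window_idx(axis, w$lo, w$hi)))))
  if (!length(idx)) stop("trim_region would leave no channels")
  idx
}

#' @export
trim_region.raman_spectrum <- function(s, keep) {
  idx <- trim_idx(s$wavenumber, keep)
  out <- s
  out$wavenumber <- as.numeric(s$wavenumber)[idx]
  out$intensity <- s$intensity[idx]
  add_history(out, "trim_region", channels = length(idx))
}

#' @export
trim_region.spectrum_set <- function(s, keep) {
  idx <- trim_idx(s$wavenumber, keep)
  out <- s
  out$wavenumber <- as.numeric(s$wavenumber)[idx]
  out$intensity <- s$intensity[, idx, drop = FALSE]
  out$history <- c(out$history, sprintf("trim_region(channels=%d)", length(idx)))
  out
}
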