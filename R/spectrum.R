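#' Construct a wavenumber axis
#'
#' Raman spectra in this package live on a shared, strictly increasing,
#' uniformly spaced wavenumber grid. The default 800--1800 cm^-1 grid at
#' 1 cm^-1 covers the phosphate nu1 (~960), carbonate (~1070), amide III
#' (~1250), lipid (1299), CH2 (~1450) and amide I (~1660) bands with margin
#' below nu1.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1).
#' @param step Grid spacing (cm^-1). Must not exceed the instrument
#'   resolution the data were collected at (~8 cm^-1 for the SORS detector
#'   this package targets).
#' @return Numeric vector of class `wavenumber_axis`.
#' @export
wavenumber_axis <- function(start = 800, stop = 1800, step = 1) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("axis limits and step must be numeric")
  }
  if (step <= 0) stop("axis step must be positive")
  if (stop <= start) stop("axis stop must exceed start")
  if (step > 8) stop("axis step exceeds the ~8 cm^-1 instrument resolution")
  ax <- seq(start, stop, by = step)
  structure(ax, class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber axis: %g..%g cm^-1, step %g, %d channels>\n",
              x[1], x[length(x)], x[2] - x[1], length(x)))
  invisible(x)
}

# internal: validate that a numeric vector is a usable axis. Strictly
# increasing is required everywhere; uniform spacing is enforced only at
# generation time (wavenumber_axis) since trimming can leave window gaps.
check_axis <- function(axis) {
  axis <- as.numeric(axis)
  if (length(axis) < 2) stop("axis must have at least 2 channels")
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  axis
}

#' Construct a single Raman spectrum
#'
#' @param axis Wavenumber axis (cm^-1), strictly increasing, uniform.
#' @param intensity Intensity vector, same length as `axis`, finite.
#' @param meta Named list of metadata (subject, cohort, site, accumulation,
#'   true_ratio, ...). Free-form; the pipeline reads `subject` and `cohort`.
#' @param history Character vector of processing-history lines.
#' @return Object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(axis, intensity, meta = list(), history = character()) {
  axis <- check_axis(axis)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(axis)) {
    stop("intensity length (", length(intensity),
         ") does not match axis length (", length(axis), ")")
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(list(wavenumber = axis, intensity = intensity,
                 meta = meta, history = history),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d channels, %g..%g cm^-1>\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (length(x$meta)) {
    keep <- intersect(c("subject", "cohort", "site", "accumulation",
                        "true_ratio"), names(x$meta))
    if (length(keep)) {
      cat("  meta: ",
          paste(sprintf("%s=%s", keep, vapply(x$meta[keep], format, "")),
                collapse = ", "), "\n", sep = "")
    }
  }
  if (length(x$history)) {
    cat("  history:\n")
    for (h in x$history) cat("    - ", h, "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ..., xlab = expression(Wavenumber~(cm^-1)),
                                ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# internal: append a history line "op(param=value, ...)"
add_history <- function(s, op, ...) {
  pars <- list(...)
  line <- if (length(pars)) {
    sprintf("%s(%s)", op,
            paste(sprintf("%s=%s", names(pars),
                          vapply(pars, function(p) paste(format(p), collapse = ";"), "")),
                  collapse = ", "))
  } else {
    sprintf("%s()", op)
  }
  s$history <- c(s$history, line)
  s
}

#' Construct a set of spectra on a common axis
#'
#' A `spectrum_set` stores an m-spectra-by-n-channel intensity matrix plus a
#' metadata data frame with one row per spectrum. It is the unit all matrix
#' operations (SVD, PCA, despiking) act on.
#'
#' @param axis Common wavenumber axis.
#' @param intensity m x n numeric matrix (rows = spectra).
#' @param meta Data frame with m rows; columns such as `subject`, `cohort`,
#'   `site`, `accumulation`, `true_ratio`.
#' @param history Character vector of set-level processing history.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, intensity, meta = NULL, history = character()) {
  axis <- check_axis(axis)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(axis)) {
    stop("intensity matrix must have one column per axis channel")
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(nrow(intensity)))
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(intensity)) {
    stop("meta must have one row per spectrum")
  }
  structure(list(wavenumber = axis, intensity = intensity,
                 meta = meta, history = history),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra x %d channels, %g..%g cm^-1>\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$wavenumber), max(x$wavenumber)))
  if ("cohort" %in% names(x$meta)) {
    tb <- table(x$meta$cohort)
    cat("  cohorts: ",
        paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$history)) cat("  history: ", paste(x$history, collapse = " | "),
                             "\n", sep = "")
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) nrow(x$intensity)

#' Extract one spectrum from a set
#'
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @return A `raman_spectrum` carrying the corresponding metadata row.
#' @export
set_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"))
  if (i < 1 || i > nrow(set$intensity)) stop("spectrum index out of range")
  raman_spectrum(set$wavenumber, set$intensity[i, ],
                 meta = as.list(set$meta[i, , drop = FALSE]),
                 history = set$history)
}

#' Bind spectra sharing one axis into a set
#'
#' @param spectra List of `raman_spectrum` objects on an identical axis.
#' @return A `spectrum_set`; scalar metadata fields become columns.
#' @export
bind_spectra <- function(spectra) {
  if (!length(spectra)) stop("no spectra to bind")
  ax <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (!isTRUE(all.equal(as.numeric(s$wavenumber), as.numeric(ax)))) {
      stop("all spectra must share one wavenumber axis")
    }
  }
  mat <- do.call(rbind, lapply(spectra, function(s) s$intensity))
  keys <- unique(unlist(lapply(spectra, function(s) names(s$meta))))
  keys <- keys[vapply(keys, function(k)
    all(vapply(spectra, function(s) length(s$meta[[k]]) <= 1, TRUE)), TRUE)]
  meta <- as.data.frame(lapply(keys, function(k) {
    vals <- lapply(spectra, function(s) {
      v <- s$meta[[k]]
      if (is.null(v) || !length(v)) NA else v
    })
    unlist(vals)
  }), col.names = keys, optional = TRUE, stringsAsFactors = FALSE)
  if (length(keys)) names(meta) <- keys
  spectrum_set(ax, mat, meta = meta)
}

# internal: indices of channels inside [lo, hi], endpoints inclusive
window_idx <- function(axis, lo, hi) {
  if (lo >= hi) stop("band window must have lo < hi")
  if (lo < min(axis) - 1e-9 || hi > max(axis) + 1e-9) {
    stop(sprintf("band window %g..%g cm^-1 lies outside the %g..%g axis",
                 lo, hi, min(axis), max(axis)))
  }
  which(axis >= lo - 1e-9 & axis <= hi + 1e-9)
}

#' Define a wavenumber band window
#'
#' Endpoints are inclusive: a channel at exactly `lo` or `hi` belongs to the
#' window.
#'
#' @param lo,hi Window limits in cm^-1, `lo < hi`.
#' @return Object of class `band_window`.
#' @export
band_window <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop("band window requires numeric lo < hi")
  }
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band window %g..%g cm^-1>\n", x$lo, x$hi))
  invisible(x)
}
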