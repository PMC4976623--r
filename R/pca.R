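# PCA collagen scoring. After carbonate normalisation the dominant
# variance in trimmed bone spectra is the amount of collagen signal
# relative to the mineral reference, so the first principal loading acts
# as a collagen axis: the projection of each centered spectrum onto it is
# its "collagen score" (higher score = more collagen = lower
# mineral-to-collagen ratio).

#' Fit a PCA collagen-scoring model
#'
#' Mean-centered SVD of the spectrum matrix, without variance scaling
#' (channels share units after carbonate normalisation). Loadings are
#' deterministically signed: the first is oriented to have positive mean
#' over the 1200--1300 cm^-1 amide III collagen window (so larger scores
#' mean more collagen), the others so their largest-magnitude element is
#' positive.
#'
#' @param set A trimmed, carbonate-normalised [spectrum_set()] with >= 2
#'   spectra.
#' @param collagen_window Window used to orient the first loading.
#' @return Object of class `collagen_pca`: `mean_spectrum`, orthonormal
#'   `loadings` (n x r), `explained_variance` (non-increasing), the axis,
#'   and a `scores` table for the training spectra.
#' @export
fit_collagen_pca <- function(set, collagen_window = band_window(1200, 1300)) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- set$intensity
  if (nrow(X) < 2) stop("PCA needs at least 2 spectra")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  r <- min(nrow(X) - 1, ncol(X))
  V <- sv$v[, seq_len(r), drop = FALSE]
  d <- sv$d[seq_len(r)]
  # orientation: collagen-positive first loading, then a deterministic
  # largest-element convention for the rest
  cw <- intersect(window_idx(set$wavenumber, collagen_window$lo,
                             collagen_window$hi), seq_len(ncol(X)))
  flip <- numeric(r)
  flip[1] <- if (mean(V[cw, 1]) < 0) -1 else 1
  if (r > 1) {
    for (j in 2:r) flip[j] <- if (V[which.max(abs(V[, j])), j] < 0) -1 else 1
  }
  V <- sweep(V, 2, flip, `*`)
  U <- sweep(sv$u[, seq_len(r), drop = FALSE], 2, flip, `*`)
  scores_mat <- sweep(U, 2, d, `*`)
  expl_var <- d^2 / (nrow(X) - 1)
  scores <- data.frame(
    spectrum = seq_len(nrow(X)),
    subject = if ("subject" %in% names(set$meta))
      as.character(set$meta$subject) else as.character(seq_len(nrow(X))),
    cohort = if ("cohort" %in% names(set$meta))
      as.character(set$meta$cohort) else NA_character_,
    collagen_score = scores_mat[, 1],
    stringsAsFactors = FALSE)
  structure(list(wavenumber = set$wavenumber, mean_spectrum = mu,
                 loadings = V, explained_variance = expl_var,
                 scores = scores, score_matrix = scores_mat,
                 collagen_window = collagen_window,
                 history = set$history),
            class = "collagen_pca")
}

#' @export
print.collagen_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<collagen_pca: %d spectra x %d channels, %d components>\n",
              nrow(x$score_matrix), length(x$mean_spectrum),
              ncol(x$loadings)))
  cat(sprintf("  PC1 (collagen axis) explains %.1f%% of variance\n", pct[1]))
  invisible(x)
}

#' @export
summary.collagen_pca <- function(object, ...) {
  pct <- 100 * object$explained_variance / sum(object$explained_variance)
  tab <- data.frame(component = seq_along(pct),
                    variance = object$explained_variance,
                    percent = pct, cumulative = cumsum(pct))
  out <- list(components = utils::head(tab, 8),
              by_cohort = if (!all(is.na(object$scores$cohort)))
                stats::aggregate(collagen_score ~ cohort, object$scores,
                                 function(v) c(mean = mean(v), sd = stats::sd(v)))
              else NULL)
  class(out) <- "summary.collagen_pca"
  out
}

#' @export
print.summary.collagen_pca <- function(x, ...) {
  cat("PCA collagen model\n\nExplained variance:\n")
  print(x$components, row.names = FALSE, digits = 4)
  if (!is.null(x$by_cohort)) {
    cat("\nCollagen score by cohort:\n")
    print(x$by_cohort, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.collagen_pca <- function(x, ...) {
  graphics::plot(x$wavenumber, x$loadings[, 1], type = "l",
                 xlab = expression(Wavenumber~(cm^-1)),
                 ylab = "PC1 loading",
                 main = "Collagen loading (PC1)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
coef.collagen_pca <- function(object, ...) object$loadings

#' Collagen score of a spectrum under a fitted model
#'
#' The inner product of the centered spectrum with the first loading.
#'
#' @param model A [fit_collagen_pca()] model.
#' @param s A [raman_spectrum()] on the model's (trimmed) axis.
#' @return Scalar score.
#' @export
collagen_score <- function(model, s) {
  stopifnot(inherits(model, "collagen_pca"), inherits(s, "raman_spectrum"))
  if (!isTRUE(all.equal(as.numeric(s$wavenumber),
                        as.numeric(model$wavenumber)))) {
    stop("spectrum axis does not match the model's trimmed axis")
  }
  drop((s$intensity - model$mean_spectrum) %*% model$loadings[, 1])
}

#' @export
predict.collagen_pca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  if (inherits(newdata, "raman_spectrum")) {
    return(collagen_score(object, newdata))
  }
  stopifnot(inherits(newdata, "spectrum_set"))
  if (!isTRUE(all.equal(as.numeric(newdata$wavenumber),
                        as.numeric(object$wavenumber)))) {
    stop("spectrum axes do not match the model's trimmed axis")
  }
  Xc <- sweep(newdata$intensity, 2, object$mean_spectrum)
  data.frame(
    spectrum = seq_len(nrow(Xc)),
    subject = if ("subject" %in% names(newdata$meta))
      as.character(newdata$meta$subject) else as.character(seq_len(nrow(Xc))),
    cohort = if ("cohort" %in% names(newdata$meta))
      as.character(newdata$meta$cohort) else NA_character_,
    collagen_score = drop(Xc %*% object$loadings[, 1]),
    stringsAsFactors = FALSE)
}

#' Average collagen scores per subject
#'
#' Bone is heterogeneous on the millimetre scale, so single-point scores
#' scatter widely within a subject; averaging them collapses the
#' within-subject variance and leaves the subject-level signal.
#'
#' @param scores Score table (`subject`, `cohort`, `collagen_score`).
#' @return One row per subject with the mean score; cohort preserved.
#'   A subject spanning two cohort labels is an error.
#' @export
average_by_subject <- function(scores) {
  if (!nrow(scores)) stop("empty score table")
  sp <- split(scores, scores$subject)
  rows <- lapply(sp, function(d) {
    if (length(unique(d$cohort)) > 1) {
      stop("subject ", d$subject[1], " appears in more than one cohort")
    }
    data.frame(subject = d$subject[1], cohort = d$cohort[1],
               n_spectra = nrow(d),
               collagen_score = mean(d$collagen_score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconstruct a cohort's mean spectrum from the PCA model
#'
#' `mean_spectrum + mean(cohort scores) * loading_1`: the rank-1
#' reconstruction of the group average along the collagen axis, used to
#' visualise and quantify the mineralisation difference between cohorts.
#'
#' @param model A [fit_collagen_pca()] model.
#' @param scores Score table containing the cohort.
#' @param cohort Cohort label.
#' @return A [raman_spectrum()] on the model's trimmed axis.
#' @export
reconstruct_group_mean <- function(model, scores, cohort) {
  stopifnot(inherits(model, "collagen_pca"))
  rows <- scores$cohort == cohort
  if (!any(rows)) stop("cohort '", cohort, "' not present in the score table")
  s_bar <- mean(scores$collagen_score[rows])
  y <- model$mean_spectrum + s_bar * model$loadings[, 1]
  raman_spectrum(model$wavenumber, y,
                 meta = list(cohort = cohort, mean_score = s_bar),
                 history = sprintf("reconstruct_group_mean(cohort=%s)", cohort))
}

#' Percent mineralisation difference between two spectra
#'
#' For carbonate-normalised spectra the mineral-to-collagen ratio is
#' proportional to `carbonate peak / integrated collagen-region intensity`,
#' so the percent difference of spectrum `a` relative to `b` reduces to
#' `100 * (int_b / int_a - 1)` where `int` is the trapezoidal integral over
#' the collagen region. The carbonate reference window is excluded from the
#' integrand: the carbonate band sits inside the nominal collagen region
#' but is mineral signal, and leaving it in dilutes the collagen contrast.
#' The result depends on the chosen collagen window (different band
#' subsets give a 5--10% spread on real bone), so the window is an
#' explicit argument.
#'
#' @param a,b Carbonate-normalised [raman_spectrum()]s on one axis
#'   (conventionally `a` = diseased/fractured, `b` = control).
#' @param collagen_region Integration window (default 988--1800 cm^-1).
#' @param carbonate_window Carbonate reference window (default 1050--1090),
#'   notched out of the collagen integral.
#' @return Percent difference: positive when `a` is more mineralised.
#' @export
percent_mineralization_difference <- function(a, b,
                                              collagen_region = band_window(988, 1800),
                                              carbonate_window = band_window(1050, 1090)) {
  stopifnot(inherits(a, "raman_spectrum"), inherits(b, "raman_spectrum"))
  if (!isTRUE(all.equal(as.numeric(a$wavenumber), as.numeric(b$wavenumber)))) {
    stop("spectra are on different axes")
  }
  ratio_of <- function(s) {
    carb <- band_intensity(s, carbonate_window)
    idx <- window_idx(s$wavenumber, collagen_region$lo, collagen_region$hi)
    w <- s$wavenumber[idx]
    keep <- w < carbonate_window$lo | w > carbonate_window$hi
    coll <- pracma::trapz(w[keep], s$intensity[idx][keep])
    if (coll == 0) stop("zero integrated collagen intensity")
    carb / coll
  }
  100 * (ratio_of(a) / ratio_of(b) - 1)
}

#' Univariate band ratio
#'
#' Peak-height ratio of two band windows, the classical univariate
#' mineral-to-collagen measure. Sensitive to which bands are picked --
#' the multivariate collagen score is preferred for inference.
#'
#' @param s A [raman_spectrum()].
#' @param numerator,denominator [band_window()]s.
#' @return Scalar ratio.
#' @export
band_ratio <- function(s, numerator, denominator) {
  den <- band_intensity(s, denominator)
  if (den == 0) stop("zero denominator band intensity")
  band_intensity(s, numerator) / den
}
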