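# Synthetic bone Raman / SORS data with known ground truth.
#
# The generator emulates the two kinds of data the analysis pipeline is
# designed for: (a) excised cortical-bone Raman spectra -- mineral and
# collagen bands on a broad fluorescence baseline with detector noise, and
# millimetre-scale within-subject heterogeneity plus between-subject
# variation of the mineral-to-collagen ratio; (b) transcutaneous SORS
# measurements -- the same bone signal mixed with a soft-tissue (lipid +
# skin) component, attenuated in the amide I region, on stronger baselines,
# recorded as repeated 1-s accumulations with cosmic-ray spikes.

# internal: run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1) stop("seed must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Define a Raman band
#'
#' Bands are pseudo-Voigt by default: a height-normalised mix of a Gaussian
#' and a Lorentzian sharing one FWHM. `mix = 0` is pure Gaussian, `mix = 1`
#' pure Lorentzian.
#'
#' @param center Band centre (cm^-1).
#' @param width Full width at half maximum (cm^-1), > 0.
#' @param height Peak height (arbitrary intensity), >= 0.
#' @param shape `"pseudo-voigt"`, `"gaussian"` or `"lorentzian"`.
#' @param mix Lorentzian fraction in `[0, 1]` for pseudo-Voigt (default 0.5).
#' @return Object of class `raman_band`.
#' @export
band <- function(center, width, height, shape = c("pseudo-voigt", "gaussian",
                                                  "lorentzian"), mix = 0.5) {
  shape <- match.arg(shape)
  if (width <= 0) stop("band width must be > 0")
  if (height < 0) stop("band height must be >= 0")
  if (mix < 0 || mix > 1) stop("pseudo-Voigt mixing fraction must be in [0, 1]")
  if (shape == "gaussian") mix <- 0
  if (shape == "lorentzian") mix <- 1
  structure(list(center = center, width = width, height = height,
                 shape = shape, mix = mix), class = "raman_band")
}

# internal: evaluate one band on an axis (unit height before scaling)
eval_band <- function(b, axis) {
  d2 <- (axis - b$center)^2
  g <- exp(-4 * log(2) * d2 / b$width^2)
  l <- 1 / (1 + 4 * d2 / b$width^2)
  b$height * ((1 - b$mix) * g + b$mix * l)
}

#' Default pure-component band table
#'
#' Band positions follow standard bone/soft-tissue Raman assignments:
#' phosphate nu1 at 960 cm^-1 and carbonate at 1070 cm^-1 for bone mineral;
#' proline/hydroxyproline (855/875), amide III (~1250), CH2 wag (~1450) and
#' amide I (~1660) for collagen; lipid CH2 twist at 1299 and CH2 bend at
#' 1440 cm^-1; broad generic protein/lipid envelopes for the skin matrix.
#' Heights are relative within each component; components are unit-max
#' normalised by [make_component_library()].
#'
#' @return Named list of lists of [band()] objects.
#' @export
default_band_table <- function() {
  list(
    bone_mineral = list(
      band(960, 15, 1.00),
      band(1070, 15, 0.20)
    ),
    collagen = list(
      band(855, 18, 0.30),
      band(875, 18, 0.30),
      band(1250, 30, 0.50),
      band(1450, 22, 0.70),
      band(1660, 40, 1.00)
    ),
    lipid = list(
      band(1299, 20, 1.00),
      band(1440, 25, 0.90)
    ),
    skin_matrix = list(
      band(1004, 12, 0.30),
      band(1270, 60, 0.60),
      band(1450, 50, 0.80),
      band(1650, 70, 1.00)
    )
  )
}

#' Build a pure-component spectral library
#'
#' Each component is the sum of its bands evaluated on the axis, rescaled to
#' unit maximum. All components are non-negative.
#'
#' @param axis Wavenumber axis from [wavenumber_axis()].
#' @param band_table Named list of lists of [band()]s; default
#'   [default_band_table()].
#' @return Object of class `component_library`: the axis plus an
#'   n-channel x k-component matrix.
#' @export
make_component_library <- function(axis = wavenumber_axis(),
                                   band_table = default_band_table()) {
  axis <- check_axis(axis)
  if (!length(band_table) || is.null(names(band_table))) {
    stop("band_table must be a named list of components")
  }
  comps <- vapply(names(band_table), function(nm) {
    bands <- band_table[[nm]]
    if (!length(bands)) stop("component '", nm, "' has an empty band list")
    for (b in bands) {
      if (b$center < min(axis) || b$center > max(axis)) {
        stop(sprintf("band at %g cm^-1 in component '%s' lies outside the axis",
                     b$center, nm))
      }
    }
    y <- Reduce(`+`, lapply(bands, eval_band, axis = axis))
    y / max(y)
  }, numeric(length(axis)))
  structure(list(wavenumber = axis, components = comps,
                 band_table = band_table),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library: %s on %d channels>\n",
              paste(colnames(x$components), collapse = ", "),
              length(x$wavenumber)))
  invisible(x)
}

# internal: random positive fluorescence baseline on the axis.
# Polynomial with N(0, scale/(k+1)) coefficients in the scaled coordinate
# u in [-1, 1], shifted so its minimum over the axis is zero.
random_baseline <- function(axis, order, scale) {
  if (scale <= 0) return(numeric(length(axis)))
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  coef <- stats::rnorm(order + 1, sd = scale / seq_len(order + 1))
  b <- drop(outer(u, 0:order, `^`) %*% coef)
  b - min(b)
}

#' Generate one noiseless-or-noisy bone spectrum
#'
#' Intensity model: `ratio * bone_mineral + collagen + baseline + noise`.
#' The mineral-to-collagen ratio is a single scale factor on the mineral
#' component; the true value is recorded in the metadata.
#'
#' @param lib A [make_component_library()] library containing `bone_mineral`
#'   and `collagen`.
#' @param ratio Mineral-to-collagen scale factor, > 0.
#' @param baseline Numeric vector of polynomial coefficients (constant
#'   first, in the `[-1, 1]`-scaled axis coordinate), or a precomputed
#'   baseline vector of axis length. Default: no baseline.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param seed Optional seed for the noise draw.
#' @param meta Extra metadata fields.
#' @return A [raman_spectrum()] with `true_ratio` in its metadata.
#' @export
generate_bone_spectrum <- function(lib, ratio, baseline = 0, noise_sd = 0,
                                   seed = NULL, meta = list()) {
  stopifnot(inherits(lib, "component_library"))
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be > 0")
  axis <- lib$wavenumber
  base <- if (length(baseline) == length(axis)) {
    as.numeric(baseline)
  } else {
    u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
    drop(outer(u, seq_along(baseline) - 1, `^`) %*% baseline)
  }
  y <- ratio * lib$components[, "bone_mineral"] + lib$components[, "collagen"] +
    base
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(length(axis), sd = noise_sd) else 0)
  raman_spectrum(axis, y,
                 meta = c(list(true_ratio = ratio), meta),
                 history = sprintf("generate_bone_spectrum(ratio=%g, noise_sd=%g)",
                                   ratio, noise_sd))
}

#' Specify a synthetic cohort
#'
#' The generative model: subject i draws a true ratio
#' `ratio_i ~ N(mean_ratio, between_subject_sd)`; each of its spectra draws
#' `ratio_ij ~ N(ratio_i, within_subject_sd)` (millimetre-scale
#' heterogeneity across probing sites). Negative draws are truncated at
#' `1e-3 * mean_ratio` so cohort sizes stay exact.
#'
#' Default variances are chosen to reproduce the qualitative structure seen
#' in excised femoral-neck studies: heavily overlapped per-spectrum score
#' distributions between cohorts a few percent apart in mean ratio, with
#' the within-subject scatter collapsing upon per-subject averaging.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param spectra_per_subject Spectra per subject, >= 1.
#' @param mean_ratio Cohort mean mineral-to-collagen scale factor.
#' @param between_subject_sd Between-subject sd of the true ratio.
#' @param within_subject_sd Within-subject (site-to-site) sd.
#' @param baseline_order Order of the random fluorescence polynomial.
#' @param baseline_scale Scale of baseline coefficients (intensity units;
#'   the nu1 band of a ratio-1 spectrum has height 1).
#' @param noise_sd Detector noise sd.
#' @param cohort Cohort label stored in metadata.
#' @param seed Seed making the cohort reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, spectra_per_subject = 15,
                        mean_ratio = 1, between_subject_sd = 0.02,
                        within_subject_sd = 0.05, baseline_order = 5,
                        baseline_scale = 1, noise_sd = 0.01,
                        cohort = "cohort", seed = NULL) {
  if (n_subjects < 1 || spectra_per_subject < 1) {
    stop("n_subjects and spectra_per_subject must be >= 1")
  }
  if (between_subject_sd < 0 || within_subject_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (mean_ratio <= 0) stop("mean_ratio must be > 0")
  structure(list(n_subjects = n_subjects,
                 spectra_per_subject = spectra_per_subject,
                 mean_ratio = mean_ratio,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 baseline_order = baseline_order,
                 baseline_scale = baseline_scale,
                 noise_sd = noise_sd, cohort = cohort, seed = seed),
            class = "cohort_spec")
}

#' Generate a cohort of excised-bone spectra
#'
#' @param lib Component library.
#' @param spec A [cohort_spec()].
#' @return A [spectrum_set()] of `n_subjects * spectra_per_subject` spectra;
#'   metadata columns `subject`, `cohort`, `site`, `true_subject_ratio`,
#'   `true_ratio`. Identical seeds give bit-identical output.
#' @export
generate_cohort <- function(lib, spec) {
  stopifnot(inherits(lib, "component_library"), inherits(spec, "cohort_spec"))
  axis <- lib$wavenumber
  floor_ratio <- 1e-3 * spec$mean_ratio
  with_seed(spec$seed, {
    subj_ratio <- stats::rnorm(spec$n_subjects, spec$mean_ratio,
                               spec$between_subject_sd)
    subj_ratio <- pmax(subj_ratio, floor_ratio)
    n <- spec$n_subjects * spec$spectra_per_subject
    mat <- matrix(0, n, length(axis))
    meta <- data.frame(subject = character(n), cohort = spec$cohort,
                       site = integer(n), true_subject_ratio = 0,
                       true_ratio = 0, stringsAsFactors = FALSE)
    row <- 0L
    for (i in seq_len(spec$n_subjects)) {
      for (j in seq_len(spec$spectra_per_subject)) {
        row <- row + 1L
        r <- max(stats::rnorm(1, subj_ratio[i], spec$within_subject_sd),
                 floor_ratio)
        base <- random_baseline(axis, spec$baseline_order, spec$baseline_scale)
        y <- r * lib$components[, "bone_mineral"] +
          lib$components[, "collagen"] + base
        if (spec$noise_sd > 0) y <- y + stats::rnorm(length(axis), sd = spec$noise_sd)
        mat[row, ] <- y
        meta$subject[row] <- sprintf("%s_%02d", spec$cohort, i)
        meta$site[row] <- j
        meta$true_subject_ratio[row] <- subj_ratio[i]
        meta$true_ratio[row] <- r
      }
    }
    spectrum_set(axis, mat, meta = meta,
                 history = sprintf("generate_cohort(cohort=%s, seed=%s)",
                                   spec$cohort, format(spec$seed)))
  })
}

#' Specify an in vivo SORS measurement
#'
#' @param soft_tissue_weight Fraction of the signal from the lipid + skin
#'   overlayer, in `[0, 1]`.
#' @param amide_I_attenuation Multiplicative attenuation applied to the bone
#'   signal above 1540 cm^-1, in `[0, 1]`; models the wavelength-dependent
#'   tissue absorption that degrades the amide I region for long-path SORS
#'   photons.
#' @param n_accumulations Number of repeated short accumulations (default
#'   60, i.e. 60 x 1 s).
#' @param spike_rate Expected cosmic-ray events per accumulation (Poisson).
#' @param spike_height Intensity added at each spiked channel.
#' @param baseline_order,baseline_scale Per-accumulation fluorescence
#'   baseline (stronger than for excised bone).
#' @param noise_sd Detector noise sd per 1-s accumulation.
#' @return Object of class `sors_config`.
#' @export
sors_config <- function(soft_tissue_weight = 0.5, amide_I_attenuation = 0.5,
                        n_accumulations = 60, spike_rate = 0.1,
                        spike_height = 50, baseline_order = 5,
                        baseline_scale = 2, noise_sd = 0.05) {
  if (soft_tissue_weight < 0 || soft_tissue_weight > 1) {
    stop("soft_tissue_weight must be in [0, 1]")
  }
  if (amide_I_attenuation < 0 || amide_I_attenuation > 1) {
    stop("amide_I_attenuation must be in [0, 1]")
  }
  if (n_accumulations < 1) stop("n_accumulations must be >= 1")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  structure(list(soft_tissue_weight = soft_tissue_weight,
                 amide_I_attenuation = amide_I_attenuation,
                 n_accumulations = n_accumulations, spike_rate = spike_rate,
                 spike_height = spike_height, baseline_order = baseline_order,
                 baseline_scale = baseline_scale, noise_sd = noise_sd),
            class = "sors_config")
}

#' Generate one SORS measurement (a stack of accumulations)
#'
#' Each accumulation is
#' `(1 - w) * bone_attenuated + w * (lipid + skin_matrix) + baseline +
#' noise + spikes`, where `bone_attenuated` multiplies the bone intensity
#' above 1540 cm^-1 by `amide_I_attenuation`, and spikes are single-channel
#' additive deltas with Poisson counts per accumulation. The fluorescence
#' baseline is drawn once per measurement and shared by all its
#' accumulations: it originates in the static tissue under the probe, so
#' successive 1-s frames see the same background while noise and spikes
#' vary frame to frame.
#'
#' @param bone A [raman_spectrum()] on the library axis (the subject's true
#'   bone spectrum).
#' @param lib Component library containing `lipid` and `skin_matrix`.
#' @param cfg A [sors_config()].
#' @param seed Optional seed.
#' @return A [spectrum_set()] with one row per accumulation; metadata carry
#'   the accumulation index, true ratio and soft-tissue weight.
#' @export
generate_sors_measurement <- function(bone, lib, cfg = sors_config(),
                                      seed = NULL) {
  stopifnot(inherits(bone, "raman_spectrum"), inherits(lib, "component_library"),
            inherits(cfg, "sors_config"))
  axis <- lib$wavenumber
  if (!isTRUE(all.equal(as.numeric(bone$wavenumber), as.numeric(axis)))) {
    stop("bone spectrum and library are on different axes")
  }
  bone_att <- bone$intensity
  hi <- axis > 1540
  bone_att[hi] <- bone_att[hi] * cfg$amide_I_attenuation
  soft <- lib$components[, "lipid"] + lib$components[, "skin_matrix"]
  w <- cfg$soft_tissue_weight
  clean <- (1 - w) * bone_att + w * soft
  nchan <- length(axis)
  with_seed(seed, {
    mat <- matrix(0, cfg$n_accumulations, nchan)
    spikes_total <- 0L
    base <- random_baseline(axis, cfg$baseline_order, cfg$baseline_scale)
    for (a in seq_len(cfg$n_accumulations)) {
      y <- clean + base
      if (cfg$noise_sd > 0) y <- y + stats::rnorm(nchan, sd = cfg$noise_sd)
      k <- stats::rpois(1, cfg$spike_rate)
      if (k > 0) {
        ch <- sample.int(nchan, min(k, nchan))
        y[ch] <- y[ch] + cfg$spike_height
        spikes_total <- spikes_total + length(ch)
      }
      mat[a, ] <- y
    }
    meta <- data.frame(
      subject = if (is.null(bone$meta$subject)) NA else bone$meta$subject,
      cohort = if (is.null(bone$meta$cohort)) NA else bone$meta$cohort,
      accumulation = seq_len(cfg$n_accumulations),
      true_ratio = if (is.null(bone$meta$true_ratio)) NA else bone$meta$true_ratio,
      soft_tissue_weight = w, stringsAsFactors = FALSE)
    spectrum_set(axis, mat, meta = meta,
                 history = sprintf(
                   "generate_sors_measurement(w=%g, atten=%g, n_acc=%d, spikes=%d)",
                   w, cfg$amide_I_attenuation, cfg$n_accumulations, spikes_total))
  })
}
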