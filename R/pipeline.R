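# End-to-end pipeline driver. Two presets mirror the two kinds of study
# the package supports:
#
#   excised: background -> nu1-normalise -> trim (987-1800) ->
#            carbonate-normalise -> PCA scoring -> diagnostics
#   invivo:  despike -> background -> lipid-normalise -> weak-mineral
#            filter -> per-subject BTEM -> trim (987-1540, dropping the
#            tissue-absorbed amide I region) -> carbonate-normalise ->
#            PCA scoring -> diagnostics

#' Pipeline configuration
#'
#' Collects every stage parameter with preset-dependent defaults; any field
#' can be overridden by name.
#'
#' @param preset `"excised"` or `"invivo"`.
#' @param ... Named overrides of the fields listed below.
#' @return Object of class `pipeline_config` with fields:
#'   `background_order`, `background_max_iter`, `background_tol`,
#'   `nu1_window`, `lipid_window`, `carbonate_window`, `trim`,
#'   `collagen_region`, `filter_threshold`, `filter_min_keep`,
#'   `btem_z`, `btem_target`, `btem_gamma`, `btem_restarts`,
#'   `specificity`, `alpha`, `power`, `seed`.
#' @export
pipeline_config <- function(preset = c("excised", "invivo"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    background_order = 5, background_max_iter = 100, background_tol = 1e-4,
    nu1_window = band_window(950, 970),
    lipid_window = band_window(1289, 1309),
    carbonate_window = band_window(1050, 1090),
    trim = if (preset == "excised") band_window(987, 1800)
           else band_window(987, 1540),
    collagen_region = if (preset == "excised") band_window(988, 1800)
                      else band_window(988, 1540),
    filter_threshold = 0.45, filter_min_keep = 5,
    btem_z = 5, btem_target = band_window(959, 963),
    btem_gamma = 1e4, btem_restarts = 8,
    specificity = 0.90, alpha = 0.05, power = 0.80,
    seed = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config: preset '%s', trim %g..%g cm^-1, seed %s>\n",
              x$preset, x$trim$lo, x$trim$hi, format(x$seed)))
  invisible(x)
}

# internal: pick diseased/control labels from a two-cohort score table
resolve_labels <- function(scores, diseased, control) {
  cohorts <- unique(as.character(scores$cohort))
  if (length(cohorts) != 2) stop("pipeline needs exactly two cohorts")
  if (is.null(diseased)) {
    means <- vapply(split(scores$collagen_score, scores$cohort), mean, 0)
    diseased <- names(which.min(means))
  }
  if (is.null(control)) control <- setdiff(cohorts, diseased)
  if (!all(c(diseased, control) %in% cohorts)) {
    stop("diseased/control labels not found among cohorts: ",
         paste(cohorts, collapse = ", "))
  }
  list(diseased = diseased, control = control)
}

#' Run the full analysis pipeline
#'
#' @param data For the excised preset, a [spectrum_set()] of raw spectra
#'   with `subject` and `cohort` metadata. For the invivo preset, a list of
#'   [spectrum_set()]s, one accumulation stack per SORS measurement.
#' @param config A [pipeline_config()]; its preset selects the stage order.
#' @param diseased,control Optional cohort labels; if omitted the diseased
#'   group is inferred as the cohort with the lower mean collagen score.
#' @return Object of class `pipeline_result`: the per-spectrum and
#'   per-subject score tables, the fitted [fit_collagen_pca()] model, the
#'   [diagnostic_summary()], reconstructed group-mean spectra, the percent
#'   mineralisation difference (diseased vs control), and preset-specific
#'   intermediates (weak-mineral filter report, per-subject BTEM results).
#'   Deterministic given `config$seed`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), diseased = NULL,
                         control = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$preset == "excised") {
    run_pipeline_excised(data, config, diseased, control)
  } else {
    run_pipeline_invivo(data, config, diseased, control)
  }
}

run_pipeline_excised <- function(set, config, diseased, control) {
  stopifnot(inherits(set, "spectrum_set"))
  set <- remove_background(set, order = config$background_order,
                           max_iter = config$background_max_iter,
                           tol = config$background_tol)
  set <- normalize_to_band(set, config$nu1_window)
  trimmed <- trim_region(set, config$trim)
  trimmed <- normalize_to_band(trimmed, config$carbonate_window)
  model <- fit_collagen_pca(trimmed)
  scores <- model$scores
  finish_pipeline(model, scores, trimmed, config, diseased, control,
                  extras = list(
                    preprocessed = set,
                    p_value_per_spectrum = {
                      lb <- resolve_labels(scores, diseased, control)
                      two_group_test(
                        scores$collagen_score[scores$cohort == lb$diseased],
                        scores$collagen_score[scores$cohort == lb$control])
                    }))
}

run_pipeline_invivo <- function(measurements, config, diseased, control) {
  if (inherits(measurements, "spectrum_set")) {
    measurements <- list(measurements)
  }
  stopifnot(all(vapply(measurements, inherits, TRUE, "spectrum_set")))
  despiked <- lapply(measurements, despike)
  set <- bind_spectra(despiked)
  set <- remove_background(set, order = config$background_order,
                           max_iter = config$background_max_iter,
                           tol = config$background_tol)
  set <- normalize_to_band(set, config$lipid_window)
  set <- filter_weak_mineral(set, threshold = config$filter_threshold,
                             min_keep = config$filter_min_keep)
  filter_report <- attr(set, "filter_report")
  btem <- btem_per_subject(set, z = config$btem_z,
                           target = config$btem_target,
                           gamma = config$btem_gamma,
                           restarts = config$btem_restarts,
                           seed = config$seed)
  if (length(btem) < 2) stop("fewer than 2 subjects survived BTEM")
  estimates <- bind_spectra(lapply(btem, `[[`, "estimate"))
  # the entropy objective is insensitive to smooth positive offsets, so a
  # final background correction of each estimate removes the baseline-like
  # residue it tolerates
  estimates <- remove_background(estimates, order = config$background_order,
                                 max_iter = config$background_max_iter,
                                 tol = config$background_tol)
  trimmed <- trim_region(estimates, config$trim)
  trimmed <- normalize_to_band(trimmed, config$carbonate_window)
  model <- fit_collagen_pca(trimmed)
  finish_pipeline(model, model$scores, trimmed, config, diseased, control,
                  extras = list(btem = btem, filter_report = filter_report,
                                despiked = set))
}

# internal: diagnostics + reconstruction shared by both presets
finish_pipeline <- function(model, scores, trimmed, config, diseased,
                            control, extras = list()) {
  lb <- resolve_labels(scores, diseased, control)
  subject_scores <- average_by_subject(scores)
  diag <- diagnostic_summary(scores, specificity = config$specificity,
                             alpha = config$alpha, power = config$power,
                             diseased = lb$diseased)
  recon <- list()
  for (ch in c(lb$diseased, lb$control)) {
    recon[[ch]] <- reconstruct_group_mean(model, scores, ch)
  }
  pct <- percent_mineralization_difference(
    recon[[lb$diseased]], recon[[lb$control]],
    collagen_region = config$collagen_region,
    carbonate_window = config$carbonate_window)
  structure(c(list(preset = config$preset, config = config,
                   diseased = lb$diseased, control = lb$control,
                   scores = scores, subject_scores = subject_scores,
                   model = model, trimmed = trimmed,
                   diagnostics = diag, reconstructions = recon,
                   percent_difference = pct),
              extras),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: preset '%s', %d spectra, %d subjects>\n",
              x$preset, nrow(x$scores), nrow(x$subject_scores)))
  cat(sprintf("  percent mineralisation difference (%s vs %s): %+.2f%%\n",
              x$diseased, x$control, x$percent_difference))
  print(x$diagnostics)
  invisible(x)
}

#' Synthesise a full excised-bone study
#'
#' Two cohorts on one instrument axis: controls at mean ratio 1 and a
#' fractured cohort whose mean mineral-to-collagen ratio is
#' `percent_difference` percent higher, with shared variance structure.
#'
#' @param percent_difference True cohort difference in percent (default 5.5).
#' @param n_control,n_fractured Subjects per cohort (default 10 + 10).
#' @param spectra_per_subject Spectra per subject (default 15).
#' @param seed Seed; the two cohorts use derived sub-seeds.
#' @param lib Component library.
#' @param ... Overrides passed to both [cohort_spec()]s.
#' @return A [spectrum_set()] with cohorts `"control"` and `"fractured"`.
#' @export
synthesize_excised_study <- function(percent_difference = 5.5,
                                     n_control = 10, n_fractured = 10,
                                     spectra_per_subject = 15, seed = NULL,
                                     lib = make_component_library(), ...) {
  sub_seed <- function(k) if (is.null(seed)) NULL else seed * 13 + k
  ctrl <- generate_cohort(lib, cohort_spec(
    n_subjects = n_control, spectra_per_subject = spectra_per_subject,
    mean_ratio = 1, cohort = "control", seed = sub_seed(1), ...))
  frac <- generate_cohort(lib, cohort_spec(
    n_subjects = n_fractured, spectra_per_subject = spectra_per_subject,
    mean_ratio = 1 + percent_difference / 100, cohort = "fractured",
    seed = sub_seed(2), ...))
  spectrum_set(lib$wavenumber, rbind(ctrl$intensity, frac$intensity),
               meta = rbind(ctrl$meta, frac$meta),
               history = sprintf("synthesize_excised_study(delta=%g%%, seed=%s)",
                                 percent_difference, format(seed)))
}

#' Synthesise a full in vivo SORS study
#'
#' Osteoporotic and control cohorts measured transcutaneously: each subject
#' draws a true mineral-to-collagen ratio, each measurement draws a
#' site-level ratio around it, and each measurement is recorded as a stack
#' of noisy, spiked, baseline-ridden accumulations through soft tissue.
#'
#' @param percent_difference True cohort difference in percent (default 10).
#' @param n_op,n_control Subjects per cohort (default 10 + 6).
#' @param measurements_per_subject SORS measurements per subject (default 10).
#' @param between_subject_sd,within_subject_sd Ratio variance components.
#'   The within-subject (measurement-to-measurement) sd defaults to 0.02,
#'   much smaller than for excised microprobe spectra: diffuse SORS photons
#'   average over centimetres of cortex, so repeated measurements see far
#'   less of the millimetre-scale heterogeneity a focused microscope does.
#' @param soft_tissue_range Range the per-measurement soft-tissue weight is
#'   drawn from (default 0.3--0.7): the sampled soft fraction varies with
#'   probe site, spatial offset and skin thickness, and that variation is
#'   what lets curve resolution separate bone from overlayer.
#' @param cfg A [sors_config()]; its `soft_tissue_weight` is overridden per
#'   measurement.
#' @param seed Seed.
#' @param lib Component library.
#' @return List of [spectrum_set()]s, one accumulation stack per
#'   measurement, ready for [run_pipeline()] with the invivo preset.
#' @export
synthesize_invivo_study <- function(percent_difference = 10, n_op = 10,
                                    n_control = 6,
                                    measurements_per_subject = 10,
                                    between_subject_sd = 0.02,
                                    within_subject_sd = 0.02,
                                    soft_tissue_range = c(0.3, 0.7),
                                    cfg = sors_config(), seed = NULL,
                                    lib = make_component_library()) {
  with_seed(seed, {
    out <- list()
    for (cohort in c("control", "op")) {
      n_subj <- if (cohort == "op") n_op else n_control
      mean_ratio <- if (cohort == "op") 1 + percent_difference / 100 else 1
      for (i in seq_len(n_subj)) {
        subj <- sprintf("%s_%02d", cohort, i)
        r_i <- max(stats::rnorm(1, mean_ratio, between_subject_sd),
                   1e-3 * mean_ratio)
        for (j in seq_len(measurements_per_subject)) {
          r_ij <- max(stats::rnorm(1, r_i, within_subject_sd),
                      1e-3 * mean_ratio)
          bone <- generate_bone_spectrum(lib, r_ij,
                                         meta = list(subject = subj,
                                                     cohort = cohort))
          cfg_j <- cfg
          cfg_j$soft_tissue_weight <- stats::runif(1, soft_tissue_range[1],
                                                   soft_tissue_range[2])
          st <- generate_sors_measurement(bone, lib, cfg_j)
          st$meta$site <- j
          out[[length(out) + 1]] <- st
        }
      }
    }
    out
  })
}
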