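# Group comparison and normal-theory diagnostic performance. Given
# per-subject collagen scores for a diseased and a control cohort, these
# functions test for a group difference, compute the sensitivity a
# threshold classifier would reach at fixed specificity if scores are
# normally distributed within groups, and the per-group sample size a
# powered replication would need.

#' Summary statistics of one score group
#'
#' @param scores Numeric vector of scores (n >= 2).
#' @param label Group label.
#' @return Object of class `group_stats` with `label`, `n`, `mean`, `sd`.
#' @export
group_stats <- function(scores, label = "group") {
  scores <- as.numeric(scores)
  if (length(scores) < 2) stop("group_stats needs n >= 2")
  structure(list(label = label, n = length(scores), mean = mean(scores),
                 sd = stats::sd(scores)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group '%s': n=%d, mean=%.4g, sd=%.4g>\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

# internal: accept group_stats or a plain list(mean, sd)
as_stats <- function(g) {
  if (inherits(g, "group_stats")) return(g)
  if (is.list(g) && all(c("mean", "sd") %in% names(g))) return(g)
  stop("expected group_stats or list(mean=, sd=)")
}

#' Two-group comparison of scores
#'
#' Two-sided Welch unequal-variance t-test by default; an exact-ish
#' permutation test on the mean difference is available as a robustness
#' check.
#'
#' @param a,b Numeric score vectors, each n >= 2.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Permutations for the permutation method.
#' @param seed Seed for the permutation draw.
#' @return Two-sided p-value. Two zero-variance groups with equal means
#'   give p = 1 (no evidence of difference).
#' @export
two_group_test <- function(a, b, method = c("welch", "permutation"),
                           n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  if (method == "welch") {
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) {
               # degenerate near-constant groups: fall back to comparing means
               if (grepl("essentially constant", conditionMessage(e))) {
                 if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
               } else stop(e)
             })
  } else {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(length(pool), na)
        if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) {
          hits <- hits + 1L
        }
      }
      (hits + 1) / (n_perm + 1)
    })
  }
}

#' Sensitivity of a threshold classifier at fixed specificity
#'
#' Assumes scores are normal within each group. The decision threshold is
#' placed `z(specificity)` control standard deviations from the control
#' mean, on the diseased side; sensitivity is the probability a diseased
#' subject falls beyond it. When the two distributions coincide this is
#' exactly `1 - specificity`.
#'
#' @param diseased,control [group_stats()] (or `list(mean=, sd=)`).
#' @param specificity Target specificity in (0, 1), default 0.90.
#' @return Sensitivity fraction in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(diseased, control, specificity = 0.90) {
  d <- as_stats(diseased); c0 <- as_stats(control)
  if (specificity <= 0 || specificity >= 1) {
    stop("specificity must be in (0, 1)")
  }
  if (d$sd <= 0 || c0$sd <= 0) {
    stop("group sds must be > 0 for the normal-theory calculation")
  }
  z <- stats::qnorm(specificity)
  if (d$mean >= c0$mean) {
    thr <- c0$mean + z * c0$sd
    1 - stats::pnorm((thr - d$mean) / d$sd)
  } else {
    thr <- c0$mean - z * c0$sd
    stats::pnorm((thr - d$mean) / d$sd)
  }
}

#' Required per-group sample size for a two-group comparison
#'
#' Normal-approximation formula
#' `n = ceiling((z_{1-alpha/2} + z_{power})^2 (sd_d^2 + sd_c^2) / delta^2)`
#' per group, floored at 2. The inputs (means, sds, alpha, power) are
#' echoed alongside the result since the answer is only meaningful with
#' respect to them.
#'
#' @param diseased,control [group_stats()] (or `list(mean=, sd=)`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80, the usual convention).
#' @return List with `n_per_group`, `n_total` and the formula inputs.
#' @export
required_sample_size <- function(diseased, control, alpha = 0.05,
                                 power = 0.80) {
  d <- as_stats(diseased); c0 <- as_stats(control)
  delta <- abs(d$mean - c0$mean)
  if (delta == 0) stop("equal group means: required sample size is infinite")
  if (d$sd < 0 || c0$sd < 0) stop("sds must be >= 0")
  n_cont <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
    (d$sd^2 + c0$sd^2) / delta^2
  n <- max(2L, as.integer(ceiling(n_cont)))
  list(n_per_group = n, n_total = 2L * n, n_continuous = n_cont,
       delta = delta, sd_diseased = d$sd, sd_control = c0$sd,
       alpha = alpha, power = power)
}

#' Full diagnostic summary of a two-cohort score table
#'
#' Averages scores per subject, computes per-cohort statistics, the Welch
#' p-value, the normal-theory sensitivity at the requested specificity and
#' the required per-group sample size. The diseased group is taken as the
#' cohort with the lower mean collagen score (more mineralised) unless
#' named explicitly.
#'
#' @param scores Score table with `subject`, `cohort`, `collagen_score`.
#' @param specificity Specificity setpoint (default 0.90).
#' @param alpha,power Passed to [required_sample_size()].
#' @param diseased Optional cohort label of the diseased group.
#' @param per_subject Average per subject before summarising (default TRUE).
#' @return Object of class `diagnostic_summary`.
#' @export
diagnostic_summary <- function(scores, specificity = 0.90, alpha = 0.05,
                               power = 0.80, diseased = NULL,
                               per_subject = TRUE) {
  cohorts <- unique(as.character(scores$cohort))
  if (length(cohorts) != 2) {
    stop("diagnostic_summary needs exactly two cohorts, got ",
         length(cohorts))
  }
  tab <- if (per_subject) average_by_subject(scores) else scores
  by <- split(tab$collagen_score, as.character(tab$cohort))
  if (is.null(diseased)) {
    means <- vapply(by, mean, 0)
    diseased <- names(which.min(means))  # lower collagen = more mineralised
  }
  if (!diseased %in% cohorts) stop("unknown diseased cohort '", diseased, "'")
  control <- setdiff(cohorts, diseased)
  gs_d <- group_stats(by[[diseased]], diseased)
  gs_c <- group_stats(by[[control]], control)
  p <- two_group_test(by[[diseased]], by[[control]])
  sens <- if (gs_d$sd > 0 && gs_c$sd > 0) {
    sensitivity_at_specificity(gs_d, gs_c, specificity)
  } else NA_real_
  nreq <- if (gs_d$mean != gs_c$mean) {
    required_sample_size(gs_d, gs_c, alpha, power)
  } else NULL
  structure(list(
    diseased = unclass(gs_d), control = unclass(gs_c),
    p_value = p, specificity_setpoint = specificity, sensitivity = sens,
    n_per_group_required = if (is.null(nreq)) NA_integer_ else nreq$n_per_group,
    sample_size = nreq, alpha = alpha, power = power,
    direction = if (gs_d$mean < gs_c$mean)
      "diseased scores lower (more mineralised)"
    else "diseased scores higher",
    per_subject = per_subject),
    class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat("Diagnostic summary (", if (x$per_subject) "per-subject scores"
      else "per-spectrum scores", ")\n", sep = "")
  cat(sprintf("  %s: n=%d, mean=%.4g, sd=%.4g\n", x$diseased$label,
              x$diseased$n, x$diseased$mean, x$diseased$sd))
  cat(sprintf("  %s: n=%d, mean=%.4g, sd=%.4g\n", x$control$label,
              x$control$n, x$control$mean, x$control$sd))
  cat(sprintf("  Welch p-value: %.4g\n", x$p_value))
  cat(sprintf("  direction: %s\n", x$direction))
  cat(sprintf("  sensitivity at %.0f%% specificity: %.1f%%\n",
              100 * x$specificity_setpoint, 100 * x$sensitivity))
  cat(sprintf("  required n per group (alpha=%g, power=%g): %s\n",
              x$alpha, x$power, format(x$n_per_group_required)))
  invisible(x)
}

#' Write / read a diagnostic summary as JSON
#'
#' @param x A [diagnostic_summary()].
#' @param path Output path.
#' @return `path` invisibly; `read_diagnostic_summary` returns the
#'   reconstructed `diagnostic_summary`.
#' @export
write_diagnostic_summary <- function(x, path) {
  stopifnot(inherits(x, "diagnostic_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_diagnostic_summary
#' @export
read_diagnostic_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$n_per_group_required)) {
    x$n_per_group_required <- as.integer(x$n_per_group_required)
  }
  if (!is.null(x$sample_size$n_per_group)) {
    x$sample_size$n_per_group <- as.integer(x$sample_size$n_per_group)
    x$sample_size$n_total <- as.integer(x$sample_size$n_total)
  }
  class(x) <- "diagnostic_summary"
  x
}
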