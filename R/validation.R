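# Agreement statistics: Bland-Altman, Pearson correlation, and the
# ANSI/AAMI/ISO 81060-2 criterion 1 and criterion 2 checks.

#' Bland-Altman statistics
#'
#' Differences are `estimate - reference`. Returns the mean difference,
#' its sample standard deviation (n - 1 denominator), and the limits of
#' agreement `mean +/- 1.96 * SD`.
#'
#' @param estimates,references Paired readings (mmHg), equal length >= 2.
#' @return List with `mean_diff`, `sd_diff`, `loa` (length-2), `n`.
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    abort_usage("'estimates' and 'references' must have equal length")
  }
  if (length(estimates) < 2L) abort_usage("need >= 2 paired readings")
  d <- estimates - references
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(m - 1.96 * s, m + 1.96 * s),
       n = length(d))
}

#' Pearson correlation between estimates and references
#'
#' @param estimates,references Paired readings, length >= 3, each with
#'   nonzero variance.
#' @return The sample correlation coefficient.
#' @export
pearson <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    abort_usage("'estimates' and 'references' must have equal length")
  }
  if (length(estimates) < 3L) abort_usage("need >= 3 paired readings")
  if (stats::var(estimates) == 0 || stats::var(references) == 0) {
    abort_data("correlation undefined: zero variance")
  }
  stats::cor(estimates, references)
}

#' ISO 81060-2 criterion 1
#'
#' Pass iff `|mean_diff| <= 5` mmHg and `sd_diff <= 8` mmHg (inclusive
#' bounds, as printed).
#'
#' @param mean_diff,sd_diff Cohort error mean and SD (mmHg).
#' @return List with `pass`, and the margins to each bound.
#' @export
iso_criterion1 <- function(mean_diff, sd_diff) {
  if (!is.finite(mean_diff) || !is.finite(sd_diff)) {
    abort_invalid("inputs must be finite")
  }
  list(pass = abs(mean_diff) <= 5 && sd_diff <= 8,
       mean_margin = 5 - abs(mean_diff),
       sd_margin = 8 - sd_diff)
}

#' ISO 81060-2 criterion 2 SD bound
#'
#' The largest standard deviation `s` of per-subject mean differences for
#' which at least 85% of a normal population with mean `m` lies within
#' +/- 10 mmHg: solves `Phi((10 - m)/s) - Phi((-10 - m)/s) = 0.85` by
#' bisection to 1e-6. At `m = 0` this equals the closed form
#' `10 / qnorm(0.925)`.
#'
#' @param mean_diff Mean of per-subject mean differences (mmHg),
#'   `|mean_diff| < 10`.
#' @return The SD bound (mmHg).
#' @export
iso_criterion2_bound <- function(mean_diff) {
  if (!is.finite(mean_diff)) abort_invalid("'mean_diff' must be finite")
  if (abs(mean_diff) >= 10) {
    abort_data("no feasible criterion-2 bound for |mean| >= 10 mmHg")
  }
  cover <- function(s) {
    stats::pnorm((10 - mean_diff) / s) - stats::pnorm((-10 - mean_diff) / s)
  }
  lo <- 1e-9
  hi <- 50
  # cover() is strictly decreasing in s on this range
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (cover(mid) >= 0.85) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Cohort validation report
#'
#' Computes, for each of SBP, DBP and MAP: Bland-Altman mean/SD/limits of
#' agreement, Pearson correlation, the criterion-1 flag, and the
#' criterion-2 check (per-subject mean differences first, then the SD
#' across subjects against the bound solved from the tolerance
#' requirement).
#'
#' @param cohort A `data.frame` with columns `subject_id`, `est_sbp`,
#'   `est_dbp`, `est_map`, `ref_sbp`, `ref_dbp`, `ref_map` (one row per
#'   reading), e.g. from [run_cohort()].
#' @return An object of class `validation_report`: per-measure statistics
#'   plus `n`.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", paste0("est_", c("sbp", "dbp", "map")),
            paste0("ref_", c("sbp", "dbp", "map")))
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort_format(paste("cohort table is missing column(s):",
                       paste(missing, collapse = ", ")))
  }
  measures <- c("sbp", "dbp", "map")
  per <- lapply(measures, function(m) {
    est <- cohort[[paste0("est_", m)]]
    ref <- cohort[[paste0("ref_", m)]]
    ba <- bland_altman(est, ref)
    r <- tryCatch(pearson(est, ref), pulsebp_error = function(e) NA_real_)
    c1 <- iso_criterion1(ba$mean_diff, ba$sd_diff)
    d <- est - ref
    subj_means <- tapply(d, cohort$subject_id, mean)
    m2 <- mean(subj_means)
    s2 <- if (length(subj_means) >= 2L) stats::sd(subj_means) else NA_real_
    bound <- tryCatch(iso_criterion2_bound(m2),
                      pulsebp_error = function(e) NA_real_)
    list(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff, loa = ba$loa,
         pearson_r = r, criterion1_pass = c1$pass,
         criterion2_bound = bound, criterion2_sd = s2,
         criterion2_pass = is.finite(bound) && is.finite(s2) && s2 <= bound)
  })
  names(per) <- measures
  structure(c(per, list(n = nrow(cohort),
                        n_subjects = length(unique(cohort$subject_id)))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %d readings, %d subjects>\n", x$n,
              x$n_subjects))
  for (m in c("sbp", "dbp", "map")) {
    p <- x[[m]]
    cat(sprintf(
      "  %s: %+.2f +/- %.2f mmHg (LoA %+.2f..%+.2f), r = %.3f, C1 %s, C2 %s (SD %.2f <= %.2f)\n",
      toupper(m), p$mean_diff, p$sd_diff, p$loa[1], p$loa[2], p$pearson_r,
      if (p$criterion1_pass) "pass" else "FAIL",
      if (p$criterion2_pass) "pass" else "FAIL",
      p$criterion2_sd, p$criterion2_bound))
  }
  invisible(x)
}

#' Bland-Altman scatter data
#'
#' Mean-versus-difference pairs for plotting.
#'
#' @param estimates,references Paired readings (mmHg).
#' @return `data.frame` with columns `mean` and `diff`.
#' @export
bland_altman_scatter <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    abort_usage("'estimates' and 'references' must have equal length")
  }
  data.frame(mean = (estimates + references) / 2,
             diff = estimates - references)
}
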