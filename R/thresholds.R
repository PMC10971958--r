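#' Analysis thresholds
#'
#' Bundle of the numeric cut-offs used across the pipeline. The defaults
#' are the published values of the serum footprinting workflow:
#' import/export calls require a linear or exponential fit with adjusted
#' R^2 above 0.7, or a greater than 3-fold change over the first 15 min
#' together with a greater than 5-fold change over 30 min; a mutant
#' differs from wild type on a >= 2-fold, non-overlapping change or a
#' Welch p below 0.01; volcano significance uses p < 0.05 with
#' |log2 fold change| > 0.5; QC reproducibility is capped at 30% CV and
#' spectral-library matches must exceed a score of 70.
#'
#' @param adj_r2_min Minimum adjusted R^2 for the linear and exponential
#'   transport criteria (dimensionless).
#' @param fc15_min Minimum fold change between 0 and 15 min for the
#'   fold-change transport criterion (fold, strict).
#' @param fc30_min Minimum fold change between 0 and 30 min for the
#'   fold-change transport criterion (fold, strict).
#' @param mutant_fc_min Minimum mutant-vs-WT fold change for differential
#'   criterion A (fold; "2-fold or higher", so non-strict).
#' @param mutant_p_max Maximum Welch p-value for differential criterion B.
#' @param volcano_p_max Maximum paired-t p-value for volcano significance.
#' @param volcano_abs_log2fc_min Minimum |log2 fold change| for volcano
#'   significance (strict).
#' @param qc_cv_max Maximum QC coefficient of variation, in percent, for a
#'   feature to enter the uniqueness (deduplication) step.
#' @param score_min Library matching score that must be exceeded
#'   (strictly) for confidence levels 1 (mzVault) and 2 (mzCloud).
#' @param mass_tol_ppm Mass tolerance for feature deduplication, in ppm.
#' @param rt_tol_min Retention-time tolerance for deduplication, minutes.
#' @param loess_span LOESS span for QC drift correction, or `"aicc"` to
#'   select the span automatically by corrected AIC.
#' @param min_qc_count Minimum number of non-missing QC measurements a
#'   feature needs for LOESS correction.
#' @param noisy_cv_max Replicate CV (percent) above which a compound's
#'   time course is flagged `noisy` for downstream triage.
#' @param seed Default integer seed for randomized operations.
#'
#' @return A named list of class `exoflux_thresholds`.
#' @examples
#' th <- exoflux_thresholds()
#' th$adj_r2_min
#' exoflux_thresholds(mutant_fc_min = 1.5)$mutant_fc_min
#' @export
exoflux_thresholds <- function(adj_r2_min = 0.7,
                               fc15_min = 3,
                               fc30_min = 5,
                               mutant_fc_min = 2,
                               mutant_p_max = 0.01,
                               volcano_p_max = 0.05,
                               volcano_abs_log2fc_min = 0.5,
                               qc_cv_max = 30,
                               score_min = 70,
                               mass_tol_ppm = 5,
                               rt_tol_min = 0.1,
                               loess_span = 0.75,
                               min_qc_count = 5,
                               noisy_cv_max = 50,
                               seed = 1L) {
  th <- list(
    adj_r2_min = adj_r2_min,
    fc15_min = fc15_min,
    fc30_min = fc30_min,
    mutant_fc_min = mutant_fc_min,
    mutant_p_max = mutant_p_max,
    volcano_p_max = volcano_p_max,
    volcano_abs_log2fc_min = volcano_abs_log2fc_min,
    qc_cv_max = qc_cv_max,
    score_min = score_min,
    mass_tol_ppm = mass_tol_ppm,
    rt_tol_min = rt_tol_min,
    loess_span = loess_span,
    min_qc_count = min_qc_count,
    noisy_cv_max = noisy_cv_max,
    seed = as.integer(seed)
  )
  class(th) <- "exoflux_thresholds"
  validate_thresholds(th)
}

validate_thresholds <- function(th) {
  num <- th[setdiff(names(th), c("loess_span", "seed"))]
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                              is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0) {
    stop("thresholds must be single positive finite numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (p in c("mutant_p_max", "volcano_p_max")) {
    if (th[[p]] >= 1) stop(p, " must lie in (0, 1)", call. = FALSE)
  }
  if (is.character(th$loess_span)) {
    if (!identical(th$loess_span, "aicc")) {
      stop("loess_span must be a positive number or \"aicc\"", call. = FALSE)
    }
  } else if (!is.numeric(th$loess_span) || th$loess_span <= 0) {
    stop("loess_span must be a positive number or \"aicc\"", call. = FALSE)
  }
  if (th$min_qc_count < 3) stop("min_qc_count must be at least 3", call. = FALSE)
  th
}

#' @export
print.exoflux_thresholds <- function(x, ...) {
  cat("<exoflux_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Resolve a thresholds argument (NULL -> defaults) with a clear error.
as_thresholds <- function(thresholds) {
  if (is.null(thresholds)) return(exoflux_thresholds())
  if (!inherits(thresholds, "exoflux_thresholds")) {
    stop("`thresholds` must come from exoflux_thresholds()", call. = FALSE)
  }
  thresholds
}
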