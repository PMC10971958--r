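#' Time-course plot of one compound across strains
#'
#' Mean peak area with standard-error bars per strain and time point,
#' the standard read-out for judging uptake (falling curves) versus
#' excretion (rising curves) and mutant/wild-type contrasts.
#'
#' @param x A [peak_matrix].
#' @param feature_id Compound to plot.
#' @param strains Strains to include (default: all non-QC strains).
#' @return A ggplot object.
#' @export
plot_time_course <- function(x, feature_id, strains = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  long <- pm_long(x)
  long <- long[long$feature_id == feature_id &
                 long$genotype_class != "QC", ]
  if (!is.null(strains)) long <- long[long$strain %in% strains, ]
  if (nrow(long) == 0) stop("nothing to plot for ", feature_id,
                            call. = FALSE)
  summ <- long |>
    dplyr::group_by(.data$strain, .data$time_min) |>
    dplyr::summarise(
      mean = mean(.data$intensity, na.rm = TRUE),
      se = stats::sd(.data$intensity, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$intensity))),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$time_min, .data$mean,
                                     colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.8) +
    ggplot2::labs(x = "Incubation time (min)", y = "Peak area",
                  title = feature_id) +
    ggplot2::theme_minimal()
}

#' Volcano plot of end-vs-start differential abundance
#'
#' @param volcano A tibble from [volcano_stats()].
#' @param thresholds An [exoflux_thresholds()] supplying the
#'   significance lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  ggplot2::ggplot(volcano, ggplot2::aes(.data$log2fc,
                                        -log10(.data$p_value),
                                        colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(th$volcano_p_max),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th$volcano_abs_log2fc_min,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (30 vs 0 min)",
                  y = "-log10 p (paired t)") +
    ggplot2::theme_minimal()
}

#' Drift diagnostic plot of a peak matrix
#'
#' Median intensity per injection against injection order, QC
#' injections highlighted — the standard visual check that LOESS
#' correction removed the run's signal drift.
#'
#' @param object A [peak_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_matrix
#' @export
autoplot.peak_matrix <- function(object, ...) {
  long <- pm_long(object)
  summ <- long |>
    dplyr::group_by(.data$sample_id, .data$injection_order,
                    .data$genotype_class) |>
    dplyr::summarise(median_intensity = stats::median(.data$intensity,
                                                      na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$injection_order,
                                     .data$median_intensity,
                                     colour = .data$genotype_class == "QC")) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "orange"),
                                 labels = c("analytical", "QC"),
                                 name = NULL) +
    ggplot2::labs(x = "Injection order", y = "Median peak area") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy view of a peak matrix
#'
#' @param x A [peak_matrix].
#' @param ... Unused.
#' @return The long tibble of [pm_long()].
#' @method tidy peak_matrix
#' @export
tidy.peak_matrix <- function(x, ...) pm_long(x)

#' One-row summary of a peak matrix
#'
#' @param x A [peak_matrix].
#' @param ... Unused.
#' @return A tibble with feature/sample counts, polarity, scale and the
#'   median QC CV (when QC injections are present).
#' @method glance peak_matrix
#' @export
glance.peak_matrix <- function(x, ...) {
  qc_ids <- pm_qc_samples(x)
  med_cv <- if (length(qc_ids) >= 2 && !x$log2) {
    qc <- as.matrix(x$intensities[, qc_ids, drop = FALSE])
    stats::median(apply(qc, 1, compute_qc_cv), na.rm = TRUE)
  } else NA_real_
  tibble::tibble(
    n_features = n_features(x), n_samples = n_samples(x),
    n_qc = length(qc_ids), polarity = x$polarity, log2 = x$log2,
    median_qc_cv = med_cv
  )
}
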