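#' Assign identification confidence levels
#'
#' Maps per-compound annotation evidence to the 1 (best) to 5 (exact
#' mass only) identification-confidence scale used in untargeted
#' metabolomics reporting. The first matching rule wins, in order:
#' \enumerate{
#'   \item mzVault library score strictly exceeding `score_min` (70);
#'   \item mzCloud library score strictly exceeding `score_min`;
#'   \item a "Full match" in the annotation source;
#'   \item a molecular formula is present;
#'   \item a confirmed molecular weight is present.
#' }
#' A record matching none of the rules gets `NA`.
#'
#' @param evidence Data frame with one row per compound and columns
#'   `mzvault_score`, `mzcloud_score` (0-100 or `NA`),
#'   `annotation_source_full_match`, `has_formula`,
#'   `has_molecular_weight` (logical); optionally `has_ms2` and
#'   `ms2_preferred_ion`.
#' @param thresholds An [exoflux_thresholds()]; uses `score_min`.
#' @return The input as a tibble with an integer `level` column.
#' @examples
#' ev <- tibble::tibble(
#'   mzvault_score = c(85, NA), mzcloud_score = c(90, 72),
#'   annotation_source_full_match = FALSE, has_formula = FALSE,
#'   has_molecular_weight = TRUE
#' )
#' assign_confidence_level(ev)$level
#' @export
assign_confidence_level <- function(evidence, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  ev <- tibble::as_tibble(evidence)
  need <- c("mzvault_score", "mzcloud_score", "annotation_source_full_match",
            "has_formula", "has_molecular_weight")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    stop("evidence lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (sc in c("mzvault_score", "mzcloud_score")) {
    v <- ev[[sc]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop(sc, " must lie in [0, 100]", call. = FALSE)
    }
  }
  if (all(c("has_ms2", "ms2_preferred_ion") %in% names(ev))) {
    if (any(ev$ms2_preferred_ion & !ev$has_ms2, na.rm = TRUE)) {
      stop("ms2_preferred_ion requires has_ms2", call. = FALSE)
    }
  }
  lvl <- dplyr::case_when(
    !is.na(ev$mzvault_score) & ev$mzvault_score > th$score_min ~ 1L,
    !is.na(ev$mzcloud_score) & ev$mzcloud_score > th$score_min ~ 2L,
    ev$annotation_source_full_match %in% TRUE ~ 3L,
    ev$has_formula %in% TRUE ~ 4L,
    ev$has_molecular_weight %in% TRUE ~ 5L,
    TRUE ~ NA_integer_
  )
  ev$level <- lvl
  ev
}

#' Percentage with the identification-summary rounding rule
#'
#' `100 * count / total`, rounded half-up to the nearest integer —
#' except that a nonzero share whose integer rounding would be 0 is
#' reported to one decimal place instead (so 16 of 9406 prints as 0.2,
#' not 0).
#'
#' @param count,total Non-negative counts (vectorised over `count`).
#' @return Numeric vector of percentages on the reported scale.
#' @examples
#' id_percent(3671, 9406)
#' id_percent(16, 9406)
#' @export
id_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  raw <- 100 * count / total
  int <- floor(raw + 0.5)
  out <- ifelse(int == 0 & count > 0, floor(raw * 10 + 0.5) / 10, int)
  out
}

id_summary_metrics <- c("n_compounds", "n_unique", "n_ms2", "n_no_ms2",
                        "n_ms2_preferred", "n_ms2_other",
                        paste0("n_level", 1:5))

#' Identification summary of an annotated compound set
#'
#' Computes the per-polarity overview of an identification run: number
#' of compounds, unique compounds (after QC-CV filtering and
#' mass/retention-time deduplication), compounds with and without MS2
#' spectra (split by preferred vs other ion), and counts per confidence
#' level, each with its percentage of all compounds under the rounding
#' rule of [id_percent()].
#'
#' Either supply per-compound `evidence` (with levels assigned) and the
#' deduplicated `features` table, or supply precomputed `counts`
#' directly (a named vector using the metric names of the output).
#'
#' @param evidence Output of [assign_confidence_level()], one row per
#'   compound, with logical `has_ms2` and `ms2_preferred_ion` columns.
#' @param features Optional output of [dedupe_features()]; its
#'   `is_unique_representative` flags define `n_unique`.
#' @param counts Optional named numeric vector of precomputed counts
#'   (must include `n_compounds`); overrides `evidence`/`features`.
#' @return A tibble with columns `metric`, `count`, `percent`.
#' @examples
#' summarize_identification(counts = c(n_compounds = 9406, n_unique = 3671))
#' @export
summarize_identification <- function(evidence = NULL, features = NULL,
                                     counts = NULL) {
  if (is.null(counts)) {
    if (is.null(evidence)) stop("supply `evidence` or `counts`", call. = FALSE)
    ev <- tibble::as_tibble(evidence)
    if (!"level" %in% names(ev)) {
      stop("assign confidence levels first (assign_confidence_level)",
           call. = FALSE)
    }
    if (nrow(ev) == 0) stop("no compounds to summarise", call. = FALSE)
    has_ms2 <- if ("has_ms2" %in% names(ev)) ev$has_ms2 %in% TRUE else
      rep(FALSE, nrow(ev))
    pref <- if ("ms2_preferred_ion" %in% names(ev))
      ev$ms2_preferred_ion %in% TRUE else rep(FALSE, nrow(ev))
    counts <- c(
      n_compounds = nrow(ev),
      n_unique = if (!is.null(features))
        sum(features$is_unique_representative %in% TRUE) else NA_real_,
      n_ms2 = sum(has_ms2),
      n_no_ms2 = sum(!has_ms2),
      n_ms2_preferred = sum(pref),
      n_ms2_other = sum(has_ms2 & !pref),
      stats::setNames(vapply(1:5, function(l) sum(ev$level %in% l),
                             numeric(1)), paste0("n_level", 1:5))
    )
  }
  if (!"n_compounds" %in% names(counts) || counts[["n_compounds"]] <= 0) {
    stop("counts must include a positive n_compounds", call. = FALSE)
  }
  total <- counts[["n_compounds"]]
  metrics <- intersect(id_summary_metrics, names(counts))
  cnt <- as.numeric(counts[metrics])
  tibble::tibble(
    metric = metrics,
    count = cnt,
    percent = ifelse(is.na(cnt), NA_real_, id_percent(ifelse(is.na(cnt), 0, cnt), total))
  )
}
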