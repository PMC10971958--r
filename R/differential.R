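#' Volcano statistics (paired t-test, end vs start of incubation)
#'
#' For one strain, compares log2 intensities at 30 min against 0 min
#' with a paired t-test, pairing by technical replicate index. The
#' log2 fold change is the mean paired difference. Significance uses
#' `volcano_p_max` and `volcano_abs_log2fc_min`.
#'
#' @param x A log2-transformed [peak_matrix] (see [log2_transform()]).
#' @param strain Strain to test.
#' @param thresholds An [exoflux_thresholds()].
#' @return A tibble with one row per feature: `feature_id`, `strain`,
#'   `log2fc`, `p_value`, `significant`.
#' @export
volcano_stats <- function(x, strain, thresholds = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!x$log2) stop("volcano_stats expects a log2-transformed matrix ",
                    "(run log2_transform first)", call. = FALSE)
  th <- as_thresholds(thresholds)
  samp <- x$samples[x$samples$strain == strain, ]
  s0 <- samp[samp$time_min == 0, ]
  s30 <- samp[samp$time_min == 30, ]
  if (nrow(s0) != nrow(s30) || nrow(s0) < 2) {
    stop("need equal replicate counts (>= 2) at t = 0 and t = 30 for ",
         strain, call. = FALSE)
  }
  s0 <- s0[order(s0$replicate), ]
  s30 <- s30[order(s30$replicate), ]
  if (!identical(s0$replicate, s30$replicate)) {
    stop("replicate indices at t = 0 and t = 30 do not match", call. = FALSE)
  }
  m0 <- as.matrix(x$intensities[, s0$sample_id, drop = FALSE])
  m30 <- as.matrix(x$intensities[, s30$sample_id, drop = FALSE])
  d <- m30 - m0
  log2fc <- rowMeans(d)
  p <- apply(d, 1, paired_p)
  tibble::tibble(
    feature_id = x$intensities$feature_id,
    strain = strain,
    log2fc = log2fc,
    p_value = p,
    significant = p < th$volcano_p_max &
      abs(log2fc) > th$volcano_abs_log2fc_min
  )
}

# p-value of the one-sample t-test on paired differences; degenerate
# zero-variance differences give 1 (all zero) or 0 (constant shift).
paired_p <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  stats::t.test(d)$p.value
}

welch_p <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

mutant_times <- c(5, 15, 30)

#' Differential-transport criterion A: fold change without overlap
#'
#' A compound differs from wild type if, at 5, 15 or 30 minutes, the
#' mutant shows a 2-fold or higher change in peak area relative to the
#' wild type (bidirectional, on replicate means) and the replicate
#' ranges (min to max) of the two strains do not overlap at that time
#' point.
#'
#' @param wt_points,mut_points Replicate-level time courses
#'   (`time_min`, `replicate`, `intensity`) for wild type and mutant.
#' @param thresholds An [exoflux_thresholds()]; uses `mutant_fc_min`.
#' @return A list with `fired`, `times` (time points that fired),
#'   `fc_map` (mutant-vs-WT oriented fold change per time) and
#'   `overlap_map` (logical per time).
#' @examples
#' wt <- tibble::tibble(time_min = 15, replicate = 1:3,
#'                      intensity = c(100, 110, 120))
#' mut <- tibble::tibble(time_min = 15, replicate = 1:3,
#'                       intensity = c(250, 260, 270))
#' criterion_a(wt, mut)
#' @export
criterion_a <- function(wt_points, mut_points, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  fc_map <- stats::setNames(rep(NA_real_, 3), mutant_times)
  overlap_map <- stats::setNames(rep(NA, 3), mutant_times)
  fired_at <- numeric(0)
  for (t in mutant_times) {
    wv <- wt_points$intensity[wt_points$time_min == t]
    mv <- mut_points$intensity[mut_points$time_min == t]
    wv <- wv[!is.na(wv)]
    mv <- mv[!is.na(mv)]
    if (length(wv) < 2 || length(mv) < 2) next
    mw <- mean(wv)
    mm <- mean(mv)
    if (mw <= 0 || mm <= 0) next
    fc_map[[as.character(t)]] <- mm / mw
    abs_fc <- max(mm / mw, mw / mm)
    overlap_map[[as.character(t)]] <- min(wv) <= max(mv) && min(mv) <= max(wv)
    if (abs_fc >= th$mutant_fc_min && !overlap_map[[as.character(t)]]) {
      fired_at <- c(fired_at, t)
    }
  }
  list(fired = length(fired_at) > 0, times = fired_at,
       fc_map = fc_map, overlap_map = overlap_map)
}

#' Differential-transport criterion B: significance against wild type
#'
#' Welch's unequal-variance t-test on log2 intensities, mutant versus
#' wild type, at each of 5, 15 and 30 minutes; the criterion fires when
#' the smallest of the per-time p-values is below `mutant_p_max`
#' (0.01). With `pooled = TRUE` a single test pools the three time
#' points instead.
#'
#' @inheritParams criterion_a
#' @param pooled Pool times 5/15/30 into one test instead of testing
#'   each time point.
#' @return A list with `fired`, `min_p` and `p_map` (per-time p-values;
#'   a single `pooled` entry when `pooled = TRUE`).
#' @export
criterion_b <- function(wt_points, mut_points, thresholds = NULL,
                        pooled = FALSE) {
  th <- as_thresholds(thresholds)
  lg <- function(v) log2(pmax(v, .Machine$double.xmin))
  if (pooled) {
    wv <- wt_points$intensity[wt_points$time_min %in% mutant_times]
    mv <- mut_points$intensity[mut_points$time_min %in% mutant_times]
    p <- welch_p(lg(wv), lg(mv))
    return(list(fired = !is.na(p) && p < th$mutant_p_max, min_p = p,
                p_map = c(pooled = p)))
  }
  p_map <- stats::setNames(rep(NA_real_, 3), mutant_times)
  for (t in mutant_times) {
    wv <- wt_points$intensity[wt_points$time_min == t]
    mv <- mut_points$intensity[mut_points$time_min == t]
    p_map[[as.character(t)]] <- welch_p(lg(wv[!is.na(wv)]), lg(mv[!is.na(mv)]))
  }
  min_p <- if (all(is.na(p_map))) NA_real_ else min(p_map, na.rm = TRUE)
  list(fired = !is.na(min_p) && min_p < th$mutant_p_max, min_p = min_p,
       p_map = p_map)
}

#' Select compounds transported differently in a mutant
#'
#' Evaluates criterion A (fold change without overlap) and criterion B
#' (Welch p < 0.01 on log2 values) for every compound of a mutant
#' against the wild type; a compound is selected when either fires.
#' Net relative changes of the replicate means over 0 to 30 minutes
#' (`change_wt`, `change_mut`) are carried along for downstream
#' direction classification, and replicate CV above `noisy_cv_max` in
#' either strain sets the `noisy` triage flag.
#'
#' @param x A raw-scale [peak_matrix].
#' @param wt,mutant Strain names.
#' @param thresholds An [exoflux_thresholds()].
#' @param pooled_b Use the pooled variant of criterion B.
#' @return A differential-call tibble, one row per compound.
#' @export
select_differential <- function(x, wt, mutant, thresholds = NULL,
                                pooled_b = FALSE) {
  stopifnot(inherits(x, "peak_matrix"))
  if (x$log2) stop("select_differential expects raw-scale intensities",
                   call. = FALSE)
  th <- as_thresholds(thresholds)
  for (s in c(wt, mutant)) {
    if (!s %in% x$samples$strain) stop("strain not present: ", s,
                                       call. = FALSE)
  }
  gclass <- unique(x$samples$genotype_class[x$samples$strain == mutant])
  get_wt <- points_factory(x, wt)
  get_mut <- points_factory(x, mutant)
  rows <- purrr::map(seq_len(n_features(x)), function(i) {
    f <- x$intensities$feature_id[i]
    wt_pts <- get_wt(i)
    mut_pts <- get_mut(i)
    a <- criterion_a(wt_pts, mut_pts, th)
    b <- criterion_b(wt_pts, mut_pts, th, pooled = pooled_b)
    mw <- time_means(wt_pts)
    mm <- time_means(mut_pts)
    chg <- function(m) {
      if (!all(c("0", "30") %in% names(m)) || m[["0"]] == 0) return(NA_real_)
      (m[["30"]] - m[["0"]]) / m[["0"]]
    }
    cv_flag <- function(pts) {
      cvs <- tapply(pts$intensity, pts$time_min, compute_qc_cv)
      any(!is.na(cvs) & cvs > th$noisy_cv_max)
    }
    tibble::tibble(
      feature_id = f,
      mutant_strain = mutant,
      genotype_class = gclass[1],
      criterion_a_fired = a$fired,
      criterion_a_times = paste(a$times, collapse = ";"),
      fc_t5 = a$fc_map[["5"]], fc_t15 = a$fc_map[["15"]],
      fc_t30 = a$fc_map[["30"]],
      overlap_t5 = a$overlap_map[["5"]], overlap_t15 = a$overlap_map[["15"]],
      overlap_t30 = a$overlap_map[["30"]],
      criterion_b_fired = b$fired,
      min_p = b$min_p,
      selected = a$fired || b$fired,
      change_wt = chg(mw),
      change_mut = chg(mm),
      noisy = cv_flag(wt_pts) || cv_flag(mut_pts)
    )
  })
  out <- new_calls(dplyr::bind_rows(rows), "differential_calls")
  message(sprintf("select_differential: %s vs %s: %d/%d compounds selected",
                  mutant, wt, sum(out$selected), nrow(out)))
  out
}
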