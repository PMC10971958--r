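#' QC coefficient of variation
#'
#' Percent coefficient of variation, `100 * sd / mean`, of a set of
#' repeated measurements (typically a feature's pooled-QC injections).
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return The CV in percent, or `NA` when fewer than two non-missing
#'   values remain or the mean is not positive.
#' @examples
#' compute_qc_cv(c(90, 100, 110))
#' @export
compute_qc_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(v) / m
}

# Corrected AIC for a loess fit (smaller is better).
loess_aicc <- function(fit) {
  n <- fit$n
  tr <- fit$trace.hat
  sigma2 <- sum(fit$residuals^2) / n
  if (n - tr - 2 <= 0) return(Inf)
  log(sigma2) + 1 + 2 * (tr + 1) / (n - tr - 2)
}

fit_qc_loess <- function(order, value, span) {
  if (identical(span, "aicc")) {
    grid <- seq(0.3, 1, by = 0.05)
    fits <- lapply(grid, function(s) {
      tryCatch(stats::loess(value ~ order, span = s, degree = 1,
                            control = stats::loess.control(surface = "direct")),
               error = function(e) NULL)
    })
    aicc <- vapply(fits, function(f) if (is.null(f)) Inf else loess_aicc(f),
                   numeric(1))
    if (all(!is.finite(aicc))) return(NULL)
    fits[[which.min(aicc)]]
  } else {
    tryCatch(stats::loess(value ~ order, span = span, degree = 1,
                          control = stats::loess.control(surface = "direct")),
             error = function(e) NULL)
  }
}

#' QC-based LOESS signal-drift correction
#'
#' Corrects injection-order signal drift per feature by fitting a LOESS
#' curve to the pooled-QC intensities against injection order and
#' dividing every sample's intensity by the fitted curve normalised to
#' the median QC intensity (QC-RLSC). Features with fewer than
#' `min_qc_count` non-missing QC measurements, or whose fitted curve is
#' non-finite or non-positive anywhere, pass through unchanged and are
#' flagged.
#'
#' @param x A raw-scale [peak_matrix] containing QC injections.
#' @param thresholds An [exoflux_thresholds()]; uses `loess_span`
#'   (a number, or `"aicc"` for automatic span selection) and
#'   `min_qc_count`.
#' @return The corrected `peak_matrix`. Its `features` table gains
#'   `qc_corrected` (logical), `qc_cv_raw` and `qc_cv` (percent CV over
#'   QC injections before/after correction).
#' @export
loess_qc_correct <- function(x, thresholds = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  if (x$log2) stop("drift correction expects raw-scale intensities",
                   call. = FALSE)
  th <- as_thresholds(thresholds)
  qc_ids <- pm_qc_samples(x)
  if (length(qc_ids) == 0) stop("no QC samples in the matrix", call. = FALSE)
  qc_order <- x$samples$injection_order[match(qc_ids, x$samples$sample_id)]
  all_ids <- x$samples$sample_id
  all_order <- x$samples$injection_order
  # evaluate the drift curve inside the QC-covered range only
  eval_order <- pmin(pmax(all_order, min(qc_order)), max(qc_order))

  ints <- x$intensities
  n_feat <- nrow(ints)
  corrected <- logical(n_feat)
  cv_raw <- numeric(n_feat)
  cv_post <- numeric(n_feat)
  raw <- as.matrix(ints[, all_ids, drop = FALSE])
  qc_idx <- match(qc_ids, all_ids)

  for (i in seq_len(n_feat)) {
    qv <- raw[i, qc_idx]
    ok <- !is.na(qv)
    cv_raw[i] <- compute_qc_cv(qv)
    if (sum(ok) < th$min_qc_count) {
      cv_post[i] <- cv_raw[i]
      next
    }
    fit <- fit_qc_loess(qc_order[ok], qv[ok], th$loess_span)
    if (is.null(fit)) {
      cv_post[i] <- cv_raw[i]
      next
    }
    pred <- stats::predict(fit, newdata = data.frame(order = eval_order))
    factor <- pred / stats::median(qv[ok])
    if (any(!is.finite(factor)) || any(factor <= 0)) {
      cv_post[i] <- cv_raw[i]
      next
    }
    raw[i, ] <- raw[i, ] / factor
    corrected[i] <- TRUE
    cv_post[i] <- compute_qc_cv(raw[i, qc_idx])
  }

  out <- x
  out$intensities <- dplyr::bind_cols(
    tibble::tibble(feature_id = ints$feature_id),
    tibble::as_tibble(raw)
  )
  out$features$qc_corrected <- corrected
  out$features$qc_cv_raw <- cv_raw
  out$features$qc_cv <- cv_post
  message(sprintf("loess_qc_correct: %d/%d features corrected (span %s, %d QC injections)",
                  sum(corrected), n_feat, format(th$loess_span),
                  length(qc_ids)))
  validate_peak_matrix(out)
}

#' Deduplicate features by exact mass and retention time
#'
#' Flags one unique representative per group of features that agree in
#' neutral mass (within `mass_tol_ppm`) and retention time (within
#' `rt_tol_min`), considering only features whose QC CV does not exceed
#' `qc_cv_max`. Clustering is greedy in descending median QC intensity
#' (ties broken by feature id), so the brightest feature of each group
#' becomes its representative; the result does not depend on the input
#' row order.
#'
#' @param x A [peak_matrix] whose `features` carry `neutral_mass` and
#'   `rt`; `qc_cv` is taken from the features table (as computed by
#'   [loess_qc_correct()]) or computed from QC columns when absent.
#' @param thresholds An [exoflux_thresholds()].
#' @return The `features` tibble with added `qc_cv` (if absent),
#'   `qc_pass`, `cluster_id` and `is_unique_representative` columns.
#' @export
dedupe_features <- function(x, thresholds = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  th <- as_thresholds(thresholds)
  feats <- x$features
  if (!all(c("neutral_mass", "rt") %in% names(feats))) {
    stop("feature metadata needs neutral_mass and rt for deduplication",
         call. = FALSE)
  }
  qc_ids <- pm_qc_samples(x)
  qc_mat <- if (length(qc_ids) > 0) {
    as.matrix(x$intensities[, qc_ids, drop = FALSE])
  } else NULL
  if (!"qc_cv" %in% names(feats)) {
    if (is.null(qc_mat)) stop("no qc_cv in feature metadata and no QC samples",
                              call. = FALSE)
    feats$qc_cv <- apply(qc_mat, 1, compute_qc_cv)
  }
  med_qc <- if (!is.null(qc_mat)) {
    apply(qc_mat, 1, function(v) stats::median(v, na.rm = TRUE))
  } else rep(NA_real_, nrow(feats))

  feats$qc_pass <- !is.na(feats$qc_cv) & feats$qc_cv <= th$qc_cv_max
  feats$cluster_id <- NA_character_
  feats$is_unique_representative <- FALSE

  elig <- which(feats$qc_pass)
  ord <- elig[order(-med_qc[elig], feats$feature_id[elig])]
  assigned <- rep(FALSE, nrow(feats))
  for (i in ord) {
    if (assigned[i]) next
    ppm <- abs(feats$neutral_mass - feats$neutral_mass[i]) /
      feats$neutral_mass[i] * 1e6
    hit <- !assigned & feats$qc_pass &
      ppm <= th$mass_tol_ppm &
      abs(feats$rt - feats$rt[i]) <= th$rt_tol_min
    feats$cluster_id[hit] <- feats$feature_id[i]
    assigned[hit] <- TRUE
    feats$is_unique_representative[i] <- TRUE
  }
  message(sprintf("dedupe_features: %d/%d features pass QC CV <= %g%%; %d unique representatives",
                  sum(feats$qc_pass), nrow(feats), th$qc_cv_max,
                  sum(feats$is_unique_representative)))
  feats
}

#' Log2 transform with half-minimum imputation
#'
#' Transforms intensities to log2 scale. Zeros and missing cells are
#' imputed with half the feature's minimum positive intensity before
#' taking logs; features with no positive measurement at all are
#' dropped. Both events are reported via `message()`.
#'
#' @param x A raw-scale [peak_matrix].
#' @return The transformed `peak_matrix` (its `log2` flag set).
#' @examples
#' sim <- simulate_serum_experiment(sim_config(n_inert = 5, seed = 1))
#' lg <- log2_transform(sim$matrix)
#' lg$log2
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "peak_matrix"))
  if (x$log2) stop("matrix is already log2-transformed", call. = FALSE)
  ids <- x$samples$sample_id
  raw <- as.matrix(x$intensities[, ids, drop = FALSE])
  keep <- logical(nrow(raw))
  n_imputed <- 0L
  for (i in seq_len(nrow(raw))) {
    v <- raw[i, ]
    pos <- v[!is.na(v) & v > 0]
    if (length(pos) == 0) next
    keep[i] <- TRUE
    fill <- is.na(v) | v == 0
    if (any(fill)) {
      v[fill] <- min(pos) / 2
      n_imputed <- n_imputed + sum(fill)
    }
    raw[i, ] <- log2(v)
  }
  if (n_imputed > 0) {
    message(sprintf("log2_transform: imputed %d zero/missing cells with half-minimum",
                    n_imputed))
  }
  if (any(!keep)) {
    message(sprintf("log2_transform: dropped %d all-zero/missing features",
                    sum(!keep)))
  }
  out <- x
  out$intensities <- dplyr::bind_cols(
    tibble::tibble(feature_id = x$intensities$feature_id[keep]),
    tibble::as_tibble(raw[keep, , drop = FALSE])
  )
  out$features <- out$features[keep, , drop = FALSE]
  out$log2 <- TRUE
  validate_peak_matrix(out)
}
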