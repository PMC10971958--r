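#' Linear fit of a compound time course
#'
#' Ordinary least squares of replicate-level intensity on time. The
#' adjusted R^2 (p = 1 predictor) is the statistic gating the linear
#' import/export criterion.
#'
#' @param points Data frame with columns `time_min` and `intensity`
#'   (replicate-level, not time-point means).
#' @return An object of class `transport_fit` with elements `type`
#'   (`"linear"`), `slope` (intensity/min), `intercept`, `adj_r2` and
#'   `n`. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' pts <- tibble::tibble(time_min = c(0, 5, 15, 30),
#'                       intensity = c(100, 90, 70, 40))
#' fit_linear(pts)$slope
#' @export
fit_linear <- function(points) {
  check_points(points, min_n = 3)
  t <- points$time_min
  y <- points$intensity
  if (stats::var(t) == 0) stop("no variation in time", call. = FALSE)
  fit <- stats::lm(y ~ t)
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  n <- length(y)
  structure(
    list(type = "linear", slope = unname(co[2]), intercept = unname(co[1]),
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n),
    class = "transport_fit"
  )
}

#' Exponential fit of a compound time course
#'
#' Fits `A * exp(k t)` by least squares on log intensities (so the
#' multiplicative, heteroscedastic error of peak areas becomes
#' approximately additive). The adjusted R^2 is computed on the
#' original intensity scale from the back-transformed fitted values,
#' with p = 2 parameters.
#'
#' @inheritParams fit_linear
#' @return A `transport_fit` with `type = "exponential"`, `rate` (per
#'   minute, negative for decay), `amplitude`, `adj_r2` and `n`.
#' @examples
#' pts <- tibble::tibble(time_min = c(0, 5, 15, 30),
#'                       intensity = 1000 * exp(-0.05 * c(0, 5, 15, 30)))
#' fit_exponential(pts)$rate
#' @export
fit_exponential <- function(points) {
  check_points(points, min_n = 3)
  y <- points$intensity
  if (any(y <= 0)) stop("exponential fit needs strictly positive intensities",
                        call. = FALSE)
  t <- points$time_min
  if (stats::var(t) == 0) stop("no variation in time", call. = FALSE)
  fit <- stats::lm(log(y) ~ t)
  co <- stats::coef(fit)
  yhat <- exp(stats::fitted(fit))
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  n <- length(y)
  structure(
    list(type = "exponential", rate = unname(co[2]),
         amplitude = exp(unname(co[1])),
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 3), n = n),
    class = "transport_fit"
  )
}

check_points <- function(points, min_n = 3) {
  if (!all(c("time_min", "intensity") %in% names(points))) {
    stop("points need columns time_min and intensity", call. = FALSE)
  }
  pts <- points[!is.na(points$intensity), ]
  if (nrow(pts) < min_n) stop("need at least ", min_n, " points", call. = FALSE)
  if (length(unique(pts$time_min)) < 2) {
    stop("need at least 2 distinct time points", call. = FALSE)
  }
  invisible(pts)
}

#' @export
print.transport_fit <- function(x, ...) {
  cat(sprintf("<transport_fit: %s> adj R^2 = %.4f (n = %d)\n",
              x$type, x$adj_r2, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy transport_fit
#' @export
tidy.transport_fit <- function(x, ...) {
  if (x$type == "linear") {
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = c(x$intercept, x$slope))
  } else {
    tibble::tibble(term = c("amplitude", "rate"),
                   estimate = c(x$amplitude, x$rate))
  }
}

#' @importFrom generics glance
#' @method glance transport_fit
#' @export
glance.transport_fit <- function(x, ...) {
  tibble::tibble(type = x$type, adj_r2 = x$adj_r2, n = x$n)
}

time_means <- function(points) {
  agg <- stats::aggregate(intensity ~ time_min,
                          data = points[!is.na(points$intensity), ], FUN = mean)
  stats::setNames(agg$intensity, agg$time_min)
}

#' Fold-change import/export criterion
#'
#' The third calling rule: the compound must show greater than a 3-fold
#' change (in either direction) between 0 and 15 minutes AND greater
#' than a 5-fold change between 0 and 30 minutes, with both changes in
#' the same direction. Fold changes use replicate means and are
#' bidirectional, `max(m_t / m_0, m_0 / m_t)`.
#'
#' @inheritParams fit_linear
#' @param thresholds An [exoflux_thresholds()].
#' @return A list with `fired`, `fc15`, `fc30` and `skipped` (`TRUE`
#'   when the t = 0 mean is zero and the rule cannot be evaluated).
#' @examples
#' pts <- tidyr::expand_grid(time_min = c(0, 5, 15, 30), replicate = 1:3)
#' pts$intensity <- rep(c(1200, 700, 350, 200), each = 3)
#' fold_change_rule(pts)
#' @export
fold_change_rule <- function(points, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  m <- time_means(points)
  need <- c("0", "15", "30")
  if (!all(need %in% names(m))) {
    stop("fold-change rule needs means at t = 0, 15 and 30 min",
         call. = FALSE)
  }
  if (m[["0"]] == 0) {
    return(list(fired = FALSE, fc15 = NA_real_, fc30 = NA_real_,
                skipped = TRUE))
  }
  fc <- function(t) {
    if (m[[t]] == 0) return(Inf)
    max(m[[t]] / m[["0"]], m[["0"]] / m[[t]])
  }
  fc15 <- fc("15")
  fc30 <- fc("30")
  same_dir <- sign(m[["15"]] - m[["0"]]) == sign(m[["30"]] - m[["0"]])
  list(fired = fc15 > th$fc15_min && fc30 > th$fc30_min && same_dir,
       fc15 = fc15, fc30 = fc30, skipped = FALSE)
}

#' Call import/export for one compound time course
#'
#' A compound is called imported or exported if at least one of three
#' criteria fires: (1) a linear fit with adjusted R^2 above
#' `adj_r2_min`; (2) an exponential fit with adjusted R^2 above
#' `adj_r2_min`; or (3) the 3-fold/15-min and 5-fold/30-min fold-change
#' rule. Direction is IMPORT when the 30-min mean is below the 0-min
#' mean, EXPORT otherwise. When serum-only control wells are supplied,
#' the same OR-rule is evaluated on them and
#' `serum_control_also_called` flags compounds whose dynamics are
#' serum-intrinsic (degradation or appearance without cells) rather
#' than cellular transport. Replicate CV above `noisy_cv_max` at any
#' time point sets the `noisy` triage flag.
#'
#' @inheritParams fold_change_rule
#' @param serum_control Optional data frame of serum-only control
#'   points, same shape as `points`.
#' @param feature_id,strain Identifiers carried into the output row.
#' @return A one-row transport-call tibble with the direction, which
#'   criteria fired, all fit statistics and flags.
#' @export
call_transport <- function(points, serum_control = NULL, thresholds = NULL,
                           feature_id = NA_character_,
                           strain = NA_character_) {
  th <- as_thresholds(thresholds)
  pts <- points[!is.na(points$intensity), ]
  fired <- character(0)

  lin <- tryCatch(fit_linear(pts), error = function(e) NULL)
  if (!is.null(lin) && is.finite(lin$adj_r2) && lin$adj_r2 > th$adj_r2_min) {
    fired <- c(fired, "LINEAR")
  }
  expf <- if (all(pts$intensity > 0)) {
    tryCatch(fit_exponential(pts), error = function(e) NULL)
  } else NULL
  if (!is.null(expf) && is.finite(expf$adj_r2) &&
      expf$adj_r2 > th$adj_r2_min) {
    fired <- c(fired, "EXPONENTIAL")
  }
  fcr <- tryCatch(fold_change_rule(pts, th),
                  error = function(e) list(fired = FALSE, fc15 = NA_real_,
                                           fc30 = NA_real_, skipped = TRUE))
  if (isTRUE(fcr$fired)) fired <- c(fired, "FOLD_CHANGE")

  m <- time_means(pts)
  t_first <- names(m)[1]
  t_last <- names(m)[length(m)]
  direction <- if (length(fired) == 0) "NONE" else
    if (m[[t_last]] < m[[t_first]]) "IMPORT" else "EXPORT"

  cv_by_time <- tapply(pts$intensity, pts$time_min,
                       function(v) compute_qc_cv(v))
  noisy <- any(!is.na(cv_by_time) & cv_by_time > th$noisy_cv_max)

  serum_flag <- FALSE
  if (!is.null(serum_control) &&
      sum(!is.na(serum_control$intensity)) >= 3) {
    ctrl <- call_transport(serum_control, serum_control = NULL,
                           thresholds = th)
    serum_flag <- ctrl$direction != "NONE" &&
      (direction == "NONE" || ctrl$direction == direction)
  }

  new_calls(tibble::tibble(
    feature_id = feature_id,
    strain = strain,
    direction = direction,
    criteria_fired = paste(fired, collapse = ";"),
    lin_slope = if (is.null(lin)) NA_real_ else lin$slope,
    lin_intercept = if (is.null(lin)) NA_real_ else lin$intercept,
    lin_adj_r2 = if (is.null(lin)) NA_real_ else lin$adj_r2,
    exp_rate = if (is.null(expf)) NA_real_ else expf$rate,
    exp_amplitude = if (is.null(expf)) NA_real_ else expf$amplitude,
    exp_adj_r2 = if (is.null(expf)) NA_real_ else expf$adj_r2,
    fc15 = fcr$fc15,
    fc30 = fcr$fc30,
    serum_control_also_called = serum_flag,
    noisy = noisy
  ), "transport_calls")
}

#' Transport calls for every compound of one strain
#'
#' Applies [call_transport()] to each feature of a peak matrix for a
#' given strain, using the matrix's serum-only control wells for the
#' serum-intrinsic flag.
#'
#' @param x A raw-scale [peak_matrix].
#' @param strain Strain to call (e.g. `"WT"`).
#' @param thresholds An [exoflux_thresholds()].
#' @return A transport-call tibble, one row per feature.
#' @export
call_strain_transport <- function(x, strain, thresholds = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  th <- as_thresholds(thresholds)
  if (!strain %in% x$samples$strain) {
    stop("strain not present: ", strain, call. = FALSE)
  }
  serum <- pm_serum_strains(x)
  get_pts <- points_factory(x, strain)
  get_ctrl <- if (length(serum) > 0) points_factory(x, serum[1]) else NULL
  calls <- purrr::map(seq_len(n_features(x)), function(i) {
    ctrl <- if (!is.null(get_ctrl)) get_ctrl(i) else NULL
    call_transport(get_pts(i), serum_control = ctrl, thresholds = th,
                   feature_id = x$intensities$feature_id[i], strain = strain)
  })
  out <- new_calls(dplyr::bind_rows(calls), "transport_calls")
  message(sprintf("call_strain_transport: %s: %d/%d compounds called (%d serum-flagged)",
                  strain, sum(out$direction != "NONE"), nrow(out),
                  sum(out$serum_control_also_called)))
  out
}
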