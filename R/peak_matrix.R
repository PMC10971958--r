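#' Peak-area matrix with sample and feature metadata
#'
#' The universal currency between pipeline stages: a features x samples
#' table of LC-MS peak areas plus a sample-metadata table (strain,
#' genotype class, time point, replicate, injection order) and an
#' optional feature-metadata table (neutral mass, retention time).
#'
#' @param intensities Data frame whose first column is `feature_id` and
#'   whose remaining columns are one numeric column per sample, named by
#'   `sample_id`. Missing measurements are `NA` (zeros are legitimate
#'   measurements and are kept as zeros).
#' @param samples Data frame with columns `sample_id`, `strain`,
#'   `genotype_class` (one of WT, KO, OE, SERUM_CONTROL, QC),
#'   `transporter_gene` (empty string when not applicable), `time_min`
#'   (0/5/15/30; `NA` allowed for QC injections), `replicate` and
#'   `injection_order`.
#' @param features Optional data frame with `feature_id` and any of
#'   `neutral_mass` (Da), `rt` (minutes), `polarity`.
#' @param polarity Acquisition polarity of the whole matrix,
#'   `"positive"` or `"negative"`.
#'
#' @return An object of class `peak_matrix`: a list with elements
#'   `intensities`, `samples`, `features`, `polarity` and a `log2` flag.
#' @examples
#' sm <- tibble::tibble(
#'   sample_id = c("s1", "s2"), strain = "WT", genotype_class = "WT",
#'   transporter_gene = "", time_min = c(0, 30), replicate = 1L,
#'   injection_order = 1:2
#' )
#' im <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(1, 2), s2 = c(3, 4))
#' pm <- peak_matrix(im, sm)
#' n_features(pm)
#' @export
peak_matrix <- function(intensities, samples, features = NULL,
                        polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  intensities <- tibble::as_tibble(intensities)
  samples <- tibble::as_tibble(samples)
  if (names(intensities)[1] != "feature_id") {
    stop("first column of `intensities` must be `feature_id`", call. = FALSE)
  }
  need <- c("sample_id", "strain", "genotype_class", "transporter_gene",
            "time_min", "replicate", "injection_order")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(features)) {
    features <- tibble::tibble(feature_id = intensities$feature_id)
  } else {
    features <- tibble::as_tibble(features)
  }
  x <- structure(
    list(intensities = intensities, samples = samples, features = features,
         polarity = polarity, log2 = FALSE),
    class = "peak_matrix"
  )
  validate_peak_matrix(x)
}

genotype_classes <- c("WT", "KO", "OE", "SERUM_CONTROL", "QC")

validate_peak_matrix <- function(x) {
  ints <- x$intensities
  samp <- x$samples
  cols <- names(ints)[-1]
  unknown_cols <- setdiff(cols, samp$sample_id)
  if (length(unknown_cols) > 0) {
    stop("intensity column(s) absent from sample metadata: ",
         paste(unknown_cols, collapse = ", "), call. = FALSE)
  }
  unknown_samp <- setdiff(samp$sample_id, cols)
  if (length(unknown_samp) > 0) {
    stop("sample(s) in metadata without an intensity column: ",
         paste(unknown_samp, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samp$sample_id)) {
    stop("duplicate sample_id in sample metadata", call. = FALSE)
  }
  if (anyDuplicated(ints$feature_id)) {
    stop("duplicate feature_id in intensity table", call. = FALSE)
  }
  bad_class <- setdiff(unique(samp$genotype_class), genotype_classes)
  if (length(bad_class) > 0) {
    stop("unknown genotype_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  non_qc <- samp[samp$genotype_class != "QC", ]
  bad_time <- !non_qc$time_min %in% c(0, 5, 15, 30)
  if (any(bad_time)) {
    stop("time_min must be one of 0/5/15/30 for non-QC samples (sample ",
         non_qc$sample_id[which(bad_time)[1]], ")", call. = FALSE)
  }
  key <- paste(non_qc$strain, non_qc$time_min, non_qc$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (strain, time_min, replicate): ",
         key[which(duplicated(key))[1]], call. = FALSE)
  }
  sc_gene <- samp$transporter_gene[samp$genotype_class == "SERUM_CONTROL"]
  if (any(!is.na(sc_gene) & sc_gene != "")) {
    stop("SERUM_CONTROL samples must have empty transporter_gene",
         call. = FALSE)
  }
  if (!x$log2) {
    for (cn in cols) {
      v <- ints[[cn]]
      if (!is.numeric(v)) stop("intensity column ", cn, " is not numeric",
                               call. = FALSE)
      neg <- which(!is.na(v) & v < 0)
      if (length(neg) > 0) {
        stop(sprintf("negative intensity at feature %s, sample %s",
                     ints$feature_id[neg[1]], cn), call. = FALSE)
      }
    }
  }
  if (!setequal(x$features$feature_id, ints$feature_id)) {
    stop("feature metadata does not match the intensity table's features",
         call. = FALSE)
  }
  x
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d features x %d samples (%s mode%s)\n",
              n_features(x), n_samples(x), x$polarity,
              if (x$log2) ", log2" else ""))
  tab <- table(x$samples$genotype_class)
  cat("  samples: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname peak_matrix
#' @param x A `peak_matrix`.
#' @export
n_features <- function(x) nrow(x$intensities)

#' @rdname peak_matrix
#' @export
n_samples <- function(x) nrow(x$samples)

#' Long (tidy) view of a peak matrix
#'
#' @param x A `peak_matrix`.
#' @return A tibble with one row per (feature, sample) joined with the
#'   sample metadata.
#' @export
pm_long <- function(x) {
  stopifnot(inherits(x, "peak_matrix"))
  tidyr::pivot_longer(x$intensities, -"feature_id",
                      names_to = "sample_id", values_to = "intensity") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

# Intensity vectors for one strain at replicate-level, ordered by
# (time, replicate); returns tibble(time_min, replicate, intensity).
pm_points <- function(x, feature_id, strain) {
  samp <- x$samples[x$samples$strain == strain &
                      x$samples$genotype_class != "QC", ]
  row <- x$intensities[x$intensities$feature_id == feature_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown feature: ", feature_id, call. = FALSE)
  tibble::tibble(
    time_min = samp$time_min,
    replicate = samp$replicate,
    intensity = as.numeric(row[1, samp$sample_id, drop = TRUE])
  ) |> dplyr::arrange(.data$time_min, .data$replicate)
}

# Matrix-backed accessor: returns function(i) giving feature i's
# replicate-level points for one strain. Avoids per-feature tibble
# subsetting when a whole strain is processed.
points_factory <- function(x, strain) {
  samp <- x$samples[x$samples$strain == strain &
                      x$samples$genotype_class != "QC", ]
  samp <- samp[order(samp$time_min, samp$replicate), ]
  mat <- as.matrix(x$intensities[, samp$sample_id, drop = FALSE])
  tm <- samp$time_min
  reps <- samp$replicate
  function(i) tibble::tibble(time_min = tm, replicate = reps,
                             intensity = mat[i, ])
}

# ids of QC pool samples ordered by injection order
pm_qc_samples <- function(x) {
  qc <- x$samples[x$samples$genotype_class == "QC", ]
  qc$sample_id[order(qc$injection_order)]
}

# serum-only control strain name(s)
pm_serum_strains <- function(x) {
  unique(x$samples$strain[x$samples$genotype_class == "SERUM_CONTROL"])
}
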