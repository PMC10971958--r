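#' Read a peak-area matrix from delimited text
#'
#' Reads the three-table representation used throughout: a wide
#' intensity table (first column `feature_id`, one tab-separated column
#' per sample), a sample-metadata table and an optional feature-metadata
#' table. Empty cells are missing measurements; zeros are kept as
#' measured zeros.
#'
#' @param intensity_path Path to the TSV intensity table.
#' @param sample_meta_path Path to the TSV sample-metadata table.
#' @param feature_meta_path Optional path to the TSV feature-metadata
#'   table.
#' @param polarity Acquisition polarity of the matrix.
#' @return A validated [peak_matrix].
#' @export
read_peak_matrix <- function(intensity_path, sample_meta_path,
                             feature_meta_path = NULL,
                             polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  ints <- readr::read_tsv(intensity_path, na = "", show_col_types = FALSE,
                          progress = FALSE)
  samp <- readr::read_tsv(sample_meta_path, na = "NA", show_col_types = FALSE,
                          progress = FALSE)
  if ("transporter_gene" %in% names(samp)) {
    samp$transporter_gene <- dplyr::coalesce(as.character(samp$transporter_gene), "")
  }
  feats <- NULL
  if (!is.null(feature_meta_path)) {
    feats <- readr::read_tsv(feature_meta_path, na = "", show_col_types = FALSE,
                             progress = FALSE)
  }
  peak_matrix(ints, samp, feats, polarity = polarity)
}

#' Write a peak-area matrix to delimited text
#'
#' Inverse of [read_peak_matrix()]: writes `<prefix>_intensities.tsv`,
#' `<prefix>_samples.tsv` and `<prefix>_features.tsv`. Missing
#' intensities become empty cells; numbers use the shortest
#' round-trippable decimal representation, so `read(write(x))`
#' reproduces `x` exactly.
#'
#' @param x A [peak_matrix].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_peak_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "peak_matrix"))
  paths <- paste0(prefix, c("_intensities.tsv", "_samples.tsv",
                            "_features.tsv"))
  readr::write_tsv(x$intensities, paths[1], na = "", progress = FALSE)
  readr::write_tsv(x$samples, paths[2], na = "NA", progress = FALSE)
  readr::write_tsv(x$features, paths[3], na = "", progress = FALSE)
  invisible(paths)
}

call_kinds <- c("transport_calls", "differential_calls",
                "direction_inferences")

new_calls <- function(tbl, kind) {
  kind <- match.arg(kind, call_kinds)
  class(tbl) <- c(kind, "exoflux_calls", class(tibble::tibble()))
  tbl
}

calls_kind <- function(calls) {
  k <- intersect(call_kinds, class(calls))
  if (length(k) != 1) {
    stop("not a transport/differential/direction call table", call. = FALSE)
  }
  k
}

#' Write call tables to TSV
#'
#' Serialises transport calls, differential calls or direction
#' inferences (or a list of tables of one single kind) to a
#' tab-separated file with a stable column order. The written file
#' carries the call kind in a `call_kind` column so [read_calls()] can
#' restore the right class.
#'
#' @param calls A call tibble produced by the pipeline, or a list of
#'   such tibbles of the same kind (they are row-bound). An empty list
#'   is not allowed; an empty tibble yields a header-only file.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  if (is.data.frame(calls)) {
    kind <- calls_kind(calls)
  } else if (is.list(calls) && length(calls) > 0) {
    kinds <- unique(vapply(calls, calls_kind, character(1)))
    if (length(kinds) != 1) {
      stop("mixed call kinds: ", paste(kinds, collapse = ", "), call. = FALSE)
    }
    kind <- kinds
    calls <- dplyr::bind_rows(calls)
  } else {
    stop("`calls` must be a call tibble or a non-empty list of them",
         call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(call_kind = rep(kind, nrow(calls))),
                          tibble::as_tibble(calls))
  if (nrow(out) == 0) out <- out[0, , drop = FALSE]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a call table written by [write_calls()]
#'
#' @param path TSV path.
#' @return The call tibble, with its kind restored from the file.
#' @export
read_calls <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         progress = FALSE)
  if (!"call_kind" %in% names(tbl)) {
    stop("not a call table: no call_kind column in ", path, call. = FALSE)
  }
  kind <- unique(tbl$call_kind)
  if (length(kind) == 0) kind <- "transport_calls"  # header-only file
  if (length(kind) > 1) stop("mixed call kinds in ", path, call. = FALSE)
  tbl$call_kind <- NULL
  for (cn in intersect(names(tbl), c("criteria_fired", "criterion_a_times"))) {
    tbl[[cn]] <- dplyr::coalesce(as.character(tbl[[cn]]), "")
  }
  new_calls(tbl, kind)
}
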