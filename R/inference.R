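#' Classify how a mutant's time course differs from wild type
#'
#' For a compound already selected as differentially transported,
#' compares the net relative change of the replicate means over the 0
#' to 30 minute incubation. When the wild type depletes the compound,
#' a mutant depleting it further is `FASTER_DEPLETION` and one
#' depleting it less is `SLOWER_DEPLETION`; when the wild type
#' accumulates it, the analogous labels are `FASTER_ACCUMULATION` and
#' `SLOWER_ACCUMULATION`. A flat wild type defers to the sign of the
#' mutant's own change.
#'
#' @param call A one-row selected differential call (from
#'   [select_differential()]). Its `change_wt`/`change_mut` columns are
#'   used when present; otherwise supply the time courses.
#' @param wt_points,mut_points Optional replicate-level time courses
#'   used to (re)compute the net changes.
#' @return A one-row evidence tibble: `feature_id`, `genotype_class`,
#'   `effect`.
#' @export
classify_effect <- function(call, wt_points = NULL, mut_points = NULL) {
  if (nrow(call) != 1) stop("classify_effect takes a single call",
                            call. = FALSE)
  if (!isTRUE(call$selected)) {
    stop("classify_effect requires a selected differential call",
         call. = FALSE)
  }
  c_wt <- call$change_wt
  c_mut <- call$change_mut
  if ((is.null(c_wt) || is.na(c_wt)) && !is.null(wt_points)) {
    m <- time_means(wt_points)
    c_wt <- (m[["30"]] - m[["0"]]) / m[["0"]]
  }
  if ((is.null(c_mut) || is.na(c_mut)) && !is.null(mut_points)) {
    m <- time_means(mut_points)
    c_mut <- (m[["30"]] - m[["0"]]) / m[["0"]]
  }
  if (is.null(c_wt) || is.null(c_mut) || is.na(c_wt) || is.na(c_mut)) {
    stop("cannot determine net changes; supply time courses", call. = FALSE)
  }
  effect <- if (c_mut == c_wt) {
    "NONE"
  } else if (c_wt < 0) {
    if (c_mut < c_wt) "FASTER_DEPLETION" else "SLOWER_DEPLETION"
  } else if (c_wt > 0) {
    if (c_mut > c_wt) "FASTER_ACCUMULATION" else "SLOWER_ACCUMULATION"
  } else {
    if (c_mut < 0) "FASTER_DEPLETION" else "FASTER_ACCUMULATION"
  }
  tibble::tibble(feature_id = call$feature_id,
                 genotype_class = call$genotype_class,
                 effect = effect)
}

# Transport direction implied by one evidence item under the simple
# transporter model (OE enhances the transporter's own function, KO
# impairs it); NA when the sign contradicts that model.
implied_direction <- function(genotype_class, effect) {
  if (is.na(effect) || effect == "NONE") return(NA_character_)
  if (genotype_class == "OE") {
    switch(effect,
           FASTER_DEPLETION = "UPTAKE",
           FASTER_ACCUMULATION = "EXPORT",
           NA_character_)
  } else if (genotype_class == "KO") {
    switch(effect,
           SLOWER_DEPLETION = "UPTAKE",
           SLOWER_ACCUMULATION = "EXPORT",
           NA_character_)
  } else {
    NA_character_
  }
}

#' Merge knockout and overexpression evidence into a direction verdict
#'
#' The convergence ("dual validation") logic: overexpression evidence
#' of faster depletion together with knockout evidence of slower
#' depletion converges on uptake (`UPTAKE_CONVERGED`); faster
#' accumulation under overexpression with slower accumulation under
#' knockout converges on export (`EXPORT_CONVERGED`). A single
#' model-consistent evidence item yields `UPTAKE_SINGLE` or
#' `EXPORT_SINGLE`; contradictory or model-inconsistent evidence
#' yields `AMBIGUOUS`; no evidence yields `NONE`. Converged verdicts
#' outrank single ones, which outrank ambiguous.
#'
#' @param oe,ko Optional one-row evidence tibbles from
#'   [classify_effect()] for the overexpression and knockout mutants.
#' @param feature_id,transporter_gene Identifiers for the output row.
#' @return A one-row direction-inference tibble: `feature_id`,
#'   `transporter_gene`, `oe_effect`, `ko_effect`, `verdict`,
#'   `confidence_rank` (1 converged, 2 single, 3 ambiguous, 4 none).
#' @examples
#' oe <- tibble::tibble(feature_id = "f", genotype_class = "OE",
#'                      effect = "FASTER_DEPLETION")
#' ko <- tibble::tibble(feature_id = "f", genotype_class = "KO",
#'                      effect = "SLOWER_DEPLETION")
#' infer_direction(oe, ko, transporter_gene = "yeaV")$verdict
#' @export
infer_direction <- function(oe = NULL, ko = NULL,
                            feature_id = NULL, transporter_gene = "") {
  oe_effect <- if (!is.null(oe)) oe$effect else NA_character_
  ko_effect <- if (!is.null(ko)) ko$effect else NA_character_
  if (is.null(feature_id)) {
    feature_id <- if (!is.null(oe)) oe$feature_id else
      if (!is.null(ko)) ko$feature_id else NA_character_
  }
  dir_oe <- if (!is.null(oe)) implied_direction("OE", oe_effect) else NULL
  dir_ko <- if (!is.null(ko)) implied_direction("KO", ko_effect) else NULL

  verdict <- if (is.null(dir_oe) && is.null(dir_ko)) {
    "NONE"
  } else if (!is.null(dir_oe) && !is.null(dir_ko)) {
    if (!is.na(dir_oe) && !is.na(dir_ko) && dir_oe == dir_ko) {
      paste0(dir_oe, "_CONVERGED")
    } else {
      "AMBIGUOUS"
    }
  } else {
    d <- if (!is.null(dir_oe)) dir_oe else dir_ko
    if (is.na(d)) "AMBIGUOUS" else paste0(d, "_SINGLE")
  }
  rank <- switch(verdict,
                 UPTAKE_CONVERGED = 1L, EXPORT_CONVERGED = 1L,
                 UPTAKE_SINGLE = 2L, EXPORT_SINGLE = 2L,
                 AMBIGUOUS = 3L, NONE = 4L)
  new_calls(tibble::tibble(
    feature_id = feature_id,
    transporter_gene = transporter_gene,
    oe_effect = oe_effect,
    ko_effect = ko_effect,
    verdict = verdict,
    confidence_rank = rank
  ), "direction_inferences")
}

#' Infer candidate substrates of one transporter
#'
#' Runs the full mutant-contrast analysis for a transporter gene:
#' selects compounds transported differently in its knockout and
#' overexpression strains versus wild type, classifies each selected
#' effect, and merges the two genotypes into a per-compound direction
#' verdict. Compounds whose wild-type time course is flagged as
#' serum-intrinsic (the same calling rule fires on the serum-only
#' control wells) are excluded by default, since their dynamics are not
#' cellular transport.
#'
#' @param x A raw-scale [peak_matrix].
#' @param gene Transporter gene; its mutants are `<gene>_KO` and
#'   `<gene>_OE` (whichever is present in the matrix).
#' @param wt Wild-type strain name.
#' @param thresholds An [exoflux_thresholds()].
#' @param exclude_serum_flagged Drop serum-intrinsic compounds.
#' @return A direction-inference tibble (compounds with a non-`NONE`
#'   verdict plus, for completeness, `NONE` rows for unselected
#'   compounds are omitted — only compounds with at least one selected
#'   mutant call are returned).
#' @export
infer_transporter <- function(x, gene, wt = "WT", thresholds = NULL,
                              exclude_serum_flagged = TRUE) {
  stopifnot(inherits(x, "peak_matrix"))
  th <- as_thresholds(thresholds)
  strains <- x$samples$strain
  ko_strain <- paste0(gene, "_KO")
  oe_strain <- paste0(gene, "_OE")
  has_ko <- ko_strain %in% strains
  has_oe <- oe_strain %in% strains
  if (!has_ko && !has_oe) {
    stop("no mutant strains found for gene ", gene, call. = FALSE)
  }
  ko_calls <- if (has_ko) select_differential(x, wt, ko_strain, th) else NULL
  oe_calls <- if (has_oe) select_differential(x, wt, oe_strain, th) else NULL

  excluded <- character(0)
  if (exclude_serum_flagged) {
    wt_calls <- call_strain_transport(x, wt, th)
    excluded <- wt_calls$feature_id[wt_calls$serum_control_also_called]
  }

  feats <- unique(c(
    if (!is.null(ko_calls)) ko_calls$feature_id[ko_calls$selected],
    if (!is.null(oe_calls)) oe_calls$feature_id[oe_calls$selected]
  ))
  feats <- setdiff(feats, excluded)
  rows <- purrr::map(feats, function(f) {
    ko_ev <- NULL
    oe_ev <- NULL
    if (!is.null(ko_calls)) {
      kc <- ko_calls[ko_calls$feature_id == f, ]
      if (isTRUE(kc$selected)) ko_ev <- classify_effect(kc)
    }
    if (!is.null(oe_calls)) {
      oc <- oe_calls[oe_calls$feature_id == f, ]
      if (isTRUE(oc$selected)) oe_ev <- classify_effect(oc)
    }
    infer_direction(oe = oe_ev, ko = ko_ev, feature_id = f,
                    transporter_gene = gene)
  })
  out <- if (length(rows) == 0) {
    new_calls(tibble::tibble(
      feature_id = character(0), transporter_gene = character(0),
      oe_effect = character(0), ko_effect = character(0),
      verdict = character(0), confidence_rank = integer(0)
    ), "direction_inferences")
  } else {
    new_calls(dplyr::bind_rows(rows), "direction_inferences")
  }
  message(sprintf("infer_transporter: %s: %d candidate compounds (%d converged, %d excluded as serum-intrinsic)",
                  gene, nrow(out), sum(out$confidence_rank == 1),
                  length(excluded)))
  out
}

#' Exclusive intersection counts across mutant compound sets
#'
#' UpSet-style summary: for every non-empty subset of mutants, the
#' number of compounds present in all sets of that subset and in none
#' of the others. The exclusive counts partition the union, so they sum
#' to its size.
#'
#' @param sets Named list of character vectors of feature ids, one per
#'   mutant.
#' @return A tibble with `members` (mutant names joined by `"&"`),
#'   `degree` and `count`, ordered by degree then count.
#' @examples
#' convergence_sets(list(A = c("x", "y"), B = c("y", "z")))
#' @export
convergence_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0 || is.null(names(sets)) ||
      any(names(sets) == "")) {
    stop("`sets` must be a non-empty named list", call. = FALSE)
  }
  nm <- names(sets)
  n <- length(nm)
  if (n > 20) stop("too many sets for exhaustive enumeration", call. = FALSE)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, nm))
  subsets <- seq_len(2^n - 1)
  rows <- purrr::map(subsets, function(bits) {
    inset <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1)))
    cnt <- if (length(universe) == 0) 0L else
      sum(apply(member, 1, function(r) all(r == inset)))
    tibble::tibble(members = paste(nm[inset], collapse = "&"),
                   degree = sum(inset), count = as.integer(cnt))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$degree, dplyr::desc(.data$count))
}

#' Score inferred substrates against simulation ground truth
#'
#' Validation harness for simulated data: positives are features with a
#' non-`NONE` verdict; a positive is true when the feature is truly
#' IMPORTED or EXPORTED and is affected by the transporter whose
#' contrast called it. Direction accuracy is computed over true
#' transported features of the inferred transporter(s) that received a
#' non-`NONE` verdict: an uptake verdict must meet an IMPORTED truth
#' and an export verdict an EXPORTED truth (AMBIGUOUS counts as
#' incorrect).
#'
#' @param inferences A direction-inference tibble (possibly several
#'   transporters row-bound).
#' @param truth Ground-truth tibble from [simulate_serum_experiment()].
#' @return A one-row tibble: `precision`, `recall`, `f1`,
#'   `direction_accuracy`, `n_called`, `n_true`.
#' @export
score_recovery <- function(inferences, truth) {
  if (is.null(truth) || nrow(truth) == 0) stop("empty ground truth",
                                               call. = FALSE)
  inf <- tibble::as_tibble(inferences)
  genes <- unique(inf$transporter_gene)
  true_pos <- truth[truth$true_class %in% c("IMPORTED", "EXPORTED") &
                      truth$affected_gene %in% genes, ]
  called <- inf[inf$verdict != "NONE", ]
  joined <- dplyr::left_join(called, truth, by = "feature_id")
  tp <- sum(joined$true_class %in% c("IMPORTED", "EXPORTED") &
              joined$affected_gene == joined$transporter_gene, na.rm = TRUE)
  precision <- if (nrow(called) > 0) tp / nrow(called) else NA_real_
  recall <- if (nrow(true_pos) > 0) tp / nrow(true_pos) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  dir_rows <- joined[!is.na(joined$true_class) &
                       joined$true_class %in% c("IMPORTED", "EXPORTED") &
                       joined$affected_gene == joined$transporter_gene, ]
  dir_ok <- (dir_rows$true_class == "IMPORTED" &
               dir_rows$verdict %in% c("UPTAKE_CONVERGED", "UPTAKE_SINGLE")) |
    (dir_rows$true_class == "EXPORTED" &
       dir_rows$verdict %in% c("EXPORT_CONVERGED", "EXPORT_SINGLE"))
  direction_accuracy <- if (nrow(dir_rows) > 0) mean(dir_ok) else NA_real_
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 direction_accuracy = direction_accuracy,
                 n_called = nrow(called), n_true = nrow(true_pos))
}
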