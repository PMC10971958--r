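sel_call <- function(change_wt, change_mut, genotype_class = "OE",
                     feature_id = "f1") {
  tibble::tibble(feature_id = feature_id, genotype_class = genotype_class,
                 selected = TRUE, change_wt = change_wt,
                 change_mut = change_mut)
}

test_that("effects compare mutant and wild-type net changes", {
  expect_equal(classify_effect(sel_call(-0.4, -0.8))$effect,
               "FASTER_DEPLETION")
  expect_equal(classify_effect(sel_call(-0.4, -0.1, "KO"))$effect,
               "SLOWER_DEPLETION")
  expect_equal(classify_effect(sel_call(1, 3))$effect,
               "FASTER_ACCUMULATION")
  expect_equal(classify_effect(sel_call(2, 0.5, "KO"))$effect,
               "SLOWER_ACCUMULATION")
  unsel <- sel_call(-0.4, -0.8)
  unsel$selected <- FALSE
  expect_error(classify_effect(unsel), "selected")
})

test_that("KO/OE evidence merges into converged, single, ambiguous or none", {
  oe_fast <- tibble::tibble(feature_id = "f", genotype_class = "OE",
                            effect = "FASTER_DEPLETION")
  ko_slow <- tibble::tibble(feature_id = "f", genotype_class = "KO",
                            effect = "SLOWER_DEPLETION")
  oe_acc <- tibble::tibble(feature_id = "f", genotype_class = "OE",
                           effect = "FASTER_ACCUMULATION")
  ko_sacc <- tibble::tibble(feature_id = "f", genotype_class = "KO",
                            effect = "SLOWER_ACCUMULATION")
  ko_fast <- tibble::tibble(feature_id = "f", genotype_class = "KO",
                            effect = "FASTER_DEPLETION")

  expect_equal(infer_direction(oe_fast, ko_slow)$verdict, "UPTAKE_CONVERGED")
  expect_equal(infer_direction(oe_acc, ko_sacc)$verdict, "EXPORT_CONVERGED")
  expect_equal(infer_direction(oe_fast, NULL)$verdict, "UPTAKE_SINGLE")
  expect_equal(infer_direction(NULL, ko_sacc)$verdict, "EXPORT_SINGLE")
  expect_equal(infer_direction(oe_fast, ko_fast)$verdict, "AMBIGUOUS")
  expect_equal(infer_direction(NULL, NULL, feature_id = "f")$verdict, "NONE")

  # ranking encodes dual validation: converged beats single beats ambiguous
  expect_lt(infer_direction(oe_fast, ko_slow)$confidence_rank,
            infer_direction(oe_fast, NULL)$confidence_rank)
  expect_lt(infer_direction(oe_fast, NULL)$confidence_rank,
            infer_direction(oe_fast, ko_fast)$confidence_rank)
})

test_that("swapping KO and OE evidence never reproduces a converged verdict", {
  effects <- c("FASTER_DEPLETION", "SLOWER_DEPLETION",
               "FASTER_ACCUMULATION", "SLOWER_ACCUMULATION")
  for (oe_eff in effects) {
    for (ko_eff in effects) {
      oe <- tibble::tibble(feature_id = "f", genotype_class = "OE",
                           effect = oe_eff)
      ko <- tibble::tibble(feature_id = "f", genotype_class = "KO",
                           effect = ko_eff)
      v <- infer_direction(oe, ko)$verdict
      sw <- infer_direction(
        oe = dplyr::mutate(ko, genotype_class = "OE"),
        ko = dplyr::mutate(oe, genotype_class = "KO")
      )$verdict
      if (grepl("CONVERGED", v)) expect_false(identical(sw, v))
      # dropping one item demotes but never flips the direction
      single <- infer_direction(oe, NULL)$verdict
      if (grepl("UPTAKE", v)) expect_false(grepl("EXPORT", single))
    }
  }
})

test_that("exclusive intersections match brute force and partition the union", {
  out <- convergence_sets(list(A = c("x", "y"), B = c("y", "z")))
  g <- function(m) out$count[out$members == m]
  expect_equal(g("A"), 1L)
  expect_equal(g("B"), 1L)
  expect_equal(g("A&B"), 1L)

  disj <- convergence_sets(list(A = c("a", "b"), B = c("c"), C = character(0)))
  expect_equal(disj$count[disj$members == "A&B"], 0L)
  expect_equal(disj$count[disj$members == "A&B&C"], 0L)

  withr::local_seed(61)
  for (rep in 1:5) {
    nm <- LETTERS[1:4]
    sets <- lapply(nm, function(i) {
      sample(paste0("m", 1:30), sample(0:15, 1))
    })
    names(sets) <- nm
    out <- convergence_sets(sets)
    expect_equal(sum(out$count), length(unique(unlist(sets))))
    # brute-force oracle: membership-profile enumeration per element
    universe <- unique(unlist(sets))
    for (k in seq_len(nrow(out))) {
      members <- strsplit(out$members[k], "&", fixed = TRUE)[[1]]
      cnt <- sum(vapply(universe, function(el) {
        inside <- vapply(nm, function(s) el %in% sets[[s]], logical(1))
        all(inside[nm %in% members]) && !any(inside[!nm %in% members])
      }, logical(1)))
      expect_equal(out$count[k], cnt)
    }
    # invariant to the order the mutants are given in
    perm <- sample(nm)
    out2 <- convergence_sets(sets[perm])
    key <- function(tb) {
      sorted <- vapply(strsplit(tb$members, "&", fixed = TRUE),
                       function(v) paste(sort(v), collapse = "&"),
                       character(1))
      setNames(tb$count, sorted)
    }
    k1 <- key(out)
    expect_equal(unname(k1[names(key(out2))]), unname(key(out2)))
  }
})

test_that("recovery scoring handles perfect, empty and mixed inference sets", {
  truth <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    true_class = c("IMPORTED", "EXPORTED", "INERT"),
    baseline = 1e5, rate_wt = c(0.05, 0.1, 0),
    affected_gene = c("yeaV", "yeaV", ""), oe_factor = 3, ko_factor = 0.3
  )
  perfect <- exoflux:::new_calls(tibble::tibble(
    feature_id = c("f1", "f2"), transporter_gene = "yeaV",
    oe_effect = c("FASTER_DEPLETION", "FASTER_ACCUMULATION"),
    ko_effect = c("SLOWER_DEPLETION", "SLOWER_ACCUMULATION"),
    verdict = c("UPTAKE_CONVERGED", "EXPORT_CONVERGED"),
    confidence_rank = 1L
  ), "direction_inferences")
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$direction_accuracy, 1)

  none <- perfect
  none$verdict <- "NONE"
  sc0 <- score_recovery(none, truth)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))

  wrong_dir <- perfect
  wrong_dir$verdict <- c("EXPORT_CONVERGED", "EXPORT_CONVERGED")
  expect_equal(score_recovery(wrong_dir, truth)$direction_accuracy, 0.5)
  expect_error(score_recovery(perfect, truth[0, ]), "empty")
})

test_that("the whole contrast pipeline recovers a transporter's substrates", {
  sim <- small_sim(seed = 62)
  inf <- suppressMessages(infer_transporter(sim$matrix, "yeaV"))
  expect_s3_class(inf, "direction_inferences")
  sc <- score_recovery(inf, sim$truth)
  expect_gte(sc$recall, 0.8)
  expect_gte(sc$direction_accuracy, 0.8)
  expect_error(infer_transporter(sim$matrix, "notagene"), "no mutant")
})
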