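test_that("QC CV follows the sd/mean definition and its edge cases", {
  expect_equal(compute_qc_cv(c(100, 100, 100)), 0)
  expect_equal(compute_qc_cv(c(90, 100, 110)), 10)
  expect_true(is.na(compute_qc_cv(c(5))))
  expect_true(is.na(compute_qc_cv(c(-10, 10))))  # mean <= 0 undefined
  withr::local_seed(7)
  sigma <- sqrt(log(1 + 0.3^2))
  draws <- exp(rnorm(10000, 0, sigma))  # lognormal at 30% CV
  expect_lt(abs(compute_qc_cv(draws) - 30), 1)
})

test_that("flat QC trend leaves the matrix unchanged; too few QCs pass through flagged", {
  sim <- small_sim(seed = 21, noise_cv = 0, drift_amplitude = 0)
  m <- sim$matrix
  out <- suppressMessages(loess_qc_correct(m))
  ids <- m$samples$sample_id
  expect_equal(as.matrix(out$intensities[, ids]),
               as.matrix(m$intensities[, ids]), tolerance = 1e-9)
  expect_true(all(out$features$qc_corrected))

  # knock a feature below min_qc_count non-missing QC values
  qc_ids <- m$samples$sample_id[m$samples$genotype_class == "QC"]
  m2 <- m
  m2$intensities[1, qc_ids[-(1:3)]] <- NA
  out2 <- suppressMessages(loess_qc_correct(m2))
  expect_false(out2$features$qc_corrected[1])
  expect_equal(as.numeric(out2$intensities[1, ids[1:5]]),
               as.numeric(m2$intensities[1, ids[1:5]]))
})

test_that("correction removes a linear drift from most features", {
  sim <- small_sim(seed = 22, noise_cv = 5, drift_amplitude = 0)
  m <- sim$matrix
  n_inj <- nrow(m$samples)
  ramp <- 1 + (m$samples$injection_order - 1) / (n_inj - 1)  # 1.0 -> 2.0
  ids <- m$samples$sample_id
  drifted <- as.matrix(m$intensities[, ids])
  drifted <- sweep(drifted, 2, ramp, `*`)
  m$intensities[, ids] <- tibble::as_tibble(drifted)
  out <- suppressMessages(loess_qc_correct(m))
  improved <- out$features$qc_cv < out$features$qc_cv_raw
  expect_gte(mean(improved), 0.95)
  expect_lt(median(out$features$qc_cv), median(out$features$qc_cv_raw))
})

test_that("correction is scale-equivariant and errors without QC samples", {
  sim <- small_sim(seed = 23, noise_cv = 5)
  m <- sim$matrix
  ids <- m$samples$sample_id
  m10 <- m
  m10$intensities[, ids] <- tibble::as_tibble(
    as.matrix(m$intensities[, ids]) * 10
  )
  a <- suppressMessages(loess_qc_correct(m))
  b <- suppressMessages(loess_qc_correct(m10))
  expect_equal(as.matrix(b$intensities[, ids]),
               as.matrix(a$intensities[, ids]) * 10, tolerance = 1e-9)

  no_qc <- m
  keep <- m$samples$genotype_class != "QC"
  no_qc$samples <- m$samples[keep, ]
  no_qc$intensities <- m$intensities[, c("feature_id",
                                         m$samples$sample_id[keep])]
  no_qc$features <- m$features
  expect_error(loess_qc_correct(no_qc), "no QC samples")
})

test_that("deduplication groups by mass and retention time and respects the CV filter", {
  sim <- small_sim(seed = 24)
  m <- suppressMessages(loess_qc_correct(sim$matrix))
  # construct a controlled feature table: two near-duplicates, one far
  m$features$neutral_mass <- seq(100, 100 + (n_features(m) - 1) * 10, by = 10)
  m$features$rt <- rep(5, n_features(m))
  m$features$neutral_mass[2] <- m$features$neutral_mass[1] * (1 + 1e-6) # 1 ppm
  m$features$qc_cv <- rep(5, n_features(m))
  out <- dedupe_features(m)
  expect_equal(out$cluster_id[1], out$cluster_id[2])
  expect_equal(sum(out$is_unique_representative[1:2]), 1)
  # all remaining masses are >= 100 ppm apart: all representatives
  expect_true(all(out$is_unique_representative[-(1:2)]))

  # a feature above the CV cap is excluded from uniqueness entirely
  m$features$qc_cv[5] <- 35
  out2 <- dedupe_features(m)
  expect_false(out2$qc_pass[5])
  expect_false(out2$is_unique_representative[5])
  expect_true(is.na(out2$cluster_id[5]))
})

test_that("deduplication does not depend on feature order", {
  sim <- small_sim(seed = 25)
  m <- suppressMessages(loess_qc_correct(sim$matrix))
  withr::local_seed(1)
  m$features$neutral_mass <- round(runif(n_features(m), 100, 110), 4)
  m$features$rt <- round(runif(n_features(m), 4.9, 5.1), 3)
  reps1 <- sort(dedupe_features(m)$feature_id[
    dedupe_features(m)$is_unique_representative])
  perm <- sample(n_features(m))
  m2 <- m
  m2$intensities <- m$intensities[perm, ]
  m2$features <- m$features[perm, ]
  out2 <- dedupe_features(m2)
  expect_equal(sort(out2$feature_id[out2$is_unique_representative]), reps1)
})

test_that("log2 transform imputes half-minimum and restores clean values", {
  m <- tiny_matrix(3, reps = 1, fill = function(n) c(8, 4, NA))
  m$intensities$WT_t00_r1 <- c(8, 0, NA)
  m$intensities$WT_t30_r1 <- c(8, 16, NA)
  out <- suppressMessages(log2_transform(m))
  expect_equal(as.numeric(out$intensities[1, -1]), c(3, 3))
  # 0 imputed with half of the minimum positive value (16/2 = 8 -> log2 = 3)
  expect_equal(as.numeric(out$intensities[2, -1]), c(3, 4))
  # all-missing feature dropped
  expect_equal(nrow(out$intensities), 2)
  expect_true(out$log2)

  sim <- small_sim(seed = 26)
  lg <- suppressMessages(log2_transform(sim$matrix))
  ids <- lg$samples$sample_id
  expect_equal(as.matrix(2^lg$intensities[, ids]),
               as.matrix(sim$matrix$intensities[, ids]), tolerance = 1e-12)
  expect_error(log2_transform(lg), "already")
})
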