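# Shared fixture builders: everything is generated in code.

# Replicate-level time-course points from per-time means (exact, no noise)
# or from a matrix of replicate values (rows = times).
make_points <- function(times, means = NULL, values = NULL, reps = 3) {
  if (!is.null(values)) {
    stopifnot(length(times) == nrow(values))
    return(tibble::tibble(
      time_min = rep(times, each = ncol(values)),
      replicate = rep(seq_len(ncol(values)), length(times)),
      intensity = as.vector(t(values))
    ))
  }
  tibble::tibble(
    time_min = rep(times, each = reps),
    replicate = rep(seq_len(reps), length(times)),
    intensity = rep(means, each = reps)
  )
}

# Minimal valid peak matrix: n_feat features, WT at 0/30 min with `reps`
# replicates, values drawn from `fill` (a function of n) or constant.
tiny_matrix <- function(n_feat = 3, reps = 1, fill = function(n) seq_len(n)) {
  grid <- expand.grid(time_min = c(0, 30), replicate = seq_len(reps))
  samples <- tibble::tibble(
    sample_id = sprintf("WT_t%02d_r%d", grid$time_min, grid$replicate),
    strain = "WT", genotype_class = "WT", transporter_gene = "",
    time_min = grid$time_min, replicate = as.integer(grid$replicate),
    injection_order = seq_len(nrow(grid))
  )
  ints <- tibble::tibble(feature_id = sprintf("f%02d", seq_len(n_feat)))
  for (sid in samples$sample_id) ints[[sid]] <- fill(n_feat)
  peak_matrix(ints, samples)
}

# Small simulated experiment shared by several tests.
small_sim <- function(seed = 42, ...) {
  simulate_serum_experiment(sim_config(
    n_imported = 6, n_exported = 6, n_serum_degrading = 3,
    n_serum_appearing = 3, n_inert = 22,
    strains = tibble::tibble(gene = "yeaV", has_ko = TRUE, has_oe = TRUE),
    seed = seed, ...
  ))
}

# Closed-form OLS oracle via normal equations, independent of lm().
ols_oracle <- function(x, y, p = 1) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  n <- length(y)
  list(intercept = beta[1], slope = beta[2],
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# Textbook paired t-test oracle.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(t_stat), df = n - 1)
}

# Textbook Welch t-test oracle (unequal variances).
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df = df)
}
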