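test_that("an exact line fits with slope -2 and perfect adjusted R^2", {
  pts <- tibble::tibble(time_min = c(0, 5, 15, 30),
                        intensity = c(100, 90, 70, 40))
  fit <- fit_linear(pts)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$intercept, 100, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate, c(100, -2), tolerance = 1e-12)
  # constant intensity carries no time trend
  flat <- tibble::tibble(time_min = c(0, 5, 15, 30), intensity = rep(7, 4))
  expect_lte(fit_linear(flat)$adj_r2, 0)
  expect_error(fit_linear(tibble::tibble(time_min = rep(5, 4),
                                         intensity = 1:4)), "time")
})

test_that("linear and exponential fits match closed-form oracles", {
  withr::local_seed(41)
  t <- rep(c(0, 5, 15, 30), each = 3)
  y <- 1000 - 12 * t + rnorm(12, 0, 30)
  fit <- fit_linear(tibble::tibble(time_min = t, intensity = y))
  oracle <- ols_oracle(t, y, p = 1)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$adj_r2, oracle$adj_r2, tolerance = 1e-10)

  ye <- 1000 * exp(-0.05 * t) * exp(rnorm(12, 0, 0.05))
  efit <- fit_exponential(tibble::tibble(time_min = t, intensity = ye))
  eo <- ols_oracle(t, log(ye), p = 1)  # log-space parameters
  expect_equal(efit$rate, eo$slope, tolerance = 1e-10)
  expect_equal(efit$amplitude, exp(eo$intercept), tolerance = 1e-8)
  # adjusted R^2 is defined on the raw intensity scale with p = 2
  yhat <- exp(eo$intercept + eo$slope * t)
  r2 <- 1 - sum((ye - yhat)^2) / sum((ye - mean(ye))^2)
  expect_equal(efit$adj_r2, 1 - (1 - r2) * 11 / 9, tolerance = 1e-10)
})

test_that("an exact exponential decays with perfect fit; exact line is not exponential", {
  t <- c(0, 5, 15, 30)
  pts <- tibble::tibble(time_min = t, intensity = 1000 * exp(-0.05 * t))
  fit <- fit_exponential(pts)
  expect_equal(fit$rate, -0.05, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  lin <- tibble::tibble(time_min = t, intensity = 1000 - 30 * t)
  expect_lt(fit_exponential(lin)$adj_r2, 1)
  expect_error(fit_exponential(tibble::tibble(time_min = t,
                                              intensity = c(-1, 1, 2, 3))),
               "positive")
})

test_that("the fold-change rule needs >3x at 15 min and >5x at 30 min in one direction", {
  fired <- fold_change_rule(make_points(c(0, 5, 15, 30),
                                        means = c(1200, 700, 350, 200)))
  expect_true(fired$fired)
  expect_equal(fired$fc15, 1200 / 350, tolerance = 1e-12)
  expect_equal(fired$fc30, 6, tolerance = 1e-12)

  not <- fold_change_rule(make_points(c(0, 15, 30),
                                      means = c(1000, 400, 250)))
  expect_false(not$fired)  # fc15 = 2.5 misses the 3-fold bar
  expect_equal(not$fc15, 2.5, tolerance = 1e-12)

  up <- fold_change_rule(make_points(c(0, 15, 30),
                                     means = c(100, 350, 600)))
  expect_true(up$fired)    # increases count too: fc15 = 3.5, fc30 = 6

  # opposite directions at 15 and 30 min never fire
  swing <- fold_change_rule(make_points(c(0, 15, 30),
                                        means = c(100, 350, 10)))
  expect_false(swing$fired)
})

test_that("calls combine criteria with OR and direction follows the net change", {
  t <- c(0, 5, 15, 30)
  decay <- make_points(t, means = 1000 * exp(-log(5) / 30 * t))
  call <- call_transport(decay, feature_id = "f", strain = "WT")
  expect_equal(call$direction, "IMPORT")
  expect_true(grepl("EXPONENTIAL", call$criteria_fired))

  up <- call_transport(make_points(t, means = c(100, 200, 350, 600)))
  expect_equal(up$direction, "EXPORT")

  flat <- call_transport(make_points(t, means = rep(500, 4)))
  expect_equal(flat$direction, "NONE")
  expect_equal(flat$criteria_fired, "")
})

test_that("reversing a fold-change time course flips IMPORT and EXPORT", {
  t <- c(0, 5, 15, 30)
  means <- c(1200, 700, 350, 200)
  fwd <- call_transport(make_points(t, means = means))
  rev <- call_transport(make_points(t, means = rev(means)))
  expect_equal(fwd$direction, "IMPORT")
  expect_equal(rev$direction, "EXPORT")
  expect_true(grepl("FOLD_CHANGE", fwd$criteria_fired))
  expect_true(grepl("FOLD_CHANGE", rev$criteria_fired))
})

test_that("calls are invariant to a global intensity rescaling", {
  withr::local_seed(42)
  t <- c(0, 5, 15, 30)
  for (i in 1:10) {
    vals <- matrix(1000 * exp(-runif(1, 0, 0.08) * rep(t, 3)) *
                     exp(rnorm(12, 0, 0.1)), nrow = 4)
    pts <- make_points(t, values = vals)
    scaled <- pts
    scaled$intensity <- scaled$intensity * 137.5
    a <- call_transport(pts)
    b <- call_transport(scaled)
    expect_equal(a$criteria_fired, b$criteria_fired)
    expect_equal(a$direction, b$direction)
  }
})

test_that("flat noisy compounds are almost never called", {
  withr::local_seed(43)
  t <- c(0, 5, 15, 30)
  n_called <- 0
  for (i in 1:1000) {
    vals <- matrix(500 * exp(rnorm(12, 0, 0.0998)), nrow = 4)  # ~10% CV
    if (call_transport(make_points(t, values = vals))$direction != "NONE") {
      n_called <- n_called + 1
    }
  }
  expect_lte(n_called / 1000, 0.01)
})

test_that("serum-driven dynamics are flagged, noisy replicates are flagged", {
  t <- c(0, 5, 15, 30)
  decay <- 1000 * exp(-0.06 * t)
  call <- call_transport(make_points(t, means = decay),
                         serum_control = make_points(t, means = decay))
  expect_true(call$serum_control_also_called)
  inert_ctrl <- call_transport(make_points(t, means = decay),
                               serum_control = make_points(t, means = rep(980, 4)))
  expect_false(inert_ctrl$serum_control_also_called)

  noisy_vals <- matrix(c(100, 500, 900, rep(500, 9)), nrow = 4, byrow = TRUE)
  expect_true(call_transport(make_points(t, values = noisy_vals))$noisy)

  # simulated serum-degrading compounds carry the flag in almost all cases
  n_flagged <- 0
  n_called <- 0
  for (seed in 1:3) {
    sim <- simulate_serum_experiment(sim_config(
      n_imported = 0, n_exported = 0, n_serum_degrading = 15,
      n_serum_appearing = 15, n_inert = 0, drift_amplitude = 0,
      seed = seed
    ))
    calls <- suppressMessages(call_strain_transport(sim$matrix, "WT"))
    called <- calls$direction != "NONE"
    n_called <- n_called + sum(called)
    n_flagged <- n_flagged + sum(calls$serum_control_also_called[called])
  }
  expect_gte(n_flagged / n_called, 0.95)
})
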