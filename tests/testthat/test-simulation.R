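test_that("effect vectors have the configured counts, signs and floor", {
  sc1 <- benchmark_scenario("sim1", seed = 61)
  d <- make_effect_vector(sc1)
  expect_length(d, 10000L)
  expect_equal(sum(d > 0), 363L)
  expect_equal(sum(d < 0), 637L)
  expect_true(all(abs(d[d != 0]) >= sc1$effect_floor))
  expect_identical(d, make_effect_vector(sc1))  # reproducible

  sc0 <- benchmark_scenario("sim2", seed = 61, effect_scale = 0)
  expect_identical(make_effect_vector(sc0), numeric(5000))

  sc3 <- benchmark_scenario("sim3", seed = 61)
  d3 <- make_effect_vector(sc3)
  expect_equal(sum(d3 > 0), 0L)
  expect_equal(sum(d3 < 0), 637L)
})

test_that("simulated data decompose into oracle plus per-sample noise", {
  sc <- simulation_scenario(m = 200, n_A = 6, n_B = 6, n_up = 10,
                            n_down = 10, seed = 67, name = "decomp")
  sim <- simulate_dataset(sc, 4)
  alpha <- sim$y - sim$x
  # alpha is constant down each column, exactly
  expect_equal(max(apply(alpha, 2, function(a) diff(range(a)))), 0)
  # truth labels match the effect vector
  expect_identical(sim$truth == "null", sim$d == 0)
  expect_identical(sim$truth == "up", sim$d > 0)

  sc_noalpha <- simulation_scenario(m = 200, n_A = 6, n_B = 6, eta = 0,
                                    seed = 67, name = "noalpha")
  sim0 <- simulate_dataset(sc_noalpha, 4)
  expect_identical(sim0$y, sim0$x)
})

test_that("per-sample random effect induces the expected gene-gene covariance", {
  sc <- simulation_scenario(m = 2000, n_A = 50, n_B = 50, seed = 71,
                            name = "cov")
  est <- vapply(1:40, function(r) {
    sim <- simulate_dataset(sc, substream_seed(71, "cov", r))
    yA <- sim$y[, 1:50]
    g <- colMeans(yA)                      # per-sample gene averages
    row_var <- rowSums((yA - rowMeans(yA))^2) / 49
    # mean off-diagonal covariance from the variance of the sample averages
    (var(g) * 2000 - mean(row_var)) / 1999
  }, numeric(1))
  expect_equal(mean(est), 0.873^2, tolerance = 0.1 * 0.873^2)
})

test_that("oracle group mean difference is unbiased for the true effect", {
  sc <- simulation_scenario(m = 100, n_A = 50, n_B = 50, n_up = 1,
                            n_down = 0, seed = 73, name = "unbiased")
  d1 <- make_effect_vector(sc)[1]
  diffs <- vapply(1:200, function(r) {
    sim <- simulate_dataset(sc, substream_seed(73, "unb", r))
    mean(sim$x[1, 1:50]) - mean(sim$x[1, 51:100])
  }, numeric(1))
  se <- sc$sigma * sqrt(2 / 50) / sqrt(200)
  expect_lt(abs(mean(diffs) - d1), 3 * se)
})

test_that("evaluate_calls computes power and type I error as percentages", {
  truth <- factor(rep(c("up", "null"), c(2, 3)),
                  levels = c("up", "down", "null"))
  expect_equal(evaluate_calls(c(TRUE, TRUE, FALSE, FALSE, FALSE), truth),
               list(power = 100, type1 = 0))
  expect_equal(evaluate_calls(rep(FALSE, 5), truth),
               list(power = 0, type1 = 0))

  # 1000 DE / 9000 null with 888 true and 36 false calls
  truth2 <- factor(rep(c("down", "null"), c(1000, 9000)),
                   levels = c("up", "down", "null"))
  calls <- c(rep(TRUE, 888), rep(FALSE, 112), rep(TRUE, 36),
             rep(FALSE, 8964))
  expect_equal(evaluate_calls(calls, truth2), list(power = 88.8, type1 = 0.4))

  all_null <- factor(rep("null", 4), levels = c("up", "down", "null"))
  expect_true(is.na(evaluate_calls(rep(FALSE, 4), all_null)$power))
})

test_that("single-gene oracle power matches the closed-form t-test power", {
  # flat effects: a vanishing exponential tail makes every |d| ~ the floor
  sc <- simulation_scenario(m = 2000, n_A = 50, n_B = 50, n_up = 1000,
                            n_down = 1000, effect_floor = 0.25,
                            effect_tail_mean = 1e-9, seed = 79,
                            name = "analytic")
  rates <- vapply(1:3, function(r) {
    sim <- simulate_dataset(sc, substream_seed(79, "an", r))
    mean(oracle_test(sim$x, sim$design)$p_raw < 0.05)
  }, numeric(1))
  ref <- power.t.test(n = 50, delta = 0.25, sd = sc$sigma,
                      sig.level = 0.05)$power
  expect_equal(mean(rates), ref, tolerance = 0.025)
})

test_that("effect-scale calibration is monotone and hits its target", {
  sc <- simulation_scenario(m = 400, n_A = 20, n_B = 20, n_up = 40,
                            n_down = 40, seed = 83, name = "cal")
  cal_lo <- calibrate_effect_scale(sc, 40, tol = 2, reps_per_eval = 3)
  cal_hi <- calibrate_effect_scale(sc, 80, tol = 2, reps_per_eval = 3)
  expect_lt(cal_lo$effect_scale, cal_hi$effect_scale)
  expect_lt(abs(cal_lo$achieved_power - 40), 2 + 1e-9)
  expect_lt(abs(cal_hi$achieved_power - 80), 2 + 1e-9)
  # replay on fresh replicates stays near the target
  sc$effect_scale <- cal_hi$effect_scale
  replay <- vapply(1:10, function(r) {
    sim <- simulate_dataset(sc, substream_seed(83, "replay", r))
    calls <- bh_adjust(oracle_test(sim$x, sim$design)$p_raw) < 0.05
    evaluate_calls(calls, sim$truth)$power
  }, numeric(1))
  expect_lt(abs(mean(replay) - 80), 5)
  expect_error(calibrate_effect_scale(sc, 99.4, tol = 0.1,
                                      reps_per_eval = 2,
                                      bracket = c(0.05, 0.2)),
               "not bracketed")
})

test_that("benchmark runs are reproducible and structurally sound", {
  sc <- simulation_scenario(m = 200, n_A = 10, n_B = 10, n_up = 15,
                            n_down = 25, effect_scale = 2, seed = 89,
                            name = "bench")
  run <- function() run_benchmark(sc, methods = c("oracle", "global",
                                                  "sd_mftm"),
                                  replicates = 2, seed = 5,
                                  n_baseline = 50)
  b1 <- run(); b2 <- run()
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_setequal(unique(b1$metric), c("power", "type1"))
  expect_true(all(b1$mean >= 0 & b1$mean <= 100))
  expect_true(all(b1$sd >= 0))
  expect_equal(nrow(b1), 3 * 2)
  reps <- attr(b1, "replicate_values")$bench
  expect_equal(dim(reps), c(2L, 3L, 2L))
})

test_that("oracle performance is unaffected by the per-sample noise level", {
  base <- list(m = 300, n_A = 15, n_B = 15, n_up = 20, n_down = 30,
               effect_scale = 1.5, seed = 97, name = "eta")
  sc0 <- do.call(simulation_scenario, c(base, eta = 0))
  sc1 <- do.call(simulation_scenario, c(base, eta = 0.873))
  s0 <- simulate_dataset(sc0, 6)
  s1 <- simulate_dataset(sc1, 6)
  expect_identical(s0$x, s1$x)  # alpha enters y only
  expect_identical(oracle_test(s0$x, s0$design),
                   oracle_test(s1$x, s1$design))
})

test_that("unbalanced DE structure biases globally normalized differences", {
  # all-down structure: global normalization shifts null genes by -sum(d)/m
  sc <- simulation_scenario(m = 1000, n_A = 30, n_B = 30, n_down = 200,
                            seed = 101, name = "bias")
  d <- make_effect_vector(sc)
  expected_bias <- -sum(d) / 1000
  est <- vapply(1:10, function(r) {
    sim <- simulate_dataset(sc, substream_seed(101, "bias", r))
    yn <- normalize_global(sim$y)
    nulls <- sim$truth == "null"
    mean(rowMeans(yn[nulls, 1:30]) - rowMeans(yn[nulls, 31:60]))
  }, numeric(1))
  expect_equal(mean(est), expected_bias, tolerance = 0.02)
  expect_gt(expected_bias, 0.1)  # the bias is material, not noise

  # balanced up/down totals: bias vanishes
  sc_bal <- simulation_scenario(m = 1000, n_A = 30, n_B = 30, n_up = 100,
                                n_down = 100, effect_tail_mean = 1e-9,
                                seed = 101, name = "bal")
  est_bal <- vapply(1:10, function(r) {
    sim <- simulate_dataset(sc_bal, substream_seed(101, "bal", r))
    yn <- normalize_global(sim$y)
    nulls <- sim$truth == "null"
    mean(rowMeans(yn[nulls, 1:30]) - rowMeans(yn[nulls, 31:60]))
  }, numeric(1))
  expect_lt(abs(mean(est_bal)), 0.02)
})
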