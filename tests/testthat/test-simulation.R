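test_that("count totals hit the analytic mean and variance", {
  swt <- count_outcome_params(7.3, 11.3)
  qwt <- count_outcome_params(3.5, 4.4)
  reps <- 10000

  x <- sample_count_total(1881, swt, reps, seed = 101)
  mu <- 1881 * 7.3
  se <- sqrt(1881 * 11.3^2) / sqrt(reps)
  expect_lt(abs(mean(x) - mu), 3 * se)
  expect_true(all(x >= 0))
  expect_true(all(x == floor(x)))  # counts are integers

  y <- sample_count_total(170, qwt, reps, seed = 102)
  expect_lt(abs(mean(y) - 170 * 3.5), 3 * sqrt(170 * 4.4^2) / sqrt(reps))
  # NB moment identity: arm variance is n * (mu + mu^2 / k) = n * sd^2
  v_target <- 170 * 4.4^2
  se_var <- sd((y - mean(y))^2) / sqrt(reps)
  expect_lt(abs(var(y) - v_target), 3 * se_var)
})

test_that("aggregate NB draw matches the per-patient summation oracle", {
  # Sums of n i.i.d. NB(mu, k) draws are NB(n*mu, n*k); the aggregate
  # sampler must agree with brute-force per-patient summation in mean and
  # variance across the published arm settings and a small stress case.
  grid <- list(
    list(n = 50, mean = 3.5, sd = 4.4),     # QWT hospitalisations
    list(n = 50, mean = 7.3, sd = 11.3),    # SWT hospitalisations
    list(n = 50, mean = 55.7, sd = 75.4),   # QWT days
    list(n = 50, mean = 135.8, sd = 167.3), # SWT days
    list(n = 7, mean = 0.8, sd = 1.6)       # small, strongly overdispersed
  )
  reps <- 2000
  for (g in grid) {
    p <- count_outcome_params(g$mean, g$sd)
    agg <- as.numeric(sample_count_total(g$n, p, reps, seed = 7))
    oracle <- with(g, {
      set.seed(8)
      colSums(matrix(rnbinom(n * reps, size = p$dispersion, mu = p$mean),
                     nrow = n))
    })
    mu <- g$n * g$mean
    se_mean <- sqrt(g$n * g$sd^2) / sqrt(reps)
    expect_lt(abs(mean(agg) - mu), 3 * se_mean)
    expect_lt(abs(mean(oracle) - mu), 3 * se_mean)
    expect_lt(abs(mean(agg) - mean(oracle)), 3 * sqrt(2) * se_mean)
    v <- g$n * g$sd^2
    expect_lt(abs(var(agg) - v), 3 * sd((agg - mean(agg))^2) / sqrt(reps))
    expect_lt(abs(var(oracle) - v),
              3 * sd((oracle - mean(oracle))^2) / sqrt(reps))
  }
})

test_that("binary totals behave as binomial draws", {
  reps <- 10000
  p <- binary_outcome_params(29, 92)
  x <- sample_binary_total(92, p, reps, seed = 5)
  se <- sqrt(92 * (29 / 92) * (1 - 29 / 92)) / sqrt(reps)
  expect_lt(abs(mean(x) - 29), 3 * se)
  expect_true(all(x >= 0 & x <= 92))

  p0 <- binary_outcome_params(0, 10)
  expect_true(all(sample_binary_total(500, p0, 100, seed = 1) == 0))
  p1 <- binary_outcome_params(10, 10)
  expect_true(all(sample_binary_total(500, p1, 100, seed = 1) == 500))
})

test_that("empty arms and single replicates degrade gracefully", {
  p <- count_outcome_params(3.5, 4.4)
  z <- sample_count_total(0, p, 50, seed = 3)
  expect_identical(as.numeric(z), rep(0, 50))
  one <- sample_count_total(10, p, 1, seed = 3)
  expect_length(one, 1)
  expect_error(sample_count_total(10, p, 0, seed = 3),
               class = "qwtsim_samples_error")
})

test_that("scenario outcomes combine the two arms replicate by replicate", {
  params <- table1_params()
  base <- allocate_scenario(2051, label = "baseline", qwt_n = 170)
  reps <- 10000

  abst <- simulate_scenario_outcome(base, params$abstinence$qwt,
                                    params$abstinence$swt, reps, 1,
                                    "abstinence")
  mu <- 170 * 29 / 92 + 1881 * 13 / 90  # 325.3 expected abstinent
  se <- analytic_total_sd(base, params$abstinence) / sqrt(reps)
  expect_lt(abs(mean(abst) - mu), 3 * se)

  half <- allocate_scenario(2051, 0.5, "qwt50")
  hosp <- simulate_scenario_outcome(half, params$hospitalisations$qwt,
                                    params$hospitalisations$swt, reps, 1,
                                    "hospitalisations")
  mu2 <- 1026 * 3.5 + 1025 * 7.3  # 11,073.5 expected hospitalisations
  se2 <- analytic_total_sd(half, params$hospitalisations) / sqrt(reps)
  expect_lt(abs(mean(hosp) - mu2), 3 * se2)

  # all-QWT allocation with zero event probability in both arms
  allq <- allocate_scenario(100, 1.0, "allq")
  zero <- binary_outcome_params(0, 10)
  out <- simulate_scenario_outcome(allq, zero, zero, 200, 1, "never")
  expect_true(all(out == 0))

  expect_error(
    simulate_scenario_outcome(base, params$abstinence$qwt,
                              params$hospitalisations$swt, 10, 1, "mixed"),
    class = "qwtsim_config_error")
})

test_that("the full simulation is complete, deterministic and stream-keyed", {
  params <- table1_params()
  scenarios <- table1_scenarios()
  sim <- run_simulation(params, scenarios, replicates = 500, master_seed = 42)
  expect_named(sim$samples, c("baseline", "qwt25", "qwt50"))
  for (sc in names(sim$samples)) {
    expect_named(sim$samples[[sc]],
                 c("hospitalisations", "hospital_days", "abstinence", "death"))
    for (nm in names(sim$samples[[sc]])) {
      expect_length(sim$samples[[sc]][[nm]], 500)
    }
  }

  sim2 <- run_simulation(params, scenarios, replicates = 500, master_seed = 42)
  expect_identical(sim$samples, sim2$samples)  # bit-identical rerun

  sim3 <- run_simulation(params, scenarios, replicates = 500, master_seed = 43)
  expect_false(identical(sim$samples$baseline$abstinence,
                         sim3$samples$baseline$abstinence))

  # distinct (scenario, outcome, arm) keys give distinct streams
  seeds <- c(
    stream_seed(42, "baseline", "abstinence", "QWT"),
    stream_seed(42, "baseline", "abstinence", "SWT"),
    stream_seed(42, "baseline", "death", "QWT"),
    stream_seed(42, "qwt25", "abstinence", "QWT")
  )
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31))

  tiny <- run_simulation(params, scenarios, replicates = 1, master_seed = 1)
  expect_true(all(vapply(tiny$samples, function(per)
    all(lengths(per) == 1L), logical(1))))
})

test_that("adding a scenario leaves existing streams untouched", {
  params <- table1_params()
  two <- table1_scenarios()[c("baseline", "qwt50")]
  three <- table1_scenarios()
  sim2 <- run_simulation(params, two, replicates = 300, master_seed = 9)
  sim3 <- run_simulation(params, three, replicates = 300, master_seed = 9)
  expect_identical(sim2$samples$baseline, sim3$samples$baseline)
  expect_identical(sim2$samples$qwt50, sim3$samples$qwt50)
})
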