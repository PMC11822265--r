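test_that("event-free arms follow the discounted closed form exactly", {
  cfg <- event_free_config()
  set.seed(1)
  tr <- simulate_patient(cfg, "A")
  expect_equal(tr$total_cost, 20837)
  expect_equal(tr$total_qaly, 0.76 * discount_sum(10, 0.03), tolerance = 1e-12)
  # undiscounted limit
  cfg0 <- event_free_config(u_success = 0.69, upfront = 9058,
                            discount_rate = 0)
  set.seed(1)
  expect_equal(simulate_patient(cfg0, "A")$total_qaly, 10 * 0.69,
               tolerance = 1e-12)
  # zero-probability configs have zero variance across patients
  set.seed(1)
  arm <- simulate_arm(cfg, "A", 50)
  expect_equal(stats::sd(arm$cost), 0)
  expect_equal(stats::sd(arm$qaly), 0)
})

test_that("a certain reoperation produces the forced-event trace", {
  cfg <- model_config(
    model_settings(),
    list(strategy_params("SCR", 20837, 1, 0, 0.76),
         strategy_params("RSA", 17210, 0, 0, 0.59)),
    conversion_target = "RSA", u_failure = 0.35)
  set.seed(1)
  tr <- simulate_patient(cfg, "SCR")
  expect_equal(tr$records$event[1], "arthroscopic_revision")
  expect_equal(tr$records$cycle_utility[1], 0.35)
  expect_equal(tr$records$event[-1], rep("none", 9))
  expect_equal(tr$records$cycle_utility[-1], rep(0.76, 9))
  expect_equal(tr$total_cost, 20837 + 1.05 * 20837 / 1.03, tolerance = 1e-12)
  expect_equal(tr$total_qaly,
               0.35 / 1.03 + 0.76 * sum(1.03^-(2:10)), tolerance = 1e-12)
})

test_that("trajectory records reproduce the discounted totals", {
  for (seed in 1:5) {
    cfg <- generate_random_config(
      scenario_spec(seed = seed, n_strategies = 3),
      post_conversion_revision = (seed %% 2 == 0))
    set.seed(seed)
    tr <- simulate_patient(cfg, "S1")
    d <- (1 + cfg$settings$discount_rate)^-(tr$records$cycle)
    upfront <- cfg$strategies[[1]]$upfront_cost
    expect_equal(tr$total_cost, upfront + sum(d * tr$records$cycle_cost),
                 tolerance = 1e-9)
    expect_equal(tr$total_qaly, sum(d * tr$records$cycle_utility),
                 tolerance = 1e-9)
    ev <- tr$records$event != "none"
    expect_true(all(tr$records$cycle_cost[!ev] == 0))
    expect_true(all(tr$records$cycle_cost[ev] > 0))
  }
})

test_that("single-patient arm and scalar trajectory share one RNG path", {
  cfg <- builtin_irct_config()
  for (s in c("SCR", "SABS", "RSA")) {
    set.seed(31); tr <- simulate_patient(cfg, s)
    set.seed(31); arm <- simulate_arm(cfg, s, 1)
    expect_equal(arm$mean_cost, tr$total_cost, tolerance = 1e-12)
    expect_equal(arm$mean_qaly, tr$total_qaly, tolerance = 1e-12)
  }
})

test_that("cohort expectation equals exhaustive enumeration", {
  for (seed in 1:8) {
    cfg <- generate_random_config(
      scenario_spec(seed = seed, horizon_range = c(2L, 8L)),
      post_conversion_revision = (seed %% 2 == 0))
    for (s in c("S1", "S4")) {
      en <- enum_expectation(cfg, s)
      ce <- cohort_expectation(cfg, s)
      expect_equal(ce[["expected_cost"]], en[["cost"]], tolerance = 1e-9)
      expect_equal(ce[["expected_qaly"]], en[["qaly"]], tolerance = 1e-9)
    }
  }
})

test_that("microsimulation means agree with the cohort oracle", {
  cfg <- builtin_irct_config()
  set.seed(2026)
  arm <- simulate_arm(cfg, "SCR", 50000)
  e <- cohort_expectation(cfg, "SCR")
  expect_lt(abs(arm$mean_cost - e[["expected_cost"]]),
            3 * stats::sd(arm$cost) / sqrt(arm$n_patients))
  expect_lt(abs(arm$mean_qaly - e[["expected_qaly"]]),
            3 * stats::sd(arm$qaly) / sqrt(arm$n_patients))
})

test_that("event hazards move cost up and QALYs down along single pathways", {
  # Monotonicity holds per competing risk in isolation. (Raising one hazard
  # with the other active need not lower QALYs: an absorbing revision can
  # shield the patient from a later conversion to a lower-utility state.)
  cfg <- builtin_irct_config()
  grid <- seq(0, 0.5, by = 0.05)
  cfg$strategies[[1]]$p_conversion <- 0
  prev <- NULL
  for (p in grid) {
    cfg$strategies[[1]]$p_reoperation <- p
    e <- cohort_expectation(cfg, "SCR")
    if (!is.null(prev)) {
      expect_gte(e[["expected_cost"]], prev[["expected_cost"]] - 1e-9)
      expect_lte(e[["expected_qaly"]], prev[["expected_qaly"]] + 1e-9)
    }
    prev <- e
  }
  cfg$strategies[[1]]$p_reoperation <- 0
  prev <- NULL
  for (p in grid) {
    cfg$strategies[[1]]$p_conversion <- p
    e <- cohort_expectation(cfg, "SCR")
    if (!is.null(prev)) {
      expect_gte(e[["expected_cost"]], prev[["expected_cost"]] - 1e-9)
      expect_lte(e[["expected_qaly"]], prev[["expected_qaly"]] + 1e-9)
    }
    prev <- e
  }
})

test_that("state occupancy is conserved at every cycle", {
  for (seed in 1:5) {
    cfg <- generate_random_config(scenario_spec(seed = seed),
                                  post_conversion_revision = TRUE)
    occ <- attr(cohort_expectation(cfg, "S1"), "occupancy")
    expect_true(all(abs(rowSums(occ) - 1) <= 1e-12))
  }
})

test_that("events only add cost and reduce QALYs relative to event-free", {
  cfg <- builtin_irct_config()
  e <- cohort_expectation(cfg, "SABS")
  expect_gt(e[["expected_cost"]], 9058)
  expect_lt(e[["expected_qaly"]], 0.69 * discount_sum(10, 0.03))
})

test_that("repeat-event structure accumulates at least as much cost", {
  base <- generate_random_config(scenario_spec(seed = 3))
  rep_cfg <- generate_random_config(scenario_spec(seed = 3),
                                    repeat_events = TRUE)
  e1 <- cohort_expectation(base, "S1")
  e2 <- cohort_expectation(rep_cfg, "S1")
  expect_gte(e2[["expected_cost"]], e1[["expected_cost"]])
  expect_lte(e2[["expected_qaly"]], e1[["expected_qaly"]])
  set.seed(5)
  expect_silent(simulate_arm(rep_cfg, "S1", 100))
})

test_that("unknown strategies are rejected", {
  expect_error(simulate_patient(builtin_irct_config(), "TSA"),
               "unknown strategy")
  expect_error(cohort_expectation(builtin_irct_config(), "nope"),
               "unknown strategy")
})
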