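#' Specification for random synthetic decision problems
#'
#' Defines the ranges from which [generate_random_config()] draws a valid
#' `model_config`. Synthetic problems keep the real model's structure (a
#' success state per strategy, annual complication hazards routing to
#' revision or conversion, discounted cost/utility accrual) with arbitrary
#' strategy counts and parameter magnitudes, so every pipeline stage can be
#' tested without the built-in base case.
#'
#' @param n_strategies Number of strategies, 2-6.
#' @param cost_range Range of upfront costs in $.
#' @param prob_range Range of each annual event probability; the generated
#'   pair is rescaled so `p_reoperation + p_conversion <= 0.5`.
#' @param util_range Range of success utilities.
#' @param u_failure_range Range of the shared failure utility; capped below
#'   the smallest generated success utility.
#' @param horizon_range Integer range of horizon years.
#' @param discount_range Range of annual discount rates.
#' @param seed Integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_strategies = 4L,
                          cost_range = c(5000, 30000),
                          prob_range = c(0, 0.25),
                          util_range = c(0.45, 0.9),
                          u_failure_range = c(0.2, 0.4),
                          horizon_range = c(3L, 10L),
                          discount_range = c(0, 0.05),
                          seed = 1L) {
  if (n_strategies < 2L || n_strategies > 6L)
    stop("n_strategies must lie in 2..6", call. = FALSE)
  rngs <- list(cost_range = cost_range, prob_range = prob_range,
               util_range = util_range, u_failure_range = u_failure_range,
               horizon_range = horizon_range,
               discount_range = discount_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop(sprintf("%s: must be an increasing pair", nm), call. = FALSE)
  }
  if (cost_range[1] <= 0) stop("cost_range: must be positive", call. = FALSE)
  if (prob_range[1] < 0 || prob_range[2] > 0.5)
    stop("prob_range: must lie within [0, 0.5]", call. = FALSE)
  if (util_range[1] < 0 || util_range[2] > 1)
    stop("util_range: must lie within [0, 1]", call. = FALSE)
  if (u_failure_range[1] < 0 || u_failure_range[2] > util_range[1])
    stop("u_failure_range: must lie within [0, min(util_range)]",
         call. = FALSE)
  structure(c(list(n_strategies = as.integer(n_strategies)), rngs,
              list(seed = as.integer(seed))),
            class = "scenario_spec")
}

runif_range <- function(n, r) stats::runif(n, r[1], r[2])

#' Generate a random valid model configuration
#'
#' Reproducible from `spec$seed`. Zero-width ranges yield the midpoint
#' value, making degenerate deterministic scenarios easy to construct in
#' tests. One strategy (the last, mimicking the arthroplasty role) is
#' designated the conversion target and given `p_conversion = 0`.
#'
#' @param spec A [scenario_spec()].
#' @param ... Settings overrides forwarded to [model_settings()] (e.g.
#'   `post_conversion_revision = TRUE`).
#' @return A validated `model_config`.
#' @export
generate_random_config <- function(spec, ...) {
  set.seed(spec$seed)
  k <- spec$n_strategies
  horizon <- if (spec$horizon_range[1] == spec$horizon_range[2])
    spec$horizon_range[1]
  else sample(spec$horizon_range[1]:spec$horizon_range[2], 1L)
  disc <- runif_range(1, spec$discount_range)
  utils <- runif_range(k, spec$util_range)
  u_fail <- min(runif_range(1, spec$u_failure_range), min(utils))
  strategies <- vector("list", k)
  for (i in seq_len(k)) {
    pre <- runif_range(1, spec$prob_range)
    pcv <- if (i == k) 0 else runif_range(1, spec$prob_range)
    if (pre + pcv > 0.5) {            # keep joint annual risk plausible
      f <- 0.5 / (pre + pcv)
      pre <- pre * f; pcv <- pcv * f
    }
    strategies[[i]] <- strategy_params(
      name = paste0("S", i),
      upfront_cost = runif_range(1, spec$cost_range),
      p_reoperation = pre, p_conversion = pcv,
      u_success = utils[i])
  }
  model_config(
    settings = model_settings(horizon_years = horizon, discount_rate = disc,
                              rng_seed = spec$seed, ...),
    strategies = strategies,
    conversion_target = paste0("S", k),
    u_failure = u_fail)
}

#' Exhaustively enumerate all patient trajectories of one arm
#'
#' Under the single-event structure, a patient's fate is fully described by
#' the kind and cycle of at most two events (an index-state event, and --
#' when post-conversion revision risk is enabled -- a later revision-RSA
#' event), so the outcome space over a T-cycle horizon is small and can be
#' enumerated exactly. Each distinguishable trajectory is returned with its
#' exact probability and its discounted cost and QALY totals; probabilities
#' sum to 1 and the probability-weighted totals equal [cohort_expectation()]
#' to numerical precision. This is the ground-truth oracle that pins down
#' the microsimulation engine's semantics in tests.
#'
#' @param config A validated `model_config` with
#'   `settings$repeat_events = FALSE` (refused otherwise: the outcome space
#'   is no longer finite-small).
#' @param strategy Strategy name.
#' @return A data.frame with one row per trajectory: `outcome` (label),
#'   `event_cycle`, `second_event_cycle`, `probability`, `total_cost`,
#'   `total_qaly`.
#' @export
enumerate_trajectories <- function(config, strategy) {
  if (config$settings$repeat_events)
    stop("enumeration requires repeat_events = FALSE", call. = FALSE)
  a <- resolve_arm_inputs(config, strategy)
  T <- a$horizon
  disc <- a$disc^seq_len(T)
  qaly_free <- function(util, from, to) {   # utility accrued cycles from..to
    if (from > to) 0 else sum(disc[from:to]) * util * a$cycle_len
  }
  p_stay <- 1 - a$p_reop - a$p_conv
  rows <- list()
  add <- function(outcome, e1, e2, p, cost, qaly) {
    rows[[length(rows) + 1L]] <<- data.frame(
      outcome = outcome, event_cycle = e1, second_event_cycle = e2,
      probability = p, total_cost = cost, total_qaly = qaly,
      stringsAsFactors = FALSE)
  }
  ## no event at all
  add("event_free", NA_integer_, NA_integer_, p_stay^T,
      a$upfront, qaly_free(a$u_success, 1L, T))
  for (i in seq_len(T)) {
    pre_i <- p_stay^(i - 1)
    base_q <- qaly_free(a$u_success, 1L, i - 1L) + disc[i] * a$u_failure *
      a$cycle_len
    ## index revision at cycle i, absorbing success afterwards
    add(a$index_rev_event, i, NA_integer_, pre_i * a$p_reop,
        a$upfront + disc[i] * a$index_rev_cost,
        base_q + qaly_free(a$u_success, i + 1L, T))
    ## conversion at cycle i
    p_conv_i <- pre_i * a$p_conv
    if (a$p_rsa_rev > 0) {
      ## possibly followed by one revision RSA at cycle j > i
      for (j in if (i < T) (i + 1L):T else integer(0)) {
        p <- p_conv_i * (1 - a$p_rsa_rev)^(j - i - 1L) * a$p_rsa_rev
        add("conversion_then_rsa_revision", i, j, p,
            a$upfront + disc[i] * a$conv_cost + disc[j] * a$rsa_rev_cost,
            base_q + qaly_free(a$ct_u_success, i + 1L, j - 1L) +
              disc[j] * a$ct_u_failure * a$cycle_len +
              qaly_free(a$ct_u_success, j + 1L, T))
      }
      p_no_rev <- p_conv_i * (1 - a$p_rsa_rev)^(T - i)
      add("conversion_only", i, NA_integer_, p_no_rev,
          a$upfront + disc[i] * a$conv_cost,
          base_q + qaly_free(a$ct_u_success, i + 1L, T))
    } else {
      add("conversion_only", i, NA_integer_, p_conv_i,
          a$upfront + disc[i] * a$conv_cost,
          base_q + qaly_free(a$ct_u_success, i + 1L, T))
    }
  }
  out <- do.call(rbind, rows)
  out[out$probability > 0, , drop = FALSE]
}
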