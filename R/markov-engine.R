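## State codes used by the engine, the cohort oracle and the enumeration
## oracle. INDEX_SUCCESS and (optionally) POST_CONVERSION_RSA are at risk;
## the two post-revision states are absorbing under the default single-event
## structure.
STATE_INDEX         <- 1L
STATE_POST_REVISION <- 2L
STATE_CONVERTED     <- 3L
STATE_POST_RSA_REV  <- 4L

state_labels <- c("INDEX_SUCCESS", "POST_REVISION_SUCCESS",
                  "POST_CONVERSION_RSA", "POST_RSA_REVISION_SUCCESS")

## Resolve everything the engine needs for one strategy arm into flat
## numerics: probabilities, utilities, event costs, discount factor.
resolve_arm_inputs <- function(config, strategy) {
  st <- get_strategy(config, strategy)
  ct <- get_strategy(config, config$conversion_target)
  s <- config$settings
  uf <- function(x) if (is.na(x$u_failure)) config$u_failure else x$u_failure
  is_rsa_arm <- identical(st$name, config$conversion_target)
  uplift <- s$revision_cost_uplift
  index_rev_uplift <- if (is_rsa_arm && !s$uplift_rsa_revision) 0 else uplift
  rsa_rev_uplift <- if (s$uplift_rsa_revision) uplift else 0
  list(
    name = st$name,
    horizon = s$horizon_years,
    cycle_len = s$cycle_length_years,
    disc = (1 + s$discount_rate)^(-s$cycle_length_years),
    upfront = st$upfront_cost,
    p_reop = st$p_reoperation,
    p_conv = st$p_conversion,
    u_success = st$u_success,
    u_failure = uf(st),
    index_rev_cost = (1 + index_rev_uplift) * st$upfront_cost,
    index_rev_event = if (is_rsa_arm) "rsa_revision" else
      "arthroscopic_revision",
    conv_cost = ct$upfront_cost,
    ct_u_success = ct$u_success,
    ct_u_failure = uf(ct),
    p_rsa_rev = if (s$post_conversion_revision) ct$p_reoperation else 0,
    rsa_rev_cost = (1 + rsa_rev_uplift) * ct$upfront_cost,
    post_conversion_revision = s$post_conversion_revision,
    repeat_events = s$repeat_events
  )
}

#' Simulate one patient through the state-transition model
#'
#' Runs a single patient trajectory over `horizon_years` annual cycles.
#' The patient starts in the index success state having paid the strategy's
#' upfront cost at cycle 0 (undiscounted). While at risk, each cycle draws
#' one categorical event (arthroscopic revision, conversion to reverse
#' shoulder arthroplasty, or none); event cycles accrue the failure utility
#' and book the event cost, non-event cycles accrue the occupied state's
#' success utility. Cycle-`t` accruals are discounted by `(1+d)^-t`.
#'
#' @param config A validated `model_config` (base case or a sampled
#'   parameter set).
#' @param strategy Strategy name.
#' @return An object of class `patient_trajectory`: list with `strategy`,
#'   `records` (a data.frame with one row per cycle: `cycle`,
#'   `state_entering`, `event`, `cycle_utility`, `cycle_cost`, all
#'   undiscounted), `total_cost` and `total_qaly` (both discounted,
#'   `total_cost` includes the upfront cost).
#' @seealso [simulate_arm()] for the vectorized multi-patient version,
#'   [cohort_expectation()] for the deterministic oracle.
#' @export
simulate_patient <- function(config, strategy) {
  a <- resolve_arm_inputs(config, strategy)
  T <- a$horizon
  state <- STATE_INDEX
  rec_state <- character(T); rec_event <- character(T)
  rec_u <- numeric(T); rec_c <- numeric(T)
  total_cost <- a$upfront; total_qaly <- 0
  for (t in seq_len(T)) {
    u <- stats::runif(1)           # one draw per cycle, at risk or not
    rec_state[t] <- state_labels[state]
    event <- "none"; ccost <- 0; cutil <- NA_real_
    if (state == STATE_INDEX) {
      if (u < a$p_reop) {
        event <- a$index_rev_event
        ccost <- a$index_rev_cost
        cutil <- a$u_failure
        state <- if (a$repeat_events) STATE_INDEX else STATE_POST_REVISION
      } else if (u < a$p_reop + a$p_conv) {
        event <- "conversion_to_rsa"
        ccost <- a$conv_cost
        cutil <- a$u_failure
        state <- STATE_CONVERTED
      } else cutil <- a$u_success
    } else if (state == STATE_POST_REVISION) {
      cutil <- a$u_success
    } else if (state == STATE_CONVERTED) {
      if (u < a$p_rsa_rev) {
        event <- "rsa_revision"
        ccost <- a$rsa_rev_cost
        cutil <- a$ct_u_failure
        state <- if (a$repeat_events) STATE_CONVERTED else STATE_POST_RSA_REV
      } else cutil <- a$ct_u_success
    } else {
      cutil <- a$ct_u_success
    }
    rec_event[t] <- event; rec_u[t] <- cutil; rec_c[t] <- ccost
    disc <- a$disc^t
    total_cost <- total_cost + disc * ccost
    total_qaly <- total_qaly + disc * cutil * a$cycle_len
  }
  structure(list(
    strategy = a$name,
    records = data.frame(cycle = seq_len(T), state_entering = rec_state,
                         event = rec_event, cycle_utility = rec_u,
                         cycle_cost = rec_c, stringsAsFactors = FALSE),
    total_cost = total_cost,
    total_qaly = total_qaly
  ), class = "patient_trajectory")
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat(sprintf("<patient_trajectory> %s: discounted cost $%.2f, QALYs %.4f\n",
              x$strategy, x$total_cost, x$total_qaly))
  print(x$records)
  invisible(x)
}

#' Simulate one treatment arm (vectorized microsimulation)
#'
#' Simulates `n_patients` independent trajectories with the same event
#' semantics as [simulate_patient()], vectorized across patients (one
#' uniform draw per patient per cycle, so with an identical RNG state
#' `simulate_arm(..., n_patients = 1)` reproduces `simulate_patient()`
#' exactly).
#'
#' @param config A validated `model_config`.
#' @param strategy Strategy name.
#' @param n_patients Number of patients (default from
#'   `config$settings$n_patients`).
#' @return An object of class `arm_result`: list with `strategy`,
#'   `n_patients`, `mean_cost`, `mean_qaly` and the per-patient discounted
#'   `cost` and `qaly` vectors.
#' @export
simulate_arm <- function(config, strategy,
                         n_patients = config$settings$n_patients) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  a <- resolve_arm_inputs(config, strategy)
  n <- as.integer(n_patients)
  state <- rep.int(STATE_INDEX, n)
  cost <- rep.int(a$upfront, n)
  qaly <- numeric(n)
  for (t in seq_len(a$horizon)) {
    u <- stats::runif(n)
    disc <- a$disc^t
    idx <- state == STATE_INDEX
    conv <- state == STATE_CONVERTED
    ev_re <- idx & u < a$p_reop
    ev_cv <- idx & !ev_re & u < a$p_reop + a$p_conv
    ev_rr <- conv & u < a$p_rsa_rev
    cutil <- ifelse(state <= STATE_POST_REVISION, a$u_success, a$ct_u_success)
    cutil[ev_re | ev_cv] <- a$u_failure
    cutil[ev_rr] <- a$ct_u_failure
    qaly <- qaly + disc * a$cycle_len * cutil
    cost <- cost + disc * (ev_re * a$index_rev_cost + ev_cv * a$conv_cost +
                             ev_rr * a$rsa_rev_cost)
    state[ev_re] <- if (a$repeat_events) STATE_INDEX else STATE_POST_REVISION
    state[ev_cv] <- STATE_CONVERTED
    state[ev_rr] <- if (a$repeat_events) STATE_CONVERTED else
      STATE_POST_RSA_REV
  }
  structure(list(strategy = a$name, n_patients = n,
                 mean_cost = mean(cost), mean_qaly = mean(qaly),
                 cost = cost, qaly = qaly),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s: n = %d, mean cost $%.2f (sd %.2f), mean QALYs %.4f (sd %.4f)\n",
    x$strategy, x$n_patients, x$mean_cost, stats::sd(x$cost), x$mean_qaly,
    stats::sd(x$qaly)))
  invisible(x)
}

#' Deterministic cohort expectation of one arm
#'
#' Exact expectation of the microsimulation: propagates the state-occupancy
#' distribution forward over the horizon, accruing per-cycle expected
#' (discounted) cost and utility. No sampling is involved; this is the
#' analytic oracle the stochastic engine is tested against.
#'
#' @param config A validated `model_config`.
#' @param strategy Strategy name.
#' @return Named numeric vector `c(expected_cost, expected_qaly)`, with an
#'   attribute `"occupancy"` holding the `(horizon+1) x 4` state-occupancy
#'   matrix (rows sum to 1).
#' @export
cohort_expectation <- function(config, strategy) {
  a <- resolve_arm_inputs(config, strategy)
  occ <- c(1, 0, 0, 0)
  occ_hist <- matrix(NA_real_, a$horizon + 1L, 4L,
                     dimnames = list(NULL, state_labels))
  occ_hist[1L, ] <- occ
  cost <- a$upfront; qaly <- 0
  p_ev1 <- a$p_reop + a$p_conv
  u1 <- p_ev1 * a$u_failure + (1 - p_ev1) * a$u_success
  c1 <- a$p_reop * a$index_rev_cost + a$p_conv * a$conv_cost
  p3 <- a$p_rsa_rev
  u3 <- p3 * a$ct_u_failure + (1 - p3) * a$ct_u_success
  c3 <- p3 * a$rsa_rev_cost
  for (t in seq_len(a$horizon)) {
    disc <- a$disc^t
    qaly <- qaly + disc * a$cycle_len *
      (occ[1] * u1 + occ[2] * a$u_success + occ[3] * u3 +
         occ[4] * a$ct_u_success)
    cost <- cost + disc * (occ[1] * c1 + occ[3] * c3)
    to2 <- if (a$repeat_events) 0 else occ[1] * a$p_reop
    to4 <- if (a$repeat_events) 0 else occ[3] * p3
    occ <- c(occ[1] * (1 - p_ev1) + (occ[1] * a$p_reop - to2),
             occ[2] + to2,
             occ[3] * (1 - p3) + occ[1] * a$p_conv + (occ[3] * p3 - to4),
             occ[4] + to4)
    occ_hist[t + 1L, ] <- occ
  }
  structure(c(expected_cost = cost, expected_qaly = qaly),
            occupancy = occ_hist)
}
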