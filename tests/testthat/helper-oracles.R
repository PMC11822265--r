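# Shared fixtures and independent oracles used across test files.

## Discounted sum of an annual accrual over T cycles: sum_{t=1..T} (1+d)^-t
discount_sum <- function(T, d) sum((1 + d)^-(seq_len(T)))

## A config in which nothing ever happens: closed forms apply exactly.
event_free_config <- function(u_success = 0.76, upfront = 20837,
                              discount_rate = 0.03, horizon = 10L) {
  model_config(
    model_settings(horizon_years = horizon, discount_rate = discount_rate),
    list(strategy_params("A", upfront, 0, 0, u_success),
         strategy_params("RSA", 17210, 0, 0, 0.59)),
    conversion_target = "RSA", u_failure = 0.35)
}

## Expectation of an arm straight from the enumeration oracle.
enum_expectation <- function(config, strategy) {
  en <- enumerate_trajectories(config, strategy)
  c(cost = sum(en$probability * en$total_cost),
    qaly = sum(en$probability * en$total_qaly))
}

## Brute-force dominance classification by definition, for cross-checking
## dominance_and_icers on small random strategy sets. Absolute dominance is
## pairwise; extended dominance tests blends of every pair of surviving
## strategies on a fine lambda grid.
brute_dominance <- function(df) {
  n <- nrow(df)
  lab <- rep("undominated", n)
  for (k in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == k) next
      if (df$mean_cost[j] <= df$mean_cost[k] &&
          df$mean_qaly[j] >= df$mean_qaly[k] &&
          (df$mean_cost[j] < df$mean_cost[k] ||
             df$mean_qaly[j] > df$mean_qaly[k])) {
        lab[k] <- "absolute_dominated"
        break
      }
    }
  }
  surv <- which(lab != "absolute_dominated")
  lam <- seq(0, 1, by = 0.0005)
  for (k in surv) {
    others <- setdiff(surv, k)
    if (length(others) < 2L) next
    found <- FALSE
    for (i in others) {
      for (j in others) {
        if (i >= j) next
        bc <- lam * df$mean_cost[i] + (1 - lam) * df$mean_cost[j]
        bq <- lam * df$mean_qaly[i] + (1 - lam) * df$mean_qaly[j]
        if (any(bc <= df$mean_cost[k] + 1e-9 &
                  bq >= df$mean_qaly[k] - 1e-9 &
                  (bc < df$mean_cost[k] - 1e-6 |
                     bq > df$mean_qaly[k] + 1e-9))) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) lab[k] <- "extended_dominated"
  }
  lab
}

## Hand-rolled psa_result for CEA-layer tests with known iteration values.
fake_psa <- function(cost, qaly, wtp_grid = seq(0, 100000, 1000),
                     wtp = 50000) {
  stopifnot(identical(dim(cost), dim(qaly)))
  strategies <- colnames(cost)
  n <- nrow(cost)
  counts <- matrix(0, length(wtp_grid), ncol(cost),
                   dimnames = list(NULL, strategies))
  for (g in seq_along(wtp_grid)) {
    win <- max.col(qaly * wtp_grid[g] - cost, ties.method = "first")
    counts[g, ] <- tabulate(win, nbins = ncol(cost))
  }
  cfg <- builtin_irct_config(wtp = wtp)
  structure(list(
    iterations = data.frame(
      iteration = rep(seq_len(n), times = ncol(cost)),
      strategy = rep(strategies, each = n),
      mean_cost = as.vector(cost), mean_qaly = as.vector(qaly),
      stringsAsFactors = FALSE),
    wtp_grid = wtp_grid, patient_optimal_counts = counts,
    config = cfg, n_iterations = n, n_patients = 1L, seed = 0L),
    class = "psa_result")
}
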