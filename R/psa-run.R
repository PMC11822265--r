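#' Run the full probabilistic sensitivity analysis
#'
#' For each PSA iteration: draw one full parameter set from the input
#' distributions ([sample_parameter_set()]), microsimulate every strategy arm
#' with `n_patients` patients ([simulate_arm()]), and record the arm means.
#' Patient-level optimal-strategy counts (per-patient net-monetary-benefit
#' winners) are accumulated on `wtp_grid` during the run so that
#' patient-level acceptability curves are available without storing every
#' patient.
#'
#' Reproducibility: iteration `i` runs under its own seed derived from
#' `seed`, so results do not depend on how iterations are batched.
#'
#' @param config A validated `model_config` (the template whose means define
#'   the PSA distributions).
#' @param n_iterations,n_patients Override the sizes in
#'   `config$settings` if given.
#' @param seed Master seed (default `config$settings$rng_seed`).
#' @param wtp_grid Willingness-to-pay grid in $/QALY on which patient-level
#'   optimal shares are accumulated (default $0 to $100,000 in $1,000 steps).
#' @param keep_patients If `TRUE`, also store every patient's discounted cost
#'   and QALY totals (needed for patient-level incremental scatters; memory
#'   grows as iterations x patients x strategies).
#' @return An object of class `psa_result`: list with `iterations` (long
#'   data.frame: `iteration`, `strategy`, `mean_cost`, `mean_qaly`),
#'   `wtp_grid`, `patient_optimal_counts` (grid x strategy matrix),
#'   `config`, `n_iterations`, `n_patients`, `seed`, and optionally
#'   `patients` (long data.frame of per-patient totals).
#' @seealso [aggregate_psa()], [cea_table()], [ceac()], [optimal_shares()]
#' @export
run_psa <- function(config,
                    n_iterations = config$settings$n_iterations,
                    n_patients = config$settings$n_patients,
                    seed = config$settings$rng_seed,
                    wtp_grid = seq(0, 100000, by = 1000),
                    keep_patients = FALSE) {
  validate_config(config)
  n_iterations <- as.integer(n_iterations)
  n_patients <- as.integer(n_patients)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  specs <- build_psa_specs(config)
  strategies <- strategy_names(config)
  k <- length(strategies)
  it_cost <- matrix(NA_real_, n_iterations, k,
                    dimnames = list(NULL, strategies))
  it_qaly <- it_cost
  counts <- matrix(0, length(wtp_grid), k,
                   dimnames = list(NULL, strategies))
  pat_list <- if (keep_patients) vector("list", n_iterations) else NULL
  for (i in seq_len(n_iterations)) {
    set.seed(iteration_seed(seed, i))
    sampled <- sample_parameter_set(config, specs)
    cost_mat <- matrix(NA_real_, n_patients, k)
    qaly_mat <- matrix(NA_real_, n_patients, k)
    for (j in seq_len(k)) {
      arm <- simulate_arm(sampled, strategies[j], n_patients)
      cost_mat[, j] <- arm$cost
      qaly_mat[, j] <- arm$qaly
    }
    it_cost[i, ] <- colMeans(cost_mat)
    it_qaly[i, ] <- colMeans(qaly_mat)
    for (g in seq_along(wtp_grid)) {
      win <- max.col(qaly_mat * wtp_grid[g] - cost_mat, ties.method = "first")
      counts[g, ] <- counts[g, ] + tabulate(win, nbins = k)
    }
    if (keep_patients)
      pat_list[[i]] <- data.frame(
        iteration = i,
        strategy = rep(strategies, each = n_patients),
        patient = rep(seq_len(n_patients), times = k),
        cost = as.vector(cost_mat), qaly = as.vector(qaly_mat))
  }
  res <- list(
    iterations = data.frame(
      iteration = rep(seq_len(n_iterations), times = k),
      strategy = rep(strategies, each = n_iterations),
      mean_cost = as.vector(it_cost),
      mean_qaly = as.vector(it_qaly),
      stringsAsFactors = FALSE),
    wtp_grid = wtp_grid,
    patient_optimal_counts = counts,
    config = config,
    n_iterations = n_iterations,
    n_patients = n_patients,
    seed = as.integer(seed)
  )
  if (keep_patients) res$patients <- do.call(rbind, pat_list)
  class(res) <- "psa_result"
  res
}

## Deterministic per-iteration substream seed below 2^31.
iteration_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647L)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d patients, %d strategies, seed %d\n",
              x$n_iterations, x$n_patients,
              length(unique(x$iterations$strategy)), x$seed))
  print(aggregate_psa(x))
  invisible(x)
}
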