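#' Model settings for the decision model
#'
#' Bundles the global simulation settings of the cost-utility model: time
#' horizon, cycle length, discounting, willingness-to-pay, microsimulation
#' sizes and the standard-deviation rules used to build PSA distributions.
#'
#' @param horizon_years Integer number of annual Markov cycles (default 10).
#' @param cycle_length_years Duration of one cycle in years (default 1).
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (default 0.03).
#' @param wtp Willingness-to-pay threshold in $/QALY (default 50000).
#' @param n_patients Patients per microsimulation arm (default 1000).
#' @param n_iterations PSA iterations (default 1000).
#' @param revision_cost_uplift Multiplicative surcharge on revision procedures
#'   relative to their primary counterparts (default 0.05).
#' @param sd_fraction_costs SD of a cost input as a fraction of its mean
#'   (default 0.20).
#' @param sd_fraction_probs SD of a probability input as a fraction of its
#'   mean (default 0.20).
#' @param sd_utilities Absolute SD of utility inputs (default 0.05).
#' @param rng_seed Integer seed for the master random stream.
#' @param post_conversion_revision Logical; if `TRUE`, patients converted to
#'   reverse shoulder arthroplasty face the annual revision-RSA hazard for the
#'   remainder of the horizon. Default `FALSE`: conversion is terminal and the
#'   patient accrues the RSA success utility thereafter (see the methods
#'   vignette for the calibration behind this default).
#' @param repeat_events Logical; if `TRUE`, revision events do not absorb and
#'   the same event type can recur in later cycles. Default `FALSE` (single
#'   event of each kind per pathway). The exhaustive enumeration oracle only
#'   supports the default.
#' @param uplift_rsa_revision Logical; apply `revision_cost_uplift` to
#'   revision RSA as well as to arthroscopic revisions (default `TRUE`).
#'
#' @return An object of class `model_settings` (a named list).
#' @seealso [model_config()], [builtin_irct_config()]
#' @export
model_settings <- function(horizon_years = 10L,
                           cycle_length_years = 1,
                           discount_rate = 0.03,
                           wtp = 50000,
                           n_patients = 1000L,
                           n_iterations = 1000L,
                           revision_cost_uplift = 0.05,
                           sd_fraction_costs = 0.20,
                           sd_fraction_probs = 0.20,
                           sd_utilities = 0.05,
                           rng_seed = 1L,
                           post_conversion_revision = FALSE,
                           repeat_events = FALSE,
                           uplift_rsa_revision = TRUE) {
  s <- list(
    horizon_years = as.integer(horizon_years),
    cycle_length_years = as.numeric(cycle_length_years),
    discount_rate = as.numeric(discount_rate),
    wtp = as.numeric(wtp),
    n_patients = as.integer(n_patients),
    n_iterations = as.integer(n_iterations),
    revision_cost_uplift = as.numeric(revision_cost_uplift),
    sd_fraction_costs = as.numeric(sd_fraction_costs),
    sd_fraction_probs = as.numeric(sd_fraction_probs),
    sd_utilities = as.numeric(sd_utilities),
    rng_seed = as.integer(rng_seed),
    post_conversion_revision = isTRUE(post_conversion_revision),
    repeat_events = isTRUE(repeat_events),
    uplift_rsa_revision = isTRUE(uplift_rsa_revision)
  )
  class(s) <- "model_settings"
  validate_settings(s)
  s
}

validate_settings <- function(s, path = "settings") {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("%s.%s: %s", path, field, msg), call. = FALSE)
  }
  chk(length(s$horizon_years) == 1L && !is.na(s$horizon_years) &&
        s$horizon_years >= 1L, "horizon_years", "must be an integer >= 1")
  chk(s$cycle_length_years > 0, "cycle_length_years", "must be positive")
  chk(s$discount_rate >= 0 && s$discount_rate < 1, "discount_rate",
      "must lie in [0, 1)")
  chk(s$wtp >= 0, "wtp", "must be nonnegative")
  chk(s$n_patients >= 1L, "n_patients", "must be >= 1")
  chk(s$n_iterations >= 1L, "n_iterations", "must be >= 1")
  chk(s$revision_cost_uplift >= 0, "revision_cost_uplift",
      "must be nonnegative")
  chk(s$sd_fraction_costs > 0 && s$sd_fraction_costs < 1,
      "sd_fraction_costs", "must lie in (0, 1)")
  chk(s$sd_fraction_probs > 0 && s$sd_fraction_probs < 1,
      "sd_fraction_probs", "must lie in (0, 1)")
  chk(s$sd_utilities > 0 && s$sd_utilities < 0.5, "sd_utilities",
      "must lie in (0, 0.5)")
  invisible(TRUE)
}

#' Parameters of one treatment strategy
#'
#' @param name Strategy label, e.g. `"SCR"`, `"LTTT"`, `"SABS"`, `"RSA"`.
#' @param upfront_cost Cost in $ of the index procedure, booked at cycle 0.
#' @param p_reoperation Annual probability of arthroscopic revision while in
#'   the index success state (for an RSA strategy this is the annual
#'   probability of revision RSA).
#' @param p_conversion Annual probability of conversion to reverse shoulder
#'   arthroplasty (0 for the RSA strategy itself).
#' @param u_success Annual utility accrued in a success state, in \[0, 1\].
#' @param u_failure Optional per-strategy override of the shared
#'   complication-year utility; `NA` (default) means use the config-level
#'   shared value.
#'
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(name, upfront_cost, p_reoperation, p_conversion,
                            u_success, u_failure = NA_real_) {
  st <- list(
    name = as.character(name),
    upfront_cost = as.numeric(upfront_cost),
    p_reoperation = as.numeric(p_reoperation),
    p_conversion = as.numeric(p_conversion),
    u_success = as.numeric(u_success),
    u_failure = as.numeric(u_failure)
  )
  class(st) <- "strategy_params"
  st
}

validate_strategy <- function(st, u_failure_shared, path) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("%s.%s: %s", path, field, msg), call. = FALSE)
  }
  chk(nzchar(st$name), "name", "must be a nonempty string")
  chk(is.finite(st$upfront_cost) && st$upfront_cost > 0, "upfront_cost",
      "must be positive")
  chk(st$p_reoperation >= 0 && st$p_reoperation <= 1, "p_reoperation",
      "must lie in [0, 1]")
  chk(st$p_conversion >= 0 && st$p_conversion <= 1, "p_conversion",
      "must lie in [0, 1]")
  chk(st$p_reoperation + st$p_conversion <= 1, "p_reoperation",
      "p_reoperation + p_conversion must not exceed 1")
  uf <- if (is.na(st$u_failure)) u_failure_shared else st$u_failure
  chk(st$u_success <= 1, "u_success", "must not exceed 1")
  chk(uf >= 0, "u_failure", "must be nonnegative")
  chk(uf <= st$u_success, "u_failure",
      "failure utility must not exceed success utility")
  invisible(TRUE)
}

#' Full decision-model configuration
#'
#' A `model_config` combines the global [model_settings()], an ordered set of
#' [strategy_params()], the shared complication-year utility and the name of
#' the strategy whose upfront cost and success utility govern life after a
#' conversion to reverse shoulder arthroplasty.
#'
#' @param settings A [model_settings()] object.
#' @param strategies A list of [strategy_params()] objects with unique names.
#' @param conversion_target Name of the strategy patients convert to
#'   (default `"RSA"`); must be among `strategies`.
#' @param u_failure Shared utility accrued in the cycle a complication occurs
#'   (default 0.35).
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(settings, strategies, conversion_target = "RSA",
                         u_failure = 0.35) {
  cfg <- list(
    settings = settings,
    strategies = strategies,
    conversion_target = as.character(conversion_target),
    u_failure = as.numeric(u_failure)
  )
  class(cfg) <- "model_config"
  validate_config(cfg)
  cfg
}

#' Validate a decision-model configuration
#'
#' Checks every invariant of the configuration (settings bounds, per-strategy
#' probability and utility bounds, unique strategy names, presence of the
#' conversion target). Errors name the offending field by path, e.g.
#' `strategies[SCR].p_reoperation`.
#'
#' @param config A `model_config` object.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "model_config"))
    stop("config: not a model_config object", call. = FALSE)
  validate_settings(config$settings)
  if (!is.finite(config$u_failure) || config$u_failure < 0 ||
      config$u_failure > 1)
    stop("u_failure: must lie in [0, 1]", call. = FALSE)
  nms <- vapply(config$strategies, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("strategies: duplicated name '%s'", nms[duplicated(nms)][1]),
         call. = FALSE)
  if (!(config$conversion_target %in% nms))
    stop(sprintf("conversion_target: '%s' is not among the strategies",
                 config$conversion_target), call. = FALSE)
  for (st in config$strategies)
    validate_strategy(st, config$u_failure,
                      sprintf("strategies[%s]", st$name))
  invisible(TRUE)
}

strategy_names <- function(config) {
  vapply(config$strategies, function(s) s$name, character(1))
}

get_strategy <- function(config, name) {
  i <- match(name, strategy_names(config))
  if (is.na(i)) stop(sprintf("unknown strategy '%s'", name), call. = FALSE)
  config$strategies[[i]]
}

#' @export
print.model_config <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<model_config> %d strategies | horizon %d y | discount %.1f%% | WTP $%s\n",
    length(x$strategies), s$horizon_years, 100 * s$discount_rate,
    format(s$wtp, big.mark = ",", scientific = FALSE)))
  for (st in x$strategies) {
    cat(sprintf(
      "  %-6s cost $%-8s p_reop %.3f  p_conv %.3f  u_success %.2f%s\n",
      st$name, format(st$upfront_cost, scientific = FALSE),
      st$p_reoperation, st$p_conversion, st$u_success,
      if (st$name == x$conversion_target) "  [conversion target]" else ""))
  }
  cat(sprintf("  shared failure utility %.2f\n", x$u_failure))
  invisible(x)
}

#' Built-in base-case configuration for irreparable rotator cuff tears
#'
#' Returns the package's reference decision problem: four strategies (SCR,
#' LTTT, SABS, RSA) with literature-derived upfront costs, annual
#' reoperation/conversion probabilities and Constant-Murley-derived success
#' utilities, a shared complication-year utility of 0.35, 3% annual
#' discounting over a 10-year horizon of 1-year cycles, a $50,000/QALY
#' willingness-to-pay threshold, a 5% revision-cost uplift and PSA
#' standard-deviation rules (20% of the mean for costs and probabilities,
#' 0.05 absolute for utilities).
#'
#' @param ... Overrides forwarded to [model_settings()].
#' @return A validated `model_config`.
#' @examples
#' cfg <- builtin_irct_config()
#' cfg
#' @export
builtin_irct_config <- function(...) {
  model_config(
    settings = model_settings(...),
    strategies = list(
      strategy_params("SCR",  20837, 0.069, 0.017, 0.76),
      strategy_params("LTTT", 16915, 0.075, 0.050, 0.67),
      strategy_params("SABS",  9058, 0.069, 0.050, 0.69),
      strategy_params("RSA",  17210, 0.080, 0.000, 0.59)
    ),
    conversion_target = "RSA",
    u_failure = 0.35
  )
}

#' Convert a Constant-Murley score to a utility
#'
#' Scales a 0-100 Constant-Murley shoulder score to a \[0, 1\] health-state
#' utility by dividing by 100.
#'
#' @param cms_score Numeric vector of scores on the 0-100 scale.
#' @return Utilities in \[0, 1\].
#' @examples
#' utility_from_cms(76) # 0.76
#' @export
utility_from_cms <- function(cms_score) {
  if (!is.numeric(cms_score) || anyNA(cms_score))
    stop("cms_score: must be numeric without NA", call. = FALSE)
  if (any(cms_score < 0 | cms_score > 100))
    stop("cms_score: must lie in [0, 100]", call. = FALSE)
  cms_score / 100
}

## ---- serialization ---------------------------------------------------------

settings_keys <- c("horizon_years", "cycle_length_years", "discount_rate",
                   "wtp", "n_patients", "n_iterations",
                   "revision_cost_uplift", "sd_fraction_costs",
                   "sd_fraction_probs", "sd_utilities", "rng_seed",
                   "post_conversion_revision", "repeat_events",
                   "uplift_rsa_revision")
strategy_keys <- c("name", "upfront_cost", "p_reoperation", "p_conversion",
                   "u_success", "u_failure")
toplevel_keys <- c("settings", "strategies", "conversion_target", "u_failure")

reject_unknown <- function(x, known, path) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(sprintf("%s: unknown key '%s'", path, extra[1]), call. = FALSE)
}

require_keys <- function(x, required, path) {
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("%s: missing required field '%s'", path, missing[1]),
         call. = FALSE)
}

#' Read a model configuration from a YAML file
#'
#' The file must have top-level keys `settings`, `strategies` (a list of
#' blocks), `conversion_target` and `u_failure`. Parsing is strict: unknown
#' keys are errors naming the key, missing required fields are errors naming
#' the field, and the resulting configuration is validated in full.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `model_config`.
#' @seealso [write_model_config()]; the shipped base case is at
#'   `system.file("extdata", "irct_base_case.yaml", package = "irctcea")`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  reject_unknown(raw, toplevel_keys, "config")
  require_keys(raw, toplevel_keys, "config")
  reject_unknown(raw$settings, settings_keys, "settings")
  require_keys(raw$settings, settings_keys, "settings")
  settings <- do.call(model_settings, raw$settings)
  strategies <- lapply(seq_along(raw$strategies), function(i) {
    blk <- raw$strategies[[i]]
    p <- sprintf("strategies[%d]", i)
    reject_unknown(blk, strategy_keys, p)
    require_keys(blk, setdiff(strategy_keys, "u_failure"), p)
    if (is.null(blk$u_failure)) blk$u_failure <- NA_real_
    do.call(strategy_params, blk)
  })
  model_config(settings, strategies,
               conversion_target = raw$conversion_target,
               u_failure = raw$u_failure)
}

#' Write a model configuration to a YAML file
#'
#' Inverse of [read_model_config()]: `read_model_config(write_model_config(x))`
#' reproduces `x` exactly for any valid configuration (numbers are written at
#' full precision).
#'
#' @param config A validated `model_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_config <- function(config, path) {
  validate_config(config)
  doc <- list(
    settings = unclass(config$settings),
    strategies = lapply(config$strategies, function(st) {
      b <- unclass(st)
      if (is.na(b$u_failure)) b$u_failure <- NULL
      b
    }),
    conversion_target = config$conversion_target,
    u_failure = config$u_failure
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
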