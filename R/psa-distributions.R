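#' Method-of-moments beta parameters
#'
#' Solves for the `(alpha, beta)` shape parameters of a beta distribution
#' with the requested mean and standard deviation:
#' `nu = mean(1-mean)/sd^2 - 1`, `alpha = mean*nu`, `beta = (1-mean)*nu`.
#' The solution is exact, so the constructed distribution reproduces the
#' requested first two moments.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with `sd^2 < mean*(1-mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_params_from_moments(0.5, 0.25) # alpha = beta = 1.5
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (!(mean > 0 && mean < 1))
    stop("beta moments: mean must lie in (0, 1)", call. = FALSE)
  if (!(sd > 0))
    stop("beta moments: sd must be positive", call. = FALSE)
  if (!(sd^2 < mean * (1 - mean)))
    stop("beta moments: infeasible pair, requires sd^2 < mean*(1-mean)",
         call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`; exact for the requested
#' moments. An SD equal to 20% of the mean always yields shape 25.
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_params_from_moments(1, 1) # the exponential case
#' @export
gamma_params_from_moments <- function(mean, sd) {
  if (!(mean > 0)) stop("gamma moments: mean must be positive", call. = FALSE)
  if (!(sd > 0)) stop("gamma moments: sd must be positive", call. = FALSE)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Construct a PSA sampling-distribution specification
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"point"`.
#' @param mean Base-case value (the distribution mean; for `"point"`, the
#'   constant).
#' @param sd Standard deviation (0 for `"point"`).
#' @return An object of class `dist_spec` with derived `shape_params`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "normal", "point"),
                      mean, sd = 0) {
  family <- match.arg(family)
  shape_params <- switch(family,
    beta   = beta_params_from_moments(mean, sd),
    gamma  = gamma_params_from_moments(mean, sd),
    normal = c(mean = mean, sd = sd),
    point  = c(value = mean)
  )
  structure(list(family = family, mean = mean,
                 sd = if (family == "point") 0 else sd,
                 shape_params = shape_params),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(mean %.6g, sd %.6g): %s\n", x$family, x$mean,
              x$sd, paste(sprintf("%s=%.6g", names(x$shape_params),
                                  x$shape_params), collapse = ", ")))
  invisible(x)
}

#' Analytic mean and SD of a distribution spec
#'
#' Recomputed from the derived shape parameters, not echoed from the inputs;
#' used in tests to verify exact moment recovery.
#'
#' @param spec A `dist_spec`.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
spec_moments <- function(spec) {
  p <- spec$shape_params
  switch(spec$family,
    beta = {
      m <- p[["alpha"]] / (p[["alpha"]] + p[["beta"]])
      v <- p[["alpha"]] * p[["beta"]] /
        ((p[["alpha"]] + p[["beta"]])^2 * (p[["alpha"]] + p[["beta"]] + 1))
      c(mean = m, sd = sqrt(v))
    },
    gamma = c(mean = p[["shape"]] * p[["scale"]],
              sd = sqrt(p[["shape"]]) * p[["scale"]]),
    normal = c(mean = p[["mean"]], sd = p[["sd"]]),
    point = c(mean = p[["value"]], sd = 0)
  )
}

#' Build the full set of PSA distributions for a configuration
#'
#' Every cost input receives a gamma distribution with SD
#' `sd_fraction_costs * mean`; every nonzero probability a beta distribution
#' with SD `sd_fraction_probs * mean`; every utility a normal distribution
#' with absolute SD `sd_utilities`. A probability of exactly 0 (the RSA
#' strategy's conversion probability) becomes a degenerate point mass.
#'
#' @param config A validated `model_config`.
#' @return Named list of [dist_spec()] objects with names
#'   `cost_<strategy>`, `p_reoperation_<strategy>`, `p_conversion_<strategy>`,
#'   `u_success_<strategy>` and `u_failure` (plus `u_failure_<strategy>` for
#'   any per-strategy override).
#' @export
build_psa_specs <- function(config) {
  validate_config(config)
  s <- config$settings
  specs <- list()
  add <- function(name, spec) specs[[name]] <<- spec
  prob_spec <- function(p) {
    if (p == 0) dist_spec("point", 0)
    else tryCatch(dist_spec("beta", p, s$sd_fraction_probs * p),
                  error = function(e) stop(conditionMessage(e), call. = FALSE))
  }
  for (st in config$strategies) {
    nm <- st$name
    withCallingHandlers({
      add(paste0("cost_", nm),
          dist_spec("gamma", st$upfront_cost,
                    s$sd_fraction_costs * st$upfront_cost))
      add(paste0("p_reoperation_", nm), prob_spec(st$p_reoperation))
      add(paste0("p_conversion_", nm), prob_spec(st$p_conversion))
      add(paste0("u_success_", nm),
          dist_spec("normal", st$u_success, s$sd_utilities))
      if (!is.na(st$u_failure))
        add(paste0("u_failure_", nm),
            dist_spec("normal", st$u_failure, s$sd_utilities))
    }, error = function(e) {
      stop(sprintf("strategy %s: %s", nm, conditionMessage(e)), call. = FALSE)
    })
  }
  specs[["u_failure"]] <- dist_spec("normal", config$u_failure,
                                    s$sd_utilities)
  specs
}

## one draw from a spec, consuming the current RNG stream
draw_spec <- function(spec, n = 1L) {
  p <- spec$shape_params
  switch(spec$family,
    beta   = stats::rbeta(n, p[["alpha"]], p[["beta"]]),
    gamma  = stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    normal = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    point  = rep(p[["value"]], n)
  )
}

#' Sample one full PSA parameter set
#'
#' Draws every input independently from its spec and assembles a new, valid
#' `model_config`. Sampled utilities are clipped into \[0, 1\]; if a sampled
#' `p_reoperation + p_conversion` exceeds 1 the pair is rescaled
#' proportionally (never triggered at base-case magnitudes).
#'
#' Sampling consumes the R random stream: call `set.seed()` (or let
#' [run_psa()] manage seeding) for reproducibility.
#'
#' @param config The template `model_config`.
#' @param specs Result of [build_psa_specs()]; rebuilt from `config` if
#'   omitted.
#' @return A validated `model_config` with sampled values.
#' @export
sample_parameter_set <- function(config, specs = build_psa_specs(config)) {
  clip01 <- function(x) min(1, max(0, x))
  u_fail <- clip01(draw_spec(specs[["u_failure"]]))
  strategies <- lapply(config$strategies, function(st) {
    nm <- st$name
    pre <- draw_spec(specs[[paste0("p_reoperation_", nm)]])
    pcv <- draw_spec(specs[[paste0("p_conversion_", nm)]])
    if (pre + pcv > 1) {
      tot <- pre + pcv
      pre <- pre / tot
      pcv <- pcv / tot
    }
    us <- clip01(draw_spec(specs[[paste0("u_success_", nm)]]))
    uf <- if (!is.na(st$u_failure))
      clip01(draw_spec(specs[[paste0("u_failure_", nm)]]))
    else NA_real_
    ## a complication cannot leave the patient better off than success
    if (!is.na(uf)) uf <- min(uf, us)
    strategy_params(nm,
                    upfront_cost = draw_spec(specs[[paste0("cost_", nm)]]),
                    p_reoperation = pre, p_conversion = pcv,
                    u_success = us, u_failure = uf)
  })
  u_min <- min(vapply(strategies, function(st) st$u_success, numeric(1)))
  model_config(config$settings, strategies,
               conversion_target = config$conversion_target,
               u_failure = min(u_fail, u_min))
}

#' Analytic quantile range of a distribution spec
#'
#' @param spec A `dist_spec`.
#' @param lo,hi Probability levels (defaults 0.10 and 0.90, the conventional
#'   PSA reporting range).
#' @return Named numeric vector `c(q_lo, q_hi)`; a point mass returns the
#'   constant twice.
#' @export
quantile_range <- function(spec, lo = 0.10, hi = 0.90) {
  p <- spec$shape_params
  q <- switch(spec$family,
    beta   = stats::qbeta(c(lo, hi), p[["alpha"]], p[["beta"]]),
    gamma  = stats::qgamma(c(lo, hi), shape = p[["shape"]],
                           scale = p[["scale"]]),
    normal = stats::qnorm(c(lo, hi), p[["mean"]], p[["sd"]]),
    point  = rep(p[["value"]], 2)
  )
  c(q_lo = q[1], q_hi = q[2])
}

#' Tabulate all PSA specs with their 10-90% ranges
#'
#' One row per model input, mirroring the layout of a published model-inputs
#' table (input name, base value, distribution family, SD, analytic 10th and
#' 90th percentiles) for side-by-side reconciliation.
#'
#' @param config A validated `model_config`.
#' @param lo,hi Quantile levels, as in [quantile_range()].
#' @return A `data.frame` with columns `input`, `base_value`, `family`, `sd`,
#'   `q_lo`, `q_hi`.
#' @export
psa_spec_table <- function(config, lo = 0.10, hi = 0.90) {
  specs <- build_psa_specs(config)
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    qr <- quantile_range(sp, lo, hi)
    data.frame(input = nm, base_value = sp$mean, family = sp$family,
               sd = sp$sd, q_lo = qr[["q_lo"]], q_hi = qr[["q_hi"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
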