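#' Aggregate PSA iterations into per-strategy means and SDs
#'
#' Means and sample standard deviations, across PSA iterations, of the
#' per-iteration arm means of discounted cost and QALYs.
#'
#' @param x A `psa_result` or a long data.frame with columns `iteration`,
#'   `strategy`, `mean_cost`, `mean_qaly`.
#' @return A data.frame with one row per strategy: `strategy`, `mean_cost`,
#'   `sd_cost`, `mean_qaly`, `sd_qaly`, `n_iterations`.
#' @export
aggregate_psa <- function(x) {
  df <- if (inherits(x, "psa_result")) x$iterations else x
  strategies <- unique(df$strategy)
  if (length(unique(df$iteration)) < 2L)
    stop("aggregate_psa requires at least 2 iterations", call. = FALSE)
  rows <- lapply(strategies, function(s) {
    d <- df[df$strategy == s, ]
    data.frame(strategy = s,
               mean_cost = mean(d$mean_cost), sd_cost = stats::sd(d$mean_cost),
               mean_qaly = mean(d$mean_qaly), sd_qaly = stats::sd(d$mean_qaly),
               n_iterations = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Net monetary benefit
#'
#' `NMB = qaly * wtp - cost`: the value of a strategy in monetary terms at a
#' given willingness-to-pay threshold.
#'
#' @param cost,qaly Numeric vectors (recycled).
#' @param wtp Willingness-to-pay in $/QALY, `>= 0`.
#' @return Numeric vector of net monetary benefits in $.
#' @examples
#' nmb(16412, 5.59, 50000)
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be nonnegative", call. = FALSE)
  qaly * wtp - cost
}

#' Dominance classification and incremental cost-effectiveness ratios
#'
#' Sorts strategies by mean cost and classifies each as `undominated`,
#' `absolute_dominated` (another strategy costs no more and yields at least
#' as many QALYs, one strictly) or `extended_dominated` (removed from the
#' efficiency frontier because successive frontier ICERs would be
#' non-monotone, i.e. a blend of two other strategies dominates it).
#' Incremental columns are reported relative to the cheapest strategy --
#' the convention of published league tables, so dominated rows can carry
#' negative ICERs -- and frontier ICERs between successive undominated
#' strategies are attached as the `"frontier"` attribute.
#'
#' @param means A data.frame with columns `strategy`, `mean_cost`,
#'   `mean_qaly` (e.g. from [aggregate_psa()]).
#' @param wtp Willingness-to-pay used for the NMB column.
#' @return A data.frame sorted by mean cost with columns `strategy`,
#'   `mean_cost`, `mean_qaly`, `dominance`, `incremental_cost`,
#'   `incremental_qaly`, `icer` (vs the cheapest; `NA` for the cheapest row
#'   itself), `nmb`. Attribute `"frontier"`: data.frame of successive
#'   undominated pairs and their ICERs.
#' @export
dominance_and_icers <- function(means, wtp = 50000) {
  if (nrow(means) < 2L)
    stop("dominance requires at least 2 strategies", call. = FALSE)
  df <- means[order(means$mean_cost, means$strategy), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  dominance <- rep("undominated", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$mean_cost[j] <= df$mean_cost[i] &&
          df$mean_qaly[j] >= df$mean_qaly[i] &&
          (df$mean_cost[j] < df$mean_cost[i] ||
             df$mean_qaly[j] > df$mean_qaly[i])) {
        dominance[i] <- "absolute_dominated"
        break
      }
    }
  }
  ## extended dominance: prune frontier candidates until ICERs increase
  cand <- which(dominance == "undominated")
  ## exact cost/QALY duplicates: keep the lexicographically first
  if (length(cand) > 1L) {
    dup <- duplicated(df[cand, c("mean_cost", "mean_qaly")])
    dominance[cand[dup]] <- "extended_dominated"
    cand <- cand[!dup]
  }
  repeat {
    if (length(cand) < 3L) break
    ic <- diff(df$mean_cost[cand]) / diff(df$mean_qaly[cand])
    bad <- which(diff(ic) < 0)   # ICER drops => middle point ext. dominated
    if (!length(bad)) break
    dominance[cand[bad[1] + 1L]] <- "extended_dominated"
    cand <- cand[-(bad[1] + 1L)]
  }
  base <- 1L  # cheapest row
  df$dominance <- dominance
  df$incremental_cost <- df$mean_cost - df$mean_cost[base]
  df$incremental_qaly <- df$mean_qaly - df$mean_qaly[base]
  df$icer <- ifelse(seq_len(n) == base, NA_real_,
                    df$incremental_cost / df$incremental_qaly)
  df$nmb <- nmb(df$mean_cost, df$mean_qaly, wtp)
  frontier <- if (length(cand) > 1L) {
    data.frame(strategy = df$strategy[cand[-1]],
               comparator = df$strategy[cand[-length(cand)]],
               icer = diff(df$mean_cost[cand]) / diff(df$mean_qaly[cand]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(strategy = character(0), comparator = character(0),
               icer = numeric(0))
  }
  attr(df, "frontier") <- frontier
  df
}

per_iteration_matrix <- function(psa, what = c("mean_cost", "mean_qaly")) {
  what <- match.arg(what)
  df <- psa$iterations
  strategies <- unique(df$strategy)
  m <- sapply(strategies, function(s) df[[what]][df$strategy == s])
  matrix(m, ncol = length(strategies), dimnames = list(NULL, strategies))
}

#' Optimal-strategy shares at a willingness-to-pay threshold
#'
#' The share of PSA units for which each strategy attains the maximal net
#' monetary benefit at `wtp`. `level = "patient"` counts individual
#' simulated patients (the per-patient reporting convention of
#' microsimulation software; requires `wtp` to lie on the grid used by
#' [run_psa()]); `level = "iteration"` counts PSA iterations using each
#' iteration's arm means (standard acceptability-curve practice). Ties go to
#' the earlier strategy in configuration order (the cheaper base-case
#' procedure should be listed first among equals).
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold (default: the configured one).
#' @param level `"patient"` (default) or `"iteration"`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
optimal_shares <- function(psa, wtp = psa$config$settings$wtp,
                           level = c("patient", "iteration")) {
  level <- match.arg(level)
  if (level == "patient") {
    g <- match(wtp, psa$wtp_grid)
    if (is.na(g))
      stop("patient-level shares are accumulated on the run's wtp_grid; ",
           "requested wtp is not on it", call. = FALSE)
    cnt <- psa$patient_optimal_counts[g, ]
    return(100 * cnt / sum(cnt))
  }
  cost <- per_iteration_matrix(psa, "mean_cost")
  qaly <- per_iteration_matrix(psa, "mean_qaly")
  win <- max.col(qaly * wtp - cost, ties.method = "first")
  cnt <- tabulate(win, nbins = ncol(cost))
  names(cnt) <- colnames(cost)
  100 * cnt / sum(cnt)
}

#' Cost-effectiveness acceptability curves
#'
#' The probability that each strategy is optimal (maximal net monetary
#' benefit) as a function of willingness-to-pay.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Grid of WTP values. For `level = "patient"` it must be a
#'   subset of the grid used by [run_psa()] (default: that whole grid).
#' @param level `"patient"` (default) or `"iteration"`; see
#'   [optimal_shares()].
#' @return A long data.frame of class `ceac_curve`: `wtp`, `strategy`,
#'   `probability`. Probabilities sum to 1 at every grid point.
#' @export
ceac <- function(psa, wtp_grid = NULL,
                 level = c("patient", "iteration")) {
  level <- match.arg(level)
  if (is.null(wtp_grid)) wtp_grid <- psa$wtp_grid
  strategies <- unique(psa$iterations$strategy)
  rows <- lapply(wtp_grid, function(w) {
    p <- optimal_shares(psa, w, level) / 100
    data.frame(wtp = w, strategy = strategies, probability = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Willingness-to-pay at which one acceptability curve overtakes another
#'
#' Scans the curve in increasing WTP for the first grid point at which
#' `strategy`'s probability of being optimal exceeds `comparator`'s, and
#' linearly interpolates the crossing between that point and the previous
#' one.
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @param strategy,comparator Strategy names on the curve.
#' @return The crossover WTP in $/QALY, or `NA_real_` if `strategy` never
#'   overtakes `comparator` on the grid.
#' @export
crossover_wtp <- function(curve, strategy, comparator) {
  for (s in c(strategy, comparator))
    if (!s %in% curve$strategy)
      stop(sprintf("strategy '%s' not on the curve", s), call. = FALSE)
  w <- sort(unique(curve$wtp))
  p1 <- curve$probability[curve$strategy == strategy][order(curve$wtp[curve$strategy == strategy])]
  p2 <- curve$probability[curve$strategy == comparator][order(curve$wtp[curve$strategy == comparator])]
  d <- p1 - p2
  idx <- which(d > 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(w[1])
  w[i - 1] + (0 - d[i - 1]) * (w[i] - w[i - 1]) / (d[i] - d[i - 1])
}

#' Per-iteration incremental cost/QALY pairs
#'
#' The raw material of incremental scatterplots and confidence ellipses on
#' the cost-effectiveness plane: for each PSA iteration, the difference in
#' arm means between `strategy` and `comparator`.
#'
#' @param psa A `psa_result`.
#' @param strategy,comparator Strategy names.
#' @param level `"iteration"` (default) pairs arm means per iteration;
#'   `"patient"` pairs same-indexed patients (requires
#'   `run_psa(keep_patients = TRUE)`).
#' @return A data.frame with columns `delta_cost`, `delta_qaly`.
#' @export
incremental_pairs <- function(psa, strategy, comparator,
                              level = c("iteration", "patient")) {
  level <- match.arg(level)
  if (level == "iteration") {
    cost <- per_iteration_matrix(psa, "mean_cost")
    qaly <- per_iteration_matrix(psa, "mean_qaly")
    data.frame(delta_cost = cost[, strategy] - cost[, comparator],
               delta_qaly = qaly[, strategy] - qaly[, comparator])
  } else {
    if (is.null(psa$patients))
      stop("patient-level pairs require run_psa(keep_patients = TRUE)",
           call. = FALSE)
    a <- psa$patients[psa$patients$strategy == strategy, ]
    b <- psa$patients[psa$patients$strategy == comparator, ]
    data.frame(delta_cost = a$cost - b$cost,
               delta_qaly = a$qaly - b$qaly)
  }
}

#' Confidence ellipse on the incremental cost-effectiveness plane
#'
#' Fits the standard normal-theory confidence ellipse to a cloud of
#' incremental (cost, QALY) pairs: center at the sample mean, axes along the
#' eigenvectors of the 2x2 sample covariance, semi-axis lengths
#' `sqrt(lambda_i * qchisq(level, df = 2))` (at the default 0.95 level the
#' chi-square quantile is 5.991).
#'
#' @param pairs A two-column matrix or data.frame (`delta_cost`,
#'   `delta_qaly`) with at least 3 rows.
#' @param level Confidence level (default 0.95).
#' @return An object of class `cea_ellipse`: list with `center`, `radii`
#'   (semi-axis lengths, major first), `angle` (radians of the major axis),
#'   `cov`, `level` and `degenerate` (TRUE when the covariance is
#'   numerically singular, in which case `radii`/`angle` are `NA`).
#' @export
confidence_ellipse <- function(pairs, level = 0.95) {
  m <- as.matrix(pairs)
  if (nrow(m) < 3L)
    stop("confidence_ellipse requires at least 3 pairs", call. = FALSE)
  center <- colMeans(m)
  S <- stats::cov(m)
  e <- eigen(S, symmetric = TRUE)
  degenerate <- !all(is.finite(e$values)) || e$values[1] <= 0 ||
    e$values[2] <= .Machine$double.eps * e$values[1]
  k <- stats::qchisq(level, df = 2)
  out <- list(
    center = center,
    radii = if (degenerate) c(NA_real_, NA_real_) else sqrt(e$values * k),
    angle = if (degenerate) NA_real_ else
      atan2(e$vectors[2, 1], e$vectors[1, 1]),
    cov = S, level = level, degenerate = degenerate)
  class(out) <- "cea_ellipse"
  out
}

#' @export
print.cea_ellipse <- function(x, ...) {
  if (x$degenerate) {
    cat("<cea_ellipse> degenerate (singular covariance)\n")
  } else {
    cat(sprintf(
      "<cea_ellipse> level %.2f, center (%.4g, %.4g), semi-axes %.4g / %.4g, angle %.3f rad\n",
      x$level, x$center[1], x$center[2], x$radii[1], x$radii[2], x$angle))
  }
  invisible(x)
}

#' Points on the boundary of a confidence ellipse
#'
#' @param ellipse A `cea_ellipse`.
#' @param n Number of boundary points.
#' @return A matrix with columns `delta_cost`, `delta_qaly`.
#' @export
ellipse_boundary <- function(ellipse, n = 100L) {
  if (ellipse$degenerate)
    stop("degenerate ellipse has no boundary", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$radii[1] * cos(th), ellipse$radii[2] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  pts <- t(rot %*% u + ellipse$center)
  colnames(pts) <- c("delta_cost", "delta_qaly")
  pts
}

#' League table of cost-effectiveness results
#'
#' Combines [aggregate_psa()], [dominance_and_icers()], per-iteration NMB
#' spread and optimal shares into one table in the layout of a published
#' cost-utility league table: per strategy, mean +/- SD cost and QALYs,
#' dominance label, incremental cost/QALYs and ICER relative to the cheapest
#' strategy, NMB +/- SD at `wtp`, and the percentage of PSA units for which
#' the strategy is optimal.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay (default: configured).
#' @param level Share level, `"patient"` (default) or `"iteration"`; see
#'   [optimal_shares()].
#' @return A data.frame of class `cea_table`, sorted by mean cost, with the
#'   frontier ICERs attached as attribute `"frontier"`.
#' @export
cea_table <- function(psa, wtp = psa$config$settings$wtp,
                      level = c("patient", "iteration")) {
  level <- match.arg(level)
  agg <- aggregate_psa(psa)
  dom <- dominance_and_icers(agg[, c("strategy", "mean_cost", "mean_qaly")],
                             wtp = wtp)
  nmb_it <- nmb(per_iteration_matrix(psa, "mean_cost"),
                per_iteration_matrix(psa, "mean_qaly"), wtp)
  sh <- optimal_shares(psa, wtp, level)
  out <- merge(dom, agg[, c("strategy", "sd_cost", "sd_qaly")],
               by = "strategy", sort = FALSE)
  out$sd_nmb <- apply(nmb_it, 2, stats::sd)[out$strategy]
  out$pct_optimal <- unname(sh[out$strategy])
  out <- out[order(out$mean_cost, out$strategy), ]
  rownames(out) <- NULL
  attr(out, "frontier") <- attr(dom, "frontier")
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_table", class(out))
  out
}
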