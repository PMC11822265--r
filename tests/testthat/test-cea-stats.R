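test_that("aggregation computes means and sample SDs across iterations", {
  cost <- cbind(A = c(10, 20), B = c(5, 5))
  qaly <- cbind(A = c(1, 1), B = c(2, 2))
  psa <- fake_psa(cost, qaly)
  agg <- aggregate_psa(psa)
  expect_equal(agg$mean_cost[agg$strategy == "A"], 15)
  expect_equal(agg$sd_cost[agg$strategy == "A"], sqrt(50), tolerance = 1e-12)
  expect_equal(agg$sd_cost[agg$strategy == "B"], 0)
  expect_error(aggregate_psa(fake_psa(cost[1, , drop = FALSE],
                                      qaly[1, , drop = FALSE])),
               "2 iterations")
})

test_that("net monetary benefit is qaly x wtp - cost", {
  expect_equal(nmb(16412, 5.59, 50000), 263088)
  expect_equal(nmb(0, 0, 50000), 0)
  expect_equal(nmb(30540, 6.17, 0), -30540)
  expect_error(nmb(1, 1, -5), "wtp")
})

test_that("dominance classification reproduces the textbook cases", {
  # costlier strategy with equal QALYs is absolutely dominated
  df <- data.frame(strategy = c("cheap", "dear"), mean_cost = c(5, 10),
                   mean_qaly = c(1, 1))
  out <- dominance_and_icers(df)
  expect_equal(out$dominance[out$strategy == "dear"], "absolute_dominated")
  expect_equal(out$dominance[out$strategy == "cheap"], "undominated")
  # middle point with non-monotone pairwise ICERs is extended-dominated
  df <- data.frame(strategy = c("a", "b", "c"), mean_cost = c(0, 1, 2),
                   mean_qaly = c(0, 0.1, 1))
  out <- dominance_and_icers(df)
  expect_equal(out$dominance[out$strategy == "b"], "extended_dominated")
  expect_equal(attr(out, "frontier")$icer, 2 / 1)
  expect_error(dominance_and_icers(df[1, ]), "2 strategies")
})

test_that("dominance agrees with brute-force blend enumeration", {
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    df <- data.frame(strategy = paste0("s", 1:k),
                     mean_cost = runif(k, 1000, 30000),
                     mean_qaly = runif(k, 1, 8))
    out <- dominance_and_icers(df)
    expected <- brute_dominance(out)
    expect_equal(out$dominance, expected,
                 info = sprintf("replicate %d", rep))
  }
})

test_that("acceptability curves are proper probabilities at every WTP", {
  set.seed(5)
  n <- 200
  cost <- cbind(A = rnorm(n, 10000, 2000), B = rnorm(n, 14000, 2000),
                C = rnorm(n, 20000, 3000))
  qaly <- cbind(A = rnorm(n, 4, 0.4), B = rnorm(n, 4.5, 0.4),
                C = rnorm(n, 5, 0.4))
  psa <- fake_psa(cost, qaly)
  cv <- ceac(psa, level = "iteration")
  sums <- tapply(cv$probability, cv$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  cvp <- ceac(psa, level = "patient")
  sums <- tapply(cvp$probability, cvp$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a strategy that always wins has a flat curve at 1
  solo <- fake_psa(cbind(A = rep(1, 5), B = rep(10, 5)),
                   cbind(A = rep(2, 5), B = rep(1, 5)))
  cv1 <- ceac(solo, level = "iteration")
  expect_true(all(cv1$probability[cv1$strategy == "A"] == 1))
})

test_that("mean-NMB argmax matches walking the ICER frontier", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    df <- data.frame(strategy = paste0("s", 1:k),
                     mean_cost = runif(k, 1000, 30000),
                     mean_qaly = runif(k, 1, 8))
    wtp <- runif(1, 0, 80000)
    out <- dominance_and_icers(df, wtp = wtp)
    best_nmb <- out$strategy[which.max(out$nmb)]
    # frontier walk: start at the cheapest undominated strategy, step up
    # whenever the incremental ICER is below the WTP
    fr <- attr(out, "frontier")
    walk <- out$strategy[out$dominance == "undominated"][1]
    for (i in seq_len(nrow(fr)))
      if (fr$icer[i] <= wtp) walk <- fr$strategy[i]
    expect_equal(best_nmb, walk, info = sprintf("replicate %d", rep))
    # absolutely dominated strategies never attain maximal NMB
    expect_false(best_nmb %in%
                   out$strategy[out$dominance == "absolute_dominated"])
  }
})

test_that("CEAC crossover is located at the indifference threshold", {
  # deterministic two-strategy problem: B overtakes A at dCost/dQALY
  n <- 50
  cost <- cbind(A = rep(0, n), B = rep(5000, n))
  qaly <- cbind(A = rep(1, n), B = rep(1.5, n))
  psa <- fake_psa(cost, qaly, wtp_grid = seq(0, 50000, 1000))
  cv <- ceac(psa, level = "iteration")
  x <- crossover_wtp(cv, "B", "A")
  expect_lt(abs(x - 5000 / 0.5), 1000)  # within one grid step
  # A leads from WTP zero, so its "crossover" is the grid origin
  expect_equal(crossover_wtp(cv, "A", "B"), 0)
  # a strategy that is never optimal produces no crossover
  cost2 <- cbind(A = rep(0, 10), B = rep(5000, 10))
  qaly2 <- cbind(A = rep(1, 10), B = rep(1, 10))
  cv2 <- ceac(fake_psa(cost2, qaly2, wtp_grid = seq(0, 50000, 1000)),
              level = "iteration")
  expect_true(is.na(crossover_wtp(cv2, "B", "A")))
  expect_error(crossover_wtp(cv, "Z", "A"), "not on the curve")
})

test_that("confidence ellipses have chi-square geometry and coverage", {
  set.seed(99)
  n <- 100000
  pts <- cbind(delta_cost = rnorm(n), delta_qaly = rnorm(n))
  el <- confidence_ellipse(pts)
  expect_false(el$degenerate)
  expect_equal(unname(el$radii), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.02)
  # empirical coverage from the ellipse's own parametrization
  rot <- matrix(c(cos(el$angle), sin(el$angle),
                  -sin(el$angle), cos(el$angle)), 2, 2)
  z <- sweep(pts, 2, el$center) %*% rot
  inside <- (z[, 1] / el$radii[1])^2 + (z[, 2] / el$radii[2])^2 <= 1
  expect_lt(abs(mean(inside) - 0.95), 0.01)
  # correlated sample: reconstructed covariance matches the fit
  S <- matrix(c(4, 1.5, 1.5, 1), 2)
  ch <- chol(S)
  pts2 <- cbind(rnorm(20000), rnorm(20000)) %*% ch
  el2 <- confidence_ellipse(pts2)
  k <- qchisq(0.95, 2)
  R <- matrix(c(cos(el2$angle), sin(el2$angle),
                -sin(el2$angle), cos(el2$angle)), 2, 2)
  S_hat <- R %*% diag(el2$radii^2 / k) %*% t(R)
  expect_equal(S_hat, unname(el2$cov), tolerance = 1e-9)
  # boundary points satisfy the quadratic form
  b <- ellipse_boundary(el2, 32)
  zb <- sweep(b, 2, el2$center) %*% R
  expect_true(all(abs((zb[, 1] / el2$radii[1])^2 +
                        (zb[, 2] / el2$radii[2])^2 - 1) < 1e-9))
  # degenerate cloud is flagged
  el3 <- confidence_ellipse(matrix(1, 5, 2))
  expect_true(el3$degenerate)
  expect_error(confidence_ellipse(pts[1:2, ]), "3 pairs")
})

test_that("the league table is internally consistent", {
  set.seed(12)
  cfg <- builtin_irct_config()
  psa <- run_psa(cfg, n_iterations = 30, n_patients = 50, seed = 4)
  tab <- cea_table(psa)
  expect_equal(sum(tab$pct_optimal), 100, tolerance = 0.01)
  expect_equal(tab$nmb, tab$mean_qaly * 50000 - tab$mean_cost,
               tolerance = 1e-9)
  expect_true(!is.unsorted(tab$mean_cost))
  expect_setequal(tab$strategy, c("SCR", "LTTT", "SABS", "RSA"))
  tab_it <- cea_table(psa, level = "iteration")
  expect_equal(sum(tab_it$pct_optimal), 100, tolerance = 0.01)
})
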