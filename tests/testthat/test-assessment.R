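# model comparison (DIC, PPO, Brier) and spatial autocorrelation

test_that("dic_from_deviance reduces correctly in closed-form cases", {
  # constant deviance: DIC = d, pD = 0
  d <- dic_from_deviance(rep(123.4, 1000), 123.4)
  expect_equal(d$dic, 123.4)
  expect_equal(d$pd, 0)
  # conjugate-normal toy: y ~ N(mu, 1), flat prior, posterior N(ybar, 1/n);
  # analytic pD = 1
  set.seed(9)
  n <- 50
  y <- rnorm(n, 2, 1)
  mu_draws <- rnorm(40000, mean(y), 1 / sqrt(n))
  dev <- vapply(mu_draws, function(m) sum((y - m)^2) + n * log(2 * pi),
                numeric(1))
  dhat <- sum((y - mean(mu_draws))^2) + n * log(2 * pi)
  toy <- dic_from_deviance(dev, dhat)
  expect_equal(toy$pd, 1, tolerance = 0.05)
  expect_equal(toy$dic, toy$dbar + toy$pd, tolerance = 1e-10)
})

test_that("dic on a fit is reproducible from stored draws", {
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 4)
  fit <- fit_zi(sim$data, zi_model("zip", "independent", "none"),
                mcmc = mcmc_config(iterations = 1200, burn_in = 600, seed = 1))
  d1 <- dic(fit)
  d2 <- dic(fit)
  expect_equal(d1$dic, d2$dic, tolerance = 1e-10)
  expect_equal(d1$dic, 2 * d1$dbar - d1$dhat, tolerance = 1e-10)
  # deviance stored by the sampler equals -2 lnL recomputed in R at a draw
  dr <- fit$chains[[1]]
  k <- 7
  lp <- linear_predictors(fit$design, alpha = dr$alpha[k, ],
                          beta = dr$beta[k, ],
                          zero_effects = dr$vartheta[k, ],
                          count_effects = dr$theta[k, ])
  dev_r <- -2 * sum(zip_logpmf(fit$design$y, lp$nu, lp$pi))
  expect_equal(unname(dr$scalars[k, "deviance"]), dev_r, tolerance = 1e-8)
})

test_that("ppo averages the per-draw pmf over the support", {
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 6)
  fit <- fit_zi(sim$data, zi_model("zip", "independent", "none"),
                mcmc = mcmc_config(iterations = 900, burn_in = 600, seed = 2))
  # single draw: PPO equals that draw's pmf row exactly
  one <- fit
  one$chains <- list(lapply(fit$chains[[1]], function(m)
    m[1, , drop = FALSE]))
  smax <- max(fit$design$y) + 5L
  P <- ppo(one, support_max = smax)
  dr <- fit$chains[[1]]
  lp <- linear_predictors(fit$design, alpha = dr$alpha[1, ],
                          beta = dr$beta[1, ],
                          zero_effects = dr$vartheta[1, ],
                          count_effects = dr$theta[1, ])
  for (k in c(1, 4)) {
    expect_equal(P[k, ], exp(zip_logpmf(0:smax, lp$nu[k], lp$pi[k])),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # rows are sub-probability vectors over the truncated support
  Pfull <- ppo(fit)
  expect_true(all(Pfull >= 0))
  expect_true(all(rowSums(Pfull) <= 1 + 1e-12))
  # the default truncation captures nearly all predictive mass for typical
  # facilities; the largest hospitals can carry mass beyond it
  expect_gt(median(rowSums(Pfull)), 0.95)
  # averaging property: PPO of all draws = mean of per-draw pmfs at s = 0
  expect_error(ppo(fit, support_max = max(fit$design$y) - 1), "support")
})

test_that("brier_score has its closed-form values and propriety", {
  # perfect predictor: mass 1 at each observed value
  y <- c(0L, 3L, 1L)
  P <- matrix(0, 3, 5)
  P[cbind(1:3, y + 1)] <- 1
  expect_equal(brier_score(P, y), 0)
  # uniform two-point toy: -((0.5-1)^2 + (0.5-0)^2) = -0.5
  expect_equal(brier_score(matrix(c(0.5, 0.5), 1), 0L), -0.5)
  # propriety spot check on a 2-point support: the score strictly decreases
  # as predictive mass moves away from the observation
  ps <- seq(1, 0, by = -0.1)
  scores <- vapply(ps, function(p) brier_score(matrix(c(p, 1 - p), 1), 0L),
                   numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_equal(max(scores), 0)
  expect_error(brier_score(matrix(c(0.5, 0.5), 1), 5L), "support")
})

test_that("morans_i detects the sign of autocorrelation and matches ape", {
  g4 <- make_lattice_graph(4, 4)
  # checkerboard: strong negative autocorrelation
  chk <- as.numeric(outer(1:4, 1:4, "+") %% 2 == 0)
  m1 <- morans_i(chk, g4, permutations = 999)
  expect_lt(m1$statistic, 0)
  # smooth two-block gradient: positive autocorrelation, small p
  grad <- as.numeric(outer(1:4, 1:4, "+"))
  m2 <- morans_i(grad, g4, permutations = 999)
  expect_gt(m2$statistic, 0)
  expect_lt(m2$p_perm, 0.01)
  expect_lt(m2$p_norm, 0.01)
  # agreement with the ape implementation (statistic, expectation, sd, p)
  skip_if_not_installed("ape")
  set.seed(12)
  v <- rnorm(16) + grad / 4
  # ape row-standardises the weight matrix internally
  mine <- morans_i(v, g4, weights = "row", permutations = 999,
                   alternative = "two.sided")
  ref <- ape::Moran.I(v, adjacency_matrix(g4), alternative = "two.sided")
  expect_equal(mine$statistic, ref$observed, tolerance = 1e-12)
  expect_equal(mine$expectation, ref$expected, tolerance = 1e-12)
  expect_equal(mine$sd, ref$sd, tolerance = 1e-12)
  expect_equal(mine$p_norm, ref$p.value, tolerance = 1e-12)
  # permutation and analytic p agree within permutation error on a null draw
  set.seed(30)
  null_v <- rnorm(16)
  m0 <- morans_i(null_v, g4, permutations = 9999)
  expect_lt(abs(m0$p_perm - m0$p_norm), 0.05)
  expect_error(morans_i(rep(1, 16), g4), "constant")
})

test_that("permutation p-values are calibrated under the null", {
  g <- make_lattice_graph(3, 3)
  set.seed(40)
  ps <- vapply(1:40, function(i) {
    morans_i(rnorm(9), g, permutations = 199)$p_perm
  }, numeric(1))
  # roughly uniform: mean near 0.5, spread over (0, 1)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(max(ps) - min(ps), 0.4)
})
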