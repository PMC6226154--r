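# posterior sampling: simulate-recover toys, conjugate and external oracles,
# determinism, prior-only validation, summaries and diagnostics

test_that("intercept-only ZIP recovers its generator", {
  set.seed(11)
  n <- 500
  y <- rzi(n, nu = 2, pi = 0.3)
  tab <- intercept_only_table(y, N = 1000L, n_districts = 10)
  fit <- fit_intercept_only(tab, zi_model("zip", "none", "none"),
                            iterations = 8000, burn_in = 4000, seed = 3)
  s <- posterior_summary(fit)
  b0 <- s[s$parameter == "beta_(Intercept)", ]
  a0 <- s[s$parameter == "alpha_(Intercept)", ]
  truth_b0 <- log(2 / 1000)
  truth_a0 <- qlogis(0.3)
  expect_lt(abs(b0$mean - truth_b0), 3.5 * b0$sd)
  expect_lt(abs(a0$mean - truth_a0), 3.5 * a0$sd)
  expect_true(b0$conf.low < truth_b0 && truth_b0 < b0$conf.high)
  expect_true(a0$conf.low < truth_a0 && truth_a0 < a0$conf.high)
})

test_that("Poisson toy matches the conjugate Gamma posterior", {
  # flat prior on log(rate) corresponds to p(lambda) ~ 1/lambda, for which
  # the posterior is Gamma(sum y, sum N) in closed form
  set.seed(4)
  N <- sample(200:800, 40, replace = TRUE)
  lam <- 0.01
  y <- rpois(40, N * lam)
  tab <- intercept_only_table(y, N = N)
  fit <- fit_intercept_only(tab, zi_model("poisson", "none", "none"),
                            priors = prior_spec(beta_prec_fixed = 1e-8),
                            iterations = 12000, burn_in = 4000, seed = 5)
  lam_draws <- exp(.subset2(fit$chains[[1]], "beta")[, 1])
  a_post <- sum(y); b_post <- sum(N)
  expect_lt(abs(mean(lam_draws) - a_post / b_post) / (a_post / b_post), 0.02)
  expect_lt(abs(var(lam_draws) - a_post / b_post^2) / (a_post / b_post^2), 0.2)
  # 95% interval endpoints agree with the analytic Gamma quantiles
  qs <- quantile(lam_draws, c(0.025, 0.975))
  expect_equal(unname(qs), qgamma(c(0.025, 0.975), a_post, b_post),
               tolerance = 0.02)
})

test_that("identical seed and configuration reproduce draws bitwise", {
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 2)
  mc <- mcmc_config(iterations = 400, burn_in = 200, seed = 9)
  f1 <- fit_zi(sim$data, zi_model("zip", "independent", "icar"),
               graph = sim$graph, mcmc = mc)
  f2 <- fit_zi(sim$data, zi_model("zip", "independent", "icar"),
               graph = sim$graph, mcmc = mc)
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$scalars, f2$chains[[1]]$scalars)
  # a different seed moves the draws
  f3 <- fit_zi(sim$data, zi_model("zip", "independent", "icar"),
               graph = sim$graph,
               mcmc = mcmc_config(iterations = 400, burn_in = 200, seed = 10))
  expect_false(identical(f1$chains[[1]]$beta, f3$chains[[1]]$beta))
})

test_that("posterior matches an independent JAGS fit on a ZIP toy", {
  skip_if_not_installed("rjags")
  set.seed(21)
  n <- 300
  y <- rzi(n, nu = 3, pi = 0.35)
  tab <- intercept_only_table(y, N = 1000L)
  fit <- fit_intercept_only(tab, zi_model("zip", "none", "none"),
                            priors = prior_spec(beta_prec_fixed = 1e-2,
                                                alpha_prec_fixed = 1e-2),
                            iterations = 20000, burn_in = 5000, seed = 6)
  s <- posterior_summary(fit)

  model_string <- "model {
    for (i in 1:n) {
      z[i] ~ dbern(p)
      mu[i] <- (1 - z[i]) * exp(b0 + log_N[i]) + 1.0E-10
      y[i] ~ dpois(mu[i])
    }
    logit(p) <- a0
    a0 ~ dnorm(0, 1.0E-2)
    b0 ~ dnorm(0, 1.0E-2)
  }"
  jm <- rjags::jags.model(textConnection(model_string),
                          data = list(y = y, n = n, log_N = rep(log(1000), n)),
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 7),
                          n.chains = 1, quiet = TRUE)
  update(jm, 5000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("a0", "b0"), n.iter = 15000,
                            progress.bar = "none")
  jmeans <- colMeans(as.matrix(js))
  expect_lt(abs(s$mean[s$parameter == "beta_(Intercept)"] - jmeans["b0"]), 0.05)
  expect_lt(abs(s$mean[s$parameter == "alpha_(Intercept)"] - jmeans["a0"]), 0.10)
})

test_that("prior-only sampling reproduces the prior block", {
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 13)
  pr <- prior_spec(beta_prec_fixed = 1, alpha_prec_fixed = 1,
                   re_prec_gamma = c(3, 3))
  fit <- fit_zi(sim$data, zi_model("zip", "independent", "none"),
                priors = pr, prior_only = TRUE,
                mcmc = mcmc_config(iterations = 30000, burn_in = 5000,
                                   seed = 31))
  beta <- fit$chains[[1]]$beta
  # fixed-precision-1 normals: unit scale, zero centre
  expect_lt(max(abs(colMeans(beta))), 0.15)
  expect_true(all(abs(apply(beta, 2, sd) - 1) < 0.2))
  # Gamma(3, 3) precision hyperprior on district intercepts (shape/rate):
  # E[precision] = 1, SD = 1/sqrt(3)
  prec <- 1 / fit$chains[[1]]$scalars[, "sigma2_theta"]
  expect_lt(abs(mean(prec) - 1), 0.15)
  expect_lt(abs(sd(prec) - 1 / sqrt(3)), 0.15)
  # correlated structure: Wishart-implied correlation is centred at zero
  fitc <- fit_zi(sim$data, zi_model("zip", "correlated", "none"),
                 priors = pr, prior_only = TRUE,
                 mcmc = mcmc_config(iterations = 60000, burn_in = 10000,
                                    seed = 33))
  rho <- fitc$chains[[1]]$scalars[, "rho"]
  # Wishart-Gibbs prior draws are strongly autocorrelated (integrated
  # autocorrelation time ~100 sweeps); the bound is ~4 MCSE at this length
  expect_lt(abs(mean(rho)), 0.12)
})

test_that("shared structure keeps vartheta proportional within each draw", {
  sim <- simulate_dataset(generator_config(rows = 4, cols = 4,
                                           effects = "shared", zeta = 1.5,
                                           spatial = "none"), seed = 17)
  fit <- fit_zi(sim$data, zi_model("zip", "shared", "none"),
                mcmc = mcmc_config(iterations = 1500, burn_in = 500, seed = 2))
  th <- fit$chains[[1]]$theta
  vt <- fit$chains[[1]]$vartheta
  zeta <- fit$chains[[1]]$scalars[, "zeta"]
  expect_lt(max(abs(vt - th * zeta)), 1e-10)
  # implied variance identity sigma_vartheta^2 = zeta^2 sigma_theta^2
  sc <- fit$chains[[1]]$scalars
  expect_lt(max(abs(sc[, "sigma2_vartheta"] - zeta^2 * sc[, "sigma2_theta"])),
            1e-10)
})

test_that("posterior_summary and summarize_draws report means and intervals", {
  set.seed(8)
  draws <- cbind(z = rnorm(1e6), c = rep(2.5, 1e6))
  s <- summarize_draws(draws)
  expect_equal(s$mean[s$parameter == "z"], 0, tolerance = 0.01)
  expect_equal(s$conf.low[s$parameter == "z"], -1.96, tolerance = 0.02)
  expect_equal(s$conf.high[s$parameter == "z"], 1.96, tolerance = 0.02)
  # constant chain: interval collapses to the constant
  expect_equal(s$mean[s$parameter == "c"], 2.5)
  expect_equal(s$conf.low[s$parameter == "c"], 2.5)
  expect_equal(s$conf.high[s$parameter == "c"], 2.5)
})

test_that("convergence diagnostics flag degeneracy and separation", {
  # two identical constant chains: degenerate, zero effective draws
  const <- list(matrix(1, 500, 1, dimnames = list(NULL, "p")),
                matrix(1, 500, 1, dimnames = list(NULL, "p")))
  r <- convergence_report(const)
  expect_true(r$degenerate)
  expect_equal(r$ess, 0)
  # independent standard-normal chains: scale reduction near 1
  set.seed(14)
  iid <- list(matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "p")),
              matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "p")))
  r2 <- convergence_report(iid)
  expect_lt(abs(r2$rhat - 1), 0.05)
  expect_gt(r2$ess, 2000)
  # deliberately offset chains: scale reduction far above 1.1
  off <- list(matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "p")),
              matrix(rnorm(2000, mean = 5), ncol = 1, dimnames = list(NULL, "p")))
  r3 <- convergence_report(off)
  expect_gt(r3$rhat, 1.5)
  # works on a fitted object with two chains
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 3)
  fit <- fit_zi(sim$data, zi_model("zip", "independent", "none"),
                mcmc = mcmc_config(iterations = 800, burn_in = 400,
                                   chains = 2, seed = 5))
  rf <- convergence_report(fit)
  expect_true(all(is.finite(rf$rhat)))
  expect_true(all(rf$ess > 0))
})

test_that("spatial misuse is rejected with informative errors", {
  sim <- simulate_dataset(generator_config(rows = 3, cols = 3), seed = 2)
  expect_error(fit_zi(sim$data, zi_model("zip", "independent", "icar")),
               "adjacency")
  # districts in the data must be nodes of the supplied graph
  small <- make_lattice_graph(2, 2)
  expect_error(fit_zi(sim$data, zi_model("zip", "independent", "icar"),
                      graph = small), "not in adjacency graph")
})
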