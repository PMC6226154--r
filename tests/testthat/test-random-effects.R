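# non-spatial bivariate intercepts and CAR structures

test_that("district_effects_logdensity matches a dense multivariate oracle", {
  # one district at the origin with identity covariance: -log(2*pi)
  expect_equal(district_effects_logdensity(0, 0, "correlated",
                                           sigma2_theta = 1,
                                           sigma2_vartheta = 1, rho = 0),
               -log(2 * pi), tolerance = 1e-12)
  # independent is correlated with rho = 0
  set.seed(3)
  th <- rnorm(5); vt <- rnorm(5)
  expect_equal(
    district_effects_logdensity(th, vt, "independent",
                                sigma2_theta = 1.3, sigma2_vartheta = 0.6),
    district_effects_logdensity(th, vt, "correlated",
                                sigma2_theta = 1.3, sigma2_vartheta = 0.6,
                                rho = 0))
  # generic dense-covariance oracle: block-diagonal MVN over all districts
  s2t <- 1.6; s2v <- 0.77; rho <- 0.44
  S <- matrix(c(s2t, rho * sqrt(s2t * s2v), rho * sqrt(s2t * s2v), s2v), 2)
  big <- kronecker(diag(5), S)
  x <- as.vector(rbind(th, vt))
  oracle <- -0.5 * (length(x) * log(2 * pi) +
                    determinant(big)$modulus[1] +
                    drop(x %*% solve(big) %*% x))
  expect_equal(district_effects_logdensity(th, vt, "correlated",
                                           sigma2_theta = s2t,
                                           sigma2_vartheta = s2v, rho = rho),
               oracle, tolerance = 1e-10)
  # shared structure: density on theta only, vartheta deterministic
  expect_equal(district_effects_logdensity(th, 2 * th, "shared",
                                           sigma2_theta = 1, zeta = 2),
               sum(dnorm(th, 0, 1, log = TRUE)))
  expect_error(district_effects_logdensity(th, vt, "shared",
                                           sigma2_theta = 1, zeta = 2),
               "vartheta == zeta")
})

test_that("icar_log_kernel equals the pairwise-difference and matrix forms", {
  g2 <- as_zi_graph(list(A = "B", B = "A"))
  u <- c(1.7, -0.3)
  s2 <- 0.8
  expect_equal(icar_log_kernel(u, g2, s2), -(1.7 + 0.3)^2 / (2 * s2))
  # constant field: improper along the constant direction
  expect_equal(icar_log_kernel(rep(3.2, 2), g2, s2), 0)
  # matrix oracle on the 3x3 rook lattice: -(1/2) u' (D - W) u / sigma2
  g <- make_lattice_graph(3, 3)
  set.seed(5)
  for (rep in 1:5) {
    u <- rnorm(9)
    Q <- graph_laplacian(g) / s2
    expect_equal(icar_log_kernel(u, g, s2), -0.5 * drop(u %*% Q %*% u),
                 tolerance = 1e-12)
    # shift invariance
    expect_equal(icar_log_kernel(u + rnorm(1), g, s2),
                 icar_log_kernel(u, g, s2), tolerance = 1e-9)
  }
})

test_that("proper CAR conditionals follow the neighbour-average form", {
  g <- make_lattice_graph(3, 3)
  u <- numeric(9)
  # single-neighbour arithmetic via a 2-node path
  g2 <- as_zi_graph(list(A = "B", B = "A"))
  cc <- proper_car_conditional(1, c(0, 2.5), g2, psi = 1, sigma2 = 0.7)
  expect_equal(cc$mean, 2.5)
  expect_equal(cc$var, 0.7)
  # psi = 0: mean 0, variance sigma2 / m_i
  centre <- which(g$m == 4)
  cc0 <- proper_car_conditional(centre, rnorm(9), g, psi = 0, sigma2 = 2)
  expect_equal(cc0$mean, 0)
  expect_equal(cc0$var, 0.5)
  # 4-neighbour node with values (1, 2, 3, 4) and psi = 0.5
  u <- numeric(9)
  u[g$nb[[centre]]] <- c(1, 2, 3, 4)
  cc5 <- proper_car_conditional(centre, u, g, psi = 0.5, sigma2 = 1)
  expect_equal(cc5$mean, 1.25)
  expect_equal(cc5$var, 0.25)
  # islands are an error
  gi <- suppressWarnings(as_zi_graph(list(A = "B", B = "A", C = character(0))))
  expect_error(proper_car_conditional(3, c(0, 0, 0), gi, 0.5, 1), "island")
})

test_that("bicar conditional matches the stacked joint-precision oracle", {
  g <- make_lattice_graph(3, 3)
  Sg <- matrix(c(0.9, 0.3, 0.3, 1.4), 2)
  set.seed(11)
  u1 <- rnorm(9); u2 <- rnorm(9)
  # all neighbours identical: the conditional mean is that pair
  ua <- rep(0.7, 9); ub <- rep(-1.1, 9)
  cc <- bicar_conditional(5, ua, ub, g, Sg)
  expect_equal(cc$mean, c(0.7, -1.1))
  expect_equal(cc$cov, Sg / g$m[5])
  # dense oracle: stacked field (u1, u2) has precision kron(solve(Sg), D - W)
  L <- graph_laplacian(g)
  Q <- kronecker(solve(Sg), L)
  x <- c(u1, u2)
  for (i in c(1, 5, 8)) {
    idx <- c(i, i + 9)
    Qii <- Q[idx, idx]
    cond_cov <- solve(Qii)
    cond_mean <- drop(-cond_cov %*% Q[idx, -idx] %*% x[-idx])
    got <- bicar_conditional(i, u1, u2, g, Sg)
    expect_equal(got$mean, cond_mean, tolerance = 1e-10)
    expect_equal(got$cov, cond_cov, tolerance = 1e-10)
  }
  # zero cross-covariance factorises into two univariate ICAR conditionals
  Sd <- diag(c(0.5, 2))
  got <- bicar_conditional(5, u1, u2, g, Sd)
  c1 <- proper_car_conditional(5, u1, g, psi = 1, sigma2 = 0.5)
  c2 <- proper_car_conditional(5, u2, g, psi = 1, sigma2 = 2)
  expect_equal(got$mean, c(c1$mean, c2$mean))
  expect_equal(diag(got$cov), c(c1$var, c2$var))
  expect_equal(got$cov[1, 2], 0)
  expect_error(bicar_conditional(5, u1, u2, g, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("sample_icar_field draws from the constrained intrinsic prior", {
  g <- make_lattice_graph(3, 3)
  set.seed(21)
  f <- sample_icar_field(g, sigma2 = 1.3)
  expect_equal(sum(f), 0, tolerance = 1e-10)
  set.seed(21)
  expect_identical(f, sample_icar_field(g, sigma2 = 1.3))
  # sample covariance matches sigma2 * pseudoinverse(D - W)
  set.seed(99)
  draws <- sample_icar_field(g, sigma2 = 1, n = 6000)
  target <- MASS::ginv(graph_laplacian(g))
  expect_lt(max(abs(cov(draws) - target)), 0.05)
  gd <- suppressWarnings(as_zi_graph(list(A = "B", B = "A", C = character(0))))
  expect_error(sample_icar_field(gd, 1), "connected")
})

test_that("sample_bicar_field honours the cross-component covariance", {
  g <- make_lattice_graph(4, 4)
  Sg <- matrix(c(1, 0.6, 0.6, 1), 2)
  set.seed(31)
  draws <- replicate(3000, sample_bicar_field(g, Sg))
  expect_equal(colSums(draws[, , 1]), c(u1 = 0, u2 = 0), tolerance = 1e-9)
  # empirical cross-component correlation at a node approaches Sg correlation
  c12 <- cor(draws[6, 1, ], draws[6, 2, ])
  expect_gt(c12, 0.4)
  # component marginals scale with the pseudoinverse diagonal
  P <- MASS::ginv(graph_laplacian(g))
  expect_equal(var(draws[6, 1, ]), P[6, 6] * Sg[1, 1], tolerance = 0.1)
})

test_that("proper-CAR Gibbs sweeps leave the joint distribution invariant", {
  # dense oracle: joint covariance sigma2 * (D - psi W)^-1 on a 3x3 lattice
  g <- make_lattice_graph(3, 3)
  psi <- 0.5; s2 <- 1
  D <- diag(g$m); W <- adjacency_matrix(g)
  target <- s2 * solve(D - psi * W)
  set.seed(77)
  u <- rnorm(9)
  nsweep <- 30000
  keep <- matrix(NA_real_, nsweep, 9)
  for (s in seq_len(nsweep)) {
    for (i in 1:9) {
      cc <- proper_car_conditional(i, u, g, psi, s2)
      u[i] <- rnorm(1, cc$mean, sqrt(cc$var))
    }
    keep[s, ] <- u
  }
  keep <- keep[-(1:1000), ]
  expect_lt(max(abs(cov(keep) - target)), 0.06)
  expect_lt(max(abs(colMeans(keep))), 0.05)
})

test_that("psi bounds bracket the valid interval and proper CAR nests ICAR", {
  g <- make_lattice_graph(3, 3)
  b <- psi_bounds(g)
  expect_lt(b[1], 0)
  expect_equal(b[2], 1, tolerance = 1e-10)  # largest eigenvalue is 1
  # psi = 1 conditional equals the bicar conditional with diagonal Sigma
  u1 <- rnorm(9); u2 <- rnorm(9)
  p1 <- proper_car_conditional(5, u2, g, psi = 1, sigma2 = 2)
  bb <- bicar_conditional(5, u1, u2, g, diag(c(1, 2)))
  expect_equal(p1$mean, bb$mean[2])
  expect_equal(p1$var, bb$cov[2, 2])
})
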