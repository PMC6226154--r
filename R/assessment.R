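#' Deviance information criterion
#'
#' `DIC = 2 * mean(D) - D(posterior means)`, with effective parameter count
#' `pD = mean(D) - D(posterior means)`. The deviance is conditional on the
#' random effects, and the plug-in evaluates the likelihood at the posterior
#' means of *all* sampled quantities, district effects included. Lower DIC is
#' better; note the plug-in makes DIC sensitive to parameterisation.
#'
#' @param fit a `zi_fit`
#' @return a list of class `zi_dic` with `dic`, `pd`, `dbar` (posterior mean
#'   deviance) and `dhat` (deviance at the posterior means)
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "zi_fit"))
  if (fit$prior_only) stop("DIC is undefined for a prior-only fit")
  dev <- .stack_draws(fit, "scalars")[, "deviance"]
  dhat <- -2 * .loglik_at_means(fit)
  dic_from_deviance(dev, dhat)
}

#' @rdname dic
#' @param dev_draws numeric vector of per-draw deviances
#' @param dev_at_mean deviance evaluated at the posterior means (plug-in)
#' @export
dic_from_deviance <- function(dev_draws, dev_at_mean) {
  dbar <- mean(dev_draws)
  structure(list(dic = 2 * dbar - dev_at_mean, pd = dbar - dev_at_mean,
                 dbar = dbar, dhat = dev_at_mean),
            class = "zi_dic")
}

#' @export
print.zi_dic <- function(x, ...) {
  cat(sprintf("DIC %.1f  (mean deviance %.1f, pD %.1f)\n", x$dic, x$dbar, x$pd))
  invisible(x)
}

# posterior-mean parameters -> joint log-likelihood (plug-in)
.loglik_at_means <- function(fit) {
  design <- fit$design
  d <- match(design$district_levels, fit$district_levels)[design$district]
  cm <- function(what) {
    m <- .stack_draws(fit, what)
    if (ncol(m) == 0) numeric(length(fit$district_levels)) else colMeans(m)
  }
  beta <- colMeans(.stack_draws(fit, "beta"))
  theta <- cm("theta"); u2 <- cm("u2")
  eta_c <- drop(design$X %*% beta) + design$offset + theta[d] + u2[d]
  nu <- exp(eta_c)
  y <- design$y
  sc <- .stack_draws(fit, "scalars")
  phi <- mean(sc[, "phi"])
  if (fit$model$zero_inflated) {
    alpha <- colMeans(.stack_draws(fit, "alpha"))
    vartheta <- cm("vartheta"); u1 <- cm("u1")
    pi <- stats::plogis(drop(design$Z %*% alpha) + vartheta[d] + u1[d])
    if (fit$model$family == "zip") sum(zip_logpmf(y, nu, pi))
    else sum(zinb_logpmf(y, nu, pi, phi))
  } else {
    if (fit$model$family == "poisson") sum(stats::dpois(y, nu, log = TRUE))
    else sum(stats::dnbinom(y, size = 1 / phi, mu = nu, log = TRUE))
  }
}

# per-draw (pi, nu, phi) for each observation; draws evenly subsampled to
# at most max_draws across the pooled chains
.predictor_draws <- function(fit, max_draws = Inf) {
  design <- fit$design
  d <- match(design$district_levels, fit$district_levels)[design$district]
  beta <- .stack_draws(fit, "beta")
  J <- nrow(beta)
  idx <- if (is.finite(max_draws) && J > max_draws) {
    unique(round(seq(1, J, length.out = max_draws)))
  } else seq_len(J)
  beta <- beta[idx, , drop = FALSE]
  sel <- function(what) {
    m <- .stack_draws(fit, what)
    if (ncol(m) == 0) matrix(0, length(idx), length(d))
    else m[idx, , drop = FALSE][, fit$district_levels, drop = FALSE][, d, drop = FALSE]
  }
  eta_c <- beta %*% t(design$X) +
    matrix(design$offset, length(idx), length(d), byrow = TRUE) +
    sel("theta") + sel("u2")
  nu <- exp(eta_c)
  if (fit$model$zero_inflated) {
    alpha <- .stack_draws(fit, "alpha")[idx, , drop = FALSE]
    pi <- stats::plogis(alpha %*% t(design$Z) + sel("vartheta") + sel("u1"))
  } else {
    pi <- matrix(0, length(idx), length(d))
  }
  phi <- .stack_draws(fit, "scalars")[idx, "phi"]
  list(pi = pi, nu = nu, phi = phi, idx = idx)
}

#' Posterior predictive ordinates
#'
#' For each observation and each support point `s = 0, ..., support_max`,
#' the MCMC estimate of the posterior predictive probability
#' `P(y_ij = s | Y)`: the average over retained draws of the model pmf at
#' `s` under that draw's parameters.
#'
#' @param fit a `zi_fit`
#' @param support_max largest support value (default: `max(y) + 20`, by which
#'   point the residual upper-tail mass is negligible for these models)
#' @param max_draws cap on the number of draws used (evenly subsampled)
#' @return an `n_obs x (support_max + 1)` matrix; rows sum to at most 1
#' @export
ppo <- function(fit, support_max = NULL, max_draws = 10000) {
  stopifnot(inherits(fit, "zi_fit"))
  y <- fit$design$y
  if (is.null(support_max)) support_max <- max(y) + 20L
  if (support_max < max(y)) stop("`support_max` must cover every observed y")
  pd <- .predictor_draws(fit, max_draws)
  nbfam <- fit$model$family %in% c("nb", "zinb")
  phi <- pd$phi
  if (!nbfam) phi <- rep(1, length(pd$idx))
  out <- .ppo_cpp(pd$pi, pd$nu, 1 / phi, nbfam, as.integer(support_max))
  colnames(out) <- as.character(0:support_max)
  out
}

#' Brier score from posterior predictive ordinates
#'
#' Negative mean squared distance between the predictive pmf of each
#' observation and the degenerate empirical pmf at its observed value:
#' `-(1/n) * sum_ij sum_s (p_ijs - 1{y_ij = s})^2`. The score is at most 0,
#' attained only by a perfect (degenerate) predictor; higher is better.
#'
#' @param ppo matrix from [ppo()] (rows = observations, columns = support
#'   `0..smax`)
#' @param y observed counts
#' @return scalar score `<= 0`
#' @export
brier_score <- function(ppo, y) {
  stopifnot(is.matrix(ppo), length(y) == nrow(ppo))
  smax <- ncol(ppo) - 1L
  if (any(y < 0) || any(y > smax)) {
    stop("observed y outside the PPO support 0..", smax)
  }
  emp <- matrix(0, nrow(ppo), ncol(ppo))
  emp[cbind(seq_along(y), y + 1L)] <- 1
  -sum((ppo - emp)^2) / length(y)
}

#' Global Moran's I
#'
#' Spatial autocorrelation of a per-district variable over the adjacency
#' graph: `I = (n / S0) * (z' W z) / (z' z)` with centred values `z` and
#' weights `W` (binary by default, optionally row-standardised). The p-value
#' is computed both by random permutation of the values over the districts
#' (seed-stable) and by the normal approximation with the randomisation
#' variance.
#'
#' @param values numeric vector, one value per graph node (graph order)
#' @param graph a `zi_graph`
#' @param weights `"binary"` (omega in 0/1) or `"row"` (row-standardised)
#' @param permutations number of random permutations (default 9999)
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two.sided"`
#' @return a tibble with `statistic`, `expectation`, `sd`, `p_norm`,
#'   `p_perm`
#' @export
morans_i <- function(values, graph, weights = c("binary", "row"),
                     permutations = 9999,
                     alternative = c("greater", "less", "two.sided")) {
  weights <- match.arg(weights)
  alternative <- match.arg(alternative)
  stopifnot(inherits(graph, "zi_graph"),
            length(values) == n_districts(graph))
  n <- length(values)
  if (n < 3) stop("Moran's I needs at least 3 districts")
  if (stats::sd(values) == 0) stop("Moran's I undefined for constant input")
  W <- adjacency_matrix(graph)
  if (weights == "row") {
    if (any(graph$m == 0)) stop("row-standardised weights undefined with islands")
    W <- W / graph$m
  }
  S0 <- sum(W)
  stat <- function(v) {
    z <- v - mean(v)
    (n / S0) * drop(z %*% W %*% z) / sum(z^2)
  }
  I <- stat(values)
  # moments under the randomisation assumption
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  z <- values - mean(values)
  k <- (sum(z^4) / n) / (sum(z^2) / n)^2
  EI <- -1 / (n - 1)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           k * (n * (n - 1) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  p_norm <- switch(alternative,
                   greater = stats::pnorm(zscore, lower.tail = FALSE),
                   less = stats::pnorm(zscore),
                   two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE))
  perm <- vapply(seq_len(permutations), function(b) stat(sample(values)),
                 numeric(1))
  p_perm <- switch(alternative,
                   greater = (1 + sum(perm >= I)) / (permutations + 1),
                   less = (1 + sum(perm <= I)) / (permutations + 1),
                   two.sided = (1 + sum(abs(perm - EI) >= abs(I - EI))) /
                     (permutations + 1))
  tibble::tibble(statistic = I, expectation = EI, sd = sqrt(VI),
                 p_norm = p_norm, p_perm = p_perm)
}
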