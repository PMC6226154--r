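#' Zero-inflated count distributions
#'
#' A zero-inflated (ZI) outcome arises from a two-component mixture: with
#' probability `pi` the observation is a structural zero, and with probability
#' `1 - pi` it is drawn from a count distribution `f` — Poisson with mean `nu`,
#' or negative binomial with mean `nu` and dispersion `phi` (variance
#' `nu * (1 + phi * nu)`). The negative binomial is parameterised through
#' Poisson–Gamma mixing with `u ~ Gamma(r, r)` and `r = 1/phi`, so `phi -> 0`
#' recovers the Poisson. In the facility-mortality application
#' `nu = N * lambda` where `N` is the number of obstetric admissions (the
#' exposure) and `lambda` the per-admission death rate.
#'
#' For numerical stability the zero-inflation probability is clipped to
#' `[1e-12, 1 - 1e-12]` inside log computations, and the `y = 0` mixture mass
#' is evaluated by log-sum-exp.
#'
#' @param y vector of non-negative integer counts
#' @param nu positive mean(s) of the count component
#' @param pi zero-inflation probability(ies) in `[0, 1]`
#' @param phi non-negative dispersion; `zinb_logpmf` requires `phi > 0`
#' @return vector of log-probabilities
#' @examples
#' zip_logpmf(0, nu = 1, pi = 0.5)   # log(0.5 + 0.5 * exp(-1))
#' zinb_logpmf(2, nu = 3, pi = 0, phi = 0.5)
#' @name zi-distributions
NULL

.clip_pi <- function(pi, eps = 1e-12) pmin(pmax(pi, eps), 1 - eps)

.zi_log_mix <- function(y, pi, log_f) {
  pi <- .clip_pi(pi)
  out <- log1p(-pi) + log_f
  at0 <- y == 0
  if (any(at0)) {
    a <- log(pi[at0])
    b <- out[at0]
    mx <- pmax(a, b)
    out[at0] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  out
}

#' @rdname zi-distributions
#' @export
zip_logpmf <- function(y, nu, pi) {
  if (any(y < 0) || any(y != floor(y))) stop("`y` must be non-negative integers")
  if (any(nu <= 0)) stop("`nu` must be positive")
  if (any(pi < 0 | pi > 1)) stop("`pi` must lie in [0, 1]")
  n <- max(length(y), length(nu), length(pi))
  y <- rep_len(y, n); nu <- rep_len(nu, n); pi <- rep_len(pi, n)
  .zi_log_mix(y, pi, stats::dpois(y, lambda = nu, log = TRUE))
}

#' @rdname zi-distributions
#' @export
zinb_logpmf <- function(y, nu, pi, phi) {
  if (any(y < 0) || any(y != floor(y))) stop("`y` must be non-negative integers")
  if (any(nu <= 0)) stop("`nu` must be positive")
  if (any(pi < 0 | pi > 1)) stop("`pi` must lie in [0, 1]")
  if (any(phi <= 0)) {
    stop("`phi` must be positive; use zip_logpmf() for the Poisson limit phi = 0")
  }
  n <- max(length(y), length(nu), length(pi), length(phi))
  y <- rep_len(y, n); nu <- rep_len(nu, n)
  pi <- rep_len(pi, n); phi <- rep_len(phi, n)
  r <- 1 / phi
  .zi_log_mix(y, pi, stats::dnbinom(y, size = r, mu = nu, log = TRUE))
}

#' Mean of a zero-inflated outcome
#'
#' `E(y) = (1 - pi) * nu`, regardless of the count family.
#'
#' @inheritParams zi-distributions
#' @return numeric vector
#' @export
zi_mean <- function(nu, pi) {
  stopifnot(all(nu >= 0), all(pi >= 0 & pi <= 1))
  (1 - pi) * nu
}

#' Simulate zero-inflated counts
#'
#' @param n number of draws (ignored if parameter vectors are longer)
#' @inheritParams zi-distributions
#' @return integer vector of draws
#' @export
rzi <- function(n, nu, pi, phi = 0) {
  len <- max(n, length(nu), length(pi), length(phi))
  nu <- rep_len(nu, len); pi <- rep_len(pi, len); phi <- rep_len(phi, len)
  structural <- stats::rbinom(len, 1, pi) == 1
  y <- integer(len)
  pois <- phi == 0
  if (any(pois)) y[pois] <- stats::rpois(sum(pois), nu[pois])
  if (any(!pois)) {
    y[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois], mu = nu[!pois])
  }
  y[structural] <- 0L
  y
}

#' Row-wise model parameters from design matrices and coefficients
#'
#' Applies the canonical links of the two-component model:
#' `logit(pi) = Z alpha + (zero-component district effects)` and
#' `log(nu) = X beta + log(N) + (count-component district effects)`,
#' where the district effects collect the non-spatial intercepts and any
#' spatial fields assigned to each component.
#'
#' @param design a `zi_design` from [build_design()]
#' @param alpha,beta coefficient vectors matching `ncol(design$Z)` and
#'   `ncol(design$X)`
#' @param zero_effects,count_effects per-district effect vectors added to the
#'   zero / count linear predictor (default all zero)
#' @return a tibble with one row per facility: `pi`, `nu` and the linear
#'   predictors `eta_zero`, `eta_count`
#' @export
linear_predictors <- function(design, alpha, beta,
                              zero_effects = NULL, count_effects = NULL) {
  stopifnot(inherits(design, "zi_design"))
  nd <- length(design$district_levels)
  if (is.null(zero_effects)) zero_effects <- numeric(nd)
  if (is.null(count_effects)) count_effects <- numeric(nd)
  if (length(alpha) != ncol(design$Z)) stop("`alpha` length must equal ncol(Z)")
  if (length(beta) != ncol(design$X)) stop("`beta` length must equal ncol(X)")
  if (length(zero_effects) != nd || length(count_effects) != nd) {
    stop("effect vectors must have one entry per district")
  }
  d <- design$district
  eta_zero <- drop(design$Z %*% alpha) + zero_effects[d]
  eta_count <- drop(design$X %*% beta) + design$offset + count_effects[d]
  bad <- !is.finite(eta_zero) | !is.finite(eta_count)
  if (any(bad)) {
    stop("non-finite linear predictor at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  tibble::tibble(
    pi = stats::plogis(eta_zero),
    nu = exp(eta_count),
    eta_zero = eta_zero,
    eta_count = eta_count
  )
}
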