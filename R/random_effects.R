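#' Log-density of the non-spatial district intercepts
#'
#' Each district carries a pair of random intercepts: `theta` shifts the
#' log-mean of the count component and `vartheta` shifts the logit of the
#' zero-inflation probability. Three structures are supported:
#'
#' * `"correlated"` — `(theta_i, vartheta_i) ~ N2(0, Sigma)` with
#'   `Sigma = [sigma2_theta, rho*st*sv; ., sigma2_vartheta]`;
#' * `"independent"` — the same with `rho = 0`;
#' * `"shared"` — one latent intercept drives both components,
#'   `vartheta_i = zeta * theta_i` with `theta_i ~ N(0, sigma2_theta)`
#'   (so `sigma2_vartheta = zeta^2 * sigma2_theta` deterministically).
#'
#' @param theta,vartheta numeric vectors of per-district intercepts
#' @param structure one of `"independent"`, `"shared"`, `"correlated"`
#' @param sigma2_theta,sigma2_vartheta positive variances
#' @param rho correlation in `(-1, 1)` (correlated structure)
#' @param zeta proportionality constant (shared structure)
#' @return total log-density (scalar)
#' @export
district_effects_logdensity <- function(theta, vartheta,
                                        structure = c("correlated",
                                                      "independent", "shared"),
                                        sigma2_theta, sigma2_vartheta = NULL,
                                        rho = 0, zeta = NULL) {
  structure <- match.arg(structure)
  stopifnot(length(theta) == length(vartheta), sigma2_theta > 0)
  if (structure == "shared") {
    if (is.null(zeta)) stop("shared structure requires `zeta`")
    if (max(abs(vartheta - zeta * theta)) > 1e-8) {
      stop("shared structure requires vartheta == zeta * theta")
    }
    return(sum(stats::dnorm(theta, 0, sqrt(sigma2_theta), log = TRUE)))
  }
  if (is.null(sigma2_vartheta) || sigma2_vartheta <= 0) {
    stop("`sigma2_vartheta` must be positive")
  }
  if (structure == "independent") rho <- 0
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)")
  st <- sqrt(sigma2_theta); sv <- sqrt(sigma2_vartheta)
  det_sigma <- sigma2_theta * sigma2_vartheta * (1 - rho^2)
  if (det_sigma <= 0) stop("Sigma_theta is not positive definite")
  # bivariate normal at (theta_i, vartheta_i), mean 0
  z1 <- theta / st
  z2 <- vartheta / sv
  quad <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  sum(-log(2 * pi) - 0.5 * log(det_sigma) - 0.5 * quad)
}

#' Unnormalised log-kernel of the intrinsic CAR (ICAR) field
#'
#' The intrinsic conditional autoregressive prior on a per-district field `u`
#' has kernel `-(1 / (2 sigma2)) * sum over unordered adjacent pairs (i, i')
#' of (u_i - u_i')^2`, equivalently `-(1/2) u' Q u` with
#' `Q = (D - W) / sigma2`. It is improper: adding a constant to `u` leaves the
#' kernel unchanged, which is why fitted fields are kept centred.
#'
#' @param u numeric field, one value per district (graph node order)
#' @param graph a `zi_graph`
#' @param sigma2 positive conditional variance parameter
#' @param island one of `"error"` (default) or `"zero"`: with `"zero"`,
#'   isolated districts are allowed and contribute nothing to the kernel
#'   (their effects are pinned to 0 by the samplers)
#' @return scalar log-kernel (unnormalised)
#' @export
icar_log_kernel <- function(u, graph, sigma2, island = c("error", "zero")) {
  island <- match.arg(island)
  stopifnot(inherits(graph, "zi_graph"), sigma2 > 0,
            length(u) == n_districts(graph))
  if (any(graph$m == 0) && island == "error") {
    stop("graph has isolated node(s); set island = \"zero\" to pin them at 0")
  }
  e <- graph$edges
  if (nrow(e) == 0) return(0)
  -sum((u[e[, 1]] - u[e[, 2]])^2) / (2 * sigma2)
}

#' Full conditional of one district under the proper CAR model
#'
#' Under the proper CAR prior the field value of district `i` given the rest is
#' normal with mean `psi * (average of neighbouring values)` and variance
#' `sigma2 / m_i`, where `m_i` is the neighbour count and `psi` the spatial
#' autocorrelation parameter (`psi = 1` gives the intrinsic model's
#' conditional).
#'
#' @param i district index (integer, graph node order)
#' @param u numeric field over all districts
#' @param graph a `zi_graph`
#' @param psi spatial autocorrelation parameter
#' @param sigma2 positive conditional variance
#' @return list with elements `mean` and `var`
#' @export
proper_car_conditional <- function(i, u, graph, psi, sigma2) {
  stopifnot(inherits(graph, "zi_graph"), sigma2 > 0,
            length(u) == n_districts(graph))
  m_i <- graph$m[i]
  if (m_i == 0) stop("district ", graph$nodes[i], " has no neighbours (island)")
  list(mean = psi * sum(u[graph$nb[[i]]]) / m_i, var = sigma2 / m_i)
}

#' Full conditional of one district under the bivariate intrinsic CAR
#'
#' The bivariate intrinsic CAR places a two-component field `(u1, u2)` on the
#' districts, with conditional `N2(ubar_i, Sigma / m_i)` where `ubar_i` holds
#' the neighbour averages of each component and `Sigma` is the 2x2
#' cross-component conditional covariance. The off-diagonal of `Sigma` links
#' the zero and count model components spatially.
#'
#' @param i district index
#' @param u1,u2 numeric fields over all districts
#' @param graph a `zi_graph`
#' @param Sigma 2x2 symmetric positive-definite covariance matrix
#' @return list with elements `mean` (length-2) and `cov` (2x2)
#' @export
bicar_conditional <- function(i, u1, u2, graph, Sigma) {
  stopifnot(inherits(graph, "zi_graph"),
            length(u1) == n_districts(graph),
            length(u2) == n_districts(graph),
            is.matrix(Sigma), all(dim(Sigma) == 2))
  if (abs(Sigma[1, 2] - Sigma[2, 1]) > 1e-12 ||
      Sigma[1, 1] <= 0 || det(Sigma) <= 0) {
    stop("`Sigma` must be symmetric positive definite")
  }
  m_i <- graph$m[i]
  if (m_i == 0) stop("district ", graph$nodes[i], " has no neighbours (island)")
  nbs <- graph$nb[[i]]
  list(mean = c(mean(u1[nbs]), mean(u2[nbs])), cov = Sigma / m_i)
}

.laplacian_eigen <- function(graph) {
  L <- graph_laplacian(graph)
  eig <- eigen(L, symmetric = TRUE)
  nzero <- sum(eig$values < max(eig$values) * 1e-10)
  list(values = eig$values, vectors = eig$vectors, nzero = nzero)
}

#' Exact draw from the intrinsic CAR prior (sum-to-zero representative)
#'
#' Draws the field from the ICAR distribution restricted to the subspace
#' orthogonal to the constant vector (the improper direction), i.e. from
#' `N(0, sigma2 * pseudoinverse(D - W))`. Requires a connected graph.
#'
#' @param graph a connected `zi_graph`
#' @param sigma2 positive conditional variance
#' @param n number of independent fields to draw
#' @return if `n = 1` a numeric vector summing to zero; otherwise an
#'   `n x n_districts` matrix of fields (one per row)
#' @export
sample_icar_field <- function(graph, sigma2, n = 1) {
  stopifnot(sigma2 > 0, n >= 1)
  if (!is_connected(graph)) stop("graph must be connected to sample an ICAR field")
  eig <- .laplacian_eigen(graph)
  nd <- n_districts(graph)
  keep <- seq_len(nd - 1)                      # drop the single zero eigenvalue
  V <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  z <- matrix(stats::rnorm((nd - 1) * n), nrow = nd - 1, ncol = n)
  fields <- V %*% (z * sqrt(sigma2 / lam))
  if (n == 1) drop(fields) else t(fields)
}

#' Exact draw from the bivariate intrinsic CAR prior
#'
#' Joint precision `(D - W) / Sigma` in Kronecker form; both component fields
#' are drawn on the sum-to-zero subspace.
#'
#' @param graph a connected `zi_graph`
#' @param Sigma 2x2 conditional covariance matrix
#' @return an `n_districts x 2` matrix with columns `u1`, `u2`, each summing
#'   to zero
#' @export
sample_bicar_field <- function(graph, Sigma) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == 2))
  if (det(Sigma) <= 0 || Sigma[1, 1] <= 0) stop("`Sigma` must be positive definite")
  if (!is_connected(graph)) stop("graph must be connected to sample a CAR field")
  eig <- .laplacian_eigen(graph)
  nd <- n_districts(graph)
  keep <- seq_len(nd - 1)
  V <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  cS <- chol(Sigma)                            # Sigma = t(cS) %*% cS
  # coefficient pairs c_k ~ N2(0, Sigma / lambda_k)
  z <- matrix(stats::rnorm(2 * (nd - 1)), ncol = 2)
  coefs <- (z %*% cS) / sqrt(lam)
  out <- V %*% coefs
  colnames(out) <- c("u1", "u2")
  out
}

#' Admissible interval for the proper-CAR autocorrelation parameter
#'
#' The joint precision `(D - psi W) / sigma2` is positive definite iff
#' `psi` lies strictly between the reciprocals of the smallest and largest
#' eigenvalues of `D^{-1/2} W D^{-1/2}`.
#'
#' @param graph a `zi_graph` with no isolated nodes
#' @return length-2 numeric vector `c(lower, upper)`
#' @export
psi_bounds <- function(graph) {
  if (any(graph$m == 0)) stop("psi bounds undefined for graphs with islands")
  W <- adjacency_matrix(graph)
  s <- 1 / sqrt(graph$m)
  A <- W * tcrossprod(s)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  c(1 / min(ev), 1 / max(ev))
}
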