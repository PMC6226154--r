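#' Model specification
#'
#' Declares which member of the model family to fit:
#'
#' * `family` — the count emission: plain `"poisson"` / `"nb"` (no
#'   zero-inflation component) or zero-inflated `"zip"` / `"zinb"`;
#' * `effects` — the non-spatial district intercepts: `"none"`,
#'   `"independent"` (`rho = 0`), `"shared"` (`vartheta_i = zeta * theta_i`)
#'   or `"correlated"` (bivariate normal with free `rho`);
#' * `spatial` — the spatial structure: `"none"`, `"icar"` (intrinsic CAR
#'   field in the count component), `"proper"` (proper CAR with
#'   autocorrelation `psi`, count component) or `"bicar"` (bivariate
#'   intrinsic CAR with one field per component, linked by a 2x2
#'   cross-component covariance).
#'
#' Non-zero-inflated families have no zero component, so `effects` there
#' reduces to a count-side intercept (`"independent"`), and `"bicar"` is
#' unavailable.
#'
#' @param family one of `"zip"`, `"zinb"`, `"poisson"`, `"nb"`
#' @param effects one of `"correlated"`, `"independent"`, `"shared"`, `"none"`
#' @param spatial one of `"none"`, `"icar"`, `"proper"`, `"bicar"`
#' @return a list of class `zi_model`
#' @examples
#' zi_model("zip", effects = "correlated", spatial = "none")   # HZIP (correlated)
#' zi_model("zip", effects = "independent", spatial = "bicar") # SpHZIP (ind-ind)
#' @export
zi_model <- function(family = c("zip", "zinb", "poisson", "nb"),
                     effects = c("correlated", "independent", "shared", "none"),
                     spatial = c("none", "icar", "proper", "bicar")) {
  family <- match.arg(family)
  effects <- match.arg(effects)
  spatial <- match.arg(spatial)
  zero_inflated <- family %in% c("zip", "zinb")
  if (!zero_inflated) {
    if (effects %in% c("shared", "correlated")) {
      stop("family \"", family, "\" has no zero component; effects must be ",
           "\"none\" or \"independent\"")
    }
    if (spatial == "bicar") {
      stop("family \"", family, "\" has no zero component; bivariate CAR ",
           "is unavailable")
    }
  }
  structure(list(family = family, effects = effects, spatial = spatial,
                 zero_inflated = zero_inflated),
            class = "zi_model")
}

#' @export
print.zi_model <- function(x, ...) {
  cat("<zi_model> family =", x$family, "| effects =", x$effects,
      "| spatial =", x$spatial, "\n")
  invisible(x)
}

#' Prior specification
#'
#' Vague priors in the convention of hierarchical disease-mapping practice.
#' Each fixed effect gets `N(0, sigma^2)` with its own precision hyperprior
#' `sigma^-2 ~ Gamma(1e-5, 1e-5)` (shape/rate); univariate district-intercept
#' precisions get `Gamma(1e-3, 1e-3)`; CAR field precisions get
#' `Gamma(5e-3, 5e-3)`; the negative-binomial order parameter `r = 1/phi`
#' gets `Gamma(1e-3, 1e-3)`; the shared-structure proportionality constant
#' `zeta` gets a normal prior specified by its precision (`1e-4`, i.e.
#' variance `1e4`); bivariate structures put `Wishart(Omega, 2)` on the
#' precision matrix with scale `Omega = I2`; the proper-CAR autocorrelation
#' `psi` is uniform on its admissible interval (see [psi_bounds()]).
#'
#' @param beta_prec_gamma,alpha_prec_gamma shape/rate of the Gamma hyperprior
#'   on the fixed-effect precision(s)
#' @param coef_prec_scope `"shared"` (default): one precision hyperprior per
#'   model component, common to its coefficients, so the coefficient scale is
#'   learned jointly and the prior stays vague without becoming improper
#'   along weakly identified directions; `"per_coefficient"`: an independent
#'   hyperprior per coefficient, whose marginal is a scale-invariant spike
#'   (collapsed to its t kernel in the sampler)
#' @param beta_prec_fixed,alpha_prec_fixed optional fixed precisions; when
#'   given, the hyperprior is dropped and every coefficient of that component
#'   uses `N(0, 1/prec)`
#' @param re_prec_gamma shape/rate for univariate district-intercept precisions
#' @param car_prec_gamma shape/rate for CAR field precisions
#' @param r_gamma shape/rate for the negative-binomial `r`
#' @param zeta_prec prior precision of `zeta`
#' @param wishart_df,wishart_scale degrees of freedom and 2x2 scale matrix of
#'   the Wishart prior on precision matrices
#' @return a list of class `zi_priors`
#' @export
prior_spec <- function(beta_prec_gamma = c(1e-5, 1e-5),
                       alpha_prec_gamma = c(1e-5, 1e-5),
                       coef_prec_scope = c("shared", "per_coefficient"),
                       beta_prec_fixed = NULL,
                       alpha_prec_fixed = NULL,
                       re_prec_gamma = c(1e-3, 1e-3),
                       car_prec_gamma = c(5e-3, 5e-3),
                       r_gamma = c(1e-3, 1e-3),
                       zeta_prec = 1e-4,
                       wishart_df = 2,
                       wishart_scale = diag(2)) {
  coef_prec_scope <- match.arg(coef_prec_scope)
  stopifnot(all(beta_prec_gamma > 0), all(alpha_prec_gamma > 0),
            all(re_prec_gamma > 0), all(car_prec_gamma > 0),
            all(r_gamma > 0), zeta_prec > 0, wishart_df > 1,
            is.matrix(wishart_scale), all(dim(wishart_scale) == 2),
            det(wishart_scale) > 0)
  structure(list(beta_prec_gamma = beta_prec_gamma,
                 alpha_prec_gamma = alpha_prec_gamma,
                 coef_prec_scope = coef_prec_scope,
                 beta_prec_fixed = beta_prec_fixed,
                 alpha_prec_fixed = alpha_prec_fixed,
                 re_prec_gamma = re_prec_gamma,
                 car_prec_gamma = car_prec_gamma,
                 r_gamma = r_gamma,
                 zeta_prec = zeta_prec,
                 wishart_df = wishart_df,
                 wishart_scale = wishart_scale),
            class = "zi_priors")
}

#' Sampler configuration
#'
#' Defaults follow common practice for these models: 50,000 iterations with a
#' 20,000-iteration burn-in. Random-walk proposal scales are adapted during
#' burn-in (target acceptance 0.44) and frozen afterwards, so retained draws
#' come from a fixed-kernel chain.
#'
#' @param iterations total MCMC iterations per chain
#' @param burn_in iterations discarded (must be `< iterations`)
#' @param thin keep every `thin`-th post-burn-in draw
#' @param chains number of independent chains
#' @param seed integer seed; chain `k` uses `seed + k - 1`
#' @return a list of class `zi_mcmc_config`
#' @export
mcmc_config <- function(iterations = 50000, burn_in = 20000, thin = 1,
                        chains = 1, seed = 1) {
  stopifnot(iterations > 0, burn_in >= 0, burn_in < iterations,
            thin >= 1, chains >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 chains = as.integer(chains),
                 seed = as.integer(seed)),
            class = "zi_mcmc_config")
}
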