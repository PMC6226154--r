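#' Fit a (spatial) hierarchical zero-inflated count model
#'
#' Posterior sampling for any [zi_model()] under the vague prior block of
#' [prior_spec()], by Metropolis-within-Gibbs: adaptive random-walk updates
#' for fixed effects and latent district effects, conjugate Gamma/Wishart
#' updates for variance components, and (for the proper CAR) a bounded
#' random-walk update of the autocorrelation parameter on its admissible
#' interval. The negative binomial is handled through its closed-form
#' Poisson-Gamma marginal, so no per-observation mixing latents are sampled.
#' Intrinsic CAR fields are kept identifiable by re-centring to mean zero
#' after every sweep, transferring the level into the component intercept
#' (a likelihood-preserving move).
#'
#' @param data a complete-case facility tibble (see [as_facility_table()])
#' @param model a [zi_model()]
#' @param graph a [`zi_graph`][as_zi_graph] of district adjacency; required
#'   iff `model$spatial != "none"`. Every district in `data` must be a node;
#'   graph nodes without facilities are allowed and receive smoothed effects.
#' @param priors a [prior_spec()]
#' @param mcmc an [mcmc_config()]
#' @param count_terms,zero_terms design terms, passed to [build_design()]
#' @param design optional pre-built `zi_design` (overrides
#'   `count_terms`/`zero_terms`)
#' @param island island policy for spatial models: `"error"` rejects graphs
#'   with isolated districts, `"zero"` pins their spatial effects at 0
#' @param prior_only if `TRUE`, sample from the prior (likelihood switched
#'   off); used to validate the prior block
#' @return an object of class `zi_fit`
#' @export
fit_zi <- function(data, model = zi_model(), graph = NULL,
                   priors = prior_spec(), mcmc = mcmc_config(),
                   count_terms = count_terms_full(),
                   zero_terms = zero_terms_full(),
                   design = NULL, island = c("error", "zero"),
                   prior_only = FALSE) {
  island <- match.arg(island)
  stopifnot(inherits(model, "zi_model"), inherits(priors, "zi_priors"),
            inherits(mcmc, "zi_mcmc_config"))
  if (is.null(design)) {
    design <- build_design(data, count_terms = count_terms,
                           zero_terms = zero_terms)
  }
  spatial_code <- match(model$spatial, c("none", "icar", "proper", "bicar")) - 1L
  effects_code <- match(model$effects, c("none", "independent", "shared",
                                         "correlated")) - 1L
  family_code <- match(model$family, c("poisson", "nb", "zip", "zinb")) - 1L

  if (spatial_code > 0L) {
    if (is.null(graph)) stop("spatial model \"", model$spatial,
                             "\" requires an adjacency graph")
    missing_d <- setdiff(design$district_levels, graph$nodes)
    if (length(missing_d) > 0) {
      stop("district(s) not in adjacency graph: ",
           paste(utils::head(missing_d, 5), collapse = ", "))
    }
    if (any(graph$m == 0) && island == "error") {
      stop("adjacency graph has isolated district(s); pass island = \"zero\" ",
           "to pin their spatial effects at 0")
    }
    district_levels <- graph$nodes
    edges <- graph$edges
    nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
    m <- as.numeric(graph$m)
  } else {
    graph <- NULL
    district_levels <- design$district_levels
    edges <- matrix(integer(0), ncol = 2)
    nb0 <- rep(list(integer(0)), length(district_levels))
    m <- numeric(length(district_levels))
  }
  nd <- length(district_levels)
  district0 <- match(design$district_levels, district_levels)[design$district] - 1L

  psi_b <- c(-0.999, 0.999)
  gamma_eigs <- numeric(0)
  if (spatial_code == 2L) {
    psi_b <- psi_bounds(graph)
    s <- 1 / sqrt(graph$m)
    gamma_eigs <- eigen(adjacency_matrix(graph) * tcrossprod(s),
                        symmetric = TRUE, only.values = TRUE)$values
  }
  if (spatial_code %in% c(1L, 3L) && !is_connected(graph) && island == "error") {
    stop("intrinsic CAR requires a connected graph (or island = \"zero\")")
  }

  cpp_priors <- priors
  class(cpp_priors) <- NULL
  # joint "ridge" proposals between the intercept and dummy blocks whose
  # reference cell is rare (facility type; zero-component location): mixing
  # aid only, the posterior is unchanged
  count_swap0 <- which(colnames(design$X) %in% c("PH", "HC1", "HC2", "RH")) - 1L
  zero_swap0 <- which(colnames(design$Z) == "LOC") - 1L
  run_chain <- function(chain) {
    set.seed(mcmc$seed + chain - 1L)
    for (attempt in 1:5) {
      init <- .zi_init(design, model, nd)
      ll0 <- .initial_loglik(design, model, init, district0)
      if (is.finite(ll0)) break
      if (attempt == 5) stop("non-finite likelihood at initialization after ",
                             "5 attempts")
    }
    out <- .zi_mcmc_cpp(
      y = as.numeric(design$y), X = design$X, Z = design$Z,
      offset = design$offset, district = district0, ndist = nd,
      nb = nb0, m = m, edges = edges - 1L,
      count_swap = count_swap0, zero_swap = zero_swap0,
      gamma_eigs = gamma_eigs,
      psi_lo = psi_b[1], psi_hi = psi_b[2],
      family = family_code, effects = effects_code, spatial = spatial_code,
      coef_scope = match(priors$coef_prec_scope %||% "shared",
                         c("shared", "per_coefficient")) - 1L,
      priors = cpp_priors,
      iterations = mcmc$iterations, burnin = mcmc$burn_in, thin = mcmc$thin,
      init = init, prior_only = prior_only)
    colnames(out$beta) <- colnames(design$X)
    if (ncol(out$alpha) > 0) colnames(out$alpha) <- colnames(design$Z)
    for (nm in c("theta", "vartheta", "u1", "u2")) {
      if (ncol(out[[nm]]) > 0) colnames(out[[nm]]) <- district_levels
    }
    colnames(out$scalars) <- c("sigma2_theta", "sigma2_vartheta", "rho",
                               "zeta", "sigma2_u1", "sigma2_u2", "sigma12_u",
                               "psi", "phi", "deviance")
    out
  }
  chains <- lapply(seq_len(mcmc$chains), run_chain)

  structure(
    list(chains = chains, model = model, design = design, graph = graph,
         priors = priors, mcmc = mcmc, data = data,
         district_levels = district_levels, prior_only = prior_only),
    class = "zi_fit"
  )
}

# initial state: fixed effects at zero apart from the count intercept, which
# starts at the crude log-rate; variance components at 1; latent effects
# jittered when the model uses them, exactly zero otherwise
.zi_init <- function(design, model, nd) {
  beta <- numeric(ncol(design$X))
  beta[1] <- log((sum(design$y) + 0.5) / sum(exp(design$offset)))
  jitter_if <- function(on) if (on) stats::rnorm(nd, 0, 0.01) else numeric(nd)
  use_theta <- model$effects != "none"
  use_vt <- model$zero_inflated && model$effects %in% c("independent",
                                                        "correlated")
  list(
    beta = beta,
    alpha = numeric(ncol(design$Z)),
    theta = jitter_if(use_theta),
    vartheta = jitter_if(use_vt),
    u1 = jitter_if(model$spatial == "bicar"),
    u2 = jitter_if(model$spatial != "none"),
    sig2_theta = 1, sig2_vartheta = 1, rho = 0, zeta = 1,
    sig2_u = 1, Sigma_u = diag(2), psi = 0, r = 1
  )
}

.initial_loglik <- function(design, model, init, district0) {
  d <- district0 + 1L
  eta_c <- drop(design$X %*% init$beta) + design$offset +
    init$theta[d] + init$u2[d]
  nu <- exp(eta_c)
  y <- design$y
  if (model$zero_inflated) {
    eta_z <- drop(design$Z %*% init$alpha) + init$vartheta[d] + init$u1[d]
    pi <- stats::plogis(eta_z)
    if (model$family == "zip") sum(zip_logpmf(y, nu, pi))
    else sum(zinb_logpmf(y, nu, pi, 1 / init$r))
  } else {
    if (model$family == "poisson") sum(stats::dpois(y, nu, log = TRUE))
    else sum(stats::dnbinom(y, size = init$r, mu = nu, log = TRUE))
  }
}

#' @export
print.zi_fit <- function(x, ...) {
  kept <- nrow(x$chains[[1]]$beta)
  cat("<zi_fit> ", x$model$family, " | effects = ", x$model$effects,
      " | spatial = ", x$model$spatial, "\n", sep = "")
  cat("  ", length(x$chains), " chain(s) x ", kept, " retained draws; ",
      length(x$design$y), " facilities, ", length(x$district_levels),
      " districts\n", sep = "")
  if (!x$prior_only) {
    d <- dic(x)
    cat(sprintf("  DIC %.1f (pD %.1f, mean deviance %.1f)\n",
                d$dic, d$pd, d$dbar))
  }
  invisible(x)
}

# stack a per-chain matrix component across chains
.stack_draws <- function(fit, what) {
  mats <- lapply(fit$chains, `[[`, what)
  do.call(rbind, mats)
}

# named list of all monitored scalar-level draws (fixed effects, variance
# components, dispersion), pooled across chains; NA columns dropped
.scalar_draws <- function(fit) {
  beta <- .stack_draws(fit, "beta")
  colnames(beta) <- paste0("beta_", colnames(beta))
  out <- list(beta)
  alpha <- .stack_draws(fit, "alpha")
  if (ncol(alpha) > 0) {
    colnames(alpha) <- paste0("alpha_", colnames(alpha))
    out <- c(out, list(alpha))
  }
  sc <- .stack_draws(fit, "scalars")
  keep <- colnames(sc)[colSums(!is.na(sc)) > 0 & colnames(sc) != "deviance"]
  out <- c(out, list(sc[, keep, drop = FALSE]))
  do.call(cbind, out)
}

#' Posterior summaries
#'
#' Posterior mean, standard deviation and central 95% credible interval for
#' every monitored parameter, pooling chains.
#'
#' @param fit a `zi_fit`
#' @param include_districts also summarise the per-district effects
#' @param level credible level (default 0.95, central interval)
#' @return a tibble with columns `parameter`, `mean`, `sd`, `median`,
#'   `conf.low`, `conf.high`
#' @export
posterior_summary <- function(fit, include_districts = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "zi_fit"))
  draws <- .scalar_draws(fit)
  if (include_districts) {
    for (what in c("theta", "vartheta", "u1", "u2")) {
      m <- .stack_draws(fit, what)
      if (ncol(m) > 0) {
        colnames(m) <- paste0(what, "_", colnames(m))
        draws <- cbind(draws, m)
      }
    }
  }
  .summarise_draw_matrix(draws, level)
}

#' @rdname posterior_summary
#' @param draws a numeric matrix of posterior draws (columns = parameters),
#'   for summarising draws produced outside a `zi_fit`
#' @export
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  .summarise_draw_matrix(draws, level)
}

.summarise_draw_matrix <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  qs <- t(apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
                names = FALSE))
  tibble::tibble(
    parameter = colnames(draws),
    mean = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, stats::sd)),
    median = unname(qs[, 2]),
    conf.low = unname(qs[, 1]),
    conf.high = unname(qs[, 3])
  )
}

#' Convergence diagnostics
#'
#' Potential scale reduction (split over chains) and effective sample size
#' per monitored parameter. Rhat uses the classic between/within-chain
#' variance ratio and needs at least two chains; ESS is computed per chain
#' with [coda::effectiveSize()] and summed. Parameters with (numerically)
#' constant draws are flagged degenerate with `ess = 0`.
#'
#' @param fit a `zi_fit`, or a list of draw matrices (one per chain, equal
#'   column names)
#' @return a tibble with columns `parameter`, `rhat`, `ess`, `degenerate`
#' @export
convergence_report <- function(fit) {
  if (inherits(fit, "zi_fit")) {
    per_chain <- lapply(seq_along(fit$chains), function(i) {
      sub <- fit
      sub$chains <- fit$chains[i]
      .scalar_draws(sub)
    })
  } else if (is.list(fit) && all(vapply(fit, is.matrix, logical(1)))) {
    per_chain <- fit
  } else {
    stop("`fit` must be a zi_fit or a list of draw matrices")
  }
  pars <- colnames(per_chain[[1]])
  nchain <- length(per_chain)
  res <- lapply(pars, function(p) {
    ch <- lapply(per_chain, function(m) m[, p])
    sds <- vapply(ch, stats::sd, numeric(1))
    degen <- all(sds < 1e-12)
    ess <- if (degen) 0 else
      sum(vapply(ch, function(v) as.numeric(coda::effectiveSize(v)), numeric(1)))
    rhat <- NA_real_
    if (nchain >= 2 && !degen) {
      # split each chain in half, classic potential scale reduction
      halves <- unlist(lapply(ch, function(v) {
        h <- length(v) %/% 2
        list(v[seq_len(h)], v[h + seq_len(h)])
      }), recursive = FALSE)
      nh <- length(halves[[1]])
      means <- vapply(halves, mean, numeric(1))
      vars <- vapply(halves, stats::var, numeric(1))
      W <- mean(vars)
      B <- nh * stats::var(means)
      rhat <- sqrt(((nh - 1) / nh * W + B / nh) / W)
    }
    tibble::tibble(parameter = p, rhat = rhat, ess = ess, degenerate = degen)
  })
  dplyr::bind_rows(res)
}

#' @rdname posterior_summary
#' @param x a `zi_fit` (for the `tidy`/`glance` methods)
#' @param ... unused
#' @export
tidy.zi_fit <- function(x, ...) {
  s <- posterior_summary(x)
  comp <- dplyr::case_when(
    startsWith(s$parameter, "beta_") ~ "count",
    startsWith(s$parameter, "alpha_") ~ "zero",
    s$parameter %in% c("rho", "zeta", "sigma2_theta", "sigma2_vartheta",
                       "sigma2_u1", "sigma2_u2", "sigma12_u", "psi") ~ "variance",
    s$parameter == "phi" ~ "dispersion",
    TRUE ~ "other"
  )
  term <- sub("^(beta|alpha)_", "", s$parameter)
  dplyr::bind_cols(tibble::tibble(component = comp, term = term),
                   s[, c("mean", "sd", "conf.low", "conf.high")]) |>
    dplyr::rename(estimate = "mean", std.error = "sd")
}

#' @rdname posterior_summary
#' @export
glance.zi_fit <- function(x, ...) {
  d <- if (x$prior_only) list(dic = NA_real_, pd = NA_real_, dbar = NA_real_)
       else dic(x)
  tibble::tibble(
    family = x$model$family,
    effects = x$model$effects,
    spatial = x$model$spatial,
    n_facilities = length(x$design$y),
    n_districts = length(x$district_levels),
    n_chains = length(x$chains),
    n_draws = nrow(x$chains[[1]]$beta) * length(x$chains),
    dic = d$dic, pd = d$pd, mean_deviance = d$dbar
  )
}
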