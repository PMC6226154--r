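#' Configuration of the synthetic facility survey generator
#'
#' Describes a survey-like population: a rook lattice of districts, a small
#' number of facilities per district, facility covariates drawn to match the
#' marginals of a national facility census (most facilities are small
#' type-II/III centres or health posts, about two thirds lie outside the
#' district capital, regions split the map into contiguous thirds), and
#' admission volumes that are log-normal with strongly type-dependent scale
#' (central hospitals admit orders of magnitude more than health posts).
#' Outcomes are generated from the full model: bivariate-normal or shared
#' district intercepts, CAR spatial fields, and ZIP/ZINB count emission with
#' a log-admissions offset.
#'
#' Default true fixed effects are the posterior means of the parsimonious
#' spatial model fitted to the motivating survey (zero component: intercept
#' -2.11, outside-capital effect 3.04; count component: intercept -3.17,
#' facility-type contrasts -0.32/-1.87/-2.78/-1.33, waiting house -0.79,
#' doctor ratio 1.12, emergency care -0.76, referral proportions -2.57 and
#' -3.62; remaining terms 0), and default variance components are that
#' model's estimates (`sigma2_theta = 1.09`, `sigma2_vartheta = 0.26`,
#' spatial conditional variances 0.84 and 2.05).
#'
#' @param rows,cols lattice dimensions (default 10 x 12 = 120 districts)
#' @param facilities one of `"survey"` (truncated-geometric 1..10, mean
#'   about 3 facilities per district) or `"uniform"` (uniform on 1..10)
#' @param family,effects,spatial model used for generation (see [zi_model()])
#' @param beta named true count-component coefficients (full 17-term design;
#'   names as in [build_design()])
#' @param alpha named true zero-component coefficients (5-term design)
#' @param sigma2_theta,sigma2_vartheta,rho,zeta non-spatial intercept
#'   parameters (interpretation depends on `effects`)
#' @param Sigma_u 2x2 conditional covariance of the bivariate CAR field
#'   (`spatial = "bicar"`); its diagonal is used for univariate fields
#' @param psi proper-CAR autocorrelation (`spatial = "proper"`)
#' @param phi negative-binomial dispersion (`family = "zinb"`)
#' @param type_probs facility-type probabilities (canonical order: central,
#'   provincial/general, health center I, health center II/III/post, rural)
#' @param p_outside probability a facility lies outside the district capital
#' @param p_wait,p_emoc probabilities of a waiting house / of
#'   partial-or-full-time emergency obstetric care
#' @param beta_means,beta_conc means and concentrations of the Beta laws of
#'   the proportion covariates `med_ratio`, `mal`, `hiv`, `ref_out`, `ref_in`
#' @param adm_meanlog named log-scale admission locations per facility type;
#'   `adm_sdlog` the common log-scale spread
#' @param missing_rate cellwise probability that a covariate value is
#'   missing (0 disables; use with [complete_case_filter()])
#' @return a list of class `zi_generator_config`
#' @export
generator_config <- function(rows = 10, cols = 12,
                             facilities = c("survey", "uniform"),
                             family = "zip",
                             effects = "independent",
                             spatial = "bicar",
                             beta = NULL, alpha = NULL,
                             sigma2_theta = 1.09, sigma2_vartheta = 0.26,
                             rho = 0, zeta = 1,
                             Sigma_u = diag(c(0.84, 2.05)),
                             psi = 0.9, phi = 0.5,
                             type_probs = c(0.006, 0.027, 0.27, 0.641, 0.056),
                             p_outside = 0.65,
                             p_wait = 0.276, p_emoc = 0.536,
                             beta_means = c(med_ratio = 0.473, mal = 0.0125,
                                            hiv = 0.0120, ref_out = 0.10,
                                            ref_in = 0.10),
                             beta_conc = c(med_ratio = 10, mal = 80,
                                           hiv = 80, ref_out = 10,
                                           ref_in = 10),
                             adm_meanlog = c("central hospital" = 9.0,
                                             "provincial/general hospital" = 8.0,
                                             "health center I" = 7.0,
                                             "health center II/III/post" = 5.7,
                                             "rural hospital" = 7.0),
                             adm_sdlog = 0.5,
                             missing_rate = 0) {
  facilities <- match.arg(facilities)
  model <- zi_model(family, effects = effects, spatial = spatial)
  stopifnot(abs(sum(type_probs) - 1) < 1e-8, length(type_probs) == 5,
            all(type_probs >= 0), p_outside >= 0, p_outside <= 1,
            sigma2_theta >= 0, sigma2_vartheta >= 0,
            is.matrix(Sigma_u), all(dim(Sigma_u) == 2),
            missing_rate >= 0, missing_rate < 1)
  beta_full <- stats::setNames(numeric(17),
                               c("(Intercept)", count_terms_full()))
  beta_full[c("(Intercept)", "PH", "HC1", "HC2", "RH", "WAIT", "MED",
              "EMOC", "REFOUT", "REFIN")] <-
    c(-3.17, -0.32, -1.87, -2.78, -1.33, -0.79, 1.12, -0.76, -2.57, -3.62)
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), names(beta_full))
    if (length(unknown) > 0) stop("unknown beta term(s): ",
                                  paste(unknown, collapse = ", "))
    beta_full[names(beta)] <- beta
  }
  alpha_full <- stats::setNames(numeric(5),
                                c("(Intercept)", zero_terms_full()))
  alpha_full[c("(Intercept)", "LOC")] <- c(-2.11, 3.04)
  if (!is.null(alpha)) {
    unknown <- setdiff(names(alpha), names(alpha_full))
    if (length(unknown) > 0) stop("unknown alpha term(s): ",
                                  paste(unknown, collapse = ", "))
    alpha_full[names(alpha)] <- alpha
  }
  structure(
    list(rows = rows, cols = cols, facilities = facilities, model = model,
         beta = beta_full, alpha = alpha_full,
         sigma2_theta = sigma2_theta, sigma2_vartheta = sigma2_vartheta,
         rho = rho, zeta = zeta, Sigma_u = Sigma_u, psi = psi, phi = phi,
         type_probs = type_probs, p_outside = p_outside,
         p_wait = p_wait, p_emoc = p_emoc,
         beta_means = beta_means, beta_conc = beta_conc,
         adm_meanlog = adm_meanlog, adm_sdlog = adm_sdlog,
         missing_rate = missing_rate),
    class = "zi_generator_config"
  )
}

.rbeta_mom <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Simulate a synthetic facility survey with known truth
#'
#' Draws a full dataset from the generative model described by a
#' [generator_config()]: district lattice, facility covariates, non-spatial
#' and spatial district effects, and counts. Region bands split the lattice
#' rows into contiguous South / Center / North thirds so that region and
#' spatial structure are confounded the way national geography confounds
#' them.
#'
#' @param config a [generator_config()]
#' @param seed integer seed (the draw is fully reproducible given
#'   `config` and `seed`)
#' @return a list with `data` (facility tibble), `graph` (the lattice
#'   `zi_graph`) and `truth` (true coefficients, district effects and
#'   per-facility `pi`, `nu`)
#' @export
simulate_dataset <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "zi_generator_config"))
  set.seed(seed)
  graph <- make_lattice_graph(config$rows, config$cols)
  nd <- n_districts(graph)
  # contiguous region bands over lattice rows: north band first
  row_of <- rep(seq_len(config$rows), each = config$cols)
  band <- cut(row_of, breaks = 3, labels = c("North", "Center", "South"))
  district_region <- as.character(band)

  n_fac <- switch(config$facilities,
                  uniform = sample(1:10, nd, replace = TRUE),
                  survey = sample(1:10, nd, replace = TRUE,
                                  prob = 0.7^(0:9)))
  district <- rep(graph$nodes, n_fac)
  n <- length(district)
  d_idx <- rep(seq_len(nd), n_fac)

  types <- zi_canonical_levels()$facility_type
  facility_type <- sample(types, n, replace = TRUE, prob = config$type_probs)
  location <- ifelse(stats::runif(n) < config$p_outside,
                     "outside capital", "inside capital")
  waiting_house <- ifelse(stats::runif(n) < config$p_wait, "yes", "no")
  emoc <- ifelse(stats::runif(n) < config$p_emoc, "partial/full time", "none")
  bm <- config$beta_means; bc <- config$beta_conc
  N <- pmax(1, round(stats::rlnorm(n,
         meanlog = config$adm_meanlog[facility_type],
         sdlog = config$adm_sdlog)))
  tab <- tibble::tibble(
    y = 0L, N = as.integer(N), district = district,
    region = district_region[d_idx],
    location = location, facility_type = facility_type,
    waiting_house = waiting_house, emoc = emoc,
    med_ratio = .rbeta_mom(n, bm["med_ratio"], bc["med_ratio"]),
    mal = .rbeta_mom(n, bm["mal"], bc["mal"]),
    hiv = .rbeta_mom(n, bm["hiv"], bc["hiv"]),
    ref_out = .rbeta_mom(n, bm["ref_out"], bc["ref_out"]),
    ref_in = .rbeta_mom(n, bm["ref_in"], bc["ref_in"])
  )
  tab <- as_facility_table(tab)

  model <- config$model
  theta <- vartheta <- numeric(nd)
  if (model$effects == "independent") {
    theta <- stats::rnorm(nd, 0, sqrt(config$sigma2_theta))
    vartheta <- stats::rnorm(nd, 0, sqrt(config$sigma2_vartheta))
  } else if (model$effects == "correlated") {
    S <- matrix(c(config$sigma2_theta,
                  config$rho * sqrt(config$sigma2_theta * config$sigma2_vartheta),
                  config$rho * sqrt(config$sigma2_theta * config$sigma2_vartheta),
                  config$sigma2_vartheta), 2, 2)
    zz <- matrix(stats::rnorm(2 * nd), ncol = 2) %*% chol(S)
    theta <- zz[, 1]; vartheta <- zz[, 2]
  } else if (model$effects == "shared") {
    theta <- stats::rnorm(nd, 0, sqrt(config$sigma2_theta))
    vartheta <- config$zeta * theta
  }
  u1 <- u2 <- numeric(nd)
  if (model$spatial == "icar") {
    u2 <- sample_icar_field(graph, config$Sigma_u[2, 2])
  } else if (model$spatial == "proper") {
    Q <- (graph_laplacian(graph) -
            (config$psi - 1) * adjacency_matrix(graph)) / config$Sigma_u[2, 2]
    u2 <- drop(backsolve(chol(Q), stats::rnorm(nd)))
  } else if (model$spatial == "bicar") {
    uu <- sample_bicar_field(graph, config$Sigma_u)
    u1 <- uu[, 1]; u2 <- uu[, 2]
  }
  if (!model$zero_inflated) vartheta <- u1 <- numeric(nd)

  design <- build_design(tab)
  lp <- linear_predictors(design, config$alpha, config$beta,
                          zero_effects = vartheta + u1,
                          count_effects = theta + u2)
  pi <- if (model$zero_inflated) lp$pi else rep(0, n)
  phi <- if (model$family %in% c("nb", "zinb")) config$phi else 0
  tab$y <- rzi(n, nu = lp$nu, pi = pi, phi = phi)
  # y is bounded by admissions in the real survey; resample the rare
  # overshoot draws by truncation
  over <- tab$y > tab$N
  while (any(over)) {
    tab$y[over] <- rzi(sum(over), nu = lp$nu[over], pi = pi[over], phi = phi)
    over <- tab$y > tab$N
  }
  if (config$missing_rate > 0) {
    for (v in c("waiting_house", "emoc", "med_ratio", "mal", "hiv",
                "ref_out", "ref_in")) {
      hit <- stats::runif(n) < config$missing_rate
      tab[[v]][hit] <- NA
    }
  }
  list(data = tab, graph = graph,
       truth = list(beta = config$beta, alpha = config$alpha,
                    theta = theta, vartheta = vartheta, u1 = u1, u2 = u2,
                    pi = pi, nu = lp$nu, phi = phi, config = config))
}

#' Simulate-and-refit calibration experiment
#'
#' Repeatedly simulates a dataset from a [generator_config()], refits the
#' generating model, and reports per-parameter bias, RMSE and 95% credible
#' interval coverage of the fixed effects across replicates.
#'
#' @param config a [generator_config()]
#' @param mcmc an [mcmc_config()]; replicate `r` uses `seed + 1000 * r`
#' @param replicates number of simulate-fit replicates
#' @param count_terms,zero_terms design terms used for fitting (defaults:
#'   full design)
#' @return a list with `by_parameter` (tibble: `parameter`, `truth`, `bias`,
#'   `rmse`, `coverage`), `coverage` (pooled share of parameter-replicate
#'   cells whose interval covers truth) and `estimates` (per-replicate tidy
#'   results)
#' @export
recovery_experiment <- function(config = generator_config(),
                                mcmc = mcmc_config(iterations = 4000,
                                                   burn_in = 2000),
                                replicates = 10,
                                count_terms = count_terms_full(),
                                zero_terms = zero_terms_full()) {
  stopifnot(replicates >= 1)
  truth_all <- c(stats::setNames(config$beta,
                                 paste0("beta_", names(config$beta))),
                 stats::setNames(config$alpha,
                                 paste0("alpha_", names(config$alpha))))
  res <- purrr::map_dfr(seq_len(replicates), function(rep) {
    sim <- simulate_dataset(config, seed = mcmc$seed + 1000L * rep)
    fit <- fit_zi(sim$data, model = config$model, graph = sim$graph,
                  mcmc = mcmc_config(iterations = mcmc$iterations,
                                     burn_in = mcmc$burn_in,
                                     thin = mcmc$thin, chains = mcmc$chains,
                                     seed = mcmc$seed + 1000L * rep),
                  count_terms = count_terms, zero_terms = zero_terms)
    s <- posterior_summary(fit)
    s <- s[startsWith(s$parameter, "beta_") | startsWith(s$parameter, "alpha_"), ]
    s$truth <- truth_all[s$parameter]
    s$replicate <- rep
    s$covered <- s$conf.low <= s$truth & s$truth <= s$conf.high
    s
  })
  by_par <- dplyr::summarise(
    dplyr::group_by(res, .data$parameter),
    truth = .data$truth[1],
    bias = mean(.data$mean - .data$truth),
    rmse = sqrt(mean((.data$mean - .data$truth)^2)),
    coverage = mean(.data$covered),
    .groups = "drop")
  list(by_parameter = by_par, coverage = mean(res$covered), estimates = res)
}
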