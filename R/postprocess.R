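#' Posterior predictive counts
#'
#' For each retained draw, simulates a replicate count for every facility
#' from the model at that draw's parameters, giving the posterior predictive
#' distribution of the data. The per-facility predictive mean estimates
#' `E(y_ij | Y)`.
#'
#' @param fit a `zi_fit`
#' @param max_draws cap on the number of draws used (evenly subsampled)
#' @return a list of class `zi_ppc`: `draws` (draws x facilities matrix of
#'   simulated counts) and `summary` (tibble with per-facility `district`,
#'   observed `y`, `N` and `predicted_mean`)
#' @export
posterior_predictive_counts <- function(fit, max_draws = 4000) {
  stopifnot(inherits(fit, "zi_fit"))
  pd <- .predictor_draws(fit, max_draws)
  J <- nrow(pd$nu); n <- ncol(pd$nu)
  nbfam <- fit$model$family %in% c("nb", "zinb")
  phi <- if (nbfam) rep(pd$phi, n) else 0
  yrep <- rzi(J * n, nu = as.vector(pd$nu), pi = as.vector(pd$pi), phi = phi)
  yrep <- matrix(yrep, J, n)
  structure(
    list(draws = yrep,
         summary = tibble::tibble(
           district = fit$data$district,
           y = fit$design$y,
           N = exp(fit$design$offset),
           predicted_mean = colMeans(yrep))),
    class = "zi_ppc"
  )
}

#' @export
print.zi_ppc <- function(x, ...) {
  cat("<zi_ppc> ", nrow(x$draws), " predictive draws x ", ncol(x$draws),
      " facilities; zero share ", sprintf("%.3f", mean(x$draws == 0)),
      "\n", sep = "")
  invisible(x)
}

#' District-level mortality rates
#'
#' Aggregates deaths and admissions within each district and expresses the
#' rate per 100,000 admissions: `rate = 100000 * sum(y) / sum(N)`. When
#' per-facility predicted counts are supplied (e.g. posterior predictive
#' means), predicted district totals and rates are added.
#'
#' @param table a facility tibble with `y`, `N`, `district`
#' @param predicted optional numeric vector of per-facility predicted counts,
#'   aligned with the rows of `table`
#' @return a tibble with one row per district: `district`, `deaths`,
#'   `admissions`, `rate` and (if predicted) `predicted_deaths`,
#'   `predicted_rate`
#' @export
district_rates <- function(table, predicted = NULL) {
  stopifnot(all(c("y", "N", "district") %in% names(table)))
  if (!is.null(predicted) && length(predicted) != nrow(table)) {
    stop("`predicted` must have one value per facility row")
  }
  tab <- tibble::tibble(district = table$district,
                        y = as.numeric(table$y), N = as.numeric(table$N))
  if (!is.null(predicted)) tab$pred <- predicted
  out <- dplyr::summarise(dplyr::group_by(tab, .data$district),
                          deaths = sum(.data$y),
                          admissions = sum(.data$N),
                          predicted_deaths = if (is.null(predicted)) NA_real_
                                             else sum(.data$pred),
                          .groups = "drop")
  if (any(out$admissions <= 0)) {
    stop("district(s) with zero admissions: ",
         paste(out$district[out$admissions <= 0], collapse = ", "))
  }
  out$rate <- 1e5 * out$deaths / out$admissions
  out <- if (is.null(predicted)) {
    out$predicted_deaths <- NULL
    out[, c("district", "deaths", "admissions", "rate")]
  } else {
    out$predicted_rate <- 1e5 * out$predicted_deaths / out$admissions
    out[, c("district", "deaths", "admissions", "rate",
            "predicted_deaths", "predicted_rate")]
  }
  class(out) <- c("zi_rates", class(out))
  out
}

#' Per-district posterior means of the random effects
#'
#' A tidy map table: one row per district, one column per effect family
#' present in the model — `vartheta` (zero-component intercept), `theta`
#' (count-component intercept), `u1`/`u2` (spatial fields of the zero/count
#' components).
#'
#' @param fit a `zi_fit`
#' @param effects which effect families to extract; default all present in
#'   the model. Requesting an absent family is an error.
#' @return a tibble keyed by `district`
#' @export
effect_map_table <- function(fit, effects = NULL) {
  stopifnot(inherits(fit, "zi_fit"))
  avail <- c("vartheta", "theta", "u1", "u2")
  present <- avail[vapply(avail, function(w) {
    ncol(fit$chains[[1]][[w]]) > 0
  }, logical(1))]
  if (is.null(effects)) effects <- present
  absent <- setdiff(effects, present)
  if (length(absent) > 0) {
    stop("effect(s) not in this model: ", paste(absent, collapse = ", "))
  }
  out <- tibble::tibble(district = fit$district_levels)
  for (w in effects) out[[w]] <- colMeans(.stack_draws(fit, w))
  out
}
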