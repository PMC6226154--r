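#' Plot district-level rates on the lattice or as a ranked bar chart
#'
#' Tabular outputs are the package's core deliverable; these ggplot helpers
#' are light visual sugar over them. Without geometry, districts are shown
#' as a ranked Cleveland-style dot plot of observed (and, when present,
#' predicted) rates per 100,000 admissions.
#'
#' @param object a tibble from [district_rates()]
#' @param top show only the `top` highest-rate districts (default 30)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.zi_rates <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(object, .data$rate, n = top)
  df$district <- stats::reorder(df$district, df$rate)
  long <- tidyr::pivot_longer(
    df, dplyr::any_of(c("rate", "predicted_rate")),
    names_to = "kind", values_to = "value")
  long$kind <- ifelse(long$kind == "rate", "observed", "predicted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$district,
                                     colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "deaths per 100,000 admissions", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.zi_rates
#' @export
plot_district_rates <- function(object, top = 30, ...) {
  if (!inherits(object, "zi_rates")) class(object) <- c("zi_rates",
                                                        class(object))
  autoplot.zi_rates(object, top = top, ...)
}

#' Posterior predictive count histogram
#'
#' Overlays the pooled posterior predictive count distribution on the
#' observed histogram — the standard visual check that the model reproduces
#' the zero share and the count tail.
#'
#' @param object a `zi_ppc` from [posterior_predictive_counts()]
#' @param max_count truncate the x axis (default 30)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.zi_ppc <- function(object, max_count = 30, ...) {
  obs <- tibble::tibble(y = pmin(object$summary$y, max_count),
                        kind = "observed")
  pred <- tibble::tibble(y = pmin(as.vector(object$draws), max_count),
                         kind = "predicted")
  ggplot2::ggplot(dplyr::bind_rows(obs, pred),
                  ggplot2::aes(x = .data$y, y = ggplot2::after_stat(density),
                               fill = .data$kind)) +
    ggplot2::geom_histogram(position = "dodge", binwidth = 1,
                            boundary = -0.5) +
    ggplot2::labs(x = "maternal deaths per facility", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Trace plot of monitored scalar parameters
#'
#' @param object a `zi_fit`
#' @param pars character vector of parameter names (default: the variance
#'   components and the first coefficients of each component)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.zi_fit <- function(object, pars = NULL, ...) {
  per_chain <- lapply(seq_along(object$chains), function(i) {
    sub <- object
    sub$chains <- object$chains[i]
    m <- .scalar_draws(sub)
    tibble::tibble(chain = factor(i),
                   iteration = rep(seq_len(nrow(m)), ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  })
  df <- dplyr::bind_rows(per_chain)
  if (is.null(pars)) {
    scal <- setdiff(unique(df$parameter),
                    grep("^(beta|alpha)_", unique(df$parameter), value = TRUE))
    pars <- utils::head(c(scal, "beta_(Intercept)", "alpha_(Intercept)"), 8)
    pars <- intersect(pars, unique(df$parameter))
  }
  df <- df[df$parameter %in% pars, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
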