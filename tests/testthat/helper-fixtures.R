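# small in-code fixtures shared across tests

# a minimal valid facility tibble (all canonical columns, no missing values)
tiny_facility_table <- function(n = 6, districts = c("A", "A", "B", "B", "C", "C"),
                                y = c(0L, 2L, 0L, 5L, 1L, 0L),
                                N = c(100L, 400L, 120L, 800L, 150L, 90L)) {
  stopifnot(length(districts) == n, length(y) == n, length(N) == n)
  zimap::as_facility_table(tibble::tibble(
    y = y, N = N, district = districts,
    region = rep(c("South", "Center", "North"), length.out = n),
    location = rep(c("inside capital", "outside capital"), length.out = n),
    facility_type = rep(c("central hospital", "health center II/III/post"),
                        length.out = n),
    waiting_house = rep(c("no", "yes"), length.out = n),
    emoc = rep(c("none", "partial/full time"), length.out = n),
    med_ratio = seq(0.1, 0.9, length.out = n),
    mal = rep(0.01, n), hiv = rep(0.02, n),
    ref_out = rep(0.1, n), ref_in = rep(0.2, n)
  ))
}

# write a facility CSV (optionally with blank cells) and return its path
write_facility_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  path
}

# intercept-only table: one district block design for sampler toys
intercept_only_table <- function(y, N = 1000L, n_districts = 1) {
  n <- length(y)
  zimap::as_facility_table(tibble::tibble(
    y = as.integer(y), N = as.integer(rep_len(N, n)),
    district = rep_len(sprintf("d%02d", seq_len(n_districts)), n),
    region = "South", location = "inside capital",
    facility_type = "central hospital", waiting_house = "no", emoc = "none",
    med_ratio = 0.5, mal = 0.01, hiv = 0.01, ref_out = 0.1, ref_in = 0.1
  ))
}

fit_intercept_only <- function(tab, model, priors = zimap::prior_spec(),
                               iterations = 6000, burn_in = 3000, seed = 1,
                               chains = 1) {
  zimap::fit_zi(tab, model, priors = priors,
                count_terms = character(0), zero_terms = character(0),
                mcmc = zimap::mcmc_config(iterations = iterations,
                                          burn_in = burn_in, seed = seed,
                                          chains = chains))
}
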