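# reading, validation, complete-case filtering, design matrices, descriptives

test_that("read_facility_table types, validates and keeps file order", {
  tab <- tiny_facility_table()
  p <- write_facility_csv(tab)
  got <- read_facility_table(p)
  expect_equal(got$y, tab$y)
  expect_equal(got$N, tab$N)
  expect_equal(as.character(got$facility_type), as.character(tab$facility_type))

  # malformed y names the offending row
  bad <- tab
  bad$y <- as.character(bad$y)
  bad$y[2] <- "two"
  expect_error(read_facility_table(write_facility_csv(bad)), "row 2")
  bad2 <- tab
  bad2$y[3] <- -1L
  expect_error(suppressWarnings(read_facility_table(write_facility_csv(bad2))),
               "row 3")
  bad3 <- tab
  bad3$y[1] <- 1000L  # exceeds N = 100
  expect_error(read_facility_table(write_facility_csv(bad3)), "row 1")

  # empty file and missing columns
  pe <- tempfile(fileext = ".csv")
  writeLines("y,N,district", pe)
  expect_error(suppressWarnings(read_facility_table(pe)))
  pm <- write_facility_csv(tab[, setdiff(names(tab), "hiv")])
  expect_error(read_facility_table(pm), "hiv")
})

test_that("schema maps column names and categorical spellings", {
  tab <- tiny_facility_table()
  renamed <- tab
  names(renamed)[names(renamed) == "y"] <- "deaths"
  renamed$location <- toupper(as.character(renamed$location))  # case variant
  renamed$region <- ifelse(renamed$region == "South", "SUL",
                           as.character(renamed$region))
  p <- write_facility_csv(renamed)
  sch <- facility_schema(columns = c(y = "deaths"),
                         levels = list(region = c(SUL = "South")))
  got <- read_facility_table(p, sch)
  expect_equal(got$y, tab$y)
  expect_equal(as.character(got$region), as.character(tab$region))
  expect_equal(as.character(got$location), as.character(tab$location))
  # unknown level without a map is an error
  expect_error(read_facility_table(p, facility_schema(columns = c(y = "deaths"))),
               "unknown level")
})

test_that("complete_case_filter drops rows with missing required values", {
  tab <- tiny_facility_table()
  tab$med_ratio[c(2, 5)] <- NA
  out <- complete_case_filter(tab)
  expect_equal(nrow(out), 4)
  rep <- attr(out, "drop_report")
  expect_equal(rep$n_missing[rep$variable == "med_ratio"], 2)
  # idempotent
  out2 <- complete_case_filter(out)
  expect_equal(nrow(out2), nrow(out))
  # identity on complete tables
  full <- tiny_facility_table()
  expect_equal(nrow(complete_case_filter(full)), nrow(full))
  # monotone in the required set
  tab$hiv[1] <- NA
  n_small <- nrow(complete_case_filter(tab, required = c("y", "N", "district")))
  n_mid <- nrow(complete_case_filter(tab, required = c("y", "med_ratio")))
  n_all <- nrow(complete_case_filter(tab))
  expect_true(n_all <= n_mid && n_mid <= n_small)
  tab$med_ratio <- NA_real_
  expect_warning(complete_case_filter(tab), "every row")
})

test_that("build_design produces the canonical 17 + 5 column matrices", {
  tab <- tiny_facility_table()
  d <- build_design(tab)
  expect_equal(ncol(d$X), 17)
  expect_equal(ncol(d$Z), 5)
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_equal(d$offset, log(tab$N))
  # reference cell: South / inside capital / central hospital / no wait /
  # no emoc -> all dummies zero
  ref <- tab[1, ]
  dr <- build_design(ref)
  dummy_cols <- setdiff(colnames(dr$X),
                        c("(Intercept)", "MED", "MAL", "HIV", "REFOUT", "REFIN"))
  expect_true(all(dr$X[1, dummy_cols] == 0))
  # a North / outside-capital row switches NORTH, LOC and their interaction
  row2 <- tab[3, ]  # North per the tiny fixture cycle
  row2$region <- factor("North", levels = levels(tab$region))
  row2$location <- factor("outside capital", levels = levels(tab$location))
  d2 <- build_design(row2)
  expect_equal(unname(d2$X[1, c("NORTH", "LOC", "NORTH:LOC")]), c(1, 1, 1))
  expect_equal(unname(d2$X[1, c("CENTER", "CENTER:LOC")]), c(0, 0))
})

test_that("design invariants hold on random generated tables", {
  sim <- simulate_dataset(generator_config(rows = 4, cols = 4), seed = 8)
  d <- build_design(sim$data)
  # facility-type dummy block: at most one dummy active per row
  block <- d$X[, c("PH", "HC1", "HC2", "RH")]
  expect_true(all(rowSums(block) <= 1))
  # interactions are elementwise products of their parents
  expect_equal(d$X[, "NORTH:LOC"], d$X[, "NORTH"] * d$X[, "LOC"])
  expect_equal(d$X[, "CENTER:LOC"], d$X[, "CENTER"] * d$X[, "LOC"])
  # district index maps into district levels
  expect_true(all(d$district %in% seq_along(d$district_levels)))
  # subsetting terms shrinks X accordingly
  d3 <- build_design(sim$data, count_terms = c("HC2", "WAIT"),
                     zero_terms = "LOC")
  expect_equal(colnames(d3$X), c("(Intercept)", "HC2", "WAIT"))
  expect_equal(colnames(d3$Z), c("(Intercept)", "LOC"))
  expect_error(build_design(sim$data, count_terms = "NOPE"), "unknown design term")
})

test_that("summarize_facilities computes count and rate descriptives", {
  one <- tiny_facility_table(1, "A", 2L, 100L)
  s <- summarize_facilities(one)
  stats <- s$stats
  expect_equal(stats$deaths[stats$statistic == "mean"], 2)
  expect_equal(stats$deaths[stats$statistic == "sd"], 0)
  expect_equal(stats$facility_rate[stats$statistic == "mean"], 2000)
  expect_equal(s$zero_share, 0)

  tab <- tiny_facility_table()
  s2 <- summarize_facilities(tab)
  expect_equal(s2$zero_share, mean(tab$y == 0))
  expect_equal(s2$n_districts, 3)
  expect_equal(s2$stats$deaths[s2$stats$statistic == "max"], max(tab$y))
  # district rate of a single-facility district equals its facility rate
  dr <- district_rates(tab)
  expect_equal(max(s2$stats$district_rate[s2$stats$statistic == "max"]),
               max(dr$rate))
  # marginals sum to one within variables
  shares <- tapply(s2$marginals$share, s2$marginals$variable, sum)
  expect_true(all(abs(shares - 1) < 1e-12))
})
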