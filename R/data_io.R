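#' Canonical facility-table variables and levels
#'
#' The modelling functions expect one row per health facility with the
#' columns below. `facility_schema()` describes how to map a raw CSV export
#' onto them: `columns` maps canonical names to file column names, `levels`
#' maps file spellings of categorical levels to the canonical levels, and
#' `na` lists strings treated as missing.
#'
#' Canonical variables: `y` (maternal deaths), `N` (obstetric admissions),
#' `district`, `region` (South/Center/North; South is the modelling
#' reference), `location` (inside/outside the district capital; inside is the
#' reference), `facility_type` (central hospital — reference —,
#' provincial/general hospital, health center I, health center II/III/post,
#' rural hospital), `waiting_house` (no/yes), `emoc` (emergency obstetric
#' care: none / partial or full time), and the proportions `med_ratio`
#' (medical doctors among staff), `mal`, `hiv` (malaria / HIV shares among
#' admissions), `ref_out`, `ref_in` (referrals to / from other facilities).
#'
#' @param columns named character vector mapping canonical names to file
#'   column names (defaults to identical names)
#' @param levels named list of named character vectors; for each categorical
#'   variable, a map from file level to canonical level (case-insensitive
#'   matches to canonical levels always work without a map)
#' @param na character vector of strings read as missing
#' @return a list of class `facility_schema`
#' @export
facility_schema <- function(columns = NULL, levels = NULL,
                            na = c("", "NA", "N/A", ".")) {
  vars <- zi_variables()
  cols <- stats::setNames(vars, vars)
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), vars)
    if (length(unknown) > 0) stop("unknown canonical column(s): ",
                                  paste(unknown, collapse = ", "))
    cols[names(columns)] <- columns
  }
  structure(list(columns = cols, levels = levels %||% list(), na = na),
            class = "facility_schema")
}

#' @rdname facility_schema
#' @export
zi_variables <- function() {
  c("y", "N", "district", "region", "location", "facility_type",
    "waiting_house", "emoc", "med_ratio", "mal", "hiv", "ref_out", "ref_in")
}

zi_canonical_levels <- function() {
  list(
    region = c("South", "Center", "North"),
    location = c("inside capital", "outside capital"),
    facility_type = c("central hospital", "provincial/general hospital",
                      "health center I", "health center II/III/post",
                      "rural hospital"),
    waiting_house = c("no", "yes"),
    emoc = c("none", "partial/full time")
  )
}

.normalize_levels <- function(x, var, map) {
  canon <- zi_canonical_levels()[[var]]
  raw <- trimws(as.character(x))
  out <- rep(NA_character_, length(raw))
  known <- !is.na(raw)
  # explicit map first, then case-insensitive canonical match
  if (!is.null(map)) {
    hit <- match(raw, names(map))
    out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  }
  todo <- known & is.na(out)
  hit <- match(tolower(raw[todo]), tolower(canon))
  out[todo][!is.na(hit)] <- canon[hit[!is.na(hit)]]
  bad <- known & is.na(out)
  if (any(bad)) {
    stop("unknown level(s) for ", var, ": ",
         paste(unique(raw[bad]), collapse = ", "))
  }
  factor(out, levels = canon)
}

#' Read and validate a facility-level CSV
#'
#' Reads a delimited facility table, renames columns per the schema,
#' normalises categorical levels to their canonical sets and validates the
#' counts: `y` must be a non-negative integer, `N` a positive integer, and
#' `y <= N` row by row. Rows are kept in file order. Missing values (per the
#' schema's `na` strings) are preserved as `NA`; use
#' [complete_case_filter()] before modelling.
#'
#' @param path path to a CSV file with a header row
#' @param schema a [facility_schema()]
#' @return a tibble with the canonical columns of [zi_variables()]
#' @export
read_facility_table <- function(path, schema = facility_schema()) {
  if (!file.exists(path)) stop("facility file not found: ", path)
  raw <- readr::read_csv(path, na = schema$na, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) stop("facility file is empty: ", path)
  missing_cols <- setdiff(unname(schema$columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("facility file lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- raw[, unname(schema$columns)]
  names(tab) <- names(schema$columns)
  as_facility_table(tab, level_maps = schema$levels)
}

#' Coerce a data frame to a validated facility table
#'
#' @param tab data frame with the canonical columns (character or typed)
#' @param level_maps optional named list of level maps (see [facility_schema()])
#' @return a validated tibble
#' @export
as_facility_table <- function(tab, level_maps = list()) {
  tab <- tibble::as_tibble(tab)
  need <- setdiff(zi_variables(), names(tab))
  if (length(need) > 0) {
    stop("facility table lacks column(s): ", paste(need, collapse = ", "))
  }
  num_parse <- function(x, var) {
    out <- suppressWarnings(as.numeric(as.character(x)))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("malformed ", var, " at row ", bad[1])
    }
    out
  }
  y <- num_parse(tab$y, "y")
  N <- num_parse(tab$N, "N")
  bad_y <- which(!is.na(y) & (y < 0 | y != floor(y)))
  if (length(bad_y) > 0) stop("invalid y (negative or non-integer) at row ", bad_y[1])
  bad_N <- which(!is.na(N) & (N < 1 | N != floor(N)))
  if (length(bad_N) > 0) stop("invalid N (must be a positive integer) at row ", bad_N[1])
  bad_yN <- which(!is.na(y) & !is.na(N) & y > N)
  if (length(bad_yN) > 0) stop("y exceeds N at row ", bad_yN[1])
  out <- tab
  out$y <- as.integer(y)
  out$N <- as.integer(N)
  out$district <- as.character(tab$district)
  for (var in names(zi_canonical_levels())) {
    out[[var]] <- .normalize_levels(tab[[var]], var, level_maps[[var]])
  }
  for (var in c("med_ratio", "mal", "hiv", "ref_out", "ref_in")) {
    v <- num_parse(tab[[var]], var)
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) stop(var, " outside [0, 1] at row ", bad[1])
    out[[var]] <- v
  }
  out
}

#' Drop rows with missing modelled variables (complete-case analysis)
#'
#' Removes every row with a missing value in any required variable, the
#' standard complete-case treatment under a missing-completely-at-random
#' assumption. The returned tibble carries a `drop_report` attribute: a
#' tibble of per-variable missing counts among the dropped rows.
#'
#' @param table a facility tibble
#' @param required character vector of variables that must be non-missing
#'   (default: every modelled variable, [zi_variables()])
#' @return the filtered tibble (possibly empty, with a warning)
#' @export
complete_case_filter <- function(table, required = zi_variables()) {
  missing_req <- setdiff(required, names(table))
  if (length(missing_req) > 0) {
    stop("required variable(s) not in table: ", paste(missing_req, collapse = ", "))
  }
  miss <- vapply(required, function(v) is.na(table[[v]]), logical(nrow(table)))
  miss <- matrix(miss, nrow = nrow(table))
  drop_row <- rowSums(miss) > 0
  report <- tibble::tibble(
    variable = required,
    n_missing = colSums(miss)
  )
  out <- table[!drop_row, , drop = FALSE]
  if (nrow(out) == 0) warning("complete-case filter removed every row")
  attr(out, "drop_report") <- report
  attr(out, "n_dropped") <- sum(drop_row)
  out
}

.zi_term_defs <- function() {
  # each term: name, evaluation function on the facility table
  list(
    NORTH  = function(t) as.numeric(t$region == "North"),
    CENTER = function(t) as.numeric(t$region == "Center"),
    PH     = function(t) as.numeric(t$facility_type == "provincial/general hospital"),
    HC1    = function(t) as.numeric(t$facility_type == "health center I"),
    HC2    = function(t) as.numeric(t$facility_type == "health center II/III/post"),
    RH     = function(t) as.numeric(t$facility_type == "rural hospital"),
    LOC    = function(t) as.numeric(t$location == "outside capital"),
    WAIT   = function(t) as.numeric(t$waiting_house == "yes"),
    MED    = function(t) t$med_ratio,
    EMOC   = function(t) as.numeric(t$emoc == "partial/full time"),
    MAL    = function(t) t$mal,
    HIV    = function(t) t$hiv,
    REFOUT = function(t) t$ref_out,
    REFIN  = function(t) t$ref_in,
    `NORTH:LOC`  = function(t) as.numeric(t$region == "North") *
                               as.numeric(t$location == "outside capital"),
    `CENTER:LOC` = function(t) as.numeric(t$region == "Center") *
                               as.numeric(t$location == "outside capital")
  )
}

#' Default term sets of the two model components
#'
#' The full count-component design has 17 columns (intercept plus the terms
#' below, including the two region-by-location interactions) and the
#' zero-component design has 5 (intercept, region dummies, location, malaria
#' share).
#'
#' @return character vector of term names
#' @export
count_terms_full <- function() {
  c("NORTH", "CENTER", "PH", "HC1", "HC2", "RH", "LOC", "WAIT", "MED",
    "EMOC", "MAL", "HIV", "REFOUT", "REFIN", "NORTH:LOC", "CENTER:LOC")
}

#' @rdname count_terms_full
#' @export
zero_terms_full <- function() c("NORTH", "CENTER", "LOC", "MAL")

#' Build the two-component design matrices
#'
#' Constructs the count-component matrix `X`, the zero-component matrix `Z`
#' (both with a leading intercept column), the exposure offset `log(N)` and
#' the district index from a complete-case facility table. Dummy coding uses
#' the canonical reference categories (South, inside capital, central
#' hospital, no waiting house, no emergency care); interaction columns are
#' elementwise products of their parent dummies.
#'
#' @param table a complete-case facility tibble
#' @param count_terms,zero_terms character vectors of term names (subsets of
#'   [count_terms_full()] / [zero_terms_full()]); the intercept is implicit
#' @return an object of class `zi_design`: list with `X`, `Z`, `offset`,
#'   `district` (integer index into `district_levels`), `district_levels`
#' @export
build_design <- function(table, count_terms = count_terms_full(),
                         zero_terms = zero_terms_full()) {
  defs <- .zi_term_defs()
  bad <- setdiff(c(count_terms, zero_terms), names(defs))
  if (length(bad) > 0) stop("unknown design term(s): ", paste(bad, collapse = ", "))
  req <- zi_variables()
  anymiss <- vapply(req, function(v) anyNA(table[[v]]), logical(1))
  if (any(anymiss)) {
    stop("design requires a complete-case table; missing values in: ",
         paste(req[anymiss], collapse = ", "))
  }
  mk <- function(terms) {
    cols <- c(list(`(Intercept)` = rep(1, nrow(table))),
              lapply(defs[terms], function(f) f(table)))
    do.call(cbind, cols)
  }
  district_levels <- sort(unique(table$district))
  structure(
    list(
      X = mk(count_terms),
      Z = mk(zero_terms),
      offset = log(table$N),
      district = match(table$district, district_levels),
      district_levels = district_levels,
      y = table$y
    ),
    class = "zi_design"
  )
}

#' @export
print.zi_design <- function(x, ...) {
  cat("<zi_design> ", length(x$y), " facilities, ",
      length(x$district_levels), " districts; X: ", ncol(x$X),
      " columns, Z: ", ncol(x$Z), " columns\n", sep = "")
  invisible(x)
}

#' Descriptive summary of a facility table
#'
#' Moments and quantiles of the death counts and of the mortality rate per
#' 100,000 admissions — at the facility level and after aggregating counts
#' and admissions within districts — plus the share of facilities reporting
#' zero deaths and the categorical/continuous covariate marginals.
#'
#' @param table a (complete-case) facility tibble
#' @return a list of class `zi_summary` with tibbles `stats` (one row per
#'   statistic; columns for deaths, facility-level rate, district-level
#'   rate), `marginals` (categorical level shares), `continuous` (means of
#'   the proportion covariates) and scalar `zero_share`
#' @export
summarize_facilities <- function(table) {
  stopifnot(nrow(table) > 0)
  rate_fac <- 1e5 * table$y / table$N
  dist <- dplyr::summarise(dplyr::group_by(table, .data$district),
                           y = sum(.data$y), N = sum(.data$N), .groups = "drop")
  rate_dist <- 1e5 * dist$y / dist$N
  stat_row <- function(v) {
    s <- if (length(v) > 1) stats::sd(v) else 0   # degenerate single-row table
    c(mean = mean(v), sd = s, variance = s^2,
      median = stats::median(v), min = min(v), max = max(v))
  }
  sm <- rbind(deaths = stat_row(as.numeric(table$y)),
              facility_rate = stat_row(rate_fac),
              district_rate = stat_row(rate_dist))
  stats_tbl <- tibble::tibble(
    statistic = colnames(sm),
    deaths = unname(sm["deaths", ]),
    facility_rate = unname(sm["facility_rate", ]),
    district_rate = unname(sm["district_rate", ])
  )
  marg <- dplyr::bind_rows(lapply(names(zi_canonical_levels()), function(v) {
    tt <- table(table[[v]])
    tibble::tibble(variable = v, level = names(tt),
                   n = as.integer(tt), share = as.numeric(tt) / nrow(table))
  }))
  cont <- tibble::tibble(
    variable = c("med_ratio", "mal", "hiv", "ref_out", "ref_in"),
    mean = vapply(c("med_ratio", "mal", "hiv", "ref_out", "ref_in"),
                  function(v) mean(table[[v]]), numeric(1))
  )
  structure(
    list(stats = stats_tbl, marginals = marg, continuous = cont,
         zero_share = mean(table$y == 0),
         n_facilities = nrow(table),
         n_districts = dplyr::n_distinct(table$district)),
    class = "zi_summary"
  )
}

#' @export
print.zi_summary <- function(x, ...) {
  cat("Facility survey summary: ", x$n_facilities, " facilities in ",
      x$n_districts, " districts; ",
      sprintf("%.1f%%", 100 * x$zero_share), " reported zero deaths\n\n",
      sep = "")
  print(x$stats)
  invisible(x)
}
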