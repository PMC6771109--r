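#' Expected counts by indirect age standardisation
#'
#' National age-specific rates are computed from the analysis data itself
#' (internal standardisation), \eqn{r_a = \sum_i y_{ia} / \sum_i n_{ia}},
#' and applied to each area's population:
#' \eqn{E_i = \sum_a n_{ia} r_a}.  By construction \eqn{\sum_i E_i =
#' \sum_i y_i}, so a standardised incidence ratio of 1 is the national
#' average.
#'
#' @param cases data frame with columns `area`, `age_band`, `count`
#'   (observed cases); an optional `sex` column is treated as an extra
#'   stratification dimension.
#' @param population data frame with the same columns giving person-years
#'   at risk.
#' @return data frame with one row per area: `area`, `observed`,
#'   `expected`, plus attribute `rates` (the national age-specific rates)
#'   and `zero_expected` (ids of areas with `E = 0`, to be excluded before
#'   modelling).
#' @export
expected_cases <- function(cases, population) {
  strat_cols <- intersect(c("age_band", "sex"), names(population))
  key <- function(df) interaction(df[strat_cols], drop = FALSE, sep = "|")
  if (!setequal(unique(key(cases)), unique(key(population))))
    stop("cases and population must share the same age bands (and sexes)")
  if (any(population$count < 0)) stop("populations must be non-negative")
  nat_y <- tapply(cases$count, key(cases), sum)
  nat_n <- tapply(population$count, key(population), sum)
  nat_n <- nat_n[names(nat_y)]
  bad <- !is.na(nat_y) & nat_y > 0 & (is.na(nat_n) | nat_n == 0)
  if (any(bad))
    stop("age band with zero national population but nonzero cases: ",
         paste(names(nat_y)[bad], collapse = ", "))
  rates <- ifelse(is.na(nat_n) | nat_n == 0, 0, nat_y / nat_n)
  E <- tapply(population$count * rates[as.character(key(population))],
              population$area, sum)
  y <- tapply(cases$count, cases$area, sum)
  areas <- names(E)
  out <- data.frame(area = areas,
                    observed = as.integer(y[areas]),
                    expected = as.numeric(E[areas]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$observed[is.na(out$observed)] <- 0L
  attr(out, "rates") <- rates
  attr(out, "zero_expected") <- areas[out$expected == 0]
  out
}

# broad survival age groups; 65-74 then 75-89, closed on the left
.surv_age_breaks <- c(15, 55, 65, 75, 90)
.surv_age_labels <- c("15-54", "55-64", "65-74", "75-89")

#' Broad age groups and strata for the survival model
#'
#' `survival_age_group()` maps age at diagnosis to the four broad age
#' groups 15-54, 55-64, 65-74 and 75-89 (intervals closed on the left, so
#' age 55 falls in the second group).  `build_strata()` crosses the age
#' group with sex (all-persons models only) and cancer site (aggregate
#' cancer groups only) to produce the stratum label of each patient.
#' `stratum_table()` enumerates the stratum levels and their indicator
#' design (reference coding, first level as reference).
#'
#' @param age numeric age(s) at diagnosis, in `[15, 89]`.
#' @return `survival_age_group`: factor of age-group labels.
#' @export
survival_age_group <- function(age) {
  if (any(age < 15 | age > 89)) stop("age at diagnosis must be in [15, 89]")
  cut(age, .surv_age_breaks, labels = .surv_age_labels, right = FALSE)
}

#' @rdname survival_age_group
#' @param sex optional sex labels (used only when `persons_model = TRUE`).
#' @param site optional cancer-site labels (aggregate cancer groups).
#' @param persons_model logical; `TRUE` for the all-persons model, where
#'   strata are additionally crossed with sex.
#' @return `build_strata`: factor of stratum labels, one per patient.
#' @export
build_strata <- function(age, sex = NULL, site = NULL, persons_model = FALSE) {
  parts <- list(age = as.character(survival_age_group(age)))
  if (persons_model) {
    if (is.null(sex)) stop("persons_model = TRUE requires sex")
    parts$sex <- as.character(sex)
  }
  if (!is.null(site)) parts$site <- as.character(site)
  lab <- do.call(paste, c(parts, sep = ":"))
  factor(lab, levels = sort(unique(lab)))
}

#' @rdname survival_age_group
#' @param sexes sex labels for the all-persons model.
#' @param sites site labels for aggregate cancer groups, or `NULL`.
#' @return `stratum_table`: data frame with column `stratum` listing levels.
#' @export
stratum_table <- function(persons_model = FALSE,
                          sexes = c("female", "male"), sites = NULL) {
  parts <- list(age = .surv_age_labels)
  if (persons_model) parts$sex <- sexes
  if (!is.null(sites)) parts$site <- sites
  grid <- rev(expand.grid(rev(parts), stringsAsFactors = FALSE))
  lab <- sort(do.call(paste, c(grid, sep = ":")))
  data.frame(stratum = lab, stringsAsFactors = FALSE)
}

#' Period-method person-time table
#'
#' Each patient contributes to follow-up year `t` (of 1..5) only the
#' overlap of the interval `(diagnosis + t - 1, diagnosis + t]` with the
#' at-risk calendar window, further truncated at death or censoring.
#' Deaths are counted in the cell where the death date falls, provided it
#' lies inside the window and within five years of diagnosis.  Dates are
#' continuous years; the window `c(w0, w1)` is the half-open interval
#' `[w0, w1)`.
#'
#' @param patients data frame with columns `area`, `stratum`, `diagnosis`,
#'   `exit` (death or censoring date) and `status` (1 = death, 0 =
#'   censored), all dates in continuous years.
#' @param window at-risk calendar window `c(start, end_exclusive)`.
#' @param area_ids,strata optional full sets of area ids and stratum
#'   labels, so that zero cells are represented.
#' @return data frame (one row per area x stratum x follow-up year):
#'   `area`, `stratum`, `fu_year`, `deaths`, `person_time`, plus attribute
#'   `slices` holding person-time split by calendar year (for
#'   calendar-year-specific background rates).
#' @export
period_person_time <- function(patients, window = c(2006, 2015),
                               area_ids = NULL, strata = NULL) {
  if (window[2] <= window[1]) stop("empty at-risk window")
  if (any(patients$exit < patients$diagnosis))
    stop("death/censoring before diagnosis")
  if (is.null(area_ids)) area_ids <- sort(unique(as.character(patients$area)))
  if (is.null(strata)) strata <- sort(unique(as.character(patients$stratum)))
  grid <- expand.grid(fu_year = 1:5, stratum = strata, area = area_ids,
                      stringsAsFactors = FALSE)[, c("area", "stratum", "fu_year")]
  cell_id <- function(area, stratum, t) paste(area, stratum, t, sep = "\r")
  grid_key <- cell_id(grid$area, grid$stratum, grid$fu_year)
  a <- as.character(patients$area)
  s <- as.character(patients$stratum)
  dgn <- patients$diagnosis
  ext <- patients$exit
  # follow-up year t contribution: (dgn + t - 1, dgn + t] within the
  # window, truncated at exit — vectorised over patients
  recs <- lapply(1:5, function(t) {
    lo <- pmax(dgn + t - 1, window[1])
    hi <- pmin(dgn + t, window[2], ext)
    keep <- hi > lo
    if (!any(keep)) return(NULL)
    data.frame(area = a[keep], stratum = s[keep], fu_year = t,
               lo = lo[keep], hi = hi[keep], stringsAsFactors = FALSE)
  })
  contrib <- do.call(rbind, recs)
  py <- setNames(numeric(nrow(grid)), grid_key)
  sl <- data.frame(area = character(), stratum = character(),
                   fu_year = integer(), year = integer(),
                   person_time = numeric())
  if (!is.null(contrib) && nrow(contrib)) {
    agg <- tapply(contrib$hi - contrib$lo,
                  cell_id(contrib$area, contrib$stratum, contrib$fu_year), sum)
    py[names(agg)] <- as.numeric(agg)
    # calendar-year slices: an interval of length <= 1 spans <= 2 years
    parts <- lapply(0:1, function(k) {
      yr <- floor(contrib$lo) + k
      ov <- pmin(contrib$hi, yr + 1) - pmax(contrib$lo, yr)
      keep <- ov > 1e-12
      if (!any(keep)) return(NULL)
      data.frame(area = contrib$area[keep], stratum = contrib$stratum[keep],
                 fu_year = contrib$fu_year[keep], year = yr[keep],
                 person_time = ov[keep], stringsAsFactors = FALSE)
    })
    sl0 <- do.call(rbind, parts)
    if (!is.null(sl0)) {
      skey <- paste(sl0$area, sl0$stratum, sl0$fu_year, sl0$year, sep = "\r")
      sagg <- tapply(sl0$person_time, skey, sum)
      sparts <- do.call(rbind, strsplit(names(sagg), "\r", fixed = TRUE))
      sl <- data.frame(area = sparts[, 1], stratum = sparts[, 2],
                       fu_year = as.integer(sparts[, 3]),
                       year = as.integer(sparts[, 4]),
                       person_time = as.numeric(sagg),
                       stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  deaths <- setNames(numeric(nrow(grid)), grid_key)
  dead <- patients$status == 1 & ext >= window[1] & ext < window[2] &
    ext > dgn & ext - dgn <= 5
  if (any(dead)) {
    dk <- cell_id(a[dead], s[dead], ceiling((ext - dgn)[dead]))
    dt <- table(dk)
    deaths[names(dt)] <- as.numeric(dt)
  }
  out <- cbind(grid, deaths = as.integer(deaths), person_time = as.numeric(py))
  attr(out, "slices") <- sl
  attr(out, "window") <- window
  out
}

#' Attach expected other-cause deaths to a survival table
#'
#' \eqn{d^*_{itk}} is the sum over the cell's person-time slices of
#' background (other-cause) mortality rate times time at risk.
#'
#' @param table a survival table from [period_person_time()].
#' @param rates either a named numeric vector of rates by stratum, or a
#'   data frame with columns `stratum`, `rate` and optionally `year` (rates
#'   per calendar year, applied to the per-year person-time slices).
#' @return the table with an `expected_deaths` column.
#' @export
attach_expected_deaths <- function(table, rates) {
  if (is.data.frame(rates) && "year" %in% names(rates)) {
    sl <- attr(table, "slices")
    if (is.null(sl)) stop("table lacks calendar-year slices")
    m <- match(paste(sl$stratum, sl$year), paste(rates$stratum, rates$year))
    if (anyNA(m)) stop("missing background rate for some stratum/year")
    sl$d <- sl$person_time * rates$rate[m]
    key <- paste(sl$area, sl$stratum, sl$fu_year)
    agg <- tapply(sl$d, key, sum)
    tk <- paste(table$area, table$stratum, table$fu_year)
    table$expected_deaths <- as.numeric(agg[tk])
    table$expected_deaths[is.na(table$expected_deaths)] <- 0
  } else {
    if (is.data.frame(rates)) rates <- setNames(rates$rate, rates$stratum)
    m <- match(as.character(table$stratum), names(rates))
    if (anyNA(m)) stop("missing background rate for some stratum")
    table$expected_deaths <- table$person_time * as.numeric(rates[m])
  }
  table
}
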