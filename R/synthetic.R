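#' Configuration for the synthetic registry generator
#'
#' The generator emulates the restricted inputs of a national small-area
#' cancer mapping study: a lattice geography with a few off-shore islands,
#' age-structured populations, Poisson case counts driven by a known Leroux
#' spatial field, and a period-method survival cohort with known excess
#' hazards and background mortality.  Defaults give a 20 x 20 grid plus two
#' islands (402 areas), a scale at which full MCMC runs in minutes.
#'
#' @param grid_rows,grid_cols lattice dimensions (rook adjacency).
#' @param n_islands number of isolated areas appended after the lattice.
#' @param rho_true spatial autocorrelation of the true Leroux field, in
#'   `[0, 1)`.
#' @param sigma2_true marginal-scale variance of the true field (> 0).
#' @param beta0_true overall log-SIR level.
#' @param age_bands ordered age-group labels (ABS-style 5-year bands to 85+).
#' @param baseline_rates per-age-band incidence rates (cases per
#'   person-year), recycled across bands; all > 0.
#' @param pop_range integer range of residents per area x age band; minimum
#'   at least 5 (areas with fewer than five average residents are excluded
#'   upstream).
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(grid_rows = 20, grid_cols = 20, n_islands = 2,
                             rho_true = 0.8, sigma2_true = 0.2,
                             beta0_true = 0,
                             age_bands = default_age_bands(),
                             baseline_rates = default_baseline_rates(age_bands),
                             pop_range = c(50, 400),
                             seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_islands >= 0,
            rho_true >= 0, rho_true <= 1, sigma2_true > 0,
            length(pop_range) == 2, pop_range[1] >= 5,
            pop_range[1] <= pop_range[2],
            all(baseline_rates > 0))
  baseline_rates <- rep_len(baseline_rates, length(age_bands))
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 n_islands = n_islands, rho_true = rho_true,
                 sigma2_true = sigma2_true, beta0_true = beta0_true,
                 age_bands = age_bands,
                 baseline_rates = setNames(baseline_rates, age_bands),
                 pop_range = pop_range, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_age_bands <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

# Incidence rising roughly log-linearly with age: realistic for most adult
# cancers, spanning ~1e-5 (children) to ~1e-2 (85+) cases per person-year.
#' @rdname synthetic_config
#' @param age_bands ordered age-band labels.
#' @export
default_baseline_rates <- function(age_bands) {
  k <- length(age_bands)
  exp(seq(log(1e-5), log(8e-3), length.out = k))
}

#' Generate a lattice geography with optional islands
#'
#' Rook-adjacency `grid_rows x grid_cols` lattice plus `n_islands` isolated
#' areas.  Centroids sit on the integer grid; islands are offset to the
#' right of the lattice.  Stands in for a national small-area geography.
#'
#' @param config a [synthetic_config()].
#' @return an [area_graph] (islands not yet repaired).
#' @export
generate_lattice_geography <- function(config) {
  r <- config$grid_rows; cc <- config$grid_cols
  if (r < 1 || cc < 1) stop("grid dimensions must be positive")
  n <- r * cc
  ids <- sprintf("A%04d", seq_len(n + config$n_islands))
  row_i <- rep(seq_len(r), each = cc)
  col_i <- rep(seq_len(cc), times = r)
  ii <- integer(0); jj <- integer(0)
  idx <- function(ri, ci) (ri - 1L) * cc + ci
  for (ri in seq_len(r)) {
    for (ci in seq_len(cc)) {
      a <- idx(ri, ci)
      if (ci < cc) { ii <- c(ii, a); jj <- c(jj, idx(ri, ci + 1L)) }
      if (ri < r)  { ii <- c(ii, a); jj <- c(jj, idx(ri + 1L, ci)) }
    }
  }
  ntot <- n + config$n_islands
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(ntot, ntot))
  cent <- cbind(c(col_i, cc + 3 + seq_len(config$n_islands) * 2),
                c(row_i, rep(1, config$n_islands)))
  area_graph(ids, W, cent)
}

#' Draw one exact sample of a Leroux Gaussian Markov random field
#'
#' Samples the joint zero-mean multivariate normal with precision
#' \eqn{Q = [\rho (D - W) + (1 - \rho) I] / \sigma^2} by solving the upper
#' Cholesky factor of `Q` against a standard-normal vector.  At `rho = 1`
#' the joint precision is rank-deficient (intrinsic CAR) and the draw is
#' refused.
#'
#' @param graph an [area_graph].
#' @param rho spatial autocorrelation in `[0, 1)`.
#' @param sigma2 conditional variance scale (> 0).
#' @param seed integer seed; same seed gives an identical draw.
#' @param n_draws number of independent draws; the Cholesky factor is
#'   computed once.
#' @return numeric vector of field values (one per area), or an
#'   `n_draws` x n matrix when `n_draws > 1`.
#' @export
simulate_leroux_field <- function(graph, rho, sigma2, seed = NULL,
                                  n_draws = 1) {
  stopifnot(rho >= 0, rho <= 1, sigma2 > 0, n_draws >= 1)
  if (rho == 1)
    stop("rho = 1 makes the joint Leroux precision singular (intrinsic CAR); ",
         "use rho < 1")
  Q <- leroux_precision(graph, rho, sigma2)
  R <- chol(as.matrix(Q))
  if (!is.null(seed)) set.seed(seed)
  n <- length(graph$area_ids)
  Z <- matrix(rnorm(n * n_draws), nrow = n)
  X <- backsolve(R, Z)
  if (n_draws == 1) as.numeric(X) else t(X)
}

#' Simulate Poisson incidence counts from a spatial field
#'
#' \eqn{y_i \sim Poisson(E_i e^{\beta_0 + S_i})}, independent given the
#' field.
#'
#' @param E per-area expected counts (> 0).
#' @param beta0 overall log-SIR level.
#' @param S per-area spatial field.
#' @param seed integer seed.
#' @return integer vector of counts.
#' @export
simulate_incidence_counts <- function(E, beta0, S, seed = NULL) {
  if (any(E <= 0)) stop("expected counts E must be positive")
  stopifnot(length(E) == length(S))
  if (!is.null(seed)) set.seed(seed)
  rpois(length(E), E * exp(beta0 + S))
}

#' Simulate a period-method survival cohort with known truth
#'
#' Patients are assigned uniformly to areas and strata with diagnosis dates
#' spread over `diagnosis_range`; person-time is accrued through
#' [period_person_time()] restricted to the at-risk window, and cell-level
#' death counts are drawn as
#' \eqn{d_{itk} \sim Poisson(d^*_{itk} + y_{itk} e^{\alpha_t + x'\beta + S_i})}
#' with \eqn{d^*_{itk}} = background rate x person-time.
#'
#' @param graph an [area_graph] (repaired).
#' @param strata data frame describing strata, with column `stratum`
#'   (labels) — e.g. from [stratum_table()].
#' @param S_true per-area excess-hazard field.
#' @param alpha_true length-5 follow-up-year log baseline excess hazards.
#' @param beta_true stratum coefficients (length `nlevels - 1`, reference
#'   coding; 0s if omitted).
#' @param background_rate scalar or per-stratum other-cause mortality rate
#'   (> 0, deaths per person-year).
#' @param window closed at-risk calendar window as `c(start, end_exclusive)`
#'   in continuous years.
#' @param n_patients cohort size.
#' @param diagnosis_range continuous-year range of diagnosis dates.
#' @param seed integer seed.
#' @return list with `table` (a survival table data frame: `area`,
#'   `stratum`, `fu_year`, `deaths`, `person_time`, `expected_deaths`),
#'   `patients`, and `truth` (alpha, beta, S, background_rate).
#' @export
simulate_survival_cohort <- function(graph, strata, S_true,
                                     alpha_true = rep(log(0.08), 5),
                                     beta_true = NULL,
                                     background_rate = 0.01,
                                     window = c(2006, 2015),
                                     n_patients = 5000,
                                     diagnosis_range = c(2001, 2014.99),
                                     seed = 1L) {
  if (window[2] <= window[1]) stop("empty at-risk window")
  if (any(background_rate <= 0)) stop("background rates must be positive")
  n_area <- length(graph$area_ids)
  stopifnot(length(S_true) == n_area, length(alpha_true) == 5)
  lev <- as.character(strata$stratum)
  K <- length(lev)
  if (is.null(beta_true)) beta_true <- rep(0, max(K - 1, 0))
  stopifnot(length(beta_true) == max(K - 1, 0))
  set.seed(seed)
  patients <- data.frame(
    id = seq_len(n_patients),
    area = graph$area_ids[sample.int(n_area, n_patients, replace = TRUE)],
    stratum = lev[sample.int(K, n_patients, replace = TRUE)],
    diagnosis = runif(n_patients, diagnosis_range[1], diagnosis_range[2]),
    stringsAsFactors = FALSE
  )
  # all patients censored at window end: deaths are injected at cell level
  patients$exit <- window[2]
  patients$status <- 0L
  skel <- period_person_time(patients, window = window,
                             area_ids = graph$area_ids, strata = lev)
  rates <- if (length(background_rate) == 1) {
    setNames(rep(background_rate, K), lev)
  } else setNames(background_rate, lev)
  tab <- attach_expected_deaths(skel, rates)
  lp <- alpha_true[tab$fu_year] +
    ifelse(match(tab$stratum, lev) > 1,
           c(0, beta_true)[match(tab$stratum, lev)], 0) +
    S_true[match(tab$area, graph$area_ids)]
  mu <- tab$expected_deaths + tab$person_time * exp(lp)
  tab$deaths <- rpois(nrow(tab), mu)
  tab$deaths[tab$person_time == 0] <- 0L
  list(table = tab, patients = patients,
       truth = list(alpha = alpha_true, beta = beta_true, S = S_true,
                    background_rate = rates))
}

#' Generate an exclusion-filter fixture
#'
#' A registry of `total` area records carrying exactly the requested
#' mutually-exclusive exclusion flags, for exercising the small-area
#' exclusion filters.
#'
#' @param total number of records.
#' @param flag_counts named integer vector, e.g.
#'   `c(no_population = 28, no_location = 18, under_5_residents = 17,
#'   remote_island = 3)`.
#' @return data frame with columns `id` and `flag` (`""` = retained).
#' @export
generate_exclusion_fixture <- function(total,
                                       flag_counts = c(no_population = 28,
                                                       no_location = 18,
                                                       under_5_residents = 17,
                                                       remote_island = 3)) {
  flag_counts <- flag_counts[flag_counts > 0]
  if (sum(flag_counts) > total) stop("flag counts exceed total records")
  flag <- c(rep(names(flag_counts), times = flag_counts),
            rep("", total - sum(flag_counts)))
  data.frame(id = sprintf("SA%04d", seq_len(total)), flag = flag,
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic input bundle
#'
#' Runs the generator end to end: geography (with island repair), a true
#' Leroux field, age-structured populations, age-specific case counts whose
#' area-level totals follow the field, and a survival cohort.  Writes the
#' plain-text artifacts consumed by the pipeline when `dir` is given.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory for `areas.csv`, `edges.csv`,
#'   `population.csv`, `cases.csv`, `survival.csv`, `truth.json`.
#' @return list with `graph`, `population`, `cases`, `incidence`
#'   (observed/expected per area), `survival` (cohort list), and `truth`.
#' @export
generate_synthetic_inputs <- function(config = synthetic_config(), dir = NULL) {
  set.seed(config$seed)
  graph0 <- generate_lattice_geography(config)
  graph <- repair_islands(graph0)
  n <- length(graph$area_ids)
  S <- simulate_leroux_field(graph, config$rho_true, config$sigma2_true,
                             seed = config$seed + 1L)
  ab <- config$age_bands
  pop <- expand.grid(area = graph$area_ids, age_band = ab,
                     stringsAsFactors = FALSE)
  pop$count <- sample(seq(config$pop_range[1], config$pop_range[2]),
                      nrow(pop), replace = TRUE)
  # age-specific Poisson counts; the area-level SIR surface follows the field
  lam <- pop$count * config$baseline_rates[pop$age_band] *
    exp(config$beta0_true + S[match(pop$area, graph$area_ids)])
  cases <- pop
  cases$count <- rpois(nrow(pop), lam)
  inc <- expected_cases(cases, pop)
  strata <- stratum_table(persons_model = FALSE)
  surv <- simulate_survival_cohort(graph, strata, S_true = S,
                                   seed = config$seed + 2L)
  out <- list(graph = graph, population = pop, cases = cases,
              incidence = inc, survival = surv,
              truth = list(rho = config$rho_true, sigma2 = config$sigma2_true,
                           beta0 = config$beta0_true, S = S,
                           alpha = surv$truth$alpha, beta = surv$truth$beta))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    areas <- data.frame(id = graph$area_ids,
                        centroid_x = graph$centroids[, 1],
                        centroid_y = graph$centroids[, 2], flag = "")
    write.csv(areas, file.path(dir, "areas.csv"), row.names = FALSE)
    write_edges(graph, file.path(dir, "edges.csv"))
    write.csv(pop, file.path(dir, "population.csv"), row.names = FALSE)
    write.csv(cases, file.path(dir, "cases.csv"), row.names = FALSE)
    write.csv(surv$table, file.path(dir, "survival.csv"), row.names = FALSE)
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
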