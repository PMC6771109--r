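test_that("survival mean inverts the excess-hazard link", {
  params <- list(alpha = rep(0, 5), beta = numeric(0), S = 0)
  expect_equal(survival_mean(list(person_time = 0, expected_deaths = 2,
                                  fu_year = 1), params), 2)
  expect_equal(survival_mean(list(person_time = 100, expected_deaths = 2,
                                  fu_year = 1), params), 102)
  p2 <- list(alpha = c(log(0.05), 0, 0, 0, 0), beta = numeric(0), S = 0)
  expect_equal(survival_mean(list(person_time = 200, expected_deaths = 1,
                                  fu_year = 1), p2), 11)
  # mu > d* whenever person-time is positive
  expect_gt(survival_mean(list(person_time = 1e-6, expected_deaths = 2,
                               fu_year = 1), params), 2)
})

make_flat_cohort <- function(n_area = 9, py = 400, h = 0.08, seed = 17) {
  g <- generate_lattice_geography(synthetic_config(sqrt(n_area), sqrt(n_area),
                                                   n_islands = 0))
  tab <- expand.grid(area = g$area_ids, stratum = c("s1", "s2"),
                     fu_year = 1:5, stringsAsFactors = FALSE)
  tab$person_time <- py
  tab$expected_deaths <- 0.01 * py
  set.seed(seed)
  tab$deaths <- rpois(nrow(tab), tab$expected_deaths + py * h)
  list(graph = g, table = tab)
}

test_that("no spatial excess gives EHR medians near 1 and centred S", {
  fc <- make_flat_cohort()
  fit <- fit_survival(fc$table, fc$graph, quick_mcmc(seed = 8))
  med <- apply(ehr_draws(fit), 2, median)
  expect_true(all(abs(med - 1) < 0.1))
  # the gauge move keeps the S mean softly centred at zero
  Smat <- fit$draws[, grep("^S\\[", colnames(fit$draws))]
  expect_lt(abs(mean(rowMeans(Smat))), 0.05)
})

test_that("single-cell reduction matches 1-D quadrature", {
  g <- area_graph("only", matrix(0, 1, 1), cbind(0, 0))
  tab <- data.frame(area = "only", stratum = "s", fu_year = 1,
                    deaths = 12L, person_time = 100,
                    expected_deaths = 2)
  fit <- fit_survival(tab, g, mcmc_config(burn_in = 4000, iterations = 16000,
                                          thin = 4, seed = 3))
  chain <- exp(fit$draws[, "alpha[1]"])
  oracle <- survival1_post_mean_exp(12, 100, 2, v = 1000)
  expect_lt(abs(mean(chain) - oracle), 3 * mcse(chain) + 1e-4)
})

test_that("with d* = 0 the model collapses to the incidence sampler", {
  set.seed(23)
  g <- chain_graph(12)
  y <- rpois(12, 60)
  E <- rep(60, 12)
  inc <- data.frame(area = g$area_ids, observed = y, expected = E)
  tab <- data.frame(area = g$area_ids, stratum = "s", fu_year = 1,
                    deaths = y, person_time = E, expected_deaths = 0)
  cfg_inc <- mcmc_config(burn_in = 4000, iterations = 20000, thin = 5,
                         seed = 5, intercept_prior_var = 1000,
                         variance_prior = list(family = "half_normal",
                                               variance = 5))
  cfg_srv <- mcmc_config(burn_in = 4000, iterations = 20000, thin = 5,
                         seed = 7)
  fi <- fit_incidence(inc, g, cfg_inc)
  fs <- fit_survival(tab, g, cfg_srv)
  for (i in c(1, 6, 12)) {
    ci <- fi$draws[, "beta0"] + fi$draws[, paste0("S[", g$area_ids[i], "]")]
    cs <- fs$draws[, "alpha[1]"] + fs$draws[, paste0("S[", g$area_ids[i], "]")]
    expect_lt(abs(mean(ci) - mean(cs)), 3 * sqrt(mcse(ci)^2 + mcse(cs)^2))
  }
})

test_that("survival fit refuses degenerate inputs", {
  fc <- make_flat_cohort()
  bad <- fc$table
  bad$person_time[bad$stratum == "s2"] <- 0
  bad$deaths[bad$stratum == "s2"] <- 0L
  expect_error(fit_survival(bad, fc$graph, quick_mcmc()), "zero total person-time")
  bad2 <- fc$table
  bad2$person_time[1] <- 0
  expect_error(fit_survival(bad2, fc$graph, quick_mcmc()),
               "zero person-time but positive deaths")
})

test_that("EHR draws are exp(S)", {
  fc <- make_flat_cohort(n_area = 4)
  fit <- fit_survival(fc$table, fc$graph,
                      mcmc_config(burn_in = 200, iterations = 400, thin = 4,
                                  seed = 2))
  S <- fit$draws[, paste0("S[", fc$graph$area_ids, "]")]
  expect_equal(unname(ehr_draws(fit)), unname(exp(S)))
})
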