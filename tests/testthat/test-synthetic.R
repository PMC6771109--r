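test_that("lattice geography has rook adjacency plus isolated islands", {
  g22 <- generate_lattice_geography(synthetic_config(2, 2, n_islands = 0))
  expect_length(g22, 4)
  expect_equal(unname(g22$neighbour_counts), rep(2, 4))

  g11 <- generate_lattice_geography(synthetic_config(1, 1, n_islands = 1))
  expect_length(g11, 2)
  expect_equal(unname(g11$neighbour_counts), c(0, 0))

  g33 <- generate_lattice_geography(synthetic_config(3, 3, n_islands = 0))
  deg <- unname(g33$neighbour_counts)
  expect_equal(deg[5], 4)                      # centre
  expect_equal(deg[c(1, 3, 7, 9)], rep(2, 4))  # corners

  expect_error(synthetic_config(0, 3), "grid_rows")
  # adjacency is symmetric with zero diagonal on every construction
  for (g in list(g22, g33)) {
    expect_true(Matrix::isSymmetric(g$W))
    expect_true(all(Matrix::diag(g$W) == 0))
  }
})

test_that("Leroux field sampling matches analytic moments", {
  # 2-area graph, one edge: precision [[1,-0.5],[-0.5,1]] at rho = 0.5,
  # sigma2 = 1 inverts to covariance [[4/3, 2/3], [2/3, 4/3]]
  g2 <- chain_graph(2)
  expect_equal(as.matrix(leroux_cov_dense(g2, 0.5, 1)),
               matrix(c(4, 2, 2, 4) / 3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(42)
  X <- field_draws(g2, 0.5, 1, 50000)
  emp <- cov(X)
  expect_lt(max(abs(emp - matrix(c(4, 2, 2, 4) / 3, 2))), 0.02)
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.5), 0.02)
})

test_that("rho = 0 gives i.i.d. normals", {
  g <- generate_lattice_geography(synthetic_config(2, 2, n_islands = 0))
  set.seed(7)
  X <- field_draws(g, 0, 2.25, 2500)   # 10,000 values, sd 1.5
  cors <- cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  ks <- stats::ks.test(as.numeric(X), "pnorm", sd = 1.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("field draws are reproducible and refuse a singular precision", {
  g <- chain_graph(4)
  expect_identical(simulate_leroux_field(g, 0.7, 0.5, seed = 11),
                   simulate_leroux_field(g, 0.7, 0.5, seed = 11))
  expect_error(simulate_leroux_field(g, 1, 0.5, seed = 1), "singular")
})

test_that("incidence count simulator follows its Poisson law", {
  set.seed(5)
  y <- simulate_incidence_counts(rep(1000, 200), 0, rep(0, 200))
  expect_lt(abs(mean(y / 1000) - 1), 0.02)
  y2 <- simulate_incidence_counts(rep(500, 400), log(2), rep(0, 400))
  expect_lt(abs(mean(y2) - 1000), 3 * sqrt(1000 / 400))
  expect_error(simulate_incidence_counts(c(1, 0), 0, c(0, 0)), "positive")
})

test_that("exclusion fixture honours requested flag counts", {
  fx <- generate_exclusion_fixture(2214)
  expect_equal(nrow(fx), 2214)
  expect_equal(sum(fx$flag != ""), 66)
  expect_equal(nrow(generate_exclusion_fixture(10, c(a = 0))), 10)
  expect_true(all(generate_exclusion_fixture(10, c(a = 0))$flag == ""))
  expect_error(generate_exclusion_fixture(10, c(a = 6, b = 5)), "exceed")
})

test_that("survival cohort simulator matches its stated cell-level law", {
  g <- generate_lattice_geography(synthetic_config(4, 4, n_islands = 0))
  strata <- stratum_table()
  h <- 0.05
  coh <- simulate_survival_cohort(g, strata, S_true = rep(0, 16),
                                  alpha_true = rep(log(h), 5),
                                  background_rate = 0.02,
                                  n_patients = 30000, seed = 3)
  tab <- coh$table
  # realised excess deaths per unit person-time close to h overall
  excess_rate <- sum(tab$deaths - tab$expected_deaths) / sum(tab$person_time)
  expect_lt(abs(excess_rate - h), 3 * sqrt(sum(tab$deaths)) /
              sum(tab$person_time))
  # d* = rate x person-time exactly
  expect_equal(tab$expected_deaths, 0.02 * tab$person_time)
  # zero person-time cells have zero deaths
  expect_true(all(tab$deaths[tab$person_time == 0] == 0))
})

test_that("cohort person-time equals an independent interval oracle", {
  g <- generate_lattice_geography(synthetic_config(2, 2, n_islands = 0))
  strata <- data.frame(stratum = "15-54")
  coh <- simulate_survival_cohort(g, strata, S_true = rep(0, 4),
                                  n_patients = 150, seed = 13)
  oracle <- person_time_oracle(coh$patients, c(2006, 2015))
  expect_lt(abs(sum(coh$table$person_time) - oracle),
            nrow(coh$patients) / 365)
  # patients diagnosed after the window end contribute nothing
  late <- coh$patients[coh$patients$diagnosis >= 2015, ]
  expect_equal(nrow(late), 0)  # generator keeps diagnoses before window end
})

test_that("generated bundle is internally consistent and reproducible", {
  cfg <- synthetic_config(grid_rows = 4, grid_cols = 4, n_islands = 1,
                          seed = 21)
  syn1 <- generate_synthetic_inputs(cfg)
  syn2 <- generate_synthetic_inputs(cfg)
  expect_identical(syn1$truth, syn2$truth)
  expect_identical(syn1$incidence, syn2$incidence)
  expect_equal(sum(syn1$incidence$expected), sum(syn1$incidence$observed),
               tolerance = 1e-9)
  expect_true(all(syn1$graph$neighbour_counts > 0))  # islands repaired
})
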