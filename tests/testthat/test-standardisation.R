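test_that("expected cases follow internal indirect standardisation", {
  cases <- data.frame(area = rep(c("a", "b"), each = 2),
                      age_band = rep(c("y", "o"), 2),
                      count = c(2, 0, 0, 2))
  pop <- data.frame(area = rep(c("a", "b"), each = 2),
                    age_band = rep(c("y", "o"), 2),
                    count = rep(100, 4))
  inc <- expected_cases(cases, pop)
  expect_equal(as.numeric(attr(inc, "rates")), c(0.01, 0.01))
  expect_equal(inc$expected, c(2, 2))
  expect_equal(inc$observed, c(2, 2))
})

test_that("identical age structures give E proportional to population, and
           the standardisation identity holds on random inputs", {
  set.seed(9)
  for (rep in 1:5) {
    n_area <- sample(3:8, 1); n_age <- sample(2:5, 1)
    pop <- expand.grid(area = paste0("z", seq_len(n_area)),
                       age_band = paste0("g", seq_len(n_age)),
                       stringsAsFactors = FALSE)
    pop$count <- sample(50:500, nrow(pop), replace = TRUE)
    cases <- pop
    cases$count <- rpois(nrow(pop), 0.02 * pop$count)
    inc <- expected_cases(cases, pop)
    expect_equal(sum(inc$expected), sum(inc$observed), tolerance = 1e-9)
  }
  # identical age structure across areas
  pop <- expand.grid(area = c("a", "b"), age_band = c("y", "o"),
                     stringsAsFactors = FALSE)
  pop$count <- c(100, 300, 100, 300)  # b = 3x a in every band
  cases <- pop; cases$count <- c(1, 3, 1, 3)
  inc <- expected_cases(cases, pop)
  expect_equal(inc$expected[inc$area == "b"] / inc$expected[inc$area == "a"],
               3)
  # zero national population with cases is an error
  bad_pop <- pop; bad_pop$count[bad_pop$age_band == "o"] <- 0
  expect_error(expected_cases(cases, bad_pop), "zero national population")
})

test_that("broad survival age groups use closed-left boundaries", {
  expect_equal(as.character(survival_age_group(c(54, 55, 60, 74, 75, 89))),
               c("15-54", "55-64", "55-64", "65-74", "75-89", "75-89"))
  expect_error(survival_age_group(90), "15, 89")
  expect_error(survival_age_group(14), "15, 89")
  # sex enters only for the all-persons model
  s1 <- build_strata(60, sex = "female", persons_model = FALSE)
  expect_equal(as.character(s1), "55-64")
  s2 <- build_strata(60, sex = "female", persons_model = TRUE)
  expect_equal(as.character(s2), "55-64:female")
  expect_error(build_strata(60, persons_model = TRUE), "requires sex")
  # stratum levels are exhaustive and mutually exclusive
  tt <- stratum_table(persons_model = TRUE)
  expect_equal(nrow(tt), 8)
  expect_false(anyDuplicated(tt$stratum) > 0)
})

test_that("period person-time splits follow-up years across the window", {
  pats <- data.frame(area = "a", stratum = "s",
                     diagnosis = c(2005.0, 2014.9, 2001.0),
                     exit = c(2007.5, 2016, 2016),
                     status = c(1L, 0L, 0L))
  tab <- period_person_time(pats, window = c(2006, 2015))
  cell <- function(t) tab[tab$fu_year == t, ]
  # patient 1: t2 fully inside (1.0), t3 half then death
  # patient 2: 0.1 person-years in t1
  # patient 3: every follow-up year before the window start
  expect_equal(cell(1)$person_time, 0.1, tolerance = 1e-9)
  expect_equal(cell(2)$person_time, 1.0, tolerance = 1e-9)
  expect_equal(cell(3)$person_time, 0.5, tolerance = 1e-9)
  expect_equal(cell(3)$deaths, 1L)
  expect_equal(sum(tab$deaths), 1L)
  expect_error(period_person_time(data.frame(area = "a", stratum = "s",
                                             diagnosis = 2010, exit = 2009,
                                             status = 1L)),
               "before diagnosis")
  expect_error(period_person_time(pats, window = c(2010, 2010)), "empty")
})

test_that("person-time agrees with a per-day discretised oracle", {
  set.seed(31)
  n <- 40
  pats <- data.frame(area = sample(c("a", "b"), n, TRUE),
                     stratum = sample(c("s1", "s2"), n, TRUE),
                     diagnosis = runif(n, 2001, 2014.9))
  pats$exit <- pats$diagnosis + rexp(n, 1 / 4)
  pats$status <- rbinom(n, 1, 0.5)
  tab <- period_person_time(pats, window = c(2006, 2015))
  expect_lt(abs(sum(tab$person_time) -
                  person_time_oracle(pats, c(2006, 2015))), n / 365)
})

test_that("expected other-cause deaths are rate x person-time", {
  tab <- data.frame(area = "a", stratum = "s", fu_year = 1:2,
                    deaths = c(0L, 0L), person_time = c(100, 0))
  out <- attach_expected_deaths(tab, c(s = 0.01))
  expect_equal(out$expected_deaths, c(1, 0))
  # two calendar-year slices with different rates: 0.01 x 50 + 0.02 x 25
  pats <- data.frame(area = "a", stratum = "s",
                     diagnosis = 2010.5, exit = 2011.25, status = 0L)
  tab2 <- period_person_time(pats, window = c(2006, 2015))
  rates <- data.frame(stratum = "s", year = c(2010, 2011),
                      rate = c(0.01, 0.02))
  out2 <- attach_expected_deaths(tab2, rates)
  expect_equal(sum(out2$expected_deaths), 0.01 * 0.5 + 0.02 * 0.25,
               tolerance = 1e-9)
  expect_error(attach_expected_deaths(tab, c(wrong = 0.01)), "missing")
})
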