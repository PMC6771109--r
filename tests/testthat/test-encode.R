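test_that("colour positions hit the published anchors", {
  expect_equal(colour_position(1), 0.5)
  expect_equal(colour_position(1.5), 1)
  expect_equal(colour_position(1 / 1.5), 0)
  expect_equal(round(1 / 1.5, 2), 0.67)
  expect_equal(colour_position(sqrt(1.5)), 0.75)
  # clamped beyond the anchors
  expect_equal(colour_position(3), 1)
  expect_equal(colour_position(0.1), 0)
  expect_error(colour_position(0), "positive")
})

test_that("colour position is log-symmetric about 1 (property)", {
  set.seed(2)
  v <- exp(runif(50, log(1 / 1.5), log(1.5)))
  expect_equal(colour_position(v) + colour_position(1 / v), rep(1, 50))
  # yellow midpoint maps to the middle stop colour
  expect_equal(atlas_colour(1), atlas_colour(1.0000001))
})

test_that("mask opacity interpolates the printed endpoints linearly", {
  expect_equal(opacity_percent(1), 0)
  expect_equal(opacity_percent(0), 100)
  expect_equal(opacity_percent(0.5), 50)
  d <- seq(0, 1, 0.1)
  expect_true(all(diff(opacity_percent(d)) < 0))
  expect_error(opacity_percent(1.2), "\\[0, 1\\]")
})

test_that("V-plot pairs estimates with their DPP", {
  set.seed(10)
  draws <- cbind(up = exp(rnorm(500, 0.5, 0.1)),
                 flat = c(rep(0.9, 250), rep(1.1, 250)))
  est <- atlas_estimates(draws, geweke = FALSE)
  vp <- vplot_data(est)
  expect_equal(nrow(vp), 2)
  expect_equal(vp$dpp[vp$area == "up"], 1)      # all draws above 1
  expect_equal(vp$dpp[vp$area == "flat"], 0)    # pp_high = 0.5
  expect_equal(vp$estimate, est$point)
})

test_that("wave plots are log-scale densities with shared CrI bounds", {
  set.seed(11)
  x <- exp(rnorm(5000, 0.2, 0.3))
  wp <- waveplot_data(x)
  # integrates to ~1 on the log axis
  area <- sum(diff(wp$x) * (head(wp$density, -1) + tail(wp$density, -1)) / 2)
  expect_lt(abs(area - 1), 1e-3)
  # symmetric about the log-median for lognormal draws
  med <- median(log(x))
  mode_x <- wp$x[which.max(wp$density)]
  expect_lt(abs(mode_x - med), 0.05)
  s <- summarise_draws(x)
  expect_equal(wp$cri60, s$cri60)
  expect_equal(wp$cri80, s$cri80)
  expect_error(waveplot_data(rep(2, 500)), "degenerate")
  expect_error(waveplot_data(x[1:50]), "100")
})

test_that("regional summaries partition areas and sum to 100%", {
  set.seed(13)
  est <- data.frame(area = sprintf("R%02d", 1:40),
                    point = c(exp(rnorm(20, -0.3, 0.1)),
                              exp(rnorm(20, 0.3, 0.1))),
                    dpp = runif(40))
  grouping <- data.frame(area = est$area,
                         group = rep(c("low", "high"), each = 20))
  rs <- region_summary(est, grouping)
  expect_lt(rs$boxstats$median[rs$boxstats$group == "low"],
            rs$boxstats$median[rs$boxstats$group == "high"])
  expect_equal(unname(rowSums(rs$band_percent)), c(100, 100))
  # single group: median equals overall median
  rs1 <- region_summary(est, data.frame(area = est$area, group = "all"))
  expect_equal(rs1$boxstats$median, median(est$point))
  expect_error(region_summary(est, grouping[-1, ]), "unassigned")
})

test_that("GeoJSON carries estimate, colour and opacity properties", {
  g <- generate_lattice_geography(synthetic_config(2, 2, n_islands = 0))
  est <- data.frame(area = g$area_ids, point = c(0.8, 1, 1.2, 1.5),
                    dpp = c(0.2, 0, 0.9, 1))
  f <- tempfile(fileext = ".geojson")
  encode_geojson(est, lattice_polygons(g), f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 4)
  pr <- gj$features[[4]]$properties
  expect_equal(pr$estimate, 1.5)
  expect_equal(pr$colour_position, 1)
  expect_equal(pr$opacity, 0)
  expect_match(pr$colour, "^#[0-9A-Fa-f]{6}")
})
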