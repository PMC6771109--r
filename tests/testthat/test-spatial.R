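unit_square <- function(x, y) {
  rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1), c(x, y))
}

test_that("edge-list adjacency is symmetric, binary, zero-diagonal", {
  g <- build_adjacency(data.frame(id_a = "A", id_b = "B"),
                       area_ids = c("A", "B", "C"))
  W <- as.matrix(g$W)
  expect_equal(W, t(W))
  expect_equal(unname(g$neighbour_counts), c(1, 1, 0))
  expect_error(build_adjacency(data.frame(id_a = "A", id_b = "A")), "self")
  expect_error(area_graph(c("A", "A"), matrix(0, 2, 2)), "duplicate")
})

test_that("2x2 rook lattice has 2 neighbours per area and 4 edges", {
  g <- generate_lattice_geography(synthetic_config(2, 2, n_islands = 0))
  expect_equal(unname(g$neighbour_counts), rep(2, 4))
  expect_equal(n_edges(g), 4L)
})

test_that("polygon adjacency requires positive-length shared boundary", {
  polys <- list(P1 = unit_square(0, 0), P2 = unit_square(1, 0),
                P3 = unit_square(1, 1))   # P3 touches P1 only at a corner
  g <- build_adjacency(polygons = polys)
  W <- as.matrix(g$W)
  expect_equal(W["P1", "P2"], 1)
  expect_equal(W["P2", "P3"], 1)
  expect_equal(W["P1", "P3"], 0)  # corner touch is not adjacency
})

test_that("a wholly enclosed polygon has exactly one neighbour", {
  host <- list(rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3), c(0, 0)),
               rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2), c(1, 1)))  # hole
  enclave <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2), c(1, 1))
  west <- rbind(c(-1, 0), c(0, 0), c(0, 3), c(-1, 3), c(-1, 0))
  g <- build_adjacency(polygons = list(host = host, enclave = enclave,
                                       west = west))
  expect_equal(unname(g$neighbour_counts["enclave"]), 1)
  expect_equal(as.matrix(g$W)["enclave", "host"], 1)
})

test_that("polygon-mode adjacency matches a brute-force segment oracle", {
  cfg <- synthetic_config(3, 4, n_islands = 0)
  g <- generate_lattice_geography(cfg)
  polys <- lattice_polygons(g)
  gp <- build_adjacency(polygons = polys)
  expect_equal(unname(as.matrix(gp$W)),
               unname(lattice_adjacency_oracle(polys)))
  # and agrees with the generator's own rook edges
  expect_equal(unname(as.matrix(gp$W)), unname(as.matrix(g$W)))
})

test_that("island repair links to nearest mainland, honours manual links", {
  cents <- rbind(c(0, 0), c(1, 0), c(5, 0), c(2, 0))
  g <- build_adjacency(data.frame(id_a = "A", id_b = "B"),
                       area_ids = c("A", "B", "C", "D"), centroids = cents)
  # D is an island too: with two islands, nearest *non-island* area applies
  r <- repair_islands(g)
  W <- as.matrix(r$W)
  expect_equal(W["C", "D"], 0)  # islands link to mainland, not each other
  expect_true(all(r$neighbour_counts > 0))
  # C's nearest mainland (degree > 0) area is B at distance 4
  expect_equal(W["C", "A"] + W["C", "B"], 1)
  expect_equal(unname(W["C", "B"]), 1)
  # idempotent
  expect_identical(as.matrix(repair_islands(r)$W), W)
  # manual link overrides nearest
  rm <- repair_islands(g, manual_links = c(C = "A"))
  expect_equal(as.matrix(rm$W)["C", "A"], 1)
  expect_equal(as.matrix(rm$W)["C", "B"], 0)
  # unchanged when no islands
  expect_identical(repair_islands(r), r)
  # all-island graph cannot be repaired
  giso <- build_adjacency(data.frame(id_a = character(), id_b = character()),
                          area_ids = c("X", "Y"),
                          centroids = rbind(c(0, 0), c(1, 1)))
  expect_error(repair_islands(giso), "only of islands")
})

test_that("exclusion filters retain the expected areas", {
  fx <- generate_exclusion_fixture(2214)
  res <- apply_exclusions(fx)
  expect_equal(res$n_retained, 2148)
  expect_equal(res$n_excluded, 66)
  expect_equal(apply_exclusions(generate_exclusion_fixture(10, c(x = 0)))$n_retained, 10)
  allflag <- generate_exclusion_fixture(4, c(no_population = 4))
  expect_equal(apply_exclusions(allflag)$n_retained, 0)
})

test_that("edge CSV round-trips a graph", {
  g <- generate_lattice_geography(synthetic_config(3, 3, n_islands = 0))
  f <- tempfile(fileext = ".csv")
  write_edges(g, f)
  g2 <- build_adjacency(read_edges(f), area_ids = g$area_ids,
                        centroids = g$centroids)
  expect_equal(as.matrix(g2$W), as.matrix(g$W))
})
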