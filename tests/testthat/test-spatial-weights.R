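grid_counts <- function(W) lengths(W$neighbours)

test_that("queen contiguity on small lattices matches known counts", {
  # 2x2 grid: all four squares meet at the centre vertex
  expect_identical(grid_counts(queen_contiguity(make_lattice(2, 2))),
                   rep(3L, 4))
  # 1x3 strip is a chain
  expect_identical(grid_counts(queen_contiguity(make_lattice(1, 3))),
                   c(1L, 2L, 1L))
  # 3x3 grid: corners 3, edges 5, centre 8 (row-major ids)
  expect_identical(grid_counts(queen_contiguity(make_lattice(3, 3))),
                   c(3L, 5L, 3L, 5L, 8L, 5L, 3L, 5L, 3L))
})

test_that("both constructors match brute-force oracles on all small lattices", {
  for (nr in 1:4) {
    for (nc in 1:3) {
      if (nr * nc < 2) next
      areas <- make_lattice(nr, nc, 1)
      expect_identical(unname(as_dense_matrix(queen_contiguity(areas))),
                       matrix(as.numeric(oracle_queen(areas)), nr * nc),
                       label = sprintf("queen %dx%d", nr, nc))
      cen <- t(sapply(areas, `[[`, "centroid"))
      for (band in c(1.0, 1.45, 2.3)) {
        Wd <- suppressWarnings(distance_band(areas, band))
        expect_identical(unname(as_dense_matrix(Wd)),
                         matrix(as.numeric(oracle_distance(cen, band)), nr * nc),
                         label = sprintf("distance %dx%d band %.2f", nr, nc, band))
      }
    }
  }
  # scattered centroids against the O(n^2) oracle
  set.seed(13)
  cen <- cbind(runif(10, 0, 5), runif(10, 0, 5))
  df <- data.frame(area_id = letters[1:10], x_km = cen[, 1], y_km = cen[, 2])
  d <- as.matrix(dist(cen)); diag(d) <- Inf
  band <- 1.5 * mean(apply(d, 1, min))
  Wd <- suppressWarnings(distance_band(df, band))
  expect_identical(unname(as_dense_matrix(Wd)),
                   matrix(as.numeric(oracle_distance(cen, band)), 10))
})

test_that("constructors yield symmetric, zero-diagonal, positive weights", {
  set.seed(21)
  areas <- make_lattice(4, 5, 2)
  for (W in list(queen_contiguity(areas), distance_band(areas, 4.5))) {
    m <- as_dense_matrix(W)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m %in% c(0, 1)))
  }
})

test_that("distance-band neighbourhoods grow monotonically with the band", {
  set.seed(31)
  df <- data.frame(area_id = sprintf("z%02d", 1:15),
                   x_km = runif(15, 0, 10), y_km = runif(15, 0, 10))
  bands <- sort(runif(5, 1, 12))
  prev <- NULL
  for (b in bands) {
    W <- suppressWarnings(distance_band(df, b))
    nb <- lapply(W$neighbours, sort)
    if (!is.null(prev))
      for (j in seq_along(nb)) expect_true(all(prev[[j]] %in% nb[[j]]))
    prev <- nb
  }
})

test_that("min_connecting_band is the max nearest-neighbour distance", {
  line <- data.frame(area_id = c("a", "b", "c"), x_km = c(0, 1, 3), y_km = 0)
  expect_equal(min_connecting_band(line), 2)
  s <- 3.7  # equilateral triangle of side s
  tri <- data.frame(area_id = c("a", "b", "c"),
                    x_km = c(0, s, s / 2), y_km = c(0, 0, s * sqrt(3) / 2))
  expect_equal(min_connecting_band(tri), s)
  set.seed(17)
  df <- data.frame(area_id = sprintf("r%02d", 1:20),
                   x_km = runif(20, 0, 50), y_km = runif(20, 0, 50))
  b <- min_connecting_band(df)
  expect_equal(b, oracle_min_band(cbind(df$x_km, df$y_km)))
  # band b connects everyone; slightly smaller leaves an isolate
  expect_gte(min(lengths(distance_band(df, b)$neighbours)), 1)
  eps <- 1e-6 * b
  expect_warning(W2 <- distance_band(df, b - eps), "isolated")
  expect_identical(min(lengths(W2$neighbours)), 0L)
})

test_that("neighbour summaries report mean/median/min/max/sd of counts", {
  chain <- weight_matrix(letters[1:4], list(2L, c(1L, 3L), c(2L, 4L), 3L))
  s <- neighbour_summary(chain)
  expect_equal(s$mean, 1.5); expect_equal(s$median, 1.5)
  expect_equal(s$min, 1); expect_equal(s$max, 2)
  full <- weight_matrix(letters[1:5],
                        lapply(1:5, function(j) setdiff(1:5, j)))
  s2 <- neighbour_summary(full)
  expect_equal(s2$mean, 4); expect_equal(s2$sd, 0)
  s3 <- neighbour_summary(queen_contiguity(make_lattice(3, 3)))
  expect_equal(s3$mean, 40 / 9, tolerance = 1e-12)
  expect_equal(s3$min, 3); expect_equal(s3$max, 8)
})

test_that("weight_matrix validates symmetry, self-loops and duplicates", {
  expect_error(weight_matrix(c("a", "a"), list(2L, 1L)), "duplicate")
  expect_error(weight_matrix(c("a", "b"), list(2L, integer(0))), "symmetric")
  expect_error(weight_matrix(c("a", "b"), list(c(1L, 2L), 1L)), "self")
  expect_error(queen_contiguity(list(make_lattice(1, 2)[[1]])), "at least 2")
  bad <- area_geometry("x", rbind(c(0, 0), c(1, 0), c(0, 0), c(0, 0)))
  expect_error(queen_contiguity(list(bad, make_lattice(1, 2)[[1]])),
               "degenerate")
})

test_that("GAL files round-trip and asymmetric files are rejected", {
  W <- queen_contiguity(make_lattice(1, 3))
  path <- tempfile(fileext = ".gal")
  write_gal(W, path)
  W2 <- read_gal(path)
  expect_identical(W2$ids, W$ids)
  expect_identical(lapply(W2$neighbours, sort), lapply(W$neighbours, sort))
  # GeoDa-style file for the 2x2 queen grid
  Wg <- queen_contiguity(make_lattice(2, 2))
  write_gal(Wg, path)
  expect_identical(lengths(read_gal(path)$neighbours), rep(3L, 4))
  # asymmetric listing: A names B but not vice versa
  writeLines(c("0 2 synthetic id", "A 1", "B", "B 0"), path)
  expect_error(read_gal(path), "symmetric")
  writeLines(c("0 2 synthetic id", "A 1", "C", "B 1", "A"), path)
  expect_error(read_gal(path), "unknown area id")
  writeLines(c("0 2 synthetic id", "A x"), path)
  expect_error(read_gal(path), "line")
})

test_that("GeoJSON areas round-trip through write and read", {
  areas <- make_lattice(2, 3, 1.5)
  path <- tempfile(fileext = ".geojson")
  write_geojson_areas(areas, path)
  back <- read_geojson_areas(path)
  expect_identical(area_ids(back), area_ids(areas))
  for (j in seq_along(areas)) {
    expect_equal(back[[j]]$rings[[1]], areas[[j]]$rings[[1]],
                 ignore_attr = TRUE)
    expect_equal(back[[j]]$centroid, areas[[j]]$centroid)
  }
  # identical weight matrices from the round-tripped geometry
  expect_identical(as_dense_matrix(queen_contiguity(back)),
                   as_dense_matrix(queen_contiguity(areas)))
})

test_that("connected components are identified", {
  W <- weight_matrix(letters[1:5],
                     list(2L, 1L, 4L, 3L, integer(0)))
  comp <- connected_components(W)
  expect_identical(comp, c(1L, 1L, 2L, 2L, 3L))
})
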