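test_that("queen contiguity on lattices matches the index-arithmetic oracle", {
  # 3x3: corner 3, edge 5, center 8
  deg <- lengths(W3_binary$neighbors)
  expect_equal(sort(deg), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
  expect_equal(weights_matrix(W3_binary),
               lattice_queen_matrix(3, 3), ignore_attr = TRUE)

  # exact neighbor sets on rectangular lattices of several shapes
  for (dims in list(c(4, 6), c(5, 5), c(2, 7))) {
    lat <- make_lattice(dims[1], dims[2])
    W <- queen_weights(lat)
    expect_equal(weights_matrix(W), lattice_queen_matrix(dims[1], dims[2]),
                 ignore_attr = TRUE)
    # degree histogram for rows, cols >= 3
    if (all(dims >= 3)) {
      expect_equal(unname(table(lengths(W$neighbors))[c("3", "5", "8")]),
                   c(4, 2 * (dims[1] - 2) + 2 * (dims[2] - 2),
                     (dims[1] - 2) * (dims[2] - 2)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("queen rule: corner touches count, distant polygons do not", {
  sq <- function(x, y) list(list(rbind(c(x, y), c(x + 1, y),
                                       c(x + 1, y + 1),
                                       c(x, y + 1), c(x, y))))
  # two squares sharing exactly one corner point
  touch <- areal_table(c("a", "b"), list(sq(0, 0), sq(1, 1)))
  Wt <- queen_weights(touch, snap = 0)
  expect_equal(Wt$neighbors[[1]], 2L)

  # isolated polygon is an island, flagged with a warning
  iso <- areal_table(c("a", "b", "c"),
                     list(sq(0, 0), sq(1, 0), sq(50, 50)))
  expect_warning(Wi <- queen_weights(iso), "island")
  expect_equal(Wi$islands, 3L)
  expect_equal(Wi$S0, 2)

  expect_error(queen_weights(areal_table("a", list(sq(0, 0)))), "at least two")
})

test_that("binary weights are symmetric and S0 is conserved across transforms", {
  set.seed(19)
  for (r in 1:20) {
    rw <- random_weights(sample(4:12, 1))
    Wm <- rw$Wm
    expect_identical(Wm, t(Wm))
    expect_equal(rw$W$S0, sum(unlist(rw$W$weights)))
    Wr <- row_standardize(rw$W)
    expect_equal(Wr$S0, sum(unlist(Wr$weights)), tolerance = 1e-12)
    expect_equal(Wr$S0, Wr$n - length(Wr$islands), tolerance = 1e-12)
    # non-island rows sum to one
    rs <- vapply(Wr$weights, sum, numeric(1))
    expect_true(all(abs(rs[lengths(Wr$neighbors) > 0] - 1) < 1e-12))
  }
})

test_that("row standardization divides by degree and is idempotent", {
  W <- W3_row
  center <- which(lengths(W$neighbors) == 8)
  expect_equal(W$weights[[center]], rep(1 / 8, 8))
  corner <- which(lengths(W$neighbors) == 3)[1]
  expect_equal(W$weights[[corner]], rep(1 / 3, 3))
  W2 <- row_standardize(W)
  expect_equal(W2$weights, W$weights, tolerance = 1e-15)
})

test_that("spatial_lag matches the explicit double loop and handles islands", {
  set.seed(5)
  for (style in c("binary", "row_standardized")) {
    rw <- random_weights(4, style = style)
    x <- rnorm(4)
    expect_equal(spatial_lag(rw$W, x), as.numeric(rw$Wm %*% x),
                 tolerance = 1e-14)
  }
  # constant vector under row-standardized weights: lag is the constant
  expect_equal(spatial_lag(W3_row, rep(7, 9)), rep(7, 9), tolerance = 1e-12)
  # indicator of unit k: lag_i = w_ik
  e5 <- as.numeric(seq_len(9) == 5)
  expect_equal(spatial_lag(W3_row, e5), weights_matrix(W3_row)[, 5],
               tolerance = 1e-14)
  expect_error(spatial_lag(W3_row, 1:4), "length")
})

test_that("GAL serialization round-trips exactly, including islands", {
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(W3_binary, path)
  back <- read_gal(path)
  expect_identical(back$neighbors, W3_binary$neighbors)
  expect_identical(back$ids, W3_binary$ids)
  expect_equal(back$S0, W3_binary$S0)

  # row-standardized style is recorded and reapplied
  write_gal(W3_row, path)
  backr <- read_gal(path)
  expect_equal(backr$style, "row_standardized")
  expect_equal(backr$weights, W3_row$weights, tolerance = 1e-15)

  # islands survive the round trip
  sq <- function(x, y) list(list(rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1),
                                       c(x, y + 1), c(x, y))))
  iso <- areal_table(c("a", "b", "c"), list(sq(0, 0), sq(1, 0), sq(9, 9)))
  Wi <- suppressWarnings(queen_weights(iso))
  write_gal(Wi, path)
  backi <- read_gal(path)
  expect_identical(backi$islands, 3L)
  expect_identical(backi$neighbors, Wi$neighbors)

  # a hand-written 4-node GAL matches directly constructed weights
  hand <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("4", "a 1", "b", "b 2", "a c", "c 2", "b d", "d 1", "c"), hand)
  Wh <- read_gal(hand)
  expect_identical(Wh$neighbors, list(2L, c(1L, 3L), c(2L, 4L), 3L))

  writeLines(c("3", "a 2", "b"), hand)
  expect_error(read_gal(hand), "line")
})

test_that("stationary_interval matches dense eigen analysis", {
  # connected row-standardized lattice: upper bound is the Perron root 1
  iv <- stationary_interval(W3_row)
  expect_equal(iv[2], 1, tolerance = 1e-9)
  ev <- eigen(weights_matrix(W3_row), only.values = TRUE)$values
  expect_equal(iv[1], 1 / min(Re(ev)), tolerance = 1e-9)

  # symmetric 2-node pair, standardized: interval (-1, 1)
  sq <- function(x, y) list(list(rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1),
                                       c(x, y + 1), c(x, y))))
  pair <- areal_table(c("a", "b"), list(sq(0, 0), sq(1, 0)))
  Wp <- row_standardize(queen_weights(pair))
  expect_equal(stationary_interval(Wp), c(-1, 1), tolerance = 1e-9)

  # random small weights against a direct dense eigensolve
  set.seed(8)
  for (r in 1:10) {
    rw <- random_weights(7, style = "row_standardized")
    if (length(rw$W$islands) == 7) next
    iv <- stationary_interval(rw$W)
    evr <- Re(eigen(rw$Wm, only.values = TRUE)$values)
    expect_equal(iv, c(1 / min(evr), 1 / max(evr)), tolerance = 1e-9)
  }
})
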