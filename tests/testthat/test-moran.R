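test_that("moran equals the brute-force double sum on random instances", {
  set.seed(101)
  for (r in 1:50) {
    n <- sample(4:25, 1)
    style <- if (r %% 2 == 0) "binary" else "row_standardized"
    rw <- random_weights(n, style = style)
    x <- rnorm(n, 50, 10)
    expect_equal(moran(x, rw$W), moran_bruteforce(x, rw$Wm), tolerance = 1e-12)
  }
})

test_that("moran has the expected sign structure", {
  # checkerboard on a lattice: perfect dissimilarity of rook neighbors
  lat <- make_lattice(6, 6)
  W <- row_standardize(queen_weights(lat))
  ij <- expand.grid(j = 1:6, i = 1:6)
  chk <- ifelse((ij$i + ij$j) %% 2 == 0, 1, -1)
  expect_lt(moran(chk, W), 0)

  # a smoothly varying surface clusters
  grad <- ij$i + ij$j + rnorm(36, 0, 0.1)
  expect_gt(moran(grad, W), 0.5)

  # 4-node path, x = 1:4, row-standardized: frozen against the oracle
  path_nbr <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  Wp <- row_standardize(spatial_weights(letters[1:4], path_nbr,
                                        lapply(path_nbr, function(v) rep(1, length(v)))))
  expect_equal(moran(1:4, Wp), moran_bruteforce(1:4, weights_matrix(Wp)),
               tolerance = 1e-14)
  expect_equal(moran(1:4, Wp), 0.4, tolerance = 1e-12)

  expect_error(moran(rep(3, 9), W3_row), "zero variance")
})

test_that("permutation test honors the pseudo p-value convention and the seed", {
  lat <- make_lattice(6, 6)
  W <- row_standardize(queen_weights(lat))
  ij <- expand.grid(j = 1:6, i = 1:6)
  grad <- ij$i + ij$j   # extreme clustering: beats every permutation
  mt <- moran_mc(grad, W, n_perm = 999, seed = 42)
  expect_equal(mt$p_sim, 0.001)
  expect_gte(mt$p_sim, 1 / (mt$n_perm + 1))
  expect_gt(mt$z_score, 3)

  mt2 <- moran_mc(grad, W, n_perm = 999, seed = 42)
  expect_identical(mt$p_sim, mt2$p_sim)
  expect_identical(mt$perm_summary, mt2$perm_summary)

  set.seed(77)
  x <- rnorm(36)
  pg <- moran_mc(x, W, n_perm = 199, seed = 1, alternative = "greater")$p_sim
  pl <- moran_mc(x, W, n_perm = 199, seed = 1, alternative = "less")$p_sim
  pd <- moran_mc(x, W, n_perm = 199, seed = 1)$p_sim
  p2 <- moran_mc(x, W, n_perm = 199, seed = 1, alternative = "two.sided")$p_sim
  expect_true(pd %in% c(pg, pl))
  expect_gte(p2, pd)
  expect_error(moran_mc(x, W, n_perm = 0), "n_perm")
})

test_that("local moran: zero deviation gives zero, sum is proportional to global I", {
  set.seed(55)
  for (r in 1:30) {
    n <- sample(5:25, 1)
    rw <- random_weights(n, style = if (r %% 2) "row_standardized" else "binary")
    x <- rnorm(n, 30, 5)
    li <- local_moran(x, rw$W)
    expect_equal(li, local_moran_bruteforce(x, rw$Wm), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(li), rw$W$S0 * moran(x, rw$W), tolerance = 1e-9)
  }

  # a unit sitting exactly at the mean contributes nothing
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 1)
  x[5] <- sum(x[-5]) / 8   # x[5] equals the mean of all nine values
  li <- local_moran(x, W3_row)
  expect_equal(li[5], 0, tolerance = 1e-10)

  # z-form differs from scaled form by the factor m2
  z <- x - mean(x)
  m2 <- sum(z^2) / 9
  expect_equal(local_moran(x, W3_row, form = "z"),
               local_moran(x, W3_row) * m2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("positive local moran flags units whose neighborhood shares their side of the mean", {
  lat <- make_lattice(5, 5)
  W <- row_standardize(queen_weights(lat))
  set.seed(12)
  x <- rnorm(25, 10, 0.5)
  x[c(7, 8, 12, 13)] <- 30    # a high block
  li <- local_moran(x, W)
  z <- x - mean(x)
  lagz <- spatial_lag(W, z)
  both_high <- z > 0 & lagz > 0
  expect_true(all(li[both_high] > 0))
})

test_that("lisa conditional permutation labels a seeded block HH and its rim LH/NS", {
  lat <- make_lattice(9, 9)
  W <- row_standardize(queen_weights(lat))
  set.seed(21)
  x <- rnorm(81, 10, 1)
  block_ids <- c("r4c4", "r4c5", "r4c6", "r5c4", "r5c5", "r5c6",
                 "r6c4", "r6c5", "r6c6")
  block <- match(block_ids, lat$unit_id)
  x[block] <- rnorm(9, 50, 1)
  ls <- lisa_mc(x, W, n_perm = 999, seed = 3)
  expect_identical(ls$label[match("r5c5", lat$unit_id)], "HH")
  # low units adjacent to the block are LH or NS (never HH/LL)
  rim <- setdiff(unique(unlist(W$neighbors[block])), block)
  expect_true(all(ls$label[rim] %in% c("LH", "NS")))
  # labels respect the alpha gate
  sig <- !is.na(ls$p_sim) & ls$p_sim < ls$alpha
  expect_identical(ls$label[!sig], rep("NS", sum(!sig)))
  expect_identical(ls$label[sig], ls$quadrant[sig])
})

test_that("lisa under an exchangeable draw is mostly NS and reproducible", {
  lat <- make_lattice(8, 8)
  W <- row_standardize(queen_weights(lat))
  set.seed(99)
  x <- rnorm(64)
  a <- lisa_mc(x, W, n_perm = 499, seed = 7)
  b <- lisa_mc(x, W, n_perm = 499, seed = 7)
  expect_identical(a$p_sim, b$p_sim)
  expect_true(all(a$p_sim >= 1 / (a$n_perm + 1), na.rm = TRUE))
  # under exchangeability the directional pseudo-p rejects ~2*alpha per unit,
  # so the NS share should average near 1 - 2*alpha
  ns_rate <- mean(vapply(1:5, function(r) {
    set.seed(1000 + r)
    mean(lisa_mc(rnorm(64), W, n_perm = 199, seed = r)$label == "NS")
  }, numeric(1)))
  expect_gte(ns_rate, 1 - 3 * a$alpha)
  expect_lte(ns_rate, 1 - a$alpha)
})

test_that("islands get zero local statistics and NS labels", {
  sq <- function(x, y) list(list(rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1),
                                       c(x, y + 1), c(x, y))))
  geom <- c(lapply(0:3, function(k) sq(k, 0)), list(sq(40, 40)))
  tab <- areal_table(paste0("u", 1:5), geom)
  W <- row_standardize(suppressWarnings(queen_weights(tab)))
  x <- c(1, 5, 2, 8, 100)
  li <- local_moran(x, W)
  expect_equal(li[5], 0)
  ls <- lisa_mc(x, W, n_perm = 99, seed = 2)
  expect_identical(ls$label[5], "NS")
  expect_true(is.na(ls$p_sim[5]))
})
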