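test_that("make_lattice tiles a rectangle with correctly identified cells", {
  one <- make_lattice(1, 1, cell_size = 2.5)
  expect_equal(one$n, 1)
  expect_equal(unit_area(one, 1), 2.5^2)

  lat <- make_lattice(3, 3)
  expect_equal(lat$n, 9)
  expect_setequal(lat$unit_id,
                  as.vector(outer(1:3, 1:3, function(i, j) sprintf("r%dc%d", i, j))))
  expect_equal(sum(vapply(seq_len(9), function(i) unit_area(lat, i), numeric(1))), 9)

  big <- make_lattice(20, 32)
  expect_equal(big$n, 640)

  expect_error(make_lattice(0, 3), "positive integers")
  expect_error(make_lattice(3, 3, cell_size = -1), "positive real")
})

test_that("simulate_covariates reproduces marginal specs and respects clipping", {
  spec <- data.frame(name = "v", mean = 21.96, sd = 14.62, clip = FALSE)
  x <- simulate_covariates(spec, 10000, seed = 42)$v
  expect_lt(abs(mean(x) - 21.96), 0.5)
  expect_lt(abs(sd(x) - 14.62), 0.5)

  clipped <- simulate_covariates(
    data.frame(name = "rural", mean = 71.57, sd = 21.66, clip = TRUE),
    5000, seed = 7)$rural
  expect_true(all(clipped >= 0 & clipped <= 100))

  # default district specs: every column within Monte-Carlo error of its
  # target at n = 640 (clipping tolerated in the band)
  specs <- district_variable_specs()
  tab <- simulate_covariates(specs, 640, seed = 3)
  expect_named(tab, specs$name)
  for (k in seq_len(nrow(specs))) {
    expect_lt(abs(mean(tab[[k]]) - specs$mean[k]), 3 * specs$sd[k] / sqrt(640) + 2)
  }

  expect_error(simulate_covariates(data.frame(name = "v", mean = 1, sd = 0), 10),
               "sd must be strictly positive")
  expect_error(simulate_covariates(data.frame(name = c("a", "a"),
                                              mean = c(1, 2), sd = c(1, 1)), 10),
               "duplicate")
})

test_that("simulate_covariates honors a supplied correlation matrix", {
  specs <- data.frame(name = c("a", "b"), mean = c(50, 50), sd = c(10, 10),
                      clip = FALSE)
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  tab <- simulate_covariates(specs, 5000, seed = 5, correlation = R)
  expect_lt(abs(cor(tab$a, tab$b) - 0.8), 0.05)
  expect_error(simulate_covariates(specs, 100, seed = 1,
                                   correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("simulate_outcome implements the three generating processes", {
  lat <- make_lattice(5, 5)
  W <- row_standardize(queen_weights(lat))
  X <- cbind(1, seq_len(25))
  beta <- c(2, 0.5)

  # sem with lambda = 0 is exactly csr on the same seed path
  a <- simulate_outcome(W, X, "csr", beta, noise_sd = 2, seed = 9)
  b <- simulate_outcome(W, X, "sem", beta, spatial_param = 0, noise_sd = 2, seed = 9)
  expect_equal(a$y, b$y, tolerance = 1e-12)

  # fixed seed => bitwise identical
  c1 <- simulate_outcome(W, X, "slm", beta, spatial_param = 0.4, seed = 11)
  c2 <- simulate_outcome(W, X, "slm", beta, spatial_param = 0.4, seed = 11)
  expect_identical(c1$y, c2$y)

  expect_error(simulate_outcome(W, X, "sem", beta, spatial_param = 1.2),
               "stationarity interval")
  expect_error(simulate_outcome(W, X[1:10, ], "csr", beta), "rows")
  Wb <- queen_weights(lat)
  expect_error(simulate_outcome(Wb, X, "csr", beta), "row-standardized")
})

test_that("sem/slm outcomes match their closed-form covariance by Monte Carlo", {
  lat <- make_lattice(4, 4)
  W <- row_standardize(queen_weights(lat))
  Wm <- weights_matrix(W)
  n <- 16
  X <- matrix(1, n, 1)
  for (case in list(list(kind = "sem", par = 0.69), list(kind = "slm", par = 0.59))) {
    A_inv <- solve(diag(n) - case$par * Wm)
    Sigma <- A_inv %*% t(A_inv)          # noise_sd = 1
    reps <- 4000
    Y <- vapply(seq_len(reps), function(r) {
      simulate_outcome(W, X, case$kind, beta = 0, spatial_param = case$par,
                       noise_sd = 1, seed = 100000L + r)$y
    }, numeric(n))
    emp <- cov(t(Y))
    expect_lt(max(abs(emp - Sigma)) / max(diag(Sigma)), 0.15)
    # spatial amplification: marginal variance exceeds the innovation variance
    expect_gt(mean(diag(emp)), 1)
  }
})

test_that("sem outcomes at the study's lambda carry detectable autocorrelation", {
  lat <- make_lattice(20, 32)
  W <- row_standardize(queen_weights(lat))
  n_sig <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    sim <- simulate_outcome(W, matrix(1, 640, 1), "sem", beta = 0,
                            spatial_param = 0.69, noise_sd = 1,
                            seed = 5000L + r)
    mt <- moran_mc(sim$y, W, n_perm = 199, seed = r, alternative = "greater")
    if (mt$I > 0 && mt$p_sim < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / reps, 0.95)
})

test_that("district_fixture assembles a coherent study-scale dataset", {
  fx <- district_fixture(rows = 6, cols = 6, seed = 2, process = "sem",
                         spatial_param = 0.5)
  expect_equal(fx$areas$n, 36)
  expect_true("cervical_screening" %in% names(fx$areas$attributes))
  expect_equal(fx$truth$process, "sem")
  expect_equal(fx$truth$spatial_param, 0.5)
  # regenerating with the same seed is identical
  fx2 <- district_fixture(rows = 6, cols = 6, seed = 2, process = "sem",
                          spatial_param = 0.5)
  expect_identical(fx$areas$attributes, fx2$areas$attributes)
})
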