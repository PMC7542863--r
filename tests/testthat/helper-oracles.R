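# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: explicit double loops, dense matrices, LU
# log-determinants, and index arithmetic instead of geometry.

# Moran's I by explicit O(n^2) double loop over a dense weight matrix
moran_bruteforce <- function(x, Wm) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Wm[i, j] * z[i] * z[j]
    }
  }
  (n / sum(Wm)) * num / sum(z^2)
}

# scaled local Moran by explicit loop
local_moran_bruteforce <- function(x, Wm) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + Wm[i, j] * z[j]
    out[i] <- z[i] * s / m2
  }
  out
}

# queen adjacency of an r x c lattice from index arithmetic (no geometry)
lattice_queen_matrix <- function(r, c) {
  n <- r * c
  m <- matrix(0, n, n)
  idx <- function(i, j) (i - 1) * c + j
  for (i in seq_len(r)) for (j in seq_len(c)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= r && jj >= 1 && jj <= c) {
        m[idx(i, j), idx(ii, jj)] <- 1
      }
    }
  }
  m
}

# random symmetric binary weights (connected enough: no all-island case),
# returned as a spatial_weights object plus its dense matrix
random_weights <- function(n, p_link = 0.35, style = "binary") {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < p_link)
    A <- A + t(A)
    deg <- rowSums(A)
    if (sum(deg > 0) >= 3) break
  }
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  W <- spatial_weights(sprintf("u%d", seq_len(n)), nbr,
                       lapply(nbr, function(x) rep(1, length(x))))
  if (style == "row_standardized") {
    W <- row_standardize(W)
  }
  Wm <- weights_matrix(W)
  list(W = W, Wm = Wm)
}

# OLS coefficients via SVD pseudoinverse (independent of lm.fit/QR)
ols_pinv <- function(X, y) {
  s <- svd(X)
  as.numeric(s$v %*% ((t(s$u) %*% y) / s$d))
}

# Independent SEM/SLM reference: concentrated log-likelihood with the
# log-determinant from a dense LU factorization (determinant()), maximized
# by a hand-rolled golden-section search; beta by pseudoinverse GLS.
sar_reference <- function(y, X, Wm, kind = c("sem", "slm"),
                          lower = -0.999, upper = 0.999, tol = 1e-8) {
  kind <- match.arg(kind)
  n <- length(y)
  cll <- function(p) {
    A <- diag(n) - p * Wm
    ys <- as.numeric(A %*% y)
    Xs <- if (kind == "sem") A %*% X else X
    b <- ols_pinv(Xs, ys)
    rss <- sum((ys - Xs %*% b)^2)
    ld <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    -(n / 2) * (log(2 * pi * rss / n) + 1) + ld
  }
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- cll(c1); f2 <- cll(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- cll(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- cll(c1)
    }
  }
  p_hat <- (a + b) / 2
  A <- diag(n) - p_hat * Wm
  ys <- as.numeric(A %*% y)
  Xs <- if (kind == "sem") A %*% X else X
  beta <- ols_pinv(Xs, ys)
  list(p = p_hat, beta = beta, logL = cll(p_hat))
}

# shared small fixtures
lattice3 <- make_lattice(3, 3)
W3_binary <- queen_weights(lattice3)
W3_row <- row_standardize(W3_binary)
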