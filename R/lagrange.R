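#' Lagrange-multiplier diagnostics for spatial dependence in OLS residuals
#'
#' Rao-score tests on the residuals of an OLS fit, in the standard spatial
#' econometrics forms. With `s2 = e'e/n`, `T = tr(W'W + WW)`,
#' `M = I - X(X'X)^{-1}X'`, `dE = e'We/s2`, `dL = e'Wy/s2` and
#' `D = (WXb)'M(WXb)/s2 + T`:
#'
#' * `lm_error = dE^2 / T` (chi-squared, 1 df)
#' * `lm_lag = dL^2 / D` (1 df)
#' * `rlm_error = (dE - (T/D) dL)^2 / (T (1 - T/D))` (1 df), robust to local
#'   lag dependence
#' * `rlm_lag = (dL - dE)^2 / (D - T)` (1 df), robust to local error
#'   dependence
#' * `sarma = lm_error + rlm_lag = lm_lag + rlm_error` (2 df), the joint test
#'
#' All statistics are nonnegative quadratic forms. A large `lm_error`
#' (relative to `lm_lag`, and especially a large robust error statistic)
#' points at a spatial error model; the mirror pattern points at a spatial
#' lag model.
#'
#' @param ols an [fit_ols] result.
#' @param W a row-standardized [spatial_weights] with no islands among the
#'   fitted units.
#' @return An object of class `lm_diagnostics`: the five statistics with
#'   their degrees of freedom and chi-squared p-values.
#' @export
lm_diagnostics <- function(ols, W) {
  if (W$style != "row_standardized") {
    stop("LM diagnostics require row-standardized weights")
  }
  if (length(W$islands) > 0) {
    stop("islands present (", paste(W$ids[W$islands], collapse = ", "),
         "); remove them with subset_weights() before fitting")
  }
  design <- ols$design
  y <- design$y; X <- design$X
  e <- ols$residuals
  n <- length(y)
  if (W$n != n) stop("weights and design sizes differ")
  s2 <- sum(e^2) / n
  Wm <- weights_matrix(W, sparse = TRUE)
  trWW <- sum(Wm@x^2)                       # tr(W'W)
  trW2 <- sum(Wm * Matrix::t(Wm))           # tr(WW)
  Tr <- trWW + trW2
  We <- as.numeric(Wm %*% e)
  Wy <- as.numeric(Wm %*% y)
  dE <- sum(e * We) / s2
  dL <- sum(e * Wy) / s2
  WXb <- as.numeric(Wm %*% ols$fitted)
  MWXb <- WXb - X %*% stats::lm.fit(X, WXb)$coefficients
  D <- sum(WXb * MWXb) / s2 + Tr
  lm_error <- dE^2 / Tr
  lm_lag <- dL^2 / D
  rlm_error <- (dE - (Tr / D) * dL)^2 / (Tr * (1 - Tr / D))
  rlm_lag <- (dL - dE)^2 / (D - Tr)
  sarma <- lm_error + rlm_lag
  stats_ <- c(lm_error = lm_error, lm_lag = lm_lag,
              rlm_error = rlm_error, rlm_lag = rlm_lag, sarma = sarma)
  df <- c(1, 1, 1, 1, 2)
  structure(list(statistics = stats_, df = df,
                 p_values = stats::pchisq(stats_, df, lower.tail = FALSE)),
            class = "lm_diagnostics")
}

#' @export
print.lm_diagnostics <- function(x, ...) {
  tab <- data.frame(statistic = x$statistics, df = x$df, p = x$p_values)
  rownames(tab) <- c("LM error", "LM lag", "Robust LM error",
                     "Robust LM lag", "SARMA")
  print(round(tab, 4))
  invisible(x)
}
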