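#' Build a regression design from an attribute table
#'
#' Assembles the outcome vector and a design matrix with a leading intercept
#' column. Refuses constant covariates and rank-deficient designs.
#'
#' @param data data.frame of numeric columns (e.g. `areas$attributes`).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @return A list of class `regression_design` with `y`, `X`,
#'   `variable_names` and `outcome`.
#' @export
regression_design <- function(data, outcome, covariates) {
  missing_cols <- setdiff(c(outcome, covariates), names(data))
  if (length(missing_cols) > 0) {
    stop("variable(s) not in table: ", paste(missing_cols, collapse = ", "))
  }
  if (outcome %in% covariates) stop("outcome cannot also be a covariate")
  y <- as.numeric(data[[outcome]])
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  const <- which(apply(X[, -1, drop = FALSE], 2, stats::sd) == 0)
  if (length(const) > 0) {
    stop("constant covariate column(s): ", paste(covariates[const], collapse = ", "))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  structure(list(y = y, X = X, variable_names = colnames(X), outcome = outcome),
            class = "regression_design")
}

# gaussian ML log-likelihood of residuals e at sigma2 = e'e/n
.gauss_logl <- function(rss, n) {
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

#' Ordinary least squares with collinearity diagnostics
#'
#' QR-based least squares fit with classical t-based standard errors, Gaussian
#' maximum-likelihood log-likelihood and AIC (parameter count = coefficients
#' plus one error variance), and variance inflation factors from auxiliary
#' regressions of each covariate on the others.
#'
#' @param design a [regression_design].
#' @return An object of class `ols_fit`: `beta`, `se`, `p_values`,
#'   `residuals`, `fitted`, `sigma2` (ML, e'e/n), `r2`, `adj_r2`, `logL`,
#'   `aic`, `vif`, plus the design.
#' @export
fit_ols <- function(design) {
  y <- design$y; X <- design$X
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  e <- fit$residuals
  rss <- sum(e^2)
  tss <- sum((y - mean(y))^2)
  s2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  r2 <- 1 - rss / tss
  logL <- .gauss_logl(rss, n)
  vif <- rep(NA_real_, p - 1)
  names(vif) <- colnames(X)[-1]
  if (p > 2) {
    for (j in 2:p) {
      aux <- stats::lm.fit(X[, -j, drop = FALSE], X[, j])
      r2j <- 1 - sum(aux$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      vif[j - 1] <- 1 / (1 - r2j)
    }
  } else {
    vif[1] <- 1
  }
  structure(list(beta = beta, se = se, p_values = pval, residuals = e,
                 fitted = fit$fitted.values, sigma2 = rss / n, r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
                 logL = logL, aic = 2 * (p + 1) - 2 * logL, vif = vif,
                 n = n, design = design),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit:", x$design$outcome, "~", length(x$beta) - 1, "covariates, n =", x$n, "\n")
  tab <- data.frame(estimate = x$beta, se = x$se, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("R2 = %.3f  adj R2 = %.3f  logL = %.2f  AIC = %.1f\n",
              x$r2, x$adj_r2, x$logL, x$aic))
  invisible(x)
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' Moran permutation test on model residuals
#'
#' Applies [moran_mc] to the residuals of a fitted model: OLS residuals for an
#' `ols_fit`, innovation residuals for a spatial fit (see [fit_sem]). This is
#' the declustering check: residual autocorrelation that an OLS leaves behind
#' should disappear once the matching spatial model absorbs it.
#'
#' @param fit a fitted model with a `residuals` method.
#' @param W a [spatial_weights] object (on the units the model was fitted to).
#' @param ... passed to [moran_mc] (`n_perm`, `seed`, `alternative`).
#' @return A `moran_mc` object.
#' @export
residual_moran <- function(fit, W, ...) {
  moran_mc(stats::residuals(fit), W, ...)
}

#' Studentized (Koenker) Breusch-Pagan heteroskedasticity test
#'
#' Regresses squared residuals on the design matrix; the statistic is
#' `n * R^2` of that auxiliary regression, compared to a chi-squared
#' distribution with one degree of freedom per covariate.
#'
#' @param fit a fitted model with residuals (`ols_fit` or `spatial_fit`).
#' @param design optional [regression_design]; defaults to the fit's own.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bp_test <- function(fit, design = fit$design) {
  e <- stats::residuals(fit)
  X <- design$X
  n <- length(e)
  u <- e^2
  aux <- stats::lm.fit(X, u)
  r2 <- 1 - sum(aux$residuals^2) / sum((u - mean(u))^2)
  stat <- n * r2
  df <- ncol(X) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
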