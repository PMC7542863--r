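#' @title Maximum-likelihood spatial error and spatial lag models
#' @description
#' The spatial error model (SEM) is `y = X beta + eps`, `eps = lambda W eps
#' + xi` with i.i.d. Gaussian innovations `xi`; lambda is the spatial error
#' coefficient (lambda = 0 recovers OLS). The spatial lag model (SLM) is
#' `y = rho W y + X beta + eps`; rho measures the average influence of
#' neighboring outcomes. Both are estimated by maximizing the concentrated
#' Gaussian log-likelihood in the single spatial parameter:
#' for a trial value p, form `A = I - p W`, transform the data (SEM: both y
#' and X by A; SLM: y only), profile out beta and sigma^2 by least squares,
#' and add the Jacobian term `log|A| = sum(log(1 - p * omega_k))` over the
#' eigenvalues omega of W. The scalar search runs over the stationarity
#' interval of W (see [stationary_interval]), clipped slightly inside its
#' endpoints. Standard errors come from the negative inverse numerical
#' Hessian of the full log-likelihood at the optimum.
#' @name spatial_models
NULL

# concentrated log-likelihood machinery shared by SEM and SLM.
# kind = "sem": y* = Ay, X* = AX;  kind = "slm": y* = Ay, X* = X.
.conc_logl <- function(p, kind, y, X, Wy, WX, ev, n) {
  ys <- y - p * Wy
  Xs <- if (kind == "sem") X - p * WX else X
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  .gauss_logl(rss, n) + sum(log(1 - p * ev))
}

# full log-likelihood at theta = (beta, p, sigma2), for Hessian-based SEs
.full_logl <- function(theta, kind, y, X, Wy, WX, ev, n) {
  ppar <- ncol(X)
  beta <- theta[seq_len(ppar)]
  p <- theta[ppar + 1]
  s2 <- theta[ppar + 2]
  if (s2 <= 0 || any(1 - p * ev <= 0)) return(-Inf)
  u <- if (kind == "sem") {
    (y - p * Wy) - (X - p * WX) %*% beta
  } else {
    (y - p * Wy) - X %*% beta
  }
  -(n / 2) * log(2 * pi * s2) + sum(log(1 - p * ev)) - sum(u^2) / (2 * s2)
}

.fit_sar <- function(design, W, kind, n_perm, seed) {
  if (W$style != "row_standardized") {
    stop("spatial models require row-standardized weights")
  }
  y <- design$y; X <- design$X
  if (W$n != length(y)) stop("weights and design sizes differ")
  if (length(W$islands) > 0) {
    keep <- setdiff(seq_len(W$n), W$islands)
    warning("dropping ", length(W$islands), " island unit(s) from the ",
            toupper(kind), " fit: ", paste(W$ids[W$islands], collapse = ", "))
    W <- subset_weights(W, keep)
    design <- structure(list(y = y[keep], X = X[keep, , drop = FALSE],
                             variable_names = design$variable_names,
                             outcome = design$outcome),
                        class = "regression_design")
    y <- design$y; X <- design$X
  }
  n <- length(y); ppar <- ncol(X)
  if (n < ppar + 2) stop("too few observations for a spatial model")
  ev <- weights_spectrum(W)
  interval <- stationary_interval(W)
  lo <- interval[1] + 1e-6
  hi <- interval[2] - 1e-6
  Wy <- spatial_lag(W, y)
  WX <- apply(X, 2, function(col) spatial_lag(W, col))
  opt <- stats::optimize(function(p) .conc_logl(p, kind, y, X, Wy, WX, ev, n),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  p_hat <- opt$maximum
  boundary <- (p_hat - lo < 1e-4) || (hi - p_hat < 1e-4)
  if (boundary) {
    warning("spatial parameter estimate at the search boundary (",
            format(p_hat), ")")
  }
  ys <- y - p_hat * Wy
  Xs <- if (kind == "sem") X - p_hat * WX else X
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  resid_inno <- fit$residuals            # xi-hat (sem) / eps-hat (slm)
  s2 <- sum(resid_inno^2) / n
  logL <- .gauss_logl(sum(resid_inno^2), n) + sum(log(1 - p_hat * ev))

  theta <- c(beta, p_hat, s2)
  H <- pracma::hessian(function(th) .full_logl(th, kind, y, X, Wy, WX, ev, n),
                       theta)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  se_all <- suppressWarnings(sqrt(diag(vc)))
  se_beta <- se_all[seq_len(ppar)]
  se_p <- se_all[ppar + 1]
  names(se_beta) <- names(beta)
  z <- beta / se_beta
  pvals <- 2 * stats::pnorm(-abs(z))
  p_spatial <- 2 * stats::pnorm(-abs(p_hat / se_p))

  ols <- fit_ols(design)
  lr_stat <- 2 * (logL - ols$logL)
  lr <- list(statistic = lr_stat, df = 1,
             p_value = stats::pchisq(max(lr_stat, 0), 1, lower.tail = FALSE))
  out <- structure(list(kind = kind, spatial_param = p_hat, se_spatial = se_p,
                        p_value_spatial = p_spatial,
                        beta = beta, se = se_beta, p_values = pvals,
                        residuals = resid_inno, sigma2 = s2, logL = logL,
                        aic = 2 * (ppar + 2) - 2 * logL,
                        lr_test = lr, converged = !boundary,
                        search_interval = c(lo, hi), n = n,
                        design = design, ols = ols),
                   class = "spatial_fit")
  out$bp_studentized <- bp_test(out, design)
  if (!is.null(n_perm)) {
    out$residual_moran <- residual_moran(out, W, n_perm = n_perm, seed = seed)
  }
  out
}

#' Fit a spatial error model by maximum likelihood
#'
#' @param design a [regression_design].
#' @param W a row-standardized [spatial_weights]; islands are dropped with a
#'   warning. Cache the spectrum with [cache_spectrum] when fitting
#'   repeatedly.
#' @param n_perm permutations for the residual Moran test carried on the
#'   result (`NULL` to skip).
#' @param seed seed for the residual Moran permutation test.
#' @return An object of class `spatial_fit` with `kind = "sem"`:
#'   `spatial_param` (lambda), `beta`, `se`, `p_values`, innovation
#'   `residuals` (xi-hat = (I - lambda W)(y - X beta)), `sigma2`, `logL`,
#'   `aic` (parameter count = coefficients + 2), `lr_test` against the OLS
#'   fit, `bp_studentized`, `residual_moran`, `converged`,
#'   `search_interval`.
#' @export
fit_sem <- function(design, W, n_perm = 999, seed = 1L) {
  .fit_sar(design, W, "sem", n_perm, seed)
}

#' Fit a spatial lag model by maximum likelihood
#'
#' @inheritParams fit_sem
#' @return An object of class `spatial_fit` with `kind = "slm"`;
#'   `spatial_param` is rho and `residuals` are
#'   `y - rho W y - X beta`.
#' @export
fit_slm <- function(design, W, n_perm = 999, seed = 1L) {
  .fit_sar(design, W, "slm", n_perm, seed)
}

#' @export
residuals.spatial_fit <- function(object, ...) object$residuals

#' @export
print.spatial_fit <- function(x, ...) {
  lab <- if (x$kind == "sem") "lambda" else "rho"
  cat(toupper(x$kind), "fit:", x$design$outcome, "~",
      length(x$beta) - 1, "covariates, n =", x$n, "\n")
  tab <- data.frame(estimate = x$beta, se = x$se, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("%s = %.4f (se %.4f, p = %.3g)\n", lab, x$spatial_param,
              x$se_spatial, x$p_value_spatial))
  cat(sprintf("logL = %.2f  AIC = %.1f  LR vs OLS = %.2f (p = %.3g)  BP = %.2f (p = %.3g)\n",
              x$logL, x$aic, x$lr_test$statistic, x$lr_test$p_value,
              x$bp_studentized$statistic, x$bp_studentized$p_value))
  invisible(x)
}

#' Compare OLS and spatial model fits by AIC
#'
#' Fits must share the same data. The preferred model has the minimum AIC;
#' ties go to the model with fewer parameters.
#'
#' @param ... named fitted models (`ols_fit` / `spatial_fit` objects).
#' @return An object of class `model_comparison`: a data.frame of logL, k,
#'   AIC (and LR/BP where available) plus the name of the preferred model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) {
      if (inherits(f, "ols_fit")) "ols" else f$kind
    }, character(1))
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) stop("models were fitted on different n")
  k <- vapply(fits, function(f) {
    length(f$beta) + 1 + as.integer(inherits(f, "spatial_fit"))
  }, numeric(1))
  tab <- data.frame(
    model = names(fits),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    k = k,
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    lr_vs_ols = vapply(fits, function(f) {
      if (inherits(f, "spatial_fit")) f$lr_test$statistic else NA_real_
    }, numeric(1)),
    bp = vapply(fits, function(f) {
      if (!is.null(f$bp_studentized)) f$bp_studentized$statistic else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  o <- order(tab$aic, tab$k)
  structure(list(table = tab[o, ], preferred = tab$model[o][1]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 6)
  cat("preferred (min AIC):", x$preferred, "\n")
  invisible(x)
}
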