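#' Default district-style variable specifications
#'
#' Marginal means and standard deviations (percent units) for the screening
#' outcomes and covariates of the district system the package emulates: the
#' 640-district summary of cervical/breast screening and its socio-demographic
#' covariates. `obese` has no published district marginal; its spec here is a
#' synthetic stand-in (mean 20.6, SD 10) chosen from national survey
#' prevalence of overweight/obesity among women, and is flagged as such.
#'
#' @return data.frame with columns `name`, `mean`, `sd`, `clip`.
#' @export
district_variable_specs <- function() {
  data.frame(
    name = c("cervical_screening", "breast_screening", "literate",
             "currently_married", "hindu", "general_caste", "rural", "rich",
             "oral_contraception", "tobacco", "insurance",
             "multiple_partners", "parity_gt3", "alcohol", "obese"),
    mean = c(21.96, 9.66, 72.39, 71.96, 74.58, 21.77, 71.57, 38.71,
             14.13, 7.13, 18.96, 4.20, 13.14, 2.59, 20.60),
    sd = c(14.62, 8.47, 14.18, 5.54, 27.69, 18.29, 21.66, 24.26,
           12.26, 10.78, 20.13, 4.75, 7.58, 6.43, 10.00),
    clip = TRUE,
    synthetic = c(rep(FALSE, 14), TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate percent-scale covariates from marginal specifications
#'
#' Draws each column independently normal with the specified mean and SD,
#' optionally through a correlation matrix, then clips flagged columns to
#' [0, 100]. Clipping slightly biases means of columns whose mass lies near
#' the bounds; recovery tests should use unclipped outcomes (see
#' [simulate_outcome]).
#'
#' @param specs data.frame with columns `name`, `mean`, `sd` (> 0) and
#'   optionally `clip` (default TRUE); see [district_variable_specs].
#' @param n number of units (>= 2).
#' @param seed integer seed.
#' @param correlation optional positive-definite correlation matrix
#'   (columns in spec order); default independent columns.
#' @return data.frame of `n` rows, one numeric column per spec.
#' @export
simulate_covariates <- function(specs, n, seed = 1L, correlation = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (anyDuplicated(specs$name)) {
    stop("duplicate variable names: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  }
  if (any(specs$sd <= 0)) {
    stop("sd must be strictly positive for: ",
         paste(specs$name[specs$sd <= 0], collapse = ", "))
  }
  if (is.null(specs$clip)) specs$clip <- TRUE
  p <- nrow(specs)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(correlation)) {
    if (!isTRUE(all.equal(dim(correlation), c(p, p)))) {
      stop("correlation must be ", p, " x ", p)
    }
    L <- tryCatch(chol(correlation),
                  error = function(e) stop("correlation matrix is not positive definite"))
    Z <- Z %*% L
  }
  out <- data.frame(row.names = seq_len(n))
  for (j in seq_len(p)) {
    v <- specs$mean[j] + specs$sd[j] * Z[, j]
    if (isTRUE(specs$clip[j])) v <- pmin(100, pmax(0, v))
    out[[specs$name[j]]] <- v
  }
  out
}

#' Simulate an outcome under a known spatial data-generating process
#'
#' Three processes over a design matrix `X` (leading intercept column) and
#' row-standardized weights `W`, with i.i.d. Gaussian innovations of standard
#' deviation `noise_sd`:
#'
#' * `csr` (complete spatial randomness): `y = X beta + xi`
#' * `sem`: `y = X beta + (I - lambda W)^{-1} xi`
#' * `slm`: `y = (I - rho W)^{-1} (X beta + eps)`
#'
#' The spatial parameter must lie strictly inside the stationarity interval
#' of `W`. The outcome is never clipped: recovery tests need the stated
#' process exactly.
#'
#' @param W a row-standardized [spatial_weights].
#' @param X numeric design matrix whose first column is the intercept.
#' @param process one of `"csr"`, `"sem"`, `"slm"`.
#' @param beta coefficient vector (length `ncol(X)`), intercept first.
#' @param spatial_param lambda (sem) or rho (slm); ignored for csr.
#' @param noise_sd positive innovation standard deviation.
#' @param seed integer seed.
#' @return list with `y` (numeric outcome) and `truth` (a record of the
#'   process, beta, spatial parameter, noise_sd and seed).
#' @export
simulate_outcome <- function(W, X, process = c("csr", "sem", "slm"),
                             beta, spatial_param = 0, noise_sd = 1,
                             seed = 1L) {
  process <- match.arg(process)
  if (W$style != "row_standardized") stop("W must be row-standardized")
  n <- W$n
  if (!is.matrix(X) || nrow(X) != n) stop("X must be a matrix with ", n, " rows")
  if (length(beta) != ncol(X)) stop("beta length must match ncol(X)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (process != "csr") {
    iv <- stationary_interval(W)
    if (spatial_param <= iv[1] || spatial_param >= iv[2]) {
      stop("spatial_param ", spatial_param,
           " outside the stationarity interval (", format(iv[1]), ", ",
           format(iv[2]), ")")
    }
  }
  set.seed(seed)
  innov <- stats::rnorm(n, 0, noise_sd)
  mu <- as.numeric(X %*% beta)
  y <- switch(process,
    csr = mu + innov,
    sem = mu + solve(diag(n) - spatial_param * weights_matrix(W), innov),
    slm = as.numeric(solve(diag(n) - spatial_param * weights_matrix(W),
                           mu + innov))
  )
  list(y = as.numeric(y),
       truth = list(process = process, beta = beta,
                    spatial_param = if (process == "csr") 0 else spatial_param,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a complete synthetic district fixture
#'
#' Convenience wrapper producing a lattice [areal_table] with simulated
#' covariates and a spatially autocorrelated screening outcome: the
#' covariates come from [district_variable_specs] (outcome columns excluded),
#' and the named outcome is generated by [simulate_outcome] under the chosen
#' process with an intercept-plus-covariates linear predictor.
#'
#' @param rows,cols lattice dimensions (default 20 x 32, n = 640).
#' @param outcome name of the outcome variable to generate.
#' @param covariates covariate names used in the outcome's linear predictor.
#' @param process,spatial_param,noise_sd passed to [simulate_outcome].
#' @param beta coefficient vector (intercept first). The default (used when
#'   the default covariate list is kept) fixes the covariate effects to the
#'   district study's reported spatial-error estimates for cervical screening
#'   (e.g. +0.33 for wealth, -0.18 for oral contraception), so the fixture's
#'   effect sizes are on the scale of the system it emulates; for other
#'   covariate lists small random effects in [-0.3, 0.3] are drawn once from
#'   the seed.
#' @param seed integer seed.
#' @return list with `areas` (an [areal_table] whose attributes hold the
#'   covariates and the outcome), `weights` (row-standardized queen weights),
#'   and `truth`.
#' @export
district_fixture <- function(rows = 20, cols = 32,
                             outcome = "cervical_screening",
                             covariates = c("literate", "currently_married",
                                            "hindu", "general_caste", "rural",
                                            "rich", "oral_contraception",
                                            "tobacco", "insurance",
                                            "multiple_partners", "parity_gt3"),
                             process = "sem", spatial_param = 0.69,
                             noise_sd = 8, beta = NULL, seed = 1L) {
  specs <- district_variable_specs()
  specs <- specs[!specs$name %in% c("cervical_screening", "breast_screening"), ]
  lat <- make_lattice(rows, cols)
  W <- row_standardize(queen_weights(lat))
  covs <- simulate_covariates(specs, lat$n, seed = seed)
  X <- cbind(1, as.matrix(covs[, covariates, drop = FALSE]))
  if (is.null(beta)) {
    defaults <- c(literate = -0.068, currently_married = 0.302,
                  hindu = -0.083, general_caste = 0.083, rural = 0.156,
                  rich = 0.332, oral_contraception = -0.176,
                  tobacco = -0.014, insurance = 0.091,
                  multiple_partners = -0.182, parity_gt3 = -0.057,
                  alcohol = -0.005, obese = -0.285)
    if (all(covariates %in% names(defaults))) {
      beta <- c(10, unname(defaults[covariates]))
    } else {
      set.seed(seed + 1L)
      beta <- c(10, stats::runif(length(covariates), -0.3, 0.3))
    }
  }
  sim <- simulate_outcome(W, X, process = process, beta = beta,
                          spatial_param = spatial_param, noise_sd = noise_sd,
                          seed = seed + 2L)
  covs[[outcome]] <- sim$y
  areas <- areal_table(lat$unit_id, lat$geometry, covs)
  attr(areas, "lattice") <- attr(lat, "lattice")
  list(areas = areas, weights = W,
       truth = c(sim$truth, list(outcome = outcome, covariates = covariates)))
}
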