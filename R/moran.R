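#' Global Moran's I
#'
#' Computes `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with
#' `z_i = x_i - mean(x)` and S0 the aggregate of all stored weights. Values
#' near +1 indicate clustering of similar values, near -1 dispersion, and the
#' expectation under no autocorrelation is `-1/(n-1)`. Islands contribute
#' nothing (their rows are empty and their lag is 0).
#'
#' @param x numeric vector, one value per unit.
#' @param W a [spatial_weights] object.
#' @return numeric scalar Moran's I.
#' @export
moran <- function(x, W) {
  n <- W$n
  if (length(x) != n) stop("x must have length ", n)
  if (n - length(W$islands) < 3) stop("need at least 3 connected units")
  if (length(W$islands) == n) stop("all units are islands")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("x has zero variance; Moran's I is undefined")
  lag <- spatial_lag(W, z)
  (n / W$S0) * sum(z * lag) / ss
}

#' Monte-Carlo permutation test for global Moran's I
#'
#' Randomly permutes `x` across units `n_perm` times and compares the observed
#' statistic with the permutation distribution. The pseudo p-value is
#' `(M + 1) / (n_perm + 1)` where M counts permuted statistics at least as
#' extreme as the observed one. The default `"directional"` alternative counts
#' the tail on the side of the observed deviation from `-1/(n-1)`;
#' `"greater"` tests for clustering only, `"less"` for dispersion,
#' `"two.sided"` doubles the directional tail (capped at 1).
#'
#' @param x numeric vector, one value per unit.
#' @param W a [spatial_weights] object.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for reproducibility (optional).
#' @param alternative tail convention, see Details.
#' @return An object of class `moran_mc`: observed `I`, `expected_I`,
#'   permutation `z_score`, `p_sim`, `n_perm`, a `perm_summary` (mean, sd,
#'   min, max), the `alternative` and the `seed`.
#' @export
moran_mc <- function(x, W, n_perm = 999, seed = NULL,
                     alternative = c("directional", "greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n <- W$n
  obs <- moran(x, W)
  e_i <- -1 / (n - 1)
  z <- x - mean(x)
  ss <- sum(z^2)
  if (!is.null(seed)) set.seed(seed)
  Zp <- vapply(seq_len(n_perm), function(r) z[sample.int(n)], numeric(n))
  Wm <- weights_matrix(W, sparse = TRUE)
  perm <- (n / W$S0) * colSums(Zp * as.matrix(Wm %*% Zp)) / ss
  upper <- sum(perm >= obs)
  lower <- sum(perm <= obs)
  p <- switch(alternative,
    greater = (upper + 1) / (n_perm + 1),
    less = (lower + 1) / (n_perm + 1),
    directional = (min(if (obs >= e_i) upper else lower, n_perm) + 1) / (n_perm + 1),
    two.sided = min(1, 2 * (min(upper, lower) + 1) / (n_perm + 1))
  )
  structure(list(I = obs, expected_I = e_i,
                 z_score = (obs - mean(perm)) / stats::sd(perm),
                 p_sim = p, n_perm = n_perm, alternative = alternative,
                 perm_summary = list(mean = mean(perm), sd = stats::sd(perm),
                                     min = min(perm), max = max(perm)),
                 seed = seed, n = n),
            class = "moran_mc")
}

#' @export
print.moran_mc <- function(x, ...) {
  cat("Moran's I permutation test (", x$n_perm, " permutations, ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("I = %.4f  E[I] = %.4f  z = %.2f  p_sim = %.4g\n",
              x$I, x$expected_I, x$z_score, x$p_sim))
  invisible(x)
}

#' Local Moran's I (LISA)
#'
#' Per-unit decomposition of global Moran's I. The primary `"scaled"` form is
#' `I_i = (z_i / m2) * sum_j w_ij z_j` with `m2 = sum(z^2) / n`, whose sum
#' over units equals `S0 * I`. The `"z"` form drops the `1/m2` scaling:
#' `I_i = z_i * sum_j w_ij z_j`. Positive values flag clustering of similar
#' values around unit i, negative values dissimilar neighbors. Islands get 0.
#'
#' @param x numeric vector, one value per unit.
#' @param W a [spatial_weights] object.
#' @param form `"scaled"` (default) or `"z"`.
#' @return numeric vector of local statistics with attribute `"island"`
#'   (logical vector).
#' @export
local_moran <- function(x, W, form = c("scaled", "z")) {
  form <- match.arg(form)
  n <- W$n
  if (length(x) != n) stop("x must have length ", n)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop("x has zero variance; local Moran is undefined")
  lag <- spatial_lag(W, z)
  li <- if (form == "scaled") z * lag / m2 else z * lag
  attr(li, "island") <- lengths(W$neighbors) == 0L
  attr(li, "form") <- form
  li
}

# deterministic per-unit RNG substream: results do not depend on the order in
# which units are processed
.unit_seed <- function(seed, i) {
  (as.integer(seed) + 1000003L * as.integer(i)) %% 2147483647L
}

#' Conditional permutation inference for local Moran (LISA)
#'
#' For each unit i the value `z_i` is held fixed and `n_perm` random
#' assignments of the remaining n-1 values to its neighbor positions are
#' drawn; the local statistic is recomputed for each draw and a one-sided
#' pseudo p-value is taken toward the observed side of the permutation
#' distribution. Each unit uses its own seeded RNG substream, so results are
#' independent of unit processing order. Units are classified into Moran
#' scatter-plot quadrants from the signs of the centered value and the
#' centered spatial lag: HH and LL are clusters of similar values, HL and LH
#' are spatial outliers. Labels keep the quadrant where `p_sim < alpha` and
#' are `"NS"` otherwise; islands are always NS.
#'
#' @param x numeric vector, one value per unit.
#' @param W a [spatial_weights] object.
#' @param n_perm number of conditional permutations per unit (default 999).
#' @param alpha per-unit significance level for labeling (default 0.05).
#' @param seed integer seed.
#' @param form local statistic form passed to [local_moran].
#' @param p_adjust optional multiple-testing correction for the labels (a
#'   method name for [stats::p.adjust], e.g. `"fdr"`); default none, matching
#'   the raw per-unit convention.
#' @return An object of class `lisa`: `local_i`, `quadrant`, `p_sim`, `label`,
#'   plus `alpha`, `n_perm`, `form`, `seed`, `is_island`.
#' @export
lisa_mc <- function(x, W, n_perm = 999, alpha = 0.05, seed = 1L,
                    form = c("scaled", "z"), p_adjust = NULL) {
  form <- match.arg(form)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n <- W$n
  li <- local_moran(x, W, form = form)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(W, z)
  quadrant <- ifelse(z > 0, ifelse(lag > 0, "HH", "HL"),
                             ifelse(lag > 0, "LH", "LL"))
  island <- lengths(W$neighbors) == 0L
  p_sim <- rep(NA_real_, n)
  scale_i <- if (form == "scaled") 1 / m2 else 1
  for (i in seq_len(n)) {
    if (island[i]) next
    nb <- W$neighbors[[i]]
    w <- W$weights[[i]]
    k <- length(nb)
    zo <- z[-i]
    set.seed(.unit_seed(seed, i))
    draws <- vapply(seq_len(n_perm), function(r) sample.int(n - 1L, k),
                    integer(k))
    lag_perm <- if (k == 1) w * zo[draws] else as.vector(w %*% matrix(zo[draws], k))
    perm <- scale_i * z[i] * lag_perm
    obs <- li[i]
    m <- if (obs >= mean(perm)) sum(perm >= obs) else sum(perm <= obs)
    p_sim[i] <- (m + 1) / (n_perm + 1)
  }
  p_lab <- p_sim
  if (!is.null(p_adjust)) p_lab <- stats::p.adjust(p_sim, method = p_adjust)
  label <- ifelse(island | is.na(p_lab) | p_lab >= alpha, "NS", quadrant)
  structure(list(local_i = as.numeric(li), quadrant = quadrant, p_sim = p_sim,
                 label = label, alpha = alpha, n_perm = n_perm, form = form,
                 seed = seed, is_island = island),
            class = "lisa")
}

#' @export
print.lisa <- function(x, ...) {
  cat("LISA (", x$form, " form, ", x$n_perm, " conditional permutations, alpha = ",
      x$alpha, ")\n", sep = "")
  print(table(factor(x$label, levels = c("HH", "LL", "HL", "LH", "NS"))))
  invisible(x)
}

#' Export LISA results as a data.frame
#' @param lisa a `lisa` object from [lisa_mc].
#' @param unit_id optional character ids.
#' @return data.frame with unit_id, local_i, p_sim, quadrant, label.
#' @export
lisa_table <- function(lisa, unit_id = NULL) {
  n <- length(lisa$local_i)
  data.frame(unit_id = if (is.null(unit_id)) seq_len(n) else unit_id,
             local_i = lisa$local_i, p_sim = lisa$p_sim,
             quadrant = lisa$quadrant, label = lisa$label,
             stringsAsFactors = FALSE)
}
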