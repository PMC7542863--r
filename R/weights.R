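#' Spatial weights objects
#'
#' A `spatial_weights` object stores a sparse neighbor structure: per-unit
#' ordered neighbor index lists with aligned weights, the weighting style
#' (`"binary"` or `"row_standardized"`), the aggregate weight S0, and the
#' indices of islands (units with no neighbors). Binary weights are symmetric
#' with all weights 1; row-standardized weights divide each non-island row by
#' its degree so rows sum to 1.
#'
#' @param ids character unit ids.
#' @param neighbors list of integer neighbor-index vectors (sorted ascending).
#' @param weights list of numeric weight vectors aligned to `neighbors`.
#' @param style `"binary"` or `"row_standardized"`.
#' @return object of class `spatial_weights`.
#' @export
spatial_weights <- function(ids, neighbors, weights, style = "binary") {
  n <- length(ids)
  if (length(neighbors) != n || length(weights) != n) {
    stop("neighbors and weights must have one entry per unit")
  }
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) != length(weights[[i]])) stop("neighbor/weight length mismatch at unit ", i)
    if (any(nb == i)) stop("self-neighbor at unit ", i)
    o <- order(nb)
    neighbors[[i]] <- as.integer(nb[o])
    weights[[i]] <- as.numeric(weights[[i]][o])
  }
  islands <- which(vapply(neighbors, length, integer(1)) == 0L)
  S0 <- sum(unlist(weights, use.names = FALSE))
  structure(list(n = n, ids = as.character(ids), neighbors = neighbors,
                 weights = weights, style = style, S0 = S0,
                 islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("spatial_weights:", x$n, "units, style =", x$style,
      ", S0 =", format(x$S0), "\n")
  cat("links:", sum(deg), " islands:", length(x$islands), "\n")
  invisible(x)
}

# min distance from points (m x 2) to one segment (a, b)
.pts_seg_dist <- function(pts, a, b) {
  d <- b - a
  len2 <- sum(d * d)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * d[1]
  py <- a[2] + t * d[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# minimum distance between the boundaries of two units
.boundary_distance <- function(rings_a, rings_b) {
  pts_a <- do.call(rbind, rings_a)
  pts_b <- do.call(rbind, rings_b)
  best <- Inf
  for (r in rings_b) {
    for (k in seq_len(nrow(r) - 1)) {
      best <- min(best, min(.pts_seg_dist(pts_a, r[k, ], r[k + 1, ])))
      if (best == 0) return(0)
    }
  }
  for (r in rings_a) {
    for (k in seq_len(nrow(r) - 1)) {
      best <- min(best, min(.pts_seg_dist(pts_b, r[k, ], r[k + 1, ])))
      if (best == 0) return(0)
    }
  }
  best
}

#' Build queen-contiguity spatial weights
#'
#' Two units are neighbors when at least one point of one boundary lies within
#' `snap` of the other boundary, so shared edges and single shared corners both
#' qualify. The result is binary and symmetric. Islands are recorded and
#' reported with a warning.
#'
#' @param areas an [areal_table] with at least two units.
#' @param snap nonnegative snap distance in map units. Default `1e-7`.
#' @return A binary [spatial_weights] object.
#' @export
queen_weights <- function(areas, snap = 1e-7) {
  n <- areas$n
  if (n < 2) stop("need at least two units to build weights")
  if (snap < 0) stop("snap must be nonnegative")
  rings <- lapply(areas$geometry, .unit_rings)
  bb <- t(vapply(areas$geometry, .unit_bbox, numeric(4)))
  nbr <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n - 1)) {
    # bbox prefilter: boundaries cannot come within snap if boxes are farther
    js <- which(bb[, 1] <= bb[i, 3] + snap & bb[, 3] >= bb[i, 1] - snap &
                bb[, 2] <= bb[i, 4] + snap & bb[, 4] >= bb[i, 2] - snap)
    js <- js[js > i]
    for (j in js) {
      if (.boundary_distance(rings[[i]], rings[[j]]) <= snap) {
        nbr[[i]] <- c(nbr[[i]], j)
        nbr[[j]] <- c(nbr[[j]], i)
      }
    }
  }
  W <- spatial_weights(areas$unit_id, nbr,
                       lapply(nbr, function(x) rep(1, length(x))),
                       style = "binary")
  if (length(W$islands) > 0) {
    warning(length(W$islands), " island unit(s) with no neighbors: ",
            paste(W$ids[W$islands], collapse = ", "))
  }
  W
}

#' Row-standardize spatial weights
#'
#' Divides each non-island row by its row sum so rows sum to 1; island rows
#' stay empty and are excluded from S0. Applying it twice is a no-op.
#'
#' @param W a [spatial_weights] object.
#' @return A row-standardized [spatial_weights] object.
#' @export
row_standardize <- function(W) {
  wts <- lapply(W$weights, function(w) {
    if (length(w) == 0) w else w / sum(w)
  })
  out <- spatial_weights(W$ids, W$neighbors, wts, style = "row_standardized")
  out
}

#' Spatial lag of a vector
#'
#' Computes `(Wx)_i = sum_j w_ij x_j`; islands get 0.
#'
#' @param W a [spatial_weights] object.
#' @param x numeric vector of length `W$n`.
#' @return numeric vector of spatial lags.
#' @export
spatial_lag <- function(W, x) {
  if (length(x) != W$n) stop("x must have length ", W$n)
  vapply(seq_len(W$n), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0) 0 else sum(W$weights[[i]] * x[nb])
  }, numeric(1))
}

#' Dense matrix form of spatial weights
#' @param W a [spatial_weights] object.
#' @param sparse return a `Matrix::sparseMatrix` instead of a base matrix.
#' @return n x n weight matrix.
#' @export
weights_matrix <- function(W, sparse = FALSE) {
  i <- rep.int(seq_len(W$n), lengths(W$neighbors))
  j <- unlist(W$neighbors, use.names = FALSE)
  v <- unlist(W$weights, use.names = FALSE)
  if (sparse) {
    Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(W$n, W$n))
  } else {
    m <- matrix(0, W$n, W$n)
    m[cbind(i, j)] <- v
    m
  }
}

#' Stationarity interval for the spatial autoregressive parameter
#'
#' Returns `(1/omega_min, 1/omega_max)` from the extreme real eigenvalues of
#' the weight matrix; for row-standardized weights the upper bound is 1 (the
#' Perron root of a row-stochastic matrix). The spatial parameter of an SEM or
#' SLM must lie strictly inside this interval for `I - par * W` to stay
#' invertible along the autoregressive family.
#'
#' @param W a [spatial_weights] object.
#' @return numeric length-2 `(lower, upper)`.
#' @export
stationary_interval <- function(W) {
  if (W$n < 2) stop("need at least two units")
  if (length(W$islands) == W$n) stop("all units are islands")
  ev <- weights_spectrum(W)
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  c(lo, hi)
}

#' Real eigenvalue spectrum of the weight matrix
#'
#' Used by the concentrated log-likelihood of the spatial models
#' (`log|I - p W| = sum(log(1 - p * omega))`). Row-standardized weights built
#' from a symmetric binary matrix are similar to a symmetric matrix, so the
#' spectrum is real; tiny imaginary parts from the general eigensolver are
#' dropped. The spectrum is cached on the object by [cache_spectrum].
#'
#' @param W a [spatial_weights] object.
#' @return numeric vector of n eigenvalues, decreasing.
#' @export
weights_spectrum <- function(W) {
  if (!is.null(W$spectrum)) return(W$spectrum)
  m <- weights_matrix(W)
  ev <- eigen(m, only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-8 * max(1, max(abs(Re(ev))))) {
      warning("weight matrix has notably complex eigenvalues; using real parts")
    }
    ev <- Re(ev)
  }
  sort(ev, decreasing = TRUE)
}

#' Attach the eigenvalue spectrum to a weights object
#'
#' Computing the spectrum is the one O(n^3) step of the spatial-model fits;
#' caching it lets repeated fits on the same weights reuse it.
#'
#' @param W a [spatial_weights] object.
#' @return `W` with a `spectrum` element.
#' @export
cache_spectrum <- function(W) {
  W$spectrum <- weights_spectrum(W)
  W
}

#' Drop units from a weights object
#'
#' Re-extracts the binary adjacency restricted to `keep` and reapplies the
#' original style. Used by the model fitters to remove islands.
#'
#' @param W a [spatial_weights] object.
#' @param keep integer indices of units to retain.
#' @return A [spatial_weights] object on the retained units.
#' @export
subset_weights <- function(W, keep) {
  keep <- sort(unique(as.integer(keep)))
  idx <- match(seq_len(W$n), keep)   # old -> new
  nbr <- lapply(keep, function(i) {
    nb <- idx[W$neighbors[[i]]]
    as.integer(nb[!is.na(nb)])
  })
  Wb <- spatial_weights(W$ids[keep], nbr,
                        lapply(nbr, function(x) rep(1, length(x))),
                        style = "binary")
  if (W$style == "row_standardized") row_standardize(Wb) else Wb
}

#' Write spatial weights in GAL format
#'
#' Standard GAL: a header line with the unit count, then for each unit a line
#' `id k` followed by a line of its k neighbor ids (empty line for islands).
#' The weighting style is recorded in a leading comment.
#'
#' @param W a [spatial_weights] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(W, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("!style ", W$style), con)
  writeLines(as.character(W$n), con)
  for (i in seq_len(W$n)) {
    nb <- W$neighbors[[i]]
    writeLines(paste(W$ids[i], length(nb)), con)
    writeLines(paste(W$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read spatial weights from GAL format
#'
#' Reads the neighbor structure written by [write_gal] (binary weights; the
#' recorded style is reapplied). Malformed files raise an error naming the
#' offending line.
#'
#' @param path GAL file path.
#' @return A [spatial_weights] object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  style <- "binary"
  ln <- 1L
  while (ln <= length(lines) && startsWith(lines[ln], "!")) {
    if (startsWith(lines[ln], "!style ")) style <- sub("^!style ", "", lines[ln])
    ln <- ln + 1L
  }
  if (ln > length(lines)) stop("GAL: missing header line")
  header <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[length(header)]))
  if (is.na(n) || n < 1) stop("GAL: bad unit count on line ", ln)
  ln <- ln + 1L
  ids <- character(n)
  raw_nbr <- vector("list", n)
  for (i in seq_len(n)) {
    if (ln > length(lines)) stop("GAL: truncated at line ", ln)
    hd <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(hd) != 2) stop("GAL: expected 'id count' on line ", ln)
    ids[i] <- hd[1]
    k <- suppressWarnings(as.integer(hd[2]))
    if (is.na(k) || k < 0) stop("GAL: bad neighbor count on line ", ln)
    ln <- ln + 1L
    if (k == 0) {
      # islands may have an empty line or none at all before the next record
      if (ln <= length(lines) && trimws(lines[ln]) == "") ln <- ln + 1L
      raw_nbr[[i]] <- character(0)
    } else {
      if (ln > length(lines)) stop("GAL: truncated at line ", ln)
      nb <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(nb) != k) stop("GAL: expected ", k, " neighbors on line ", ln)
      raw_nbr[[i]] <- nb
      ln <- ln + 1L
    }
  }
  nbr <- lapply(raw_nbr, function(nb) {
    idx <- match(nb, ids)
    if (anyNA(idx)) stop("GAL: unknown neighbor id '", nb[is.na(idx)][1], "'")
    as.integer(idx)
  })
  Wb <- spatial_weights(ids, nbr,
                        lapply(nbr, function(x) rep(1, length(x))),
                        style = "binary")
  if (style == "row_standardized") row_standardize(Wb) else Wb
}
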