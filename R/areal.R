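#' Areal table: polygon units joined to a numeric attribute table
#'
#' The central data container of the package: a set of areal units (districts,
#' lattice cells), each with a unique string id, a polygon or multipolygon
#' geometry, and zero or more fully numeric attribute columns in percent units.
#'
#' Geometry is stored as a list, one element per unit; each element is a list
#' of polygon parts, and each part a list of rings, a ring being a closed
#' two-column coordinate matrix (first row equals last row). A single-part,
#' single-ring unit is an ordinary simple polygon.
#'
#' @param unit_id character vector of unique unit identifiers.
#' @param geometry list of geometries as described above, same length as
#'   `unit_id`.
#' @param attributes data.frame of numeric columns, one row per unit (may have
#'   zero columns).
#' @return An object of class `areal_table` with elements `unit_id`,
#'   `geometry`, `attributes` and `n`.
#' @export
areal_table <- function(unit_id, geometry, attributes = NULL) {
  unit_id <- as.character(unit_id)
  n <- length(unit_id)
  if (anyDuplicated(unit_id)) {
    stop("duplicate unit ids: ", paste(unique(unit_id[duplicated(unit_id)]), collapse = ", "))
  }
  if (length(geometry) != n) stop("geometry and unit_id lengths differ")
  if (is.null(attributes)) {
    attributes <- data.frame(row.names = seq_len(n))
  }
  if (nrow(attributes) != n) stop("attributes must have one row per unit")
  for (nm in names(attributes)) {
    if (!is.numeric(attributes[[nm]])) {
      stop("attribute column '", nm, "' is not numeric")
    }
  }
  structure(list(unit_id = unit_id, geometry = geometry,
                 attributes = attributes, n = n),
            class = "areal_table")
}

#' @export
print.areal_table <- function(x, ...) {
  cat("areal_table:", x$n, "units,", ncol(x$attributes), "attribute column(s)\n")
  if (ncol(x$attributes) > 0) {
    cat("attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  }
  invisible(x)
}

# closed square ring (counter-clockwise) with lower-left corner (x, y)
.square_ring <- function(x, y, s) {
  rbind(c(x, y), c(x + s, y), c(x + s, y + s), c(x, y + s), c(x, y))
}

#' Generate a square-lattice set of areal units
#'
#' Builds `rows * cols` axis-aligned square cells tiling a rectangle with no
#' gaps or overlaps. Cell ids are `"r{i}c{j}"` with row index i from 1 at the
#' bottom and column index j from 1 at the left. The default 20 x 32 lattice
#' has 640 cells, matching the number of districts in the study system this
#' package is designed around.
#'
#' @param rows,cols positive integer lattice dimensions.
#' @param cell_size positive cell edge length in map units.
#' @param origin numeric length-2, coordinates of the lower-left corner.
#' @return An [areal_table] with `rows * cols` units and no attributes.
#' @examples
#' lat <- make_lattice(3, 3)
#' lat$unit_id
#' @export
make_lattice <- function(rows = 20, cols = 32, cell_size = 1, origin = c(0, 0)) {
  if (length(rows) != 1 || length(cols) != 1 || rows < 1 || cols < 1 ||
      rows != floor(rows) || cols != floor(cols)) {
    stop("rows and cols must be positive integers")
  }
  if (rows * cols < 1) stop("empty lattice")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a positive real")
  }
  ids <- character(rows * cols)
  geom <- vector("list", rows * cols)
  k <- 0L
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      k <- k + 1L
      ids[k] <- sprintf("r%dc%d", i, j)
      ring <- .square_ring(origin[1] + (j - 1) * cell_size,
                           origin[2] + (i - 1) * cell_size, cell_size)
      geom[[k]] <- list(list(ring))
    }
  }
  out <- areal_table(ids, geom)
  attr(out, "lattice") <- c(rows = rows, cols = cols)
  out
}

# all rings of one unit as a single list of matrices
.unit_rings <- function(g) {
  unlist(g, recursive = FALSE)
}

# bounding box (xmin, ymin, xmax, ymax) of one unit
.unit_bbox <- function(g) {
  rings <- .unit_rings(g)
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Planar area of one areal unit (shoelace formula, holes subtracted)
#' @param areas an [areal_table].
#' @param i unit index.
#' @return numeric area in squared map units.
#' @export
unit_area <- function(areas, i) {
  parts <- areas$geometry[[i]]
  total <- 0
  for (part in parts) {
    for (k in seq_along(part)) {
      r <- part[[k]]
      x <- r[, 1]; y <- r[, 2]
      a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
      total <- total + if (k == 1) a else -a
    }
  }
  total
}
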