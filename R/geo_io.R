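#' @title GeoJSON and CSV input/output
#' @description Readers and writers for the formats the pipeline touches:
#'   GeoJSON FeatureCollections for geometry (and cluster/residual exports),
#'   CSV for attribute tables, GAL for weights (see [write_gal]).
#' @name geo_io
NULL

.ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
  # GeoJSON rings should be closed; close them if the source did not
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

.parse_geometry <- function(gj) {
  type <- gj$type
  if (is.null(type)) stop("feature has no geometry type")
  if (type == "Polygon") {
    list(lapply(gj$coordinates, .ring_to_matrix))
  } else if (type == "MultiPolygon") {
    lapply(gj$coordinates, function(part) lapply(part, .ring_to_matrix))
  } else {
    stop("unsupported geometry type: ", type)
  }
}

#' Read a GeoJSON FeatureCollection of polygons
#'
#' @param path file path to a GeoJSON file of Polygon/MultiPolygon features.
#' @param id_field property name holding the unit identifier.
#' @return An [areal_table] whose attribute table contains every numeric,
#'   non-id property found in the features.
#' @export
read_geojson <- function(path, id_field = "unit_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path)
  feats <- gj$features
  n <- length(feats)
  if (n == 0) stop("empty FeatureCollection: ", path)
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_field]]
    if (is.null(v)) stop("feature missing id field '", id_field, "'")
    as.character(v)
  }, character(1))
  geom <- lapply(feats, function(f) .parse_geometry(f$geometry))
  # collect numeric properties shared by all features
  prop_names <- setdiff(names(feats[[1]]$properties), id_field)
  attrs <- data.frame(row.names = seq_len(n))
  for (nm in prop_names) {
    vals <- lapply(feats, function(f) f$properties[[nm]])
    if (all(vapply(vals, function(v) is.null(v) || is.numeric(v), logical(1)))) {
      attrs[[nm]] <- vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
    }
  }
  areal_table(ids, geom, attrs)
}

.geometry_to_list <- function(g) {
  ring_list <- function(r) lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  if (length(g) == 1) {
    list(type = "Polygon", coordinates = lapply(g[[1]], ring_list))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(g, function(part) lapply(part, ring_list)))
  }
}

#' Write an areal table (or per-unit values) as GeoJSON
#'
#' @param areas an [areal_table].
#' @param path output file path.
#' @param properties optional data.frame of extra per-unit properties to merge
#'   with the attribute table (aligned by position).
#' @param id_field property name for the unit identifier.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(areas, path, properties = NULL, id_field = "unit_id") {
  props <- areas$attributes
  if (!is.null(properties)) {
    if (nrow(properties) != areas$n) stop("properties must have one row per unit")
    for (nm in names(properties)) props[[nm]] <- properties[[nm]]
  }
  feats <- lapply(seq_len(areas$n), function(i) {
    p <- list()
    p[[id_field]] <- areas$unit_id[i]
    for (nm in names(props)) p[[nm]] <- props[[nm]][i]
    list(type = "Feature",
         properties = p,
         geometry = .geometry_to_list(areas$geometry[[i]]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 12, pretty = FALSE)
  invisible(path)
}

#' Read areal units: join geometry to a CSV attribute table
#'
#' Performs an inner join of a GeoJSON polygon layer and a CSV attribute table
#' on `id_field`. Unmatched ids on either side are dropped with a warning that
#' lists them; zero matches, duplicated ids, or non-numeric attribute cells are
#' errors (missing values are never imputed).
#'
#' @param geometry_path GeoJSON file of Polygon/MultiPolygon features.
#' @param attribute_path CSV file with one row per unit.
#' @param id_field column/property name of the unit identifier in both files.
#' @return An [areal_table] restricted to the matched units, attributes taken
#'   from the CSV (all non-id columns).
#' @export
read_areas <- function(geometry_path, attribute_path, id_field = "unit_id") {
  geo <- read_geojson(geometry_path, id_field = id_field)
  if (!file.exists(attribute_path)) stop("file not found: ", attribute_path)
  tab <- utils::read.csv(attribute_path, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (!id_field %in% names(tab)) {
    stop("id field '", id_field, "' not present in ", attribute_path)
  }
  ids <- tab[[id_field]]
  if (anyDuplicated(ids)) {
    stop("duplicate ids in attribute table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  attr_cols <- setdiff(names(tab), id_field)
  num <- data.frame(row.names = seq_len(nrow(tab)))
  for (nm in attr_cols) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric value in attribute column '", nm, "', row ", bad[1],
           " (id ", ids[bad[1]], "): '", tab[[nm]][bad[1]], "'")
    }
    num[[nm]] <- v
  }
  matched <- intersect(geo$unit_id, ids)
  if (length(matched) == 0) stop("no ids match between geometry and attributes")
  orphan_geo <- setdiff(geo$unit_id, ids)
  orphan_tab <- setdiff(ids, geo$unit_id)
  if (length(orphan_geo) > 0) {
    warning(length(orphan_geo), " geometry unit(s) without attributes dropped: ",
            paste(utils::head(orphan_geo, 10), collapse = ", "))
  }
  if (length(orphan_tab) > 0) {
    warning(length(orphan_tab), " attribute row(s) without geometry dropped: ",
            paste(utils::head(orphan_tab, 10), collapse = ", "))
  }
  keep <- match(matched, geo$unit_id)
  rows <- match(matched, ids)
  out <- areal_table(geo$unit_id[keep], geo$geometry[keep],
                     num[rows, , drop = FALSE])
  attr(out, "unmatched") <- list(geometry = orphan_geo, attributes = orphan_tab)
  out
}

#' Write a LISA cluster map as GeoJSON
#'
#' Each feature carries the unit id, the local Moran statistic, its pseudo
#' p-value and the cluster label (one of HH, LL, HL, LH, NS).
#'
#' @param areas an [areal_table].
#' @param labels character vector of cluster labels, one per unit.
#' @param stats numeric vector of local statistics, one per unit.
#' @param p_values numeric vector of pseudo p-values, one per unit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_geojson <- function(areas, labels, stats, p_values, path) {
  if (length(labels) != areas$n || length(stats) != areas$n ||
      length(p_values) != areas$n) {
    stop("labels, stats and p_values must all have length ", areas$n)
  }
  ok <- labels %in% c("HH", "LL", "HL", "LH", "NS")
  if (!all(ok)) stop("invalid cluster label: ", labels[!ok][1])
  bare <- areal_table(areas$unit_id, areas$geometry)
  write_geojson(bare, path,
                properties = data.frame(local_i = as.numeric(stats),
                                        p_sim = as.numeric(p_values),
                                        label = labels,
                                        stringsAsFactors = FALSE))
}

#' Read back a LISA cluster GeoJSON
#'
#' Inverse of [write_cluster_geojson] for the per-unit table: returns the
#' unit ids, local statistics, pseudo p-values and labels (geometry is not
#' re-materialized).
#'
#' @param path GeoJSON file written by [write_cluster_geojson].
#' @param id_field property name of the unit identifier.
#' @return data.frame with columns `unit_id`, `local_i`, `p_sim`, `label`.
#' @export
read_cluster_geojson <- function(path, id_field = "unit_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    data.frame(unit_id = as.character(p[[id_field]]),
               local_i = as.numeric(p$local_i),
               p_sim = if (is.null(p$p_sim)) NA_real_ else as.numeric(p$p_sim),
               label = as.character(p$label), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
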