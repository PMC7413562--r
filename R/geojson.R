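# GeoJSON interchange for polygon layers, on top of jsonlite.
#
# A HOLC layer is a list with elements
#   polygons: list of GradedPolygon records
#             (polygon_id, grade, metro, geometry = polygon)
#   boundary: named list, metro label -> boundary polygon (the per-metro map
#             boundary that defines the NG / outside distinction)
# A tract layer is a list with element
#   tracts: list of (tract_id, geometry, metrics = named numeric list)

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))[1:2]))
  # drop the closing vertex if present
  if (nrow(m) > 3 && isTRUE(all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)))
    m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

geom_to_geojson <- function(poly) {
  list(type = "Polygon", coordinates = lapply(poly, ring_to_coords))
}

geojson_to_geom <- function(geom) {
  if (identical(geom$type, "Polygon")) {
    lapply(geom$coordinates, coords_to_ring)
  } else if (identical(geom$type, "MultiPolygon")) {
    # flatten: the pipeline only needs areas/containment, and all rings of
    # all parts participate identically; keep first part's outer first
    rings <- list()
    for (part in geom$coordinates) for (cr in part)
      rings[[length(rings) + 1L]] <- coords_to_ring(cr)
    rings
  } else stop("unsupported geometry type: ", geom$type)
}

#' Write a HOLC polygon layer to GeoJSON
#'
#' Grades, identifiers and metro labels become feature properties; per-metro
#' map-boundary polygons are written as features with `role = "map_boundary"`.
#'
#' @param layer a HOLC layer (list with `polygons` and `boundary`).
#' @param path output file path.
#' @export
write_holc_geojson <- function(layer, path) {
  feats <- lapply(layer$polygons, function(p) list(
    type = "Feature",
    properties = list(polygon_id = p$polygon_id, grade = p$grade, metro = p$metro),
    geometry = geom_to_geojson(p$geometry)))
  for (m in names(layer$boundary)) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(role = "map_boundary", metro = m),
      geometry = geom_to_geojson(layer$boundary[[m]]))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a HOLC polygon layer from GeoJSON
#'
#' @param path GeoJSON file written by [write_holc_geojson()] or any
#'   FeatureCollection with `polygon_id`/`grade`/`metro` properties and
#'   `role = "map_boundary"` boundary features.
#' @return A HOLC layer list.
#' @export
read_holc_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polygons <- list(); boundary <- list()
  for (f in gj$features) {
    props <- f$properties
    if (identical(props$role, "map_boundary")) {
      boundary[[props$metro]] <- geojson_to_geom(f$geometry)
    } else {
      polygons[[length(polygons) + 1L]] <- list(
        polygon_id = props$polygon_id,
        grade = props$grade,
        metro = if (is.null(props$metro)) "ALL" else props$metro,
        geometry = geojson_to_geom(f$geometry))
    }
  }
  ids <- vapply(polygons, `[[`, "", "polygon_id")
  if (anyDuplicated(ids)) stop("duplicate polygon_id in layer: ", ids[duplicated(ids)][1])
  list(polygons = polygons, boundary = boundary)
}

#' Write a 1940 census tract layer to GeoJSON
#'
#' @param tracts list with element `tracts` (each `tract_id`, `geometry`,
#'   `metrics` named numeric list).
#' @param path output file path.
#' @export
write_tract_geojson <- function(tracts, path) {
  feats <- lapply(tracts$tracts, function(tr) list(
    type = "Feature",
    properties = c(list(tract_id = tr$tract_id), as.list(tr$metrics)),
    geometry = geom_to_geojson(tr$geometry)))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 1940 census tract layer from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with a `tract_id` property; all other
#'   numeric properties are taken as tract metrics.
#' @return A tract layer list.
#' @export
read_tract_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  tracts <- lapply(gj$features, function(f) {
    props <- f$properties
    metrics <- props[setdiff(names(props), "tract_id")]
    list(tract_id = props$tract_id,
         geometry = geojson_to_geom(f$geometry),
         metrics = vapply(metrics, as.numeric, 0))
  })
  list(tracts = tracts)
}
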