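# Areal apportionment of 1940 census tract metrics onto HOLC polygons.
#
# Each (HOLC polygon, tract) pair with positive intersection area gets an
# overlap weight = intersection area / HOLC polygon area (the *target*
# polygon's area is the denominator). Areal-weighted metrics are
# sum(weight * tract metric), applied uniformly to counts, median home value
# and population density; derived rates are ratios of weighted numerators to
# weighted denominators.

# metrics every tract must carry
TRACT_COUNT_FIELDS <- c(
  "total_pop", "white", "nonwhite", "foreign_born_white", "black", "employed",
  "total_homes", "homes_major_repairs", "homes_radio", "homes_no_radio",
  "homes_refrigerator", "homes_no_refrigerator", "homes_heating",
  "homes_no_heating", "edu_no_hs", "edu_hs", "edu_some_college",
  "edu_college", "housing_units")
TRACT_VALUE_FIELDS <- c(TRACT_COUNT_FIELDS, "median_home_value")

#' Compute overlap weights between HOLC polygons and census tracts
#'
#' Intersects every HOLC polygon with every census tract (bounding-box
#' pre-filtered) and records, for each pair with positive intersection area,
#' the weight = intersection area / HOLC polygon area. Intersections smaller
#' than `sliver_tol` times the HOLC polygon area are dropped as slivers.
#'
#' @param holc a HOLC layer (see [read_holc_geojson()]) or a bare list of
#'   GradedPolygon records.
#' @param tracts a tract layer (see [read_tract_geojson()]).
#' @param sliver_tol relative-area tolerance below which an intersection is
#'   discarded.
#' @return A data.frame with columns `polygon_id`, `tract_id`,
#'   `overlap_area`, `weight`.
#' @export
compute_overlaps <- function(holc, tracts, sliver_tol = 1e-10) {
  polys <- if (!is.null(holc$polygons)) holc$polygons else holc
  trs <- if (!is.null(tracts$tracts)) tracts$tracts else tracts
  if (length(polys) == 0L) stop("empty HOLC layer")
  tb <- t(vapply(trs, function(tr) poly_bbox(tr$geometry), numeric(4)))
  rows <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    pa <- poly_area(p$geometry)
    if (!is.finite(pa) || pa <= 0)
      stop("invalid geometry (non-positive area) for polygon ", p$polygon_id)
    bb <- poly_bbox(p$geometry)
    cand <- which(tb[, "xmin"] < bb["xmax"] & tb[, "xmax"] > bb["xmin"] &
                  tb[, "ymin"] < bb["ymax"] & tb[, "ymax"] > bb["ymin"])
    if (!length(cand)) next
    areas <- vapply(cand, function(j)
      poly_intersection_area(p$geometry, trs[[j]]$geometry), 0)
    keep <- areas > sliver_tol * pa
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      polygon_id = p$polygon_id,
      tract_id = vapply(trs[cand[keep]], `[[`, "", "tract_id"),
      overlap_area = areas[keep],
      weight = areas[keep] / pa,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(polygon_id = character(), tract_id = character(),
                      overlap_area = numeric(), weight = numeric())
  rownames(out) <- NULL
  out[order(out$polygon_id, out$tract_id), , drop = FALSE]
}

#' Apportion tract metrics onto HOLC polygons by overlap weight
#'
#' Every tract metric (counts, median home value, and tract population
#' density alike) is multiplied by its overlap weight and summed per HOLC
#' polygon. Derived rates are computed from the weighted numerators and
#' denominators, e.g. `pct_radio = 100 * weighted homes_radio / weighted
#' total_homes`. Weight sums below 1 (partial tract coverage) are *not*
#' renormalised; the coverage fraction is reported per polygon.
#'
#' @param overlaps overlap table from [compute_overlaps()].
#' @param tracts tract layer whose tracts carry `metrics` (all of
#'   `TRACT_VALUE_FIELDS`) and a geometry (for population density).
#' @return A data.frame keyed by `polygon_id` with areal-weighted metrics,
#'   derived percentage rates, `population_density`,
#'   `persons_per_housing_unit` and `coverage` (sum of overlap weights).
#' @export
apportion_metrics <- function(overlaps, tracts) {
  trs <- if (!is.null(tracts$tracts)) tracts$tracts else tracts
  tid <- vapply(trs, `[[`, "", "tract_id")
  miss <- setdiff(unique(overlaps$tract_id), tid)
  if (length(miss)) stop("overlap references tract without metrics: ", miss[1])
  met <- t(vapply(trs, function(tr) {
    v <- tr$metrics[TRACT_VALUE_FIELDS]
    if (anyNA(v)) stop("tract ", tr$tract_id, " missing metric fields")
    as.numeric(v)
  }, numeric(length(TRACT_VALUE_FIELDS))))
  colnames(met) <- TRACT_VALUE_FIELDS
  tarea <- vapply(trs, function(tr) poly_area(tr$geometry), 0)
  if (any(tarea <= 0)) stop("tract with non-positive area")
  dens <- met[, "total_pop"] / tarea
  row_of <- match(overlaps$tract_id, tid)
  pids <- sort(unique(overlaps$polygon_id))
  out <- matrix(0, length(pids), ncol(met) + 2,
                dimnames = list(pids, c(colnames(met), "population_density", "coverage")))
  for (r in seq_len(nrow(overlaps))) {
    i <- match(overlaps$polygon_id[r], pids)
    w <- overlaps$weight[r]
    j <- row_of[r]
    out[i, seq_len(ncol(met))] <- out[i, seq_len(ncol(met))] + w * met[j, ]
    out[i, "population_density"] <- out[i, "population_density"] + w * dens[j]
    out[i, "coverage"] <- out[i, "coverage"] + w
  }
  df <- as.data.frame(out)
  df <- cbind(polygon_id = pids, df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  rate <- function(num, den, label) {
    bad <- den <= 0
    if (any(bad)) warning("zero weighted denominator for ", label,
                          " in ", sum(bad), " polygon(s); rate set to NA")
    ifelse(bad, NA_real_, 100 * num / den)
  }
  edu_total <- df$edu_no_hs + df$edu_hs + df$edu_some_college + df$edu_college
  df$pct_nonwhite <- rate(df$nonwhite, df$total_pop, "pct_nonwhite")
  df$pct_black <- rate(df$black, df$total_pop, "pct_black")
  df$pct_foreign_born_white <- rate(df$foreign_born_white, df$total_pop, "pct_foreign_born_white")
  df$pct_employed <- rate(df$employed, df$total_pop, "pct_employed")
  df$pct_radio <- rate(df$homes_radio, df$total_homes, "pct_radio")
  df$pct_refrigerator <- rate(df$homes_refrigerator, df$total_homes, "pct_refrigerator")
  df$pct_heating <- rate(df$homes_heating, df$total_homes, "pct_heating")
  df$pct_major_repairs <- rate(df$homes_major_repairs, df$total_homes, "pct_major_repairs")
  df$pct_hs_educated <- rate(df$edu_hs + df$edu_some_college + df$edu_college,
                             edu_total, "pct_hs_educated")
  ppu_bad <- df$housing_units <= 0
  df$persons_per_housing_unit <- ifelse(ppu_bad, NA_real_, df$total_pop / df$housing_units)
  df
}

# covariate set used for propensity estimation ("all 1940s census variables")
AREAL_COVARIATES <- c(
  "total_pop", "total_homes", "median_home_value", "population_density",
  "persons_per_housing_unit", "pct_nonwhite", "pct_black",
  "pct_foreign_born_white", "pct_employed", "pct_radio", "pct_refrigerator",
  "pct_heating", "pct_major_repairs", "pct_hs_educated")

# the four covariates of the adjusted outcome models
MODEL_COVARIATES <- c("median_home_value", "pct_employed", "pct_radio", "pct_nonwhite")

# the seven covariates of the balance table
BALANCE_COVARIATES <- c("median_home_value", "pct_major_repairs",
                        "pct_hs_educated", "pct_nonwhite", "pct_employed",
                        "pct_radio", "pct_refrigerator")
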