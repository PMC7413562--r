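# Synthetic city generator: a rectangular grid of HOLC polygons with
# spatially smoothed grades, overlaid by an offset rectangular grid of 1940
# census tracts whose count metrics follow grade-dependent profiles.

#' Generate a synthetic city
#'
#' Builds an `n_cols` x `n_rows` grid of HOLC polygons with grades sampled
#' from `grade_probs` (with spatial smoothing: a cell copies an
#' already-assigned neighbour's grade with probability `grade_smoothing`,
#' which leaves the marginal grade distribution unchanged), plus a 1940
#' census tract grid offset by `tract_offset` so the two tessellations
#' genuinely misalign. Per-metro map-boundary polygons cover the full HOLC
#' grid.
#'
#' @param config a [sim_config()] object.
#' @return A `synthetic_city` list with elements `holc` (polygon layer),
#'   `tracts` (tract layer, metrics unfilled until
#'   [generate_tract_metrics()]), and `cell_size`.
#' @export
generate_city <- function(config) {
  validate_sim_config(config)
  cs <- config$cell_size
  off <- config$tract_offset
  if (abs(off %% cs) < 1e-12 || abs(off %% cs - cs) < 1e-12)
    stop("degenerate overlay: tract_offset must not be 0 or a whole cell width")
  if (off <= 0 || off >= cs)
    stop("tract_offset must lie strictly between 0 and one cell width")
  set.seed(stage_seed(config$seed, 1L))
  nc <- config$n_cols; nr <- config$n_rows
  # grades in row-major order with neighbour copying
  grades <- matrix(NA_character_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nbrs <- character(0)
    if (c > 1) nbrs <- c(nbrs, grades[r, c - 1])
    if (r > 1) nbrs <- c(nbrs, grades[r - 1, c])
    if (length(nbrs) && stats::runif(1) < config$grade_smoothing) {
      grades[r, c] <- nbrs[sample.int(length(nbrs), 1)]
    } else {
      grades[r, c] <- sample(GRADES, 1, prob = config$grade_probs)
    }
  }
  n_la_cols <- max(1L, min(nc - 1L, round(config$metro_split * nc)))
  polygons <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- k + 1L
    polygons[[k]] <- list(
      polygon_id = sprintf("p%04d", k),
      grade = grades[r, c],
      metro = if (c <= n_la_cols) "LA" else "SFOAK",
      geometry = hm_polygon(rect_ring((c - 1) * cs, (r - 1) * cs, c * cs, r * cs)))
  }
  boundary <- list(
    LA = hm_polygon(rect_ring(0, 0, n_la_cols * cs, nr * cs)),
    SFOAK = hm_polygon(rect_ring(n_la_cols * cs, 0, nc * cs, nr * cs)))
  if (n_la_cols >= nc) boundary$SFOAK <- NULL
  # tract grid: one extra ring of tiles so the HOLC grid is fully covered
  tracts <- list()
  tk <- 0L
  for (r in 0:nr) for (c in 0:nc) {
    x0 <- off - cs + c * cs
    y0 <- off - cs + r * cs
    tk <- tk + 1L
    tracts[[tk]] <- list(
      tract_id = sprintf("t%05d", tk),
      geometry = hm_polygon(rect_ring(x0, y0, x0 + cs, y0 + cs)),
      metrics = NULL)
  }
  structure(list(holc = list(polygons = polygons, boundary = boundary),
                 tracts = list(tracts = tracts),
                 cell_size = cs),
            class = "synthetic_city")
}

#' Fill 1940 tract metrics with grade-dependent confounding
#'
#' Each tract's generating profile is the area-weighted mix of the per-grade
#' metric profiles over the HOLC grades it overlaps; counts are drawn from
#' non-negative distributions around that profile (gamma totals, binomial
#' splits), so subcounts respect their totals by construction. Tracts that
#' overlap no HOLC polygon (the fringe ring) fall back to the NG profile.
#'
#' @param config a [sim_config()] object.
#' @param city a `synthetic_city` from [generate_city()].
#' @return The city with `tracts$tracts[[i]]$metrics` filled.
#' @export
generate_tract_metrics <- function(config, city) {
  validate_sim_config(config)
  mm <- config$metric_means_by_grade
  if (!all(GRADES %in% rownames(mm)))
    stop("configuration error: metric means missing for a present grade")
  set.seed(stage_seed(config$seed, 2L))
  cv <- config$metric_cv
  shape <- 1 / cv^2
  cfg_rate_sd <- if (is.null(config$metric_rate_sd)) 0.9 else config$metric_rate_sd
  # grade mix per tract from exact rectangle overlap areas
  pb <- t(vapply(city$holc$polygons, function(p) poly_bbox(p$geometry), numeric(4)))
  pg <- vapply(city$holc$polygons, `[[`, "", "grade")
  for (i in seq_along(city$tracts$tracts)) {
    tr <- city$tracts$tracts[[i]]
    bb <- poly_bbox(tr$geometry)
    cand <- which(pb[, "xmin"] < bb["xmax"] & pb[, "xmax"] > bb["xmin"] &
                  pb[, "ymin"] < bb["ymax"] & pb[, "ymax"] > bb["ymin"])
    wts <- stats::setNames(rep(0, 5), GRADES)
    for (j in cand) {
      a <- poly_intersection_area(tr$geometry, city$holc$polygons[[j]]$geometry)
      wts[pg[j]] <- wts[pg[j]] + a
    }
    if (sum(wts) <= 0) wts["NG"] <- 1
    wts <- wts / sum(wts)
    prof <- as.numeric(wts %*% mm[GRADES, , drop = FALSE])
    names(prof) <- colnames(mm)
    # census rates are heavily overdispersed between tracts: jitter each
    # profile rate on the logit scale before the binomial split
    rs <- cfg_rate_sd
    od <- function(pct) {
      p <- min(max(pct / 100, 1e-4), 1 - 1e-4)
      stats::plogis(stats::qlogis(p) + stats::rnorm(1, 0, rs))
    }
    pop <- max(1L, round(stats::rgamma(1, shape, scale = prof["total_pop"] / shape)))
    nonwhite <- stats::rbinom(1, pop, od(prof["pct_nonwhite"]))
    white <- pop - nonwhite
    black <- stats::rbinom(1, nonwhite, od(prof["pct_black_of_nonwhite"]))
    fbw <- stats::rbinom(1, white, od(prof["pct_fbw_of_white"]))
    employed <- stats::rbinom(1, pop, od(prof["pct_employed"]))
    homes <- max(1L, round(pop / prof["persons_per_home"] *
                             exp(stats::rnorm(1, 0, 0.2 * rs))))
    radio <- stats::rbinom(1, homes, od(prof["pct_radio"]))
    fridge <- stats::rbinom(1, homes, od(prof["pct_refrigerator"]))
    heat <- stats::rbinom(1, homes, od(prof["pct_heating"]))
    repairs <- stats::rbinom(1, homes, od(prof["pct_major_repairs"]))
    adults <- stats::rbinom(1, pop, od(prof["pct_adults"]))
    hs_plus <- stats::rbinom(1, adults, od(prof["pct_hs_educated"]))
    hs_split <- stats::rmultinom(1, hs_plus, c(0.55, 0.2, 0.25))
    mhv <- stats::rgamma(1, shape, scale = prof["median_home_value"] / shape)
    city$tracts$tracts[[i]]$metrics <- c(
      total_pop = pop, white = white, nonwhite = nonwhite,
      foreign_born_white = fbw, black = black, employed = employed,
      total_homes = homes, homes_major_repairs = repairs,
      homes_radio = radio, homes_no_radio = homes - radio,
      homes_refrigerator = fridge, homes_no_refrigerator = homes - fridge,
      homes_heating = heat, homes_no_heating = homes - heat,
      edu_no_hs = adults - hs_plus, edu_hs = hs_split[1],
      edu_some_college = hs_split[2], edu_college = hs_split[3],
      housing_units = homes, median_home_value = mhv)
  }
  city
}

#' Grade lookup table for a city
#'
#' @param city a `synthetic_city` (or any HOLC layer list).
#' @return data.frame with `polygon_id`, `grade`, `metro`.
#' @export
city_grades <- function(city) {
  polys <- if (!is.null(city$holc)) city$holc$polygons else city$polygons
  data.frame(polygon_id = vapply(polys, `[[`, "", "polygon_id"),
             grade = vapply(polys, `[[`, "", "grade"),
             metro = vapply(polys, `[[`, "", "metro"),
             stringsAsFactors = FALSE)
}
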