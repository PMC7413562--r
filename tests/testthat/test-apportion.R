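two_tract_layer <- function() {
  list(tracts = list(
    list(tract_id = "T1", geometry = hm_polygon(rect_ring(0, 0, 2, 1)),
         metrics = NULL),
    list(tract_id = "T2", geometry = hm_polygon(rect_ring(2, 0, 10, 1)),
         metrics = NULL)))
}

fill_metrics <- function(layer, values) {
  for (i in seq_along(layer$tracts)) {
    m <- rep(0, length(holcmatch:::TRACT_VALUE_FIELDS))
    names(m) <- holcmatch:::TRACT_VALUE_FIELDS
    for (nm in names(values[[i]])) m[nm] <- values[[i]][[nm]]
    layer$tracts[[i]]$metrics <- m
  }
  layer
}

test_that("the two-tract worked example yields overlap weights 0.2 and 0.8", {
  holc <- list(polygons = list(list(polygon_id = "H", grade = "C", metro = "LA",
                                    geometry = hm_polygon(rect_ring(0, 0, 10, 1)))))
  ov <- compute_overlaps(holc, two_tract_layer())
  expect_equal(ov$weight[ov$tract_id == "T1"], 0.2)
  expect_equal(ov$weight[ov$tract_id == "T2"], 0.8)
  expect_equal(sum(ov$weight), 1)
})

test_that("a tract identical to the polygon carries weight 1 and nested tracts conserve counts", {
  holc <- list(polygons = list(list(polygon_id = "H", grade = "C", metro = "LA",
                                    geometry = hm_polygon(rect_ring(0, 0, 3, 3)))))
  same <- list(tracts = list(list(tract_id = "T", geometry = hm_polygon(rect_ring(0, 0, 3, 3)))))
  ov <- compute_overlaps(holc, same)
  expect_equal(ov$weight, 1)
  # nested: two polygons each exactly one tract -> apportioned counts equal
  # tract counts, total population conserved
  holc2 <- list(polygons = list(
    list(polygon_id = "H1", grade = "C", metro = "LA",
         geometry = hm_polygon(rect_ring(0, 0, 1, 1))),
    list(polygon_id = "H2", grade = "D", metro = "LA",
         geometry = hm_polygon(rect_ring(1, 0, 2, 1)))))
  tl <- list(tracts = list(
    list(tract_id = "T1", geometry = hm_polygon(rect_ring(0, 0, 1, 1))),
    list(tract_id = "T2", geometry = hm_polygon(rect_ring(1, 0, 2, 1)))))
  tl <- fill_metrics(tl, list(list(total_pop = 120, total_homes = 30, housing_units = 30),
                              list(total_pop = 80, total_homes = 25, housing_units = 25)))
  am <- suppressWarnings(apportion_metrics(compute_overlaps(holc2, tl), tl))
  expect_equal(am$total_pop, c(120, 80))
  expect_equal(sum(am$total_pop), 200)
})

test_that("areal weighting of median home value follows the stated arithmetic", {
  holc <- list(polygons = list(list(polygon_id = "H", grade = "C", metro = "LA",
                                    geometry = hm_polygon(rect_ring(0, 0, 10, 1)))))
  tl <- fill_metrics(two_tract_layer(),
                     list(list(median_home_value = 10, total_pop = 100,
                               total_homes = 20, housing_units = 20),
                          list(median_home_value = 20, total_pop = 100,
                               total_homes = 20, housing_units = 20)))
  am <- suppressWarnings(apportion_metrics(compute_overlaps(holc, tl), tl))
  expect_equal(am$median_home_value, 0.2 * 10 + 0.8 * 20) # 18.0
})

test_that("identical tract metrics pass through unchanged under full coverage", {
  st <- small_study()
  tl <- st$city$tracts
  m <- tl$tracts[[1]]$metrics
  for (i in seq_along(tl$tracts)) tl$tracts[[i]]$metrics <- m
  ov <- compute_overlaps(st$city$holc, tl)
  am <- apportion_metrics(ov, tl)
  for (f in holcmatch:::TRACT_VALUE_FIELDS)
    expect_equal(am[[f]], rep(unname(m[f]), nrow(am)), tolerance = 1e-9)
})

test_that("overlap weights sum to one under full coverage on the synthetic city", {
  st <- small_study()
  ov <- compute_overlaps(st$city$holc, st$city$tracts)
  sums <- tapply(ov$weight, ov$polygon_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # interior polygons genuinely intersected by several tracts
  expect_true(all(tapply(ov$tract_id, ov$polygon_id, length) >= 2))
})

test_that("apportionment is linear and order-invariant", {
  st <- small_study()
  ov <- compute_overlaps(st$city$holc, st$city$tracts)
  tl <- st$city$tracts
  am1 <- apportion_metrics(ov, tl)
  tl2 <- tl
  for (i in seq_along(tl2$tracts)) tl2$tracts[[i]]$metrics <- 2 * tl2$tracts[[i]]$metrics
  am2 <- apportion_metrics(ov, tl2)
  expect_equal(am2$total_pop, 2 * am1$total_pop)
  expect_equal(am2$median_home_value, 2 * am1$median_home_value)
  # shuffled overlap rows give identical output
  set.seed(1)
  am3 <- apportion_metrics(ov[sample(nrow(ov)), ], tl)
  expect_equal(am3, am1)
})

test_that("weighted values stay inside the convex hull of contributing tracts", {
  st <- small_study()
  ov <- compute_overlaps(st$city$holc, st$city$tracts)
  am <- apportion_metrics(ov, st$city$tracts)
  mhv <- vapply(st$city$tracts$tracts, function(tr) tr$metrics[["median_home_value"]], 0)
  names(mhv) <- vapply(st$city$tracts$tracts, `[[`, "", "tract_id")
  for (i in seq_len(nrow(am))) {
    tids <- ov$tract_id[ov$polygon_id == am$polygon_id[i]]
    expect_gte(am$median_home_value[i], min(mhv[tids]) - 1e-9)
    expect_lte(am$median_home_value[i], max(mhv[tids]) + 1e-9)
  }
  expect_true(all(am$pct_nonwhite >= 0 & am$pct_nonwhite <= 100))
  expect_true(all(am$pct_radio >= 0 & am$pct_radio <= 100))
})

test_that("zero weighted denominators warn and record missing rates", {
  holc <- list(polygons = list(list(polygon_id = "H", grade = "C", metro = "LA",
                                    geometry = hm_polygon(rect_ring(0, 0, 1, 1)))))
  tl <- list(tracts = list(list(tract_id = "T", geometry = hm_polygon(rect_ring(0, 0, 1, 1)))))
  tl <- fill_metrics(tl, list(list(median_home_value = 5)))
  w <- capture_warnings(am <- apportion_metrics(compute_overlaps(holc, tl), tl))
  expect_true(any(grepl("zero weighted denominator", w)))
  expect_true(is.na(am$pct_radio))
})
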