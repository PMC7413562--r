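# Synthetic birth cohort generator.
#
# Outcome indicators are generated from logistic models
#   logit P(outcome) = intercept + cumulative grade effect
#                    + confounder_coefs . (centred areal-weighted metrics of
#                      the birth's polygon)
#                    + maternal covariate terms,
# for each outcome independently, and the continuous fields (gestational
# days, birth weight, death timing) are then drawn *conditionally* on the
# generated indicators so that the downstream outcome coding recovers them
# exactly (SGA is the exception: it is injected as a birth-weight shift, see
# the methods vignette).

# conditional draws used to realise the binary indicators as continuous fields
rtrunc_days <- function(n, lo, hi, peak_hi = TRUE) {
  if (n == 0L) return(integer(0))
  raw <- if (peak_hi) hi - stats::rgamma(n, shape = 1.5, scale = (hi - lo) / 5)
         else lo + stats::rgamma(n, shape = 1.5, scale = (hi - lo) / 5)
  as.integer(pmin(pmax(round(raw), lo), hi))
}

#' Generate a synthetic birth cohort
#'
#' Births are located uniformly within a HOLC polygon chosen with probability
#' proportional to per-grade birth intensity times polygon area; a configured
#' fraction falls outside every map boundary and another below 24 weeks of
#' gestation, to exercise the inclusion flow. Maternal covariates follow
#' grade-dependent distributions; outcome indicators follow the configured
#' logistic models.
#'
#' @param config a [sim_config()] object.
#' @param city a `synthetic_city` with tract metrics filled.
#' @param polygon_metrics optional precomputed areal-weighted metric table
#'   (from [apportion_metrics()]); computed from the city when omitted.
#' @return A data.frame of birth records (one row per birth). The attribute
#'   `expected_prevalence` carries the analytic mean outcome probabilities
#'   among modelled births; `sim_polygon_id` records the simulator's truth
#'   for the containing polygon ("" for births placed outside the map).
#' @export
generate_births <- function(config, city, polygon_metrics = NULL) {
  validate_sim_config(config)
  n <- config$n_births
  if (n == 0L) return(empty_cohort())
  if (any(config$birth_intensity < 0)) stop("configuration error: negative birth intensity")
  if (is.null(polygon_metrics)) {
    ov <- compute_overlaps(city$holc, city$tracts)
    polygon_metrics <- apportion_metrics(ov, city$tracts)
  }
  set.seed(stage_seed(config$seed, 3L))
  polys <- city$holc$polygons
  pid <- vapply(polys, `[[`, "", "polygon_id")
  pgrade <- vapply(polys, `[[`, "", "grade")
  pmetro <- vapply(polys, `[[`, "", "metro")
  parea <- vapply(polys, function(p) poly_area(p$geometry), 0)
  pbb <- t(vapply(polys, function(p) poly_bbox(p$geometry), numeric(4)))

  n_out <- round(config$frac_outside * n)
  n_in <- n - n_out
  wsel <- config$birth_intensity[pgrade] * parea
  sel <- sample.int(length(polys), n_in, replace = TRUE, prob = wsel)
  # uniform point inside the polygon by rejection from its bounding box
  px <- stats::runif(n_in, pbb[sel, "xmin"], pbb[sel, "xmax"])
  py <- stats::runif(n_in, pbb[sel, "ymin"], pbb[sel, "ymax"])
  for (it in 1:100) {
    bad <- integer(0)
    for (s in unique(sel)) {
      i <- which(sel == s)
      st <- point_in_poly(px[i], py[i], polys[[s]]$geometry)
      bad <- c(bad, i[st == 0L])
    }
    if (!length(bad)) break
    px[bad] <- stats::runif(length(bad), pbb[sel[bad], "xmin"], pbb[sel[bad], "xmax"])
    py[bad] <- stats::runif(length(bad), pbb[sel[bad], "ymin"], pbb[sel[bad], "ymax"])
  }
  # outside births: strictly left of every boundary polygon
  all_bb <- c(xmin = min(pbb[, "xmin"]), ymin = min(pbb[, "ymin"]),
              xmax = max(pbb[, "xmax"]), ymax = max(pbb[, "ymax"]))
  ox <- stats::runif(n_out, all_bb["xmin"] - 3 * city$cell_size,
                     all_bb["xmin"] - 1.5 * city$cell_size)
  oy <- stats::runif(n_out, all_bb["ymin"], all_bb["ymax"])

  x <- c(px, ox); y <- c(py, oy)
  sim_pid <- c(pid[sel], rep("", n_out))
  grade <- c(pgrade[sel], rep("NG", n_out)) # outside births use NG covariate profiles
  metro <- c(pmetro[sel], rep("LA", n_out))

  # maternal covariates by grade
  draw_cat <- function(probmat, grade) {
    lv <- colnames(probmat)
    out <- character(length(grade))
    for (g in unique(grade)) {
      i <- which(grade == g)
      out[i] <- lv[sample.int(length(lv), length(i), replace = TRUE, prob = probmat[g, ])]
    }
    out
  }
  race <- draw_cat(config$race_probs, grade)
  education <- draw_cat(config$edu_probs, grade)
  payer <- draw_cat(config$payer_probs, grade)
  mage <- round(pmin(pmax(stats::rnorm(n, config$maternal_age_mean[grade],
                                       config$maternal_age_sd[grade]), 14), 55), 1)
  parity <- stats::rpois(n, config$parity_mean[grade])
  sex <- ifelse(stats::runif(n) < 0.512, "male", "female")
  birth_year <- sample(2006:2015, n, replace = TRUE)

  # linear-predictor pieces shared by the outcome models
  cc <- config$confounder_coefs
  conf_lp <- rep(0, n)
  if (length(cc)) {
    pm_row <- match(sim_pid, polygon_metrics$polygon_id)
    for (m in names(cc)) {
      v <- polygon_metrics[[m]]
      if (is.null(v)) stop("confounder_coefs names an unknown areal metric: ", m)
      ctr <- v[pm_row] - mean(v, na.rm = TRUE)
      ctr[is.na(ctr)] <- 0 # outside-map births sit at the centre
      conf_lp <- conf_lp + cc[[m]] * ctr
    }
  }
  mat_lp <- config$maternal_coefs[["maternal_age"]] * (mage - 30) +
    config$maternal_coefs[["parity"]] * parity
  eff <- function(outcome) grade_effect_by_grade(config, outcome)[grade]
  base <- config$outcome_base_logodds
  lp <- function(outcome) base[[outcome]] + eff(outcome) + conf_lp + mat_lp

  pre24 <- stats::runif(n) < config$frac_pre24
  modeled <- !pre24

  p_pt <- stats::plogis(lp("preterm"))
  preterm <- modeled & (stats::runif(n) < p_pt)
  p_vpt <- stats::plogis(lp("very_preterm"))
  very_preterm <- preterm & (stats::runif(n) < p_vpt)
  p_lbw <- stats::plogis(lp("lbw"))
  lbw <- modeled & (stats::runif(n) < p_lbw)
  vlbw <- lbw & (stats::runif(n) < stats::plogis(lp("vlbw")))

  gest <- integer(n)
  gest[very_preterm] <- rtrunc_days(sum(very_preterm), 168L, 223L)
  ptl <- preterm & !very_preterm
  gest[ptl] <- rtrunc_days(sum(ptl), 224L, 258L)
  term <- modeled & !preterm
  gest[term] <- as.integer(pmin(pmax(round(stats::rnorm(sum(term), 280, 9)), 259), 300))
  gest[pre24] <- as.integer(round(stats::runif(sum(pre24), 100, 167)))

  # birth weight: mean increases with gestational age, male shift, SGA
  # injected as a standardised downward shift (see vignette)
  sga_excess <- eff("sga") + conf_lp + mat_lp # grade + confounder shift for SGA
  zshift <- sga_excess / 1.95
  male <- sex == "male"
  bw <- numeric(n)
  i <- vlbw
  bw[i] <- pmin(pmax(round(1100 + 2 * (gest[i] - 200) + 60 * male[i] +
                             stats::rnorm(sum(i), 0, 200) - 200 * zshift[i]), 500), 1499)
  i <- lbw & !vlbw
  bw[i] <- pmin(pmax(round(1950 + 5 * (gest[i] - 230) + 60 * male[i] +
                             stats::rnorm(sum(i), 0, 220) - 220 * zshift[i]), 1500), 2499)
  i <- modeled & !lbw
  bw[i] <- pmax(round(3250 + 14 * (gest[i] - 280) + 110 * male[i] +
                        stats::rnorm(sum(i), 0, 330) - 330 * zshift[i]), 2500)
  bw[pre24] <- pmax(round(stats::runif(sum(pre24), 150, 700)), 100)

  elective <- modeled & (stats::runif(n) < 0.0008)
  p_pm <- stats::plogis(lp("perinatal_mortality"))
  perinatal <- modeled & !elective & (stats::runif(n) < p_pm)
  neonatal <- perinatal & (stats::runif(n) < stats::plogis(lp("neonatal_mortality")))
  death_age <- rep(NA_integer_, n)
  death_age[neonatal] <- sample(0:27, sum(neonatal), replace = TRUE)
  late <- perinatal & !neonatal
  death_age[late] <- sample(28:365, sum(late), replace = TRUE)
  death_age[elective] <- 0L
  death_age[pre24] <- ifelse(stats::runif(sum(pre24)) < 0.5, 0L, NA_integer_)

  births <- data.frame(
    birth_id = sprintf("b%07d", seq_len(n)),
    x = x, y = y,
    gest_age_days = gest, birth_weight_g = bw, sex = sex,
    death_age_days = death_age, elective_abortion_flag = elective,
    race = race, maternal_age = mage, parity = parity,
    education = education, payer = payer, metro = metro,
    birth_year = birth_year, sim_polygon_id = sim_pid,
    stringsAsFactors = FALSE)
  attr(births, "expected_prevalence") <- c(
    preterm = mean(p_pt[modeled]),
    lbw = mean(p_lbw[modeled]),
    perinatal_mortality = mean(((1 - 0.0008) * p_pm)[modeled]))
  births
}

empty_cohort <- function() {
  data.frame(birth_id = character(), x = numeric(), y = numeric(),
             gest_age_days = integer(), birth_weight_g = numeric(),
             sex = character(), death_age_days = integer(),
             elective_abortion_flag = logical(), race = character(),
             maternal_age = numeric(), parity = integer(),
             education = character(), payer = character(),
             metro = character(), birth_year = integer(),
             sim_polygon_id = character(), stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_city()], [generate_tract_metrics()],
#' areal apportionment and [generate_births()] under one configuration.
#'
#' @param config a [sim_config()] object.
#' @return List with `city`, `overlaps`, `polygon_metrics`, `births`.
#' @export
simulate_study <- function(config) {
  city <- generate_city(config)
  city <- generate_tract_metrics(config, city)
  ov <- compute_overlaps(city$holc, city$tracts)
  pm <- apportion_metrics(ov, city$tracts)
  births <- generate_births(config, city, polygon_metrics = pm)
  list(city = city, overlaps = ov, polygon_metrics = pm, births = births)
}

#' Write a birth cohort to CSV
#'
#' Column dictionary: `birth_id`; planar `x`,`y`; `gest_age_days` (integer
#' days); `birth_weight_g` (grams); `sex` (male/female); `death_age_days`
#' (integer or empty); `elective_abortion_flag`; maternal `race`,
#' `maternal_age` (years), `parity`, `education`, `payer`; `metro`;
#' `birth_year`; `sim_polygon_id` (simulator truth, empty when outside the
#' map).
#'
#' @param births cohort data.frame.
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(births, path) {
  utils::write.csv(births, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a birth cohort from CSV
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return Cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(birth_id = "character"))
}
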