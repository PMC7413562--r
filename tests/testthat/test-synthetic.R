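test_that("same seed reproduces the city and cohort byte-identically", {
  cfg <- sim_config(seed = 7L, n_cols = 4, n_rows = 4, n_births = 500)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$city, b$city)
  expect_identical(a$births, b$births)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a$births, f1); write_cohort_csv(b$births, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate tract offsets are rejected", {
  expect_error(generate_city(sim_config(tract_offset = 0)), "degenerate overlay")
  expect_error(generate_city(sim_config(tract_offset = 1, cell_size = 1)), "degenerate overlay")
  expect_error(sim_config(n_cols = 1), "2 x 2")
  expect_error(sim_config(grade_probs = c(A = .3, B = .3, C = .3, D = .2, NG = 0)), "sum to 1")
})

test_that("half-cell offset on a 2x2 grid yields four quarter overlaps per cell", {
  cfg <- sim_config(seed = 1, n_cols = 2, n_rows = 2, tract_offset = 0.5)
  city <- generate_city(cfg)
  ov <- compute_overlaps(city$holc, city$tracts)
  for (p in unique(ov$polygon_id)) {
    w <- ov$weight[ov$polygon_id == p]
    expect_length(w, 4)
    expect_equal(w, rep(0.25, 4))
  }
})

test_that("grade frequencies track grade_probs within binomial 99% bounds", {
  probs <- c(A = .1, B = .2, C = .35, D = .3, NG = .05)
  counts <- stats::setNames(rep(0, 5), names(probs))
  n_tot <- 0
  for (s in 1:50) {
    cfg <- sim_config(seed = s, n_cols = 10, n_rows = 10,
                      grade_probs = probs, grade_smoothing = 0)
    g <- vapply(generate_city(cfg)$holc$polygons, `[[`, "", "grade")
    counts[names(table(g))] <- counts[names(table(g))] + as.numeric(table(g))
    n_tot <- n_tot + length(g)
  }
  for (g in names(probs)) {
    bound <- stats::qnorm(0.995) * sqrt(probs[g] * (1 - probs[g]) / n_tot)
    expect_lt(abs(counts[g] / n_tot - probs[g]), bound + 1e-12)
  }
})

test_that("neighbour smoothing preserves marginal grade frequencies", {
  probs <- c(A = .1, B = .2, C = .35, D = .3, NG = .05)
  counts <- stats::setNames(rep(0, 5), names(probs))
  n_tot <- 0
  for (s in 1:60) {
    cfg <- sim_config(seed = s + 300, n_cols = 10, n_rows = 10,
                      grade_probs = probs, grade_smoothing = 0.5)
    g <- vapply(generate_city(cfg)$holc$polygons, `[[`, "", "grade")
    counts[names(table(g))] <- counts[names(table(g))] + as.numeric(table(g))
    n_tot <- n_tot + length(g)
  }
  # spatial copying correlates cells, so allow a design-effect factor on the
  # binomial standard error
  for (g in names(probs)) {
    bound <- stats::qnorm(0.995) * 2 * sqrt(probs[g] * (1 - probs[g]) / n_tot)
    expect_lt(abs(counts[g] / n_tot - probs[g]), bound)
  }
})

test_that("tract count metrics respect their logical bounds", {
  st <- small_study()
  for (tr in st$city$tracts$tracts) {
    m <- tr$metrics
    expect_true(all(m >= 0))
    expect_lte(m["homes_radio"], m["total_homes"])
    expect_lte(m["homes_refrigerator"], m["total_homes"])
    expect_lte(m["homes_major_repairs"], m["total_homes"])
    expect_lte(m["black"], m["nonwhite"])
    expect_lte(m["foreign_born_white"], m["white"])
    expect_lte(m["employed"], m["total_pop"])
    expect_equal(unname(m["white"] + m["nonwhite"]), unname(m["total_pop"]))
    expect_lte(m["edu_no_hs"] + m["edu_hs"] + m["edu_some_college"] + m["edu_college"],
               m["total_pop"])
  }
})

test_that("halved grade-D home value yields a significant negative pre-match difference", {
  hits <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    mm <- default_metric_means()
    mm["D", "median_home_value"] <- mm["C", "median_home_value"] / 2
    cfg <- sim_config(seed = s + 900, n_cols = 20, n_rows = 10,
                      metric_means_by_grade = mm)
    city <- generate_tract_metrics(cfg, generate_city(cfg))
    pm <- apportion_metrics(compute_overlaps(city$holc, city$tracts), city$tracts)
    gr <- city_grades(city)
    g <- gr$grade[match(pm$polygon_id, gr$polygon_id)]
    tt <- weighted_t_test(pm$median_home_value[g == "D"],
                          pm$median_home_value[g == "C"])
    if (tt$diff < 0 && tt$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("null generator equalises outcome prevalence across grades", {
  cfg <- sim_config(seed = 5, n_cols = 10, n_rows = 10, n_births = 100000,
                    confounder_coefs = c(median_home_value = 0, pct_nonwhite = 0))
  st <- simulate_study(cfg)
  asn <- assign_grade(st$births, st$city$holc)
  coh <- code_outcomes(apply_inclusion_flow(st$births, asn)$cohort)
  pr <- tapply(coh$preterm, coh$grade, mean)[c("A", "B", "C", "D")]
  p0 <- mean(coh$preterm)
  for (g in names(pr)) {
    n_g <- sum(coh$grade == g)
    expect_lt(abs(pr[g] - p0), 4 * sqrt(p0 * (1 - p0) / n_g))
  }
})

test_that("marginal prevalence matches the analytic logistic expectation", {
  cfg <- sim_config(seed = 9, n_cols = 10, n_rows = 10, n_births = 100000)
  st <- simulate_study(cfg)
  exp_prev <- attr(st$births, "expected_prevalence")
  asn <- assign_grade(st$births, st$city$holc)
  fl <- apply_inclusion_flow(st$births, asn)
  coh <- code_outcomes(fl$cohort)
  # compare on the full modelled cohort (exclusions are outcome-independent)
  modeled <- st$births$gest_age_days >= 168
  obs <- c(preterm = mean(st$births$gest_age_days[modeled] < 259),
           lbw = mean(st$births$birth_weight_g[modeled] < 2500),
           perinatal_mortality = mean(!is.na(st$births$death_age_days[modeled]) &
                                        !st$births$elective_abortion_flag[modeled]))
  for (oc in names(exp_prev)) {
    mc_se <- sqrt(exp_prev[oc] * (1 - exp_prev[oc]) / sum(modeled))
    expect_lt(abs(obs[oc] - exp_prev[oc]), 3 * mc_se + 0.002)
  }
})

test_that("injected conditional log-OR appears in the crude odds ratio without confounding", {
  eff <- holcmatch:::zero_contrast_effects()
  eff$D_vs_C["preterm"] <- log(0.93)
  cfg <- sim_config(seed = 77, n_cols = 10, n_rows = 10, n_births = 500000,
                    grade_effect_logodds = eff,
                    confounder_coefs = c(median_home_value = 0, pct_nonwhite = 0))
  st <- simulate_study(cfg)
  asn <- assign_grade(st$births, st$city$holc)
  coh <- code_outcomes(apply_inclusion_flow(st$births, asn)$cohort)
  tab <- table(coh$grade[coh$grade %in% c("C", "D")],
               coh$preterm[coh$grade %in% c("C", "D")]) * 1.0
  crude_or <- (tab["D", "TRUE"] * tab["C", "FALSE"]) /
    (tab["D", "FALSE"] * tab["C", "TRUE"])
  expect_lt(abs(crude_or - 0.93), 0.02)
})

test_that("confounding moves the crude OR away from the conditional OR as the signs imply", {
  # negative MHV coefficient + lower MHV in D than C => crude D:C OR above
  # the conditional (null) OR
  cfg <- sim_config(seed = 31, n_cols = 20, n_rows = 10, n_births = 200000,
                    confounder_coefs = c(median_home_value = -0.15))
  st <- simulate_study(cfg)
  asn <- assign_grade(st$births, st$city$holc)
  coh <- code_outcomes(apply_inclusion_flow(st$births, asn)$cohort)
  tab <- table(coh$grade[coh$grade %in% c("C", "D")],
               coh$preterm[coh$grade %in% c("C", "D")]) * 1.0
  crude_or <- (tab["D", "TRUE"] * tab["C", "FALSE"]) /
    (tab["D", "FALSE"] * tab["C", "TRUE"])
  expect_gt(crude_or, 1.02)
})

test_that("configuration round-trips through yaml and degenerate cohorts are allowed", {
  cfg <- sim_config(seed = 3, n_births = 0)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$grade_probs, cfg$grade_probs)
  expect_equal(back$metric_means_by_grade, cfg$metric_means_by_grade)
  expect_equal(back$grade_effect_logodds, cfg$grade_effect_logodds)
  city <- generate_tract_metrics(cfg, generate_city(cfg))
  expect_equal(nrow(generate_births(cfg, city)), 0)
  expect_error(sim_config(birth_intensity = c(A = -1, B = 1, C = 1, D = 1, NG = 1)),
               "negative")
})
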