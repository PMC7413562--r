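test_that("gestational and weight thresholds code exactly at their boundaries", {
  g <- code_gestational(c(259L, 258L, 223L, 224L, 240L, 168L))
  expect_equal(g$preterm, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(g$very_preterm, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(code_gestational(167L), "refused")
  w <- code_weight(c(2500, 2499, 1499, 1500, NA), rep(280L, 5))
  expect_equal(w$lbw, c(FALSE, TRUE, TRUE, TRUE, NA))
  expect_equal(w$vlbw, c(FALSE, FALSE, TRUE, FALSE, NA))
  expect_error(code_weight(0, 280L), "positive")
})

test_that("mortality codes non-elective deaths with the 28-day neonatal boundary", {
  m <- code_mortality(c(27L, 28L, NA, 0L, 400L),
                      c(FALSE, FALSE, FALSE, TRUE, FALSE),
                      rep(280L, 5))
  expect_equal(m$perinatal_mortality, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(m$neonatal_mortality, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("the empirical SGA reference uses the linear-interpolation quantile", {
  coh <- data.frame(
    birth_weight_g = rep(seq(1000, 10000, by = 1000), 10),
    sex = "male",
    gest_age_days = rep(38L * 7L, 100))
  ref <- build_sga_reference(coh, min_cell = 100L)
  expect_equal(ref$p10_grams[ref$week == 38], 1900)
  # all weights equal -> percentile equals that weight
  coh2 <- data.frame(birth_weight_g = rep(3000, 120), sex = "female",
                     gest_age_days = rep(40L * 7L, 120))
  ref2 <- build_sga_reference(coh2, min_cell = 100L)
  expect_equal(ref2$p10_grams[1], 3000)
  # determinism
  st <- small_study()
  expect_identical(build_sga_reference(st$cohort), build_sga_reference(st$cohort))
})

test_that("under-filled cells are unsupported and SGA is missing there", {
  coh <- data.frame(birth_weight_g = c(rep(3000, 120), rep(2800, 10)),
                    sex = "male",
                    gest_age_days = c(rep(280L, 120), rep(190L, 10)))
  ref <- build_sga_reference(coh, min_cell = 100L)
  expect_false(ref$supported[ref$week == 27])
  sga <- code_sga(2800, "male", 190L, ref)
  expect_true(is.na(sga))
})

test_that("SGA coding is strict, sex-specific and reproduces ~10% prevalence", {
  st <- small_study()
  ref <- attr(st$cohort, "sga_reference")
  # weight exactly at the percentile is not SGA
  row <- ref[ref$supported, ][1, ]
  expect_false(code_sga(row$p10_grams, row$sex, row$week * 7L, ref))
  expect_true(code_sga(row$p10_grams - 1, row$sex, row$week * 7L, ref))
  # reference strictly increases across supported weeks within sex
  for (s in unique(ref$sex)) {
    q <- ref$p10_grams[ref$sex == s & ref$supported]
    expect_true(all(diff(q) > 0))
  }
  # self-referenced prevalence close to 10% in big supported cells
  coh <- st$cohort
  week <- coh$gest_age_days %/% 7L
  for (s in c("male", "female")) {
    big <- ref$week[ref$sex == s & ref$supported & ref$n >= 400]
    for (wk in big) {
      cell <- coh$sga[coh$sex == s & week == wk]
      expect_lt(abs(mean(cell) - 0.10), 3 * sqrt(0.1 * 0.9 / length(cell)) + 0.01)
    }
  }
})

test_that("coded outcomes respect the implication lattice and are row-wise", {
  st <- small_study()
  coh <- st$cohort
  expect_true(all(!coh$very_preterm | coh$preterm))
  expect_true(all(!coh$vlbw | coh$lbw))
  expect_true(all(!coh$neonatal_mortality | coh$perinatal_mortality))
  set.seed(4)
  perm <- sample(nrow(coh))
  reord <- code_outcomes(st$cohort[perm, setdiff(names(st$cohort),
    c("preterm", "very_preterm", "lbw", "vlbw", "sga",
      "perinatal_mortality", "neonatal_mortality"))],
    sga_ref = attr(st$cohort, "sga_reference"))
  expect_equal(reord$preterm, coh$preterm[perm])
  expect_equal(reord$sga, coh$sga[perm])
})

test_that("a user-supplied SGA reference loads and validates monotonicity", {
  f <- withr::local_tempfile(fileext = ".csv")
  ref <- data.frame(sex = rep(c("male", "female"), each = 3),
                    week = rep(38:40, 2),
                    p10_grams = c(2600, 2750, 2900, 2500, 2650, 2800))
  utils::write.csv(ref, f, row.names = FALSE)
  got <- load_sga_reference(f)
  expect_true(all(got$supported))
  expect_false(code_sga(2600, "male", 38L * 7L, got))  # at percentile
  expect_true(code_sga(2499, "female", 38L * 7L, got))
  # same weight, same week, sex-specific verdicts differ
  expect_true(code_sga(2550, "male", 38L * 7L, got) !=
                code_sga(2550, "female", 38L * 7L, got))
  bad <- ref; bad$p10_grams[2] <- 2500
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(load_sga_reference(f), "increase")
})
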