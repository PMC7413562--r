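test_that("the weighted t-test reduces to the classical Welch test at unit weights", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  got <- weighted_t_test(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(got$diff, unname(diff(rev(ref$estimate))), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(got$ci, as.numeric(ref$conf.int), tolerance = 1e-9)
})

test_that("the weighted t-test is weight-scale invariant and null on identical arms", {
  set.seed(12)
  x <- rnorm(20); w <- runif(20, 0.5, 2)
  a <- weighted_t_test(x, x + 1, w, w)
  b <- weighted_t_test(x, x + 1, 2 * w, 2 * w)
  expect_equal(a$diff, b$diff); expect_equal(a$p, b$p); expect_equal(a$se, b$se)
  same <- weighted_t_test(x, x, w, w)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_error(weighted_t_test(x, x, rep(0, 20), w), "zero total weight")
})

test_that("the Spearman screen equals rank-then-Pearson and honours invariances", {
  set.seed(13)
  X <- as.data.frame(matrix(rnorm(100), 20, 5))
  names(X) <- holcmatch:::AREAL_COVARIATES[1:5]
  X$polygon_id <- sprintf("p%02d", 1:20)
  sc <- spearman_screen(X, covariates = names(X)[1:5], threshold = 0.7)
  oracle <- stats::cor(apply(as.matrix(X[, 1:5]), 2, rank))
  expect_equal(unname(sc$rho), unname(oracle), tolerance = 1e-12)
  expect_equal(diag(sc$rho), rep(1, 5), ignore_attr = TRUE)
  # strictly monotone transform has rho 1 with the original
  X2 <- X[, 1:5]
  X2[[2]] <- exp(X2[[1]])
  X2$polygon_id <- X$polygon_id
  sc2 <- spearman_screen(X2, covariates = names(X2)[1:5], threshold = 0.7)
  expect_equal(unname(sc2$rho[1, 2]), 1)
  expect_true(nrow(sc2$flagged) >= 1)
  expect_equal(sc$retained, holcmatch:::MODEL_COVARIATES)
  # constant column: rho recorded as missing
  X3 <- X; X3[[3]] <- 1
  sc3 <- spearman_screen(X3, covariates = names(X)[1:5])
  expect_true(all(is.na(sc3$rho[3, ])))
})

test_that("an unadjusted unit-weight model reproduces the 2x2 cross-product odds ratio", {
  set.seed(14)
  n <- 400
  d <- data.frame(
    grade = sample(c("D", "C"), n, replace = TRUE),
    polygon_id = sprintf("p%02d", sample(1:30, n, replace = TRUE)))
  d$preterm <- runif(n) < ifelse(d$grade == "D", 0.3, 0.2)
  res <- fit_outcome_model(d, rep(1, n), "preterm", "D",
                           covariates = character(0), robust = FALSE)
  tab <- table(d$grade, d$preterm)
  expect_equal(res$or,
               (tab["D", "TRUE"] * tab["C", "FALSE"]) /
                 (tab["D", "FALSE"] * tab["C", "TRUE"]),
               tolerance = 1e-6)
})

test_that("duplicating records at half weight reproduces the point estimate", {
  set.seed(15)
  n <- 300
  d <- data.frame(grade = sample(c("D", "C"), n, replace = TRUE),
                  polygon_id = sprintf("p%02d", sample(1:20, n, replace = TRUE)),
                  median_home_value = rnorm(n, 5), pct_employed = rnorm(n, 40),
                  pct_radio = rnorm(n, 90), pct_nonwhite = rnorm(n, 4))
  d$preterm <- runif(n) < plogis(-2 + 0.2 * (d$grade == "D") - 0.05 * d$median_home_value)
  base <- fit_outcome_model(d, rep(1, n), "preterm", "D")
  dup <- rbind(d, d)
  doubled <- fit_outcome_model(dup, rep(0.5, 2 * n), "preterm", "D")
  expect_equal(doubled$or, base$or, tolerance = 1e-6)
})

test_that("CR2/CR3 with singleton clusters agree with the HC2/HC3 sandwiches", {
  set.seed(16)
  n <- 120
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- runif(n) < plogis(0.3 + 0.5 * d$x)
  w <- runif(n, 0.5, 2)
  fit <- glm(y ~ x + z, data = d, weights = w, family = quasibinomial())
  cr <- holcmatch:::vcov_cr2(fit, cluster = seq_len(n), type = "CR2")
  hc2 <- sandwich::vcovHC(fit, type = "HC2")
  expect_equal(cr$vcov, hc2, tolerance = 1e-6, ignore_attr = TRUE)
  cr3 <- holcmatch:::vcov_cr2(fit, cluster = seq_len(n), type = "CR3")
  hc3 <- sandwich::vcovHC(fit, type = "HC3")
  expect_equal(cr3$vcov, hc3, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("balance tables carry valid intervals and matched samples balance confounders", {
  st <- small_study()
  f <- suppressWarnings(holc_fit(st$cohort, st$polygon_metrics, st$grades,
                                 contrast = "D_vs_C", outcomes = "preterm",
                                 k_folds = 5, seed = 3))
  b <- f$balance
  expect_true(all(b$pre_lo <= b$pre_diff & b$pre_diff <= b$pre_hi))
  expect_true(all(b$post_lo <= b$post_diff & b$post_diff <= b$post_hi))
  # post-match absolute standardised difference no larger than pre-match for
  # the two Mahalanobis covariates
  for (cv in c("median_home_value", "pct_nonwhite")) {
    row <- b[b$covariate == cv, ]
    expect_lte(abs(row$post_diff), abs(row$pre_diff) + 1e-9)
  }
})
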