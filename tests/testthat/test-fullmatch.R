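test_that("identical units match with all weights one and zero distance", {
  fit <- fake_psfit(c(0.5, 0.5), c(0.5, 0.5))
  metrics <- fake_metrics(fit$polygon_id, rep(5, 4), rep(10, 4))
  m <- full_match(fit, NULL, metrics)
  expect_equal(m$total_distance, 0)
  expect_equal(sort(m$unit_weights$weight), rep(1, 4))
  # every subclass has at least one treated and one control
  for (s in m$subclasses) {
    expect_gte(length(s$treated), 1)
    expect_gte(length(s$control), 1)
    expect_true(length(s$treated) == 1 || length(s$control) == 1)
  }
})

test_that("units beyond the caliper of every partner are discarded with zero weight", {
  fit <- fake_psfit(c(0.30, 0.32, 0.31), c(0.30, 0.33, 0.90))
  metrics <- fake_metrics(fit$polygon_id, c(1, 2, 3, 1, 2, 50), c(5, 6, 7, 5, 6, 90))
  m <- full_match(fit, NULL, metrics)
  expect_true("c03" %in% m$discarded$polygon_id)
  expect_false("c03" %in% m$unit_weights$polygon_id)
  # caliper respected inside every subclass
  ps <- stats::setNames(fit$propensity, fit$polygon_id)
  for (s in m$subclasses)
    for (t in s$treated) for (c in s$control)
      expect_lte(abs(ps[t] - ps[c]), m$caliper + 1e-9)
})

test_that("matching weight invariants hold on synthetic contrasts", {
  st <- small_study()
  fit <- fit_propensity(st$polygon_metrics, st$grades, "D_vs_C", k_folds = 5, seed = 2)
  bounds <- trim_support(fit)
  m <- full_match(fit, bounds, st$polygon_metrics)
  uw <- m$unit_weights
  n_matched_t <- length(unique(unlist(lapply(m$subclasses, `[[`, "treated"))))
  expect_equal(sum(uw$weight[uw$role == "treated"]), n_matched_t)
  for (k in unique(m$weights$subclass)) {
    wsub <- m$weights[m$weights$subclass == k, ]
    expect_equal(sum(wsub$weight[wsub$role == "control"]),
                 sum(wsub$role == "treated"))
  }
  expect_true(all(uw$weight > 0))
})

test_that("the minimum-cost full match equals exhaustive enumeration on small instances", {
  set.seed(99)
  done <- 0
  for (rep in 1:20) {
    nt <- sample(2:4, 1); nc <- sample(2:4, 1)
    fit <- fake_psfit(runif(nt, 0.3, 0.7), runif(nc, 0.3, 0.7))
    metrics <- fake_metrics(fit$polygon_id,
                            rnorm(nt + nc, 10, 4), rnorm(nt + nc, 8, 3))
    csd <- sample(c(0.8, 1.5, 3), 1)
    m <- tryCatch(full_match(fit, NULL, metrics, caliper_sd = csd),
                  error = function(e) NULL)
    if (is.null(m)) next
    # oracle distance matrix, computed independently
    X <- as.matrix(metrics[, c("pct_nonwhite", "median_home_value")])
    S <- stats::cov(X) + diag(1e-8, 2)
    D <- matrix(0, nt, nc)
    for (j in seq_len(nc))
      D[, j] <- sqrt(stats::mahalanobis(X[seq_len(nt), , drop = FALSE],
                                        X[nt + j, ], S))
    ps <- fit$propensity
    cal <- csd * stats::sd(ps)
    adm <- abs(outer(ps[seq_len(nt)], ps[nt + seq_len(nc)], `-`)) <= cal + 1e-12
    adm[rowSums(adm) == 0, ] <- FALSE
    keep_t <- rowSums(adm) > 0; keep_c <- colSums(adm) > 0
    if (!any(keep_t) || !any(keep_c)) next
    best <- brute_force_cover(D[keep_t, keep_c, drop = FALSE],
                              adm[keep_t, keep_c, drop = FALSE])
    expect_equal(m$total_distance, best, tolerance = 1e-8)
    done <- done + 1
  }
  expect_gte(done, 10)
})

test_that("birth weight propagation conserves totals and ignores order", {
  st <- small_study()
  fit <- fit_propensity(st$polygon_metrics, st$grades, "D_vs_C", k_folds = 5, seed = 2)
  m <- full_match(fit, trim_support(fit), st$polygon_metrics)
  coh <- st$cohort
  w <- assign_birth_weights(m, coh)
  uw <- m$unit_weights
  counts <- table(coh$polygon_id)
  expected_total <- sum(uw$weight * as.numeric(counts[uw$polygon_id]), na.rm = TRUE)
  expect_equal(sum(w), expected_total)
  expect_true(all(w[!coh$polygon_id %in% uw$polygon_id] == 0))
  perm <- sample(nrow(coh))
  expect_equal(assign_birth_weights(m, coh[perm, ]), w[perm])
  # a neighborhood with weight 1 passes weight 1 to each of its births
  one_ids <- uw$polygon_id[uw$weight == 1]
  if (length(one_ids)) expect_true(all(w[coh$polygon_id %in% one_ids] == 1))
})
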