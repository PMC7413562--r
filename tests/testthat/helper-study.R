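# Shared fixtures and independent oracles.

# small synthetic study used across test files (memoised per test run)
.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config(seed = 42L, n_cols = 8, n_rows = 8, n_births = 4000)
    st <- simulate_study(cfg)
    st$grades <- city_grades(st$city)
    st$assignments <- assign_grade(st$births, st$city$holc)
    fl <- apply_inclusion_flow(st$births, st$assignments)
    st$flow <- fl$flow
    st$cohort <- code_outcomes(fl$cohort)
    st$config <- cfg
    .fixture_env$study <- st
  }
  .fixture_env$study
}

# independent exhaustive minimum-cost star edge cover (<= ~16 edges)
brute_force_cover <- function(D, adm) {
  edges <- which(adm, arr.ind = TRUE)
  ne <- nrow(edges)
  stopifnot(ne >= 1, ne <= 16)
  costs <- D[edges]
  cov_t <- sort(unique(edges[, 1]))
  cov_c <- sort(unique(edges[, 2]))
  nmask <- 2^ne - 1
  bits <- matrix(0L, nmask, ne)
  for (e in seq_len(ne)) bits[, e] <- (seq_len(nmask) %/% 2^(e - 1)) %% 2
  It <- matrix(0, ne, nrow(D)); It[cbind(seq_len(ne), edges[, 1])] <- 1
  Ic <- matrix(0, ne, ncol(D)); Ic[cbind(seq_len(ne), edges[, 2])] <- 1
  degt <- bits %*% It
  degc <- bits %*% Ic
  covered <- rowSums(degt[, cov_t, drop = FALSE] == 0) == 0 &
    rowSums(degc[, cov_c, drop = FALSE] == 0) == 0
  viol <- rowSums(bits * (degt[, edges[, 1], drop = FALSE] > 1) *
                    (degc[, edges[, 2], drop = FALSE] > 1)) > 0
  ok <- covered & !viol
  if (!any(ok)) return(Inf)
  min((bits %*% costs)[ok])
}

# fabricate a propensity_fit for matching tests
fake_psfit <- function(ps_t, ps_c) {
  ids <- c(sprintf("t%02d", seq_along(ps_t)), sprintf("c%02d", seq_along(ps_c)))
  structure(list(polygon_id = ids,
                 propensity = c(ps_t, ps_c),
                 treated = c(rep(1L, length(ps_t)), rep(0L, length(ps_c)))),
            class = "propensity_fit")
}

fake_metrics <- function(ids, pnw, mhv) {
  data.frame(polygon_id = ids, pct_nonwhite = pnw, median_home_value = mhv,
             stringsAsFactors = FALSE)
}
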