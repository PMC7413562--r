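# Weighted balance tests, collinearity screening and weighted outcome
# regression with cluster-robust standard errors.

# Cluster-robust variance for a fitted glm with small-sample leverage
# adjustment and Imbens-Kolesar (Satterthwaite-type) degrees of freedom.
# Matching weights concentrate mass on few neighborhoods, so the plain CR0
# sandwich is anticonservative. `type = "CR3"` (default) rescales each
# cluster's working residuals by (I - H_cc)^(-1) (jackknife-type), the
# recommended choice under few or highly unbalanced clusters; "CR2" uses the
# Bell-McCaffrey (I - H_cc)^(-1/2). Only the rank-k structure of H_cc is
# needed, so the adjustment is computed in the k-dimensional column space of
# each cluster block. The degrees of freedom follow the Bell-McCaffrey
# construction (computed for the CR2 form) in either case.
vcov_cr2 <- function(fit, cluster, type = c("CR3", "CR2")) {
  type <- match.arg(type)
  X <- stats::model.matrix(fit)
  ok <- !is.na(stats::coef(fit))
  X <- X[, ok, drop = FALSE]
  k <- ncol(X)
  wi <- fit$weights # IRLS working weights (prior weight * mu(1-mu))
  u <- stats::residuals(fit, type = "working") * sqrt(wi)
  Xs <- X * sqrt(wi)
  M <- chol2inv(chol(crossprod(Xs)))
  cl <- as.character(cluster)
  levs <- unique(cl)
  G <- length(levs)
  meat <- matrix(0, k, k)
  lam <- matrix(0, G, k)        # a_j' X*_c'(I-H_cc)^{-1}X*_c a_j
  mvec <- array(0, c(G, k, k))  # m_c(j) = X*_c' A_c X*_c M e_j
  for (ci in seq_len(G)) {
    idx <- which(cl == levs[ci])
    Xc <- Xs[idx, , drop = FALSE]
    uc <- u[idx]
    qr_ <- qr(Xc)
    r <- qr_$rank
    Qc <- qr.Q(qr_)[, seq_len(r), drop = FALSE]
    Rc <- qr.R(qr_)[seq_len(r), , drop = FALSE]
    Sc <- Rc %*% M %*% t(Rc)
    es <- eigen((Sc + t(Sc)) / 2, symmetric = TRUE)
    d <- pmax(1 - es$values, 1e-8)
    Ui <- es$vectors
    half <- Ui %*% diag(1 / sqrt(d), r) %*% t(Ui)
    inv1 <- Ui %*% diag(1 / d, r) %*% t(Ui)
    scale_ <- if (type == "CR3") inv1 else half
    g <- drop(crossprod(Xc, uc)) +
      drop(t(Rc) %*% (scale_ - diag(r)) %*% crossprod(Qc, uc))
    meat <- meat + tcrossprod(g)
    W <- t(Rc) %*% inv1 %*% Rc   # X*_c' (I-H_cc)^{-1} X*_c
    Ac <- t(Rc) %*% half %*% Rc  # X*_c' (I-H_cc)^{-1/2} X*_c
    lam[ci, ] <- colSums((W %*% M) * M)  # diag of M W M
    mvec[ci, , ] <- Ac %*% M
  }
  V <- M %*% meat %*% M
  # Imbens-Kolesar degrees of freedom: eigen-sum of B = diag(lambda) - Km,
  # Km_cd = m_c' M m_d, accounting for the global residual projection
  df <- numeric(k)
  for (j in seq_len(k)) {
    Mm <- mvec[, , j, drop = TRUE]
    if (is.null(dim(Mm))) Mm <- matrix(Mm, nrow = G)
    Km <- Mm %*% M %*% t(Mm)
    B <- diag(lam[, j], G) - Km
    trB <- sum(diag(B))
    trB2 <- sum(B * B)
    df[j] <- if (trB2 > 0) trB^2 / trB2 else G - 1
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  names(df) <- colnames(X)
  list(vcov = V, df = df)
}

#' Weighted two-sample t-test
#'
#' Weighted means and variances with effective sample sizes
#' `n_eff = (sum w)^2 / sum w^2` and Welch-Satterthwaite degrees of freedom.
#' With all weights 1 this is the classical Welch test.
#'
#' @param x_a,x_b numeric samples.
#' @param w_a,w_b non-negative weights (default 1).
#' @return list with `diff` (mean a - mean b), `ci` (95% interval), `se`,
#'   `df`, `p`, `n_eff` (per arm).
#' @export
weighted_t_test <- function(x_a, x_b, w_a = rep(1, length(x_a)),
                            w_b = rep(1, length(x_b))) {
  stats_arm <- function(x, w) {
    keep <- w > 0 & !is.na(x)
    x <- x[keep]; w <- w[keep]
    sw <- sum(w)
    if (sw <= 0) stop("zero total weight in an arm")
    neff <- sw^2 / sum(w^2)
    if (neff < 2) stop("fewer than 2 effective observations in an arm")
    m <- sum(w * x) / sw
    v <- sum(w * (x - m)^2) / sw * neff / (neff - 1)
    list(m = m, v = v, neff = neff)
  }
  a <- stats_arm(x_a, w_a); b <- stats_arm(x_b, w_b)
  se2a <- a$v / a$neff; se2b <- b$v / b$neff
  se <- sqrt(se2a + se2b)
  diffm <- a$m - b$m
  if (se == 0) {
    return(list(diff = diffm, ci = c(diffm, diffm), se = 0, df = NA_real_,
                p = if (abs(diffm) < 1e-12) 1 else 0,
                n_eff = c(a = a$neff, b = b$neff)))
  }
  df <- (se2a + se2b)^2 / (se2a^2 / (a$neff - 1) + se2b^2 / (b$neff - 1))
  tval <- diffm / se
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- diffm + c(-1, 1) * stats::qt(0.975, df) * se
  list(diff = diffm, ci = ci, se = se, df = df, p = p,
       n_eff = c(a = a$neff, b = b$neff))
}

#' Spearman collinearity screen
#'
#' Pairwise Spearman rank correlations (average ranks for ties) over the
#' candidate covariates; pairs with `|rho|` above the threshold are flagged.
#' The four default model covariates are retained regardless — the screen is
#' a reported diagnostic, not a selector.
#'
#' @param metrics areal-weighted metric table.
#' @param covariates columns to screen (default: the full 1940 set).
#' @param threshold collinearity flag threshold on `|rho|` (default 0.7).
#' @return list with `rho` (correlation matrix), `flagged` (data.frame of
#'   high-correlation pairs), `retained` (the model covariates).
#' @export
spearman_screen <- function(metrics, covariates = AREAL_COVARIATES,
                            threshold = 0.7) {
  covariates <- intersect(covariates, names(metrics))
  X <- as.matrix(metrics[, covariates, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 neighborhoods for the screen")
  const <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  rho <- suppressWarnings(stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho)[!const] <- 1
  ut <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(rho)[ut[, 1]],
                        var2 = colnames(rho)[ut[, 2]],
                        rho = rho[ut], stringsAsFactors = FALSE)
  list(rho = rho, flagged = flagged, retained = MODEL_COVARIATES)
}

#' Weighted adjusted logistic outcome model for one contrast
#'
#' Weighted logistic regression of a binary outcome on the treated-grade
#' indicator plus the four areal-weighted 1940 covariates (median home
#' value, percent employed, percent radio ownership, percent non-White), with
#' the odds ratio and a 95% Wald confidence interval from cluster-robust
#' (Bell-McCaffrey CR2 sandwich, Satterthwaite degrees of freedom) standard
#' errors clustered on neighborhood. Weights are
#' rescaled to mean 1 among included births (this leaves point estimates
#' unchanged).
#'
#' @param cohort coded analysis cohort carrying the outcome column, the
#'   covariates (merged from the metric table) and `polygon_id`.
#' @param weights per-birth matching weights (zeros excluded).
#' @param outcome outcome column name.
#' @param treated_grade grade defining the exposure indicator.
#' @param covariates adjustment covariates (default the four 1940 metrics).
#' @param extra_covariates additional columns (e.g. `maternal_age`,
#'   `parity`, `birth_year` for the sensitivity analysis).
#' @param robust use cluster-robust standard errors (default) or model-based.
#' @return A one-row data.frame (`outcome`, `or`, `ci_low`, `ci_high`,
#'   `log_or`, `se`, `p`, `n_births`, `n_neighborhoods`, `converged`).
#' @export
fit_outcome_model <- function(cohort, weights, outcome, treated_grade,
                              covariates = MODEL_COVARIATES,
                              extra_covariates = character(0),
                              robust = TRUE) {
  y <- cohort[[outcome]]
  keep <- weights > 0 & !is.na(y)
  for (cv in c(covariates, extra_covariates)) keep <- keep & !is.na(cohort[[cv]])
  d <- cohort[keep, , drop = FALSE]
  w <- weights[keep]
  w <- w / mean(w)
  d$.treated <- as.integer(d$grade == treated_grade)
  if (length(unique(d$.treated)) < 2L)
    stop("both exposure levels must be present with positive weight")
  d$.y <- as.numeric(d[[outcome]])
  rhs <- paste(c(".treated", covariates, extra_covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- suppressWarnings(stats::glm(fml, data = d, weights = w,
                                     family = stats::quasibinomial(),
                                     control = stats::glm.control(maxit = 100)))
  if (!fit$converged) stop("outcome model failed to converge for ", outcome)
  b <- stats::coef(fit)[".treated"]
  if (is.na(b) || abs(b) > 15) stop("degenerate estimate (separation?) for ", outcome)
  if (robust) {
    cr <- vcov_cr2(fit, d$polygon_id)
    se <- sqrt(cr$vcov[".treated", ".treated"])
    z <- stats::qt(0.975, max(cr$df[".treated"], 2))
  } else {
    se <- sqrt(stats::vcov(fit)[".treated", ".treated"])
    z <- stats::qnorm(0.975)
  }
  data.frame(outcome = outcome, or = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se), log_or = unname(b), se = se,
             p = if (robust) 2 * stats::pt(-abs(b) / se, max(cr$df[".treated"], 2))
                 else 2 * stats::pnorm(-abs(b) / se),
             n_births = nrow(d), n_neighborhoods = length(unique(d$polygon_id)),
             converged = fit$converged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pre/post-matching covariate balance table
#'
#' Mean differences (treated minus control) of the seven 1940 balance
#' covariates at the neighborhood level, before matching (unweighted, full
#' contrast sample) and after (matching weights, on-support sample), each
#' with a 95% interval and p-value from the weighted t-test.
#'
#' @param metrics areal-weighted metric table.
#' @param fit a `propensity_fit`.
#' @param match a `matched_sample`.
#' @param covariates columns to compare (default the seven of the balance
#'   table).
#' @return data.frame, one row per covariate.
#' @export
balance_table <- function(metrics, fit, match,
                          covariates = BALANCE_COVARIATES) {
  rows <- list()
  pre_t <- fit$polygon_id[fit$treated == 1]
  pre_c <- fit$polygon_id[fit$treated == 0]
  uw <- match$unit_weights
  post_t <- uw[uw$role == "treated", ]
  post_c <- uw[uw$role == "control", ]
  val <- function(ids, col) metrics[[col]][match(ids, metrics$polygon_id)]
  for (cv in covariates) {
    pre <- weighted_t_test(val(pre_t, cv), val(pre_c, cv))
    post <- weighted_t_test(val(post_t$polygon_id, cv), val(post_c$polygon_id, cv),
                            post_t$weight, post_c$weight)
    rows[[cv]] <- data.frame(
      covariate = cv,
      pre_diff = pre$diff, pre_lo = pre$ci[1], pre_hi = pre$ci[2], pre_p = pre$p,
      post_diff = post$diff, post_lo = post$ci[1], post_hi = post$ci[2],
      post_p = post$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
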