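# Neighborhood propensity scores for adjacent-grade contrasts, estimated by
# a cross-validated stacked ensemble of five learner families:
#   1. grand-mean model
#   2. linear-logistic regression
#   3. ridge-penalised logistic regression
#   4. adaptive piecewise-linear (hinge) spline logistic regression
#   5. penalised additive natural-spline logistic regression
# combined with non-negative weights summing to one, chosen to minimise the
# cross-validated log-loss of the stack.

PS_EPS <- 1e-6

#' Specify an adjacent-grade contrast
#'
#' Only the three adjacent pairs are permitted (positivity: non-adjacent
#' grades have near-zero overlap in propensity).
#'
#' @param label one of `"B_vs_A"`, `"C_vs_B"`, `"D_vs_C"` (worse grade
#'   first: the worse grade is "treated").
#' @return list with `treated`, `control`, `label`.
#' @export
contrast_spec <- function(label) {
  label <- match.arg(label, CONTRASTS)
  parts <- strsplit(label, "_vs_")[[1]]
  list(treated = parts[1], control = parts[2], label = label)
}

# deterministic-given-seed stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- sample(which(y == cls))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

clip_p <- function(p, eps = PS_EPS) pmin(pmax(p, eps), 1 - eps)

ensure_mat2 <- function(X) if (ncol(X) >= 2) X else cbind(X, X)

det_foldid <- function(y, k = 5L) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    f[i] <- rep_len(seq_len(k), length(i))
  }
  f
}

# ---- learner families -------------------------------------------------------

fit_mean_learner <- function(X, y) {
  p <- mean(y)
  list(predict = function(Xn) rep(p, nrow(Xn)))
}

fit_glm_learner <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(predict = function(Xn) clip_p(stats::plogis(drop(cbind(1, Xn) %*% beta))))
}

fit_ridge_learner <- function(X, y) {
  Xs <- ensure_mat2(X)
  fit <- tryCatch({
    cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 0,
                            foldid = det_foldid(y, 5L), nlambda = 30)
    list(m = cv$glmnet.fit, s = cv$lambda.min)
  }, error = function(e) NULL)
  if (is.null(fit)) return(fit_mean_learner(X, y))
  list(predict = function(Xn)
    clip_p(drop(stats::predict(fit$m, ensure_mat2(Xn), s = fit$s, type = "response"))))
}

# forward selection over hinge bases h(x - k)+ and h(k - x)+ at tercile
# knots, scored by AIC; a light stand-in for multivariate adaptive
# regression splines with deterministic fits
fit_hinge_learner <- function(X, y, max_terms = 6L) {
  n <- nrow(X)
  cand <- list()
  for (j in seq_len(ncol(X))) {
    ks <- unique(stats::quantile(X[, j], c(1 / 3, 2 / 3), type = 7, names = FALSE))
    for (k in ks) {
      if (stats::sd(pmax(X[, j] - k, 0)) > 0)
        cand[[length(cand) + 1L]] <- list(j = j, k = k, dir = 1)
      if (stats::sd(pmax(k - X[, j], 0)) > 0)
        cand[[length(cand) + 1L]] <- list(j = j, k = k, dir = -1)
    }
  }
  basis_col <- function(b) if (b$dir > 0) pmax(X[, b$j] - b$k, 0) else pmax(b$k - X[, b$j], 0)
  B <- matrix(1, n, 1)
  chosen <- list()
  dev0 <- suppressWarnings(stats::glm.fit(B, y, family = stats::binomial()))$deviance
  aic0 <- dev0 + 2
  repeat {
    if (length(chosen) >= max_terms || !length(cand)) break
    # screen candidates by score correlation with the current residual,
    # then refit only the leaders
    cur <- suppressWarnings(stats::glm.fit(B, y, family = stats::binomial()))
    res <- y - cur$fitted.values
    sc <- vapply(cand, function(b) {
      v <- basis_col(b)
      s <- stats::sd(v)
      if (s == 0) 0 else abs(sum(v * res)) / s
    }, 0)
    top <- utils::head(order(sc, decreasing = TRUE), 8L)
    best <- NULL; best_aic <- aic0
    for (ci in top) {
      Bt <- cbind(B, basis_col(cand[[ci]]))
      f <- suppressWarnings(tryCatch(
        stats::glm.fit(Bt, y, family = stats::binomial()), error = function(e) NULL))
      if (is.null(f)) next
      aic <- f$deviance + 2 * ncol(Bt)
      if (aic < best_aic - 1e-8) { best <- ci; best_aic <- aic }
    }
    if (is.null(best)) break
    B <- cbind(B, basis_col(cand[[best]]))
    chosen[[length(chosen) + 1L]] <- cand[[best]]
    cand <- cand[-best]
    aic0 <- best_aic
  }
  fit <- suppressWarnings(stats::glm.fit(B, y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(predict = function(Xn) {
    Bn <- matrix(1, nrow(Xn), 1)
    for (b in chosen)
      Bn <- cbind(Bn, if (b$dir > 0) pmax(Xn[, b$j] - b$k, 0) else pmax(b$k - Xn[, b$j], 0))
    clip_p(stats::plogis(drop(Bn %*% beta)))
  })
}

# penalised additive natural-spline logistic model: ns(x, df = 3) basis per
# covariate, ridge penalty chosen by deterministic internal cross-validation
fit_addspline_learner <- function(X, y) {
  make_basis <- function(Xm, specs = NULL) {
    cols <- list(); out_specs <- list()
    for (j in seq_len(ncol(Xm))) {
      x <- Xm[, j]
      if (is.null(specs)) {
        if (length(unique(x)) > 4) {
          b <- splines::ns(x, df = 3)
          out_specs[[j]] <- list(knots = attr(b, "knots"),
                                 bk = attr(b, "Boundary.knots"))
          cols[[j]] <- unclass(b)
        } else {
          out_specs[j] <- list(NULL)
          cols[[j]] <- matrix(x, ncol = 1)
        }
      } else {
        sp <- if (j <= length(specs)) specs[[j]] else NULL
        cols[[j]] <- if (is.null(sp)) matrix(x, ncol = 1)
          else unclass(splines::ns(x, knots = sp$knots, Boundary.knots = sp$bk))
      }
    }
    list(B = do.call(cbind, cols), specs = out_specs)
  }
  bs <- make_basis(X)
  fit <- tryCatch({
    cv <- glmnet::cv.glmnet(ensure_mat2(bs$B), y, family = "binomial", alpha = 0,
                            foldid = det_foldid(y, 5L), nlambda = 30)
    list(m = cv$glmnet.fit, s = cv$lambda.min)
  }, error = function(e) NULL)
  if (is.null(fit)) return(fit_mean_learner(X, y))
  list(predict = function(Xn) {
    Bn <- make_basis(Xn, specs = bs$specs)$B
    clip_p(drop(stats::predict(fit$m, ensure_mat2(Bn), s = fit$s, type = "response")))
  })
}

LEARNERS <- list(mean = fit_mean_learner, glm = fit_glm_learner,
                 ridge = fit_ridge_learner, hinge = fit_hinge_learner,
                 addspline = fit_addspline_learner)

log_loss <- function(y, p) {
  p <- clip_p(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# non-negative simplex stacking weights minimising log-loss of Z %*% w
stack_weights <- function(Z, y) {
  Z <- clip_p(Z)
  obj <- function(b) {
    w <- exp(b - max(b)); w <- w / sum(w)
    log_loss(y, drop(Z %*% w))
  }
  opt <- stats::optim(rep(0, ncol(Z)), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  w <- exp(opt$par - max(opt$par))
  w <- w / sum(w)
  stats::setNames(w, colnames(Z))
}

#' Fit ensemble propensity scores for one adjacent-grade contrast
#'
#' @param metrics areal-weighted metric table from [apportion_metrics()]
#'   (one row per HOLC polygon, `polygon_id` column).
#' @param grades data.frame `polygon_id`, `grade` (see [city_grades()]).
#' @param contrast a contrast label or [contrast_spec()].
#' @param k_folds number of stratified cross-validation folds.
#' @param seed integer seed controlling fold assignment.
#' @param covariates covariate columns; defaults to the full 1940 set.
#' @return A `propensity_fit`: per-neighborhood propensities in (0,1)
#'   (clipped at 1e-6), learner-level out-of-fold predictions, simplex
#'   stacking weights, fold assignment and refit learners.
#' @export
fit_propensity <- function(metrics, grades, contrast, k_folds = 10L, seed = 1L,
                           covariates = AREAL_COVARIATES) {
  ct <- if (is.character(contrast)) contrast_spec(contrast) else contrast
  g <- grades$grade[match(metrics$polygon_id, grades$polygon_id)]
  keep <- g %in% c(ct$treated, ct$control)
  sub <- metrics[keep, , drop = FALSE]
  g <- g[keep]
  y <- as.integer(g == ct$treated)
  if (length(unique(y)) < 2L) stop("all neighborhoods in one arm; cannot fit propensity")
  if (min(table(y)) < 10L)
    stop("need at least 10 neighborhoods per arm (got ", min(table(y)), ")")
  covariates <- intersect(covariates, names(sub))
  X <- as.matrix(sub[, covariates, drop = FALSE])
  if (anyNA(X)) stop("missing covariate values in propensity sample")
  set.seed(stage_seed(seed, 7L))
  k_folds <- min(k_folds, min(table(y)))
  fold <- stratified_folds(y, k_folds)
  Z <- matrix(NA_real_, length(y), length(LEARNERS),
              dimnames = list(NULL, names(LEARNERS)))
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- fold == f
    for (ln in names(LEARNERS)) {
      m <- LEARNERS[[ln]](X[tr, , drop = FALSE], y[tr])
      Z[te, ln] <- m$predict(X[te, , drop = FALSE])
    }
  }
  w <- stack_weights(Z, y)
  finals <- lapply(LEARNERS, function(fn) fn(X, y))
  P <- vapply(finals, function(m) m$predict(X), numeric(length(y)))
  ps <- clip_p(drop(P %*% w))
  structure(list(contrast = ct, polygon_id = sub$polygon_id, grade = g,
                 treated = y, propensity = ps, cv_preds = Z,
                 stack_weights = w, folds = fold, covariates = covariates,
                 learners = finals, cv_log_loss = log_loss(y, drop(clip_p(Z) %*% w))),
            class = "propensity_fit")
}

#' Trim neighborhoods outside the propensity support window
#'
#' Lower bound: empirical 1st percentile of propensity among the
#' better-graded (control) arm; upper: 99th percentile among the
#' worse-graded (treated) arm; neighborhoods outside `[lower, upper]` are
#' excluded (linear-interpolation quantiles).
#'
#' @param fit a `propensity_fit`.
#' @param lower_q,upper_q percentile levels (defaults 0.01 / 0.99).
#' @return list with `lower`, `upper`, `retained` (polygon ids), `excluded`
#'   (data.frame of dropped ids with their propensities and arm).
#' @export
trim_support <- function(fit, lower_q = 0.01, upper_q = 0.99) {
  ps <- fit$propensity
  if (!any(fit$treated == 1) || !any(fit$treated == 0)) stop("an arm is empty")
  lower <- stats::quantile(ps[fit$treated == 0], lower_q, type = 7, names = FALSE)
  upper <- stats::quantile(ps[fit$treated == 1], upper_q, type = 7, names = FALSE)
  if (lower > upper)
    stop("empty support: lower trim bound ", signif(lower, 4),
         " exceeds upper ", signif(upper, 4))
  keep <- ps >= lower & ps <= upper
  list(lower = lower, upper = upper,
       retained = fit$polygon_id[keep],
       excluded = data.frame(polygon_id = fit$polygon_id[!keep],
                             propensity = ps[!keep],
                             treated = fit$treated[!keep],
                             stringsAsFactors = FALSE))
}
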