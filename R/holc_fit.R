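# The central fitting function: one adjacent-grade contrast, end to end
# (propensity ensemble -> support trimming -> optimal full matching ->
# birth weights -> balance table -> weighted adjusted outcome models).

#' Fit one adjacent-grade HOLC contrast
#'
#' Runs the full estimation pipeline for a single contrast: stacked-ensemble
#' propensity scores over the 1940 areal-weighted covariates, 1st/99th
#' percentile support trimming, optimal full matching under a 0.2-SD
#' propensity caliper with Mahalanobis within-caliper distance, propagation
#' of neighborhood weights to births, covariate balance, and weighted
#' adjusted logistic models for the requested outcomes with cluster-robust
#' confidence intervals.
#'
#' @param births coded analysis cohort (see [code_outcomes()] and
#'   [apply_inclusion_flow()]); must carry `polygon_id` and `grade`.
#' @param metrics areal-weighted metric table from [apportion_metrics()].
#' @param grades data.frame `polygon_id`, `grade` (see [city_grades()]).
#' @param contrast contrast label (`"B_vs_A"`, `"C_vs_B"`, `"D_vs_C"`).
#' @param outcomes outcome columns to model (default the four primary).
#' @param trim apply support trimming (FALSE reproduces the unrestricted
#'   analysis).
#' @param k_folds,seed cross-validation folds and seed for the ensemble.
#' @param covariates adjustment covariates of the outcome models.
#' @param extra_covariates appended to the outcome models (sensitivity
#'   analysis: `c("maternal_age", "parity", "birth_year")`).
#' @param robust cluster-robust (default) or model-based standard errors.
#' @return An object of class `holc_fit`.
#' @export
holc_fit <- function(births, metrics, grades, contrast = "D_vs_C",
                     outcomes = OUTCOMES_PRIMARY, trim = TRUE,
                     k_folds = 10L, seed = 1L,
                     covariates = MODEL_COVARIATES,
                     extra_covariates = character(0), robust = TRUE) {
  ct <- contrast_spec(contrast)
  fit <- fit_propensity(metrics, grades, ct, k_folds = k_folds, seed = seed)
  bounds <- if (trim) trim_support(fit) else NULL
  match_ <- full_match(fit, bounds, metrics)
  w <- assign_birth_weights(match_, births)
  bal <- balance_table(metrics, fit, match_)
  cohort <- births
  for (cv in union(covariates, MODEL_COVARIATES)) {
    if (!cv %in% names(cohort))
      cohort[[cv]] <- metrics[[cv]][match(cohort$polygon_id, metrics$polygon_id)]
  }
  results <- list()
  for (oc in outcomes) {
    results[[oc]] <- tryCatch(
      cbind(contrast = ct$label, stratum = "all",
            fit_outcome_model(cohort, w, oc, ct$treated,
                              covariates = covariates,
                              extra_covariates = extra_covariates,
                              robust = robust),
            stringsAsFactors = FALSE),
      error = function(e) data.frame(contrast = ct$label, stratum = "all",
                                     outcome = oc, or = NA_real_,
                                     ci_low = NA_real_, ci_high = NA_real_,
                                     log_or = NA_real_, se = NA_real_,
                                     p = NA_real_, n_births = NA_integer_,
                                     n_neighborhoods = NA_integer_,
                                     converged = FALSE, note = conditionMessage(e),
                                     stringsAsFactors = FALSE))
  }
  results <- do.call(rbind, lapply(results, function(r) {
    if (!"note" %in% names(r)) r$note <- ""
    r
  }))
  rownames(results) <- NULL
  structure(list(contrast = ct, propensity = fit, support = bounds,
                 match = match_, birth_weights = w, balance = bal,
                 results = results, cohort = cohort,
                 outcomes = outcomes, covariates = covariates,
                 extra_covariates = extra_covariates, robust = robust,
                 trim = trim),
            class = "holc_fit")
}

#' @export
print.holc_fit <- function(x, ...) {
  ct <- x$contrast
  cat("HOLC adjacent-grade contrast:", ct$treated, "vs", ct$control,
      if (x$trim) "(support-trimmed)" else "(unrestricted)", "\n")
  nt <- sum(x$propensity$treated == 1); ncl <- sum(x$propensity$treated == 0)
  cat(sprintf("neighborhoods: %d %s, %d %s; caliper %.4f; %d subclasses\n",
              nt, ct$treated, ncl, ct$control, x$match$caliper,
              length(x$match$subclasses)))
  cat("ensemble stacking weights:\n")
  print(round(x$propensity$stack_weights, 3))
  cat("\nadjusted odds ratios (95% CI):\n")
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-20s OR %5.3f (%5.3f, %5.3f)  n=%d\n", r$outcome[i],
                r$or[i], r$ci_low[i], r$ci_high[i], r$n_births[i]))
  invisible(x)
}

#' @export
summary.holc_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.holc_fit")
}

#' @export
print.summary.holc_fit <- function(x, ...) {
  print(x$fit)
  cat("\ncovariate balance (diff treated - control, 95% CI, p):\n")
  b <- x$fit$balance
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-22s pre %7.2f (p=%.3f)   post %7.2f (p=%.3f)\n",
                b$covariate[i], b$pre_diff[i], b$pre_p[i],
                b$post_diff[i], b$post_p[i]))
  if (!is.null(x$fit$support))
    cat(sprintf("\nsupport window [%.4f, %.4f]; %d neighborhoods trimmed\n",
                x$fit$support$lower, x$fit$support$upper,
                nrow(x$fit$support$excluded)))
  invisible(x)
}

#' @export
coef.holc_fit <- function(object, ...) {
  stats::setNames(object$results$log_or, object$results$outcome)
}

#' @export
confint.holc_fit <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(r$log_or - z * r$se, r$log_or + z * r$se)
  dimnames(out) <- list(r$outcome,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predict ensemble propensity scores for new neighborhoods
#'
#' @param object a `holc_fit`.
#' @param newdata metric table rows with the fitted covariate columns;
#'   defaults to the fitted sample.
#' @param ... unused.
#' @return Numeric vector of propensities in (0, 1).
#' @export
predict.holc_fit <- function(object, newdata = NULL, ...) {
  pf <- object$propensity
  if (is.null(newdata)) return(pf$propensity)
  X <- as.matrix(newdata[, pf$covariates, drop = FALSE])
  P <- vapply(pf$learners, function(m) m$predict(X), numeric(nrow(X)))
  if (nrow(X) == 1L) P <- matrix(P, nrow = 1)
  clip_p(drop(P %*% pf$stack_weights))
}

#' @export
weights.holc_fit <- function(object, ...) object$birth_weights

#' Plot propensity distributions by arm
#'
#' @param x a `holc_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.holc_fit <- function(x, ...) {
  pf <- x$propensity
  ps1 <- pf$propensity[pf$treated == 1]
  ps0 <- pf$propensity[pf$treated == 0]
  br <- seq(0, 1, by = 0.05)
  h1 <- graphics::hist(ps1, breaks = br, plot = FALSE)
  h0 <- graphics::hist(ps0, breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h0$counts))
  graphics::plot(h0, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, xlab = "propensity of worse grade",
                 main = paste("Propensity overlap:", pf$contrast$label), ...)
  graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5), add = TRUE)
  if (!is.null(x$support))
    graphics::abline(v = c(x$support$lower, x$support$upper), lty = 2)
  graphics::legend("topright", fill = c("steelblue", "firebrick"),
                   legend = c(pf$contrast$control, pf$contrast$treated),
                   bty = "n")
  invisible(x)
}
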