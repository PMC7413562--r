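# Full study analysis: all contrasts x outcomes x strata, descriptive
# tables, the collinearity screen and grade-specific outcome prevalences.

descriptive_table <- function(cohort) {
  grades_present <- intersect(GRADES, unique(cohort$grade))
  cat_rows <- list()
  for (v in c("race", "education", "payer", "metro")) {
    tab <- table(cohort[[v]], factor(cohort$grade, levels = grades_present))
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    for (lev in rownames(tab)) {
      counts <- tab[lev, ]
      pct <- 100 * counts / pmax(colSums(tab), 1)
      cat_rows[[paste(v, lev)]] <- data.frame(
        variable = v, level = lev,
        t(stats::setNames(sprintf("%d (%.1f%%)", counts, pct),
                          paste0("grade_", grades_present))),
        p_value = p, test = "chi-square",
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  for (v in c("maternal_age", "parity")) {
    m <- tapply(cohort[[v]], factor(cohort$grade, levels = grades_present),
                mean, na.rm = TRUE)
    s <- tapply(cohort[[v]], factor(cohort$grade, levels = grades_present),
                stats::sd, na.rm = TRUE)
    p <- tryCatch(summary(stats::aov(cohort[[v]] ~ factor(cohort$grade)))[[1]][["Pr(>F)"]][1],
                  error = function(e) NA_real_)
    cat_rows[[v]] <- data.frame(
      variable = v, level = "mean (sd)",
      t(stats::setNames(sprintf("%.1f (%.1f)", m, s),
                        paste0("grade_", grades_present))),
      p_value = p, test = "anova",
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, cat_rows)
  rownames(out) <- NULL
  out
}

metrics_by_grade_table <- function(metrics, grades) {
  g <- grades$grade[match(metrics$polygon_id, grades$polygon_id)]
  rows <- list()
  for (cv in c(AREAL_COVARIATES)) {
    m <- tapply(metrics[[cv]], factor(g, levels = GRADES), mean, na.rm = TRUE)
    s <- tapply(metrics[[cv]], factor(g, levels = GRADES), stats::sd, na.rm = TRUE)
    rows[[cv]] <- data.frame(metric = cv,
                             t(stats::setNames(sprintf("%.2f (%.2f)", m, s),
                                               paste0("grade_", GRADES))),
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prevalence_by_grade <- function(cohort,
                                outcomes = c(OUTCOMES_PRIMARY, OUTCOMES_SECONDARY)) {
  grades_present <- intersect(GRADES, unique(cohort$grade))
  rows <- list()
  for (oc in outcomes) {
    pr <- tapply(as.numeric(cohort[[oc]]), factor(cohort$grade, levels = grades_present),
                 mean, na.rm = TRUE)
    rows[[oc]] <- data.frame(outcome = oc,
                             t(stats::setNames(100 * pr, paste0("grade_", grades_present))),
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the complete study analysis
#'
#' Fits every available adjacent-grade contrast with [holc_fit()], models
#' the primary and secondary outcomes overall and within metro and maternal
#' race strata, and assembles the descriptive tables (maternal
#' characteristics by grade, areal-weighted metrics by grade, grade-specific
#' outcome prevalences) plus the Spearman collinearity screen. A stratum
#' cell with an empty arm is reported as unavailable and the run continues.
#'
#' @param cohort coded analysis cohort (post inclusion flow and
#'   [code_outcomes()]).
#' @param metrics areal-weighted metric table.
#' @param grades polygon grade lookup.
#' @param contrasts contrast labels to fit.
#' @param outcomes outcome columns (default all seven).
#' @param strata stratifying columns among `"metro"` and `"race"`.
#' @param sensitivity also fit models adding maternal age, parity and birth
#'   year.
#' @param trim support trimming (FALSE = unrestricted analysis).
#' @param k_folds,seed passed to the propensity ensemble.
#' @return An object of class `holc_analysis`: `fits` (per-contrast
#'   `holc_fit`s), `results` (all contrast x outcome x stratum rows),
#'   `balance`, `descriptive`, `metrics_by_grade`, `prevalence`,
#'   `spearman`, `n_tests`.
#' @export
run_full_analysis <- function(cohort, metrics, grades,
                              contrasts = CONTRASTS,
                              outcomes = c(OUTCOMES_PRIMARY, OUTCOMES_SECONDARY),
                              strata = c("metro", "race"),
                              sensitivity = FALSE, trim = TRUE,
                              k_folds = 10L, seed = 1L) {
  fits <- list(); all_rows <- list(); bal <- list()
  for (ct in contrasts) {
    f <- tryCatch(
      holc_fit(cohort, metrics, grades, contrast = ct, outcomes = outcomes,
               trim = trim, k_folds = k_folds, seed = seed),
      error = function(e) e)
    if (inherits(f, "error")) {
      all_rows[[ct]] <- data.frame(contrast = ct, stratum = "all",
                                   outcome = outcomes, or = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   log_or = NA_real_, se = NA_real_, p = NA_real_,
                                   n_births = NA_integer_,
                                   n_neighborhoods = NA_integer_,
                                   converged = FALSE,
                                   note = conditionMessage(f),
                                   stringsAsFactors = FALSE)
      next
    }
    fits[[ct]] <- f
    rows <- list(f$results)
    spec <- contrast_spec(ct)
    for (sv in strata) {
      for (lev in sort(unique(f$cohort[[sv]]))) {
        sub <- f$cohort[[sv]] == lev
        row <- tryCatch(
          cbind(contrast = ct, stratum = paste0(sv, ":", lev),
                do.call(rbind, lapply(outcomes, function(oc)
                  fit_outcome_model(f$cohort[sub, , drop = FALSE],
                                    f$birth_weights[sub], oc, spec$treated,
                                    covariates = f$covariates,
                                    extra_covariates = f$extra_covariates,
                                    robust = f$robust))),
                note = "", stringsAsFactors = FALSE),
          error = function(e) data.frame(contrast = ct,
                                         stratum = paste0(sv, ":", lev),
                                         outcome = outcomes, or = NA_real_,
                                         ci_low = NA_real_, ci_high = NA_real_,
                                         log_or = NA_real_, se = NA_real_,
                                         p = NA_real_, n_births = NA_integer_,
                                         n_neighborhoods = NA_integer_,
                                         converged = FALSE,
                                         note = conditionMessage(e),
                                         stringsAsFactors = FALSE))
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (sensitivity) {
      sens <- tryCatch(
        cbind(contrast = ct, stratum = "all+sensitivity",
              do.call(rbind, lapply(outcomes, function(oc)
                fit_outcome_model(f$cohort, f$birth_weights, oc, spec$treated,
                                  covariates = f$covariates,
                                  extra_covariates = c("maternal_age", "parity", "birth_year"),
                                  robust = f$robust))),
              note = "", stringsAsFactors = FALSE),
        error = function(e) NULL)
      if (!is.null(sens)) rows[[length(rows) + 1L]] <- sens
    }
    all_rows[[ct]] <- do.call(rbind, rows)
    bal[[ct]] <- cbind(contrast = ct, f$balance, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  structure(list(
    fits = fits,
    results = results,
    balance = if (length(bal)) do.call(rbind, bal) else NULL,
    descriptive = descriptive_table(cohort),
    metrics_by_grade = metrics_by_grade_table(metrics, grades),
    prevalence = prevalence_by_grade(cohort, outcomes),
    spearman = spearman_screen(metrics),
    n_tests = sum(!is.na(results$or))),
    class = "holc_analysis")
}

#' @export
print.holc_analysis <- function(x, ...) {
  cat("HOLC grade contrast analysis\n")
  cat(sprintf("contrasts fitted: %s\n", paste(names(x$fits), collapse = ", ")))
  cat(sprintf("%d odds ratios estimated (no multiplicity adjustment)\n", x$n_tests))
  main <- x$results[x$results$stratum == "all", , drop = FALSE]
  for (ct in unique(main$contrast)) {
    cat("\n", ct, ":\n", sep = "")
    r <- main[main$contrast == ct, ]
    for (i in seq_len(nrow(r))) {
      if (is.na(r$or[i])) cat(sprintf("  %-20s unavailable (%s)\n",
                                      r$outcome[i], r$note[i]))
      else cat(sprintf("  %-20s OR %5.3f (%5.3f, %5.3f)\n", r$outcome[i],
                       r$or[i], r$ci_low[i], r$ci_high[i]))
    }
  }
  invisible(x)
}

#' Write the analysis tables to a directory
#'
#' Emits the results CSV (one row per contrast x outcome x stratum), the
#' balance CSV, the descriptive CSVs, the Spearman matrix and a
#' run-metadata JSON.
#'
#' @param analysis a `holc_analysis`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the metadata.
#' @export
write_analysis <- function(analysis, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis$results, file.path(dir, "results.csv"), row.names = FALSE)
  if (!is.null(analysis$balance))
    utils::write.csv(analysis$balance, file.path(dir, "balance.csv"), row.names = FALSE)
  utils::write.csv(analysis$descriptive, file.path(dir, "descriptive.csv"), row.names = FALSE)
  utils::write.csv(analysis$metrics_by_grade, file.path(dir, "metrics_by_grade.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$prevalence, file.path(dir, "prevalence_by_grade.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$spearman$rho),
                   file.path(dir, "spearman.csv"), row.names = TRUE)
  meta <- list(seed = seed, n_tests = analysis$n_tests,
               package_version = as.character(utils::packageVersion("holcmatch")),
               r_version = R.version.string)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
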