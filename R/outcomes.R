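# Coding of the seven binary perinatal outcomes from gestational age, birth
# weight, infant sex and death timing.
#
# Thresholds: preterm < 259 days (37 weeks), very preterm < 224 days
# (32 weeks), LBW < 2500 g, VLBW < 1500 g, SGA strictly below the
# sex-specific 10th-percentile weight for the completed gestational week;
# perinatal mortality is any recorded non-elective death, neonatal mortality
# a death before 28 completed days of life. All coding presumes gestational
# age of at least 168 days (records below that are excluded upstream).

#' Code preterm and very preterm from gestational days
#'
#' @param gest_age_days integer vector of gestational ages in days (>= 168).
#' @return data.frame with logical `preterm` (< 259 days) and `very_preterm`
#'   (< 224 days).
#' @export
code_gestational <- function(gest_age_days) {
  if (any(gest_age_days < 168L, na.rm = TRUE))
    stop("coding refused: gestational age below 168 days (upstream exclusion violated)")
  data.frame(preterm = gest_age_days < 259L,
             very_preterm = gest_age_days < 224L)
}

#' Code low and very low birth weight
#'
#' @param birth_weight_g birth weight in grams (NA allowed; flags NA then).
#' @param gest_age_days gestational age in days (>= 168).
#' @return data.frame with logical `lbw` (< 2500 g) and `vlbw` (< 1500 g).
#' @export
code_weight <- function(birth_weight_g, gest_age_days) {
  if (any(gest_age_days < 168L, na.rm = TRUE))
    stop("coding refused: gestational age below 168 days (upstream exclusion violated)")
  if (any(birth_weight_g <= 0, na.rm = TRUE)) stop("birth weight must be positive")
  data.frame(lbw = birth_weight_g < 2500, vlbw = birth_weight_g < 1500)
}

#' Build an empirical small-for-gestational-age reference
#'
#' Computes, per (sex, completed gestational week) cell with at least
#' `min_cell` births, the empirical 10th-percentile birth weight
#' (linear-interpolation quantile), then enforces monotonicity across weeks
#' within sex by isotonic adjustment. Under-filled cells are unsupported and
#' code SGA as missing.
#'
#' @param cohort data.frame with `birth_weight_g`, `sex`, `gest_age_days`.
#' @param min_cell minimum births per cell (default 100).
#' @param p percentile (default 0.10).
#' @return An `sga_reference`: data.frame `sex`, `week`, `p10_grams`,
#'   `n`, `supported`.
#' @export
build_sga_reference <- function(cohort, min_cell = 100L, p = 0.10) {
  week <- cohort$gest_age_days %/% 7L
  ok <- !is.na(cohort$birth_weight_g) & !is.na(week) & !is.na(cohort$sex) &
    week >= 24L & week <= 42L
  rows <- list()
  for (s in sort(unique(cohort$sex[ok]))) {
    wk <- sort(unique(week[ok & cohort$sex == s]))
    q <- rep(NA_real_, length(wk)); nn <- integer(length(wk))
    for (i in seq_along(wk)) {
      wts <- cohort$birth_weight_g[ok & cohort$sex == s & week == wk[i]]
      nn[i] <- length(wts)
      # snap to microgram resolution: the interpolation arithmetic otherwise
      # leaves float fuzz that breaks the strict SGA boundary on clean data
      if (nn[i] >= min_cell)
        q[i] <- round(stats::quantile(wts, p, type = 7, names = FALSE), 6)
    }
    sup <- !is.na(q)
    if (any(sup)) {
      iso <- stats::isoreg(wk[sup], q[sup])
      qfit <- iso$yf[order(order(wk[sup]))]
      # enforce *strict* increase across supported weeks
      if (length(qfit) > 1)
        for (k in 2:length(qfit))
          if (qfit[k] <= qfit[k - 1]) qfit[k] <- qfit[k - 1] + 1e-6
      q[sup] <- qfit
    }
    rows[[s]] <- data.frame(sex = s, week = wk, p10_grams = q, n = nn,
                            supported = sup, stringsAsFactors = FALSE)
  }
  ref <- do.call(rbind, rows)
  rownames(ref) <- NULL
  class(ref) <- c("sga_reference", class(ref))
  ref
}

#' Load a user-supplied SGA reference table
#'
#' @param path CSV with columns `sex`, `week`, `p10_grams`.
#' @return An `sga_reference` data.frame.
#' @export
load_sga_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "week", "p10_grams") %in% names(ref)))
  ref$supported <- !is.na(ref$p10_grams)
  if (!"n" %in% names(ref)) ref$n <- NA_integer_
  for (s in unique(ref$sex)) {
    i <- which(ref$sex == s & ref$supported)
    i <- i[order(ref$week[i])]
    if (length(i) > 1 && any(diff(ref$p10_grams[i]) <= 0))
      stop("SGA reference percentile weights must increase with week within sex")
  }
  class(ref) <- c("sga_reference", class(ref))
  ref
}

#' Code small-for-gestational-age against a reference
#'
#' @param birth_weight_g,sex,gest_age_days birth fields.
#' @param ref an `sga_reference`.
#' @return Logical vector; `NA` where the (sex, week) cell is unsupported or
#'   a field is missing.
#' @export
code_sga <- function(birth_weight_g, sex, gest_age_days, ref) {
  week <- gest_age_days %/% 7L
  key <- paste(sex, week)
  rkey <- paste(ref$sex, ref$week)
  idx <- match(key, rkey)
  cut <- ref$p10_grams[idx]
  cut[!is.na(idx) & !ref$supported[idx]] <- NA_real_
  birth_weight_g < cut
}

#' Code perinatal and neonatal mortality
#'
#' @param death_age_days age at death in days, `NA` when no death recorded.
#' @param elective_abortion_flag logical; elective abortions are not deaths.
#' @param gest_age_days gestational age in days (>= 168).
#' @return data.frame with logical `perinatal_mortality` (any non-elective
#'   recorded death, unbounded in age) and `neonatal_mortality` (death before
#'   28 completed days).
#' @export
code_mortality <- function(death_age_days, elective_abortion_flag, gest_age_days) {
  if (any(gest_age_days < 168L, na.rm = TRUE))
    stop("coding refused: gestational age below 168 days (upstream exclusion violated)")
  pm <- !is.na(death_age_days) & !elective_abortion_flag
  data.frame(perinatal_mortality = pm,
             neonatal_mortality = pm & death_age_days < 28L)
}

#' Code all seven outcomes onto a cohort
#'
#' @param cohort analysis cohort (post inclusion flow).
#' @param sga_ref an `sga_reference`; built empirically from the cohort when
#'   omitted.
#' @return The cohort with the seven flag columns appended.
#' @export
code_outcomes <- function(cohort, sga_ref = NULL) {
  if (is.null(sga_ref)) sga_ref <- build_sga_reference(cohort)
  g <- code_gestational(cohort$gest_age_days)
  w <- code_weight(cohort$birth_weight_g, cohort$gest_age_days)
  m <- code_mortality(cohort$death_age_days, cohort$elective_abortion_flag,
                      cohort$gest_age_days)
  cohort$preterm <- g$preterm
  cohort$very_preterm <- g$very_preterm
  cohort$lbw <- w$lbw
  cohort$vlbw <- w$vlbw
  cohort$sga <- code_sga(cohort$birth_weight_g, cohort$sex,
                         cohort$gest_age_days, sga_ref)
  cohort$perinatal_mortality <- m$perinatal_mortality
  cohort$neonatal_mortality <- m$neonatal_mortality
  attr(cohort, "sga_reference") <- sga_ref
  cohort
}
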