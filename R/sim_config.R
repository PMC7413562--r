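# Simulation configuration for the synthetic city and birth cohort.

GRADES <- c("A", "B", "C", "D", "NG")
CONTRASTS <- c("B_vs_A", "C_vs_B", "D_vs_C")
OUTCOMES_PRIMARY <- c("preterm", "lbw", "sga", "perinatal_mortality")
OUTCOMES_SECONDARY <- c("very_preterm", "vlbw", "neonatal_mortality")
RACE_LEVELS <- c("hispanic", "nh_api", "nh_black", "nh_other", "nh_white")
EDU_LEVELS <- c("no_hs", "hs_only", "associates", "bachelors", "masters_plus", "unknown")
PAYER_LEVELS <- c("private", "medical", "other")

#' Default per-grade 1940 metric generating profiles
#'
#' Units: `total_pop` is persons per tract; median home value in thousands of
#' (1940) dollars; the `pct_*` entries are percentages used as binomial
#' success rates for the count splits. Levels move across grades in the
#' directions of the observed pre-match differences (worse grades: lower home
#' value, more residents of color, more homes needing repairs, denser
#' occupancy).
#'
#' @return grade x parameter matrix.
#' @export
# persons per tract; median home value in thousands of (1940) dollars; the
# pct_* entries are percentages used as binomial success rates for the count
# splits. Levels move across grades in the directions of the observed
# pre-match differences (worse grades: lower home value, more residents of
# color, more homes needing repairs, denser occupancy).
default_metric_means <- function() {
  m <- rbind(
    A  = c(total_pop = 3000, median_home_value = 8.0, pct_nonwhite = 3.0,
           pct_black_of_nonwhite = 50, pct_fbw_of_white = 8, pct_employed = 40,
           persons_per_home = 3.4, pct_major_repairs = 4.0, pct_radio = 88.0,
           pct_refrigerator = 60.0, pct_heating = 80, pct_adults = 62,
           pct_hs_educated = 60.0),
    B  = c(3400, 5.7, 2.0, 50, 10, 37, 3.6, 5.0, 91.5, 72.9, 75, 62, 52.5),
    C  = c(4000, 4.4, 2.4, 55, 12, 36.5, 3.8, 5.8, 91.3, 71.2, 70, 61, 52.0),
    D  = c(4600, 3.3, 5.8, 60, 14, 36.1, 4.1, 9.2, 88.5, 77.7, 60, 60, 54.2),
    NG = c(3800, 4.0, 3.5, 55, 12, 36.5, 3.8, 6.0, 90.0, 72.0, 68, 61, 53.0))
  colnames(m) <- c("total_pop", "median_home_value", "pct_nonwhite",
                   "pct_black_of_nonwhite", "pct_fbw_of_white", "pct_employed",
                   "persons_per_home", "pct_major_repairs", "pct_radio",
                   "pct_refrigerator", "pct_heating", "pct_adults",
                   "pct_hs_educated")
  m
}

default_race_probs <- function() {
  m <- rbind( # Hispanic share rising, NH-White falling with worse grade
    A  = c(hispanic = 0.12, nh_api = 0.21, nh_black = 0.05, nh_other = 0.05, nh_white = 0.57),
    B  = c(0.36, 0.18, 0.07, 0.04, 0.35),
    C  = c(0.58, 0.14, 0.09, 0.03, 0.16),
    D  = c(0.67, 0.10, 0.09, 0.02, 0.12),
    NG = c(0.57, 0.18, 0.05, 0.02, 0.18))
  colnames(m) <- RACE_LEVELS
  m / rowSums(m)
}

default_edu_probs <- function() {
  m <- rbind(
    A  = c(no_hs = 0.02, hs_only = 0.17, associates = 0.04, bachelors = 0.38, masters_plus = 0.36, unknown = 0.03),
    B  = c(0.14, 0.30, 0.05, 0.27, 0.21, 0.03),
    C  = c(0.30, 0.38, 0.04, 0.15, 0.10, 0.03),
    D  = c(0.37, 0.39, 0.04, 0.11, 0.07, 0.02),
    NG = c(0.24, 0.40, 0.06, 0.18, 0.10, 0.02))
  colnames(m) <- EDU_LEVELS
  m / rowSums(m)
}

default_payer_probs <- function() {
  m <- rbind(
    A  = c(private = 0.85, medical = 0.09, other = 0.06),
    B  = c(0.63, 0.33, 0.04),
    C  = c(0.39, 0.57, 0.04),
    D  = c(0.31, 0.65, 0.04),
    NG = c(0.46, 0.47, 0.07))
  colnames(m) <- PAYER_LEVELS
  m / rowSums(m)
}

zero_contrast_effects <- function() {
  out <- lapply(CONTRASTS, function(ct)
    stats::setNames(rep(0, 7), c(OUTCOMES_PRIMARY, OUTCOMES_SECONDARY)))
  names(out) <- CONTRASTS
  out
}

#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set for the synthetic city and
#' birth cohort: grid geometry, grade frequencies, per-grade 1940 metric
#' profiles, outcome model intercepts, injected adjacent-grade conditional
#' log-odds effects, and confounder coefficients linking areal-weighted 1940
#' metrics to outcome risk.
#'
#' @param seed integer RNG seed; the same seed reproduces the whole study
#'   byte-identically.
#' @param n_cols,n_rows HOLC grid dimensions (cells become HOLC polygons).
#' @param cell_size side length of a grid cell, arbitrary planar units.
#' @param grade_probs probability vector over grades A, B, C, D, NG; must sum
#'   to 1.
#' @param grade_smoothing probability that a cell copies the grade of an
#'   already-assigned neighbour instead of drawing fresh (spatial clustering;
#'   the marginal grade distribution is unchanged).
#' @param tract_offset planar offset of the 1940 tract grid relative to the
#'   HOLC grid, strictly between 0 and `cell_size`.
#' @param metric_means_by_grade grade x parameter matrix of 1940 metric
#'   generating profiles (see [default_metric_means()]).
#' @param metric_cv coefficient of variation of tract-level totals (population,
#'   home value).
#' @param metric_rate_sd logit-scale between-tract overdispersion of the
#'   percentage profiles (census rates vary far more between tracts than
#'   binomial sampling alone would allow).
#' @param n_births cohort size.
#' @param birth_intensity relative birth rate per unit area by grade.
#' @param frac_outside fraction of births placed outside every map boundary.
#' @param frac_pre24 fraction of births with gestational age below 168 days
#'   (excluded by the inclusion flow).
#' @param outcome_base_logodds named intercepts: `preterm`, `lbw`,
#'   `perinatal_mortality` are marginal logits; `very_preterm`, `vlbw`,
#'   `neonatal_mortality` are logits conditional on the parent outcome.
#' @param grade_effect_logodds list by contrast (`B_vs_A`, `C_vs_B`,
#'   `D_vs_C`) of named per-outcome injected conditional log-odds.
#' @param confounder_coefs named log-odds per unit of areal-weighted metric
#'   (applied to centred metrics, identically for all outcomes).
#' @param maternal_coefs named log-odds per unit of maternal age (centred at
#'   30) and parity; default 0, i.e. maternal covariates are grade-dependent
#'   markers but not causes.
#' @param race_probs,edu_probs,payer_probs grade x level probability
#'   matrices for maternal covariates.
#' @param maternal_age_mean,maternal_age_sd,parity_mean per-grade named
#'   vectors.
#' @param metro_split fraction of grid columns labelled `LA` (the rest
#'   `SFOAK`).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cols = 10L, n_rows = 10L, cell_size = 1,
                       grade_probs = c(A = 0.10, B = 0.20, C = 0.35, D = 0.30, NG = 0.05),
                       grade_smoothing = 0.3,
                       tract_offset = 0.4,
                       metric_means_by_grade = default_metric_means(),
                       metric_cv = 0.3,
                       metric_rate_sd = 0.9,
                       n_births = 10000L,
                       birth_intensity = c(A = 0.6, B = 0.8, C = 1.1, D = 1.3, NG = 1.0),
                       frac_outside = 0.02,
                       frac_pre24 = 0.004,
                       outcome_base_logodds = c(preterm = stats::qlogis(0.08),
                                                lbw = stats::qlogis(0.05),
                                                perinatal_mortality = stats::qlogis(0.005),
                                                very_preterm = stats::qlogis(0.16),
                                                vlbw = stats::qlogis(0.25),
                                                neonatal_mortality = stats::qlogis(0.5)),
                       grade_effect_logodds = zero_contrast_effects(),
                       confounder_coefs = c(median_home_value = -0.04, pct_nonwhite = 0.012),
                       maternal_coefs = c(maternal_age = 0, parity = 0),
                       race_probs = default_race_probs(),
                       edu_probs = default_edu_probs(),
                       payer_probs = default_payer_probs(),
                       maternal_age_mean = c(A = 33.8, B = 31.2, C = 28.8, D = 28.2, NG = 29.1),
                       maternal_age_sd = c(A = 5.2, B = 6.2, C = 6.4, D = 6.5, NG = 6.3),
                       parity_mean = c(A = 0.9, B = 1.0, C = 1.3, D = 1.5, NG = 1.2),
                       metro_split = 0.75) {
  cfg <- list(seed = as.integer(seed), n_cols = as.integer(n_cols),
              n_rows = as.integer(n_rows), cell_size = cell_size,
              grade_probs = grade_probs, grade_smoothing = grade_smoothing,
              tract_offset = tract_offset,
              metric_means_by_grade = metric_means_by_grade,
              metric_cv = metric_cv, metric_rate_sd = metric_rate_sd,
              n_births = as.integer(n_births),
              birth_intensity = birth_intensity, frac_outside = frac_outside,
              frac_pre24 = frac_pre24,
              outcome_base_logodds = outcome_base_logodds,
              grade_effect_logodds = grade_effect_logodds,
              confounder_coefs = confounder_coefs,
              maternal_coefs = maternal_coefs,
              race_probs = race_probs, edu_probs = edu_probs,
              payer_probs = payer_probs,
              maternal_age_mean = maternal_age_mean,
              maternal_age_sd = maternal_age_sd, parity_mean = parity_mean,
              metro_split = metro_split)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grade_probs) == 5L)
  if (is.null(names(cfg$grade_probs))) names(cfg$grade_probs) <- GRADES
  if (abs(sum(cfg$grade_probs) - 1) > 1e-9)
    stop("grade_probs must sum to 1 (got ", sum(cfg$grade_probs), ")")
  if (any(cfg$grade_probs < 0)) stop("grade_probs must be non-negative")
  if (cfg$n_cols < 2L || cfg$n_rows < 2L) stop("grid must be at least 2 x 2")
  if (any(cfg$metric_means_by_grade < 0)) stop("metric means must be non-negative")
  if (!all(GRADES %in% rownames(cfg$metric_means_by_grade)))
    stop("metric_means_by_grade must have a row per grade A, B, C, D, NG")
  if (cfg$n_births < 0L) stop("n_births must be >= 0")
  if (any(cfg$birth_intensity < 0)) stop("negative birth intensity")
  if (cfg$metric_cv <= 0) stop("metric_cv must be positive")
  if (is.null(cfg$metric_rate_sd) || cfg$metric_rate_sd < 0)
    stop("metric_rate_sd must be non-negative")
  invisible(cfg)
}

# derive an independent sub-seed for a pipeline stage from the master seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 9973L) %% 2147483647L
}

# Cumulative per-grade conditional effect relative to grade A, for one
# outcome: eff(A)=0, eff(B)=theta(B_vs_A), eff(C)=eff(B)+theta(C_vs_B), ...
# NG carries no grade effect (NG births never enter a contrast).
grade_effect_by_grade <- function(cfg, outcome) {
  th <- vapply(CONTRASTS, function(ct) {
    v <- cfg$grade_effect_logodds[[ct]][outcome]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }, 0)
  c(A = 0, B = th[["B_vs_A"]], C = th[["B_vs_A"]] + th[["C_vs_B"]],
    D = th[["B_vs_A"]] + th[["C_vs_B"]] + th[["D_vs_C"]], NG = 0)
}

#' Write a simulation configuration to YAML
#'
#' @param cfg a `sim_config` object.
#' @param path output file path.
#' @export
write_sim_config <- function(cfg, path) {
  ser <- unclass(cfg)
  for (nm in c("metric_means_by_grade", "race_probs", "edu_probs", "payer_probs")) {
    m <- ser[[nm]]
    ser[[nm]] <- lapply(stats::setNames(rownames(m), rownames(m)),
                        function(g) as.list(m[g, ]))
  }
  # named vectors must become maps or yaml drops the names
  for (nm in c("grade_probs", "birth_intensity", "outcome_base_logodds",
               "confounder_coefs", "maternal_coefs", "maternal_age_mean",
               "maternal_age_sd", "parity_mean"))
    ser[[nm]] <- as.list(ser[[nm]])
  ser$grade_effect_logodds <- lapply(ser$grade_effect_logodds, as.list)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path a YAML file written by [write_sim_config()].
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  ser <- yaml::read_yaml(path)
  for (nm in c("metric_means_by_grade", "race_probs", "edu_probs", "payer_probs")) {
    rows <- ser[[nm]]
    m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
    rownames(m) <- names(rows)
    ser[[nm]] <- m
  }
  for (nm in c("grade_probs", "birth_intensity", "outcome_base_logodds",
               "confounder_coefs", "maternal_coefs", "maternal_age_mean",
               "maternal_age_sd", "parity_mean"))
    ser[[nm]] <- unlist(ser[[nm]])
  ser$grade_effect_logodds <- lapply(ser$grade_effect_logodds, unlist)
  cfg <- ser
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}
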