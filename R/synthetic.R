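#' Default synthetic-cohort configuration
#'
#' The study conditions the generator emulates: a per-sex four-component
#' Gaussian mixture over (glucose AUC, insulin AUC, uric acid) whose
#' component means are the published k-means cluster centers of the main
#' cohort and whose mixture weights are the published subtype prevalences
#' (MHO 44%, HMO-U 33%, HMO-I 8%, LMO 15%), with OGTT curves constructed to
#' integrate exactly to the sampled AUCs, cluster-dependent comorbidity odds,
#' and an optional partial-sampling (missingness) pattern.
#'
#' Within-cluster SDs (glucose AUC 70 mmol/L·min, insulin AUC 3500 mU/L·min,
#' uric acid 35 \eqn{\mu}mol/L, diagonal covariance) are a generator
#' assumption -- real dispersions are not published -- chosen so nearest
#' centers sit several within-SDs apart, consistent with the clean
#' silhouette structure the subtyping model finds. The insulin curve
#' template peaks later and carries more per-timepoint noise than the
#' glucose template, so imputation quality is ordered glucose > insulin.
#'
#' @param n Cohort size (default 882, the main-cohort size).
#' @param sex_ratio Fraction female (default 482/882).
#' @param missing_fraction Fraction of records losing the timepoints absent
#'   from `missing_pattern` (default 0: complete cohort).
#' @param missing_pattern An [availability_pattern()] describing what the
#'   affected records keep.
#' @return A `synthetic_config` list; see the fields in the source.
#' @export
default_config <- function(n = 882, sex_ratio = 482 / 882,
                           missing_fraction = 0,
                           missing_pattern = availability_pattern(
                             glucose = c(0, 60, 120), insulin = c(0, 60, 120))) {
  centers <- list(
    male = matrix(c(
       993, 17089, 405,
       982, 19951, 585,
      1008, 50543, 489,
      1845,  9477, 404), nrow = 4, byrow = TRUE,
      dimnames = list(subtype_levels(), FEATURE_VARS)),
    female = matrix(c(
       928, 12894, 331,
      1100, 21895, 454,
      1094, 54645, 392,
      1829,  9320, 356), nrow = 4, byrow = TRUE,
      dimnames = list(subtype_levels(), FEATURE_VARS))
  )
  comorbidity_spec <- data.frame(
    name = c("diabetes", "hyperuricemia", "hypertension"),
    base_logodds = c(-2.2, -1.4, -1.7),
    shift_hmo_u = c(0.3, 3.2, 0.7),
    shift_hmo_i = c(0.0, 1.4, 0.4),
    shift_lmo = c(3.0, 0.4, 0.6),
    effect_female = c(-0.2, -0.6, -0.3),
    effect_age = c(0.03, 0.0, 0.04),
    stringsAsFactors = FALSE
  )
  cfg <- list(
    n = n,
    sex_ratio = sex_ratio,
    mixture_weights = setNames(c(0.44, 0.33, 0.08, 0.15), subtype_levels()),
    centers = centers,
    sds = c(glucose_auc = 70, insulin_auc = 3500, uric_acid = 35),
    curve_noise = c(glucose = 0.05, insulin = 0.15),
    templates = list(glucose = c(0, 1, 1, 0.5), insulin = c(0, 0.6, 1, 0.7)),
    fasting_frac = list(glucose = c(0.55, 0.75), insulin = c(0.10, 0.22)),
    age = list(meanlog = log(29), sdlog = 0.28, min = 16, max = 65),
    bmi = list(meanlog = log(35.9), sdlog = 0.12),
    comorbidity_spec = comorbidity_spec,
    missingness = list(pattern = missing_pattern, fraction = missing_fraction)
  )
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  if (abs(sum(cfg$mixture_weights) - 1) > 1e-12) {
    .err("mixture weights must sum to 1", "obty_error_validation")
  }
  if (any(cfg$sds <= 0)) .err("within-cluster SDs must be positive", "obty_error_validation")
  for (s in c("male", "female")) {
    if (any(cfg$centers[[s]] <= 0)) {
      .err("component means must be positive (truncation impossible otherwise)",
           "obty_error_validation")
    }
  }
  invisible(cfg)
}

#' Construct a four-point OGTT curve with a prescribed AUC
#'
#' Builds `fasting + s * template` over the 0/30/60/120 min grid, where the
#' template is a non-negative peak profile with `template[1] = 0` (so the
#' fasting value is preserved exactly) and the scale `s` is solved in closed
#' form from the trapezoid weights so that [trapezoid_auc()] of the curve
#' equals `target_auc` exactly. Optional multiplicative per-timepoint noise
#' perturbs the template shape first; the AUC constraint is then re-imposed
#' through `s`, so the target is preserved under noise.
#'
#' @param target_auc Desired area, concentration·min (must exceed
#'   `120 * fasting`, the flat-curve minimum).
#' @param fasting Fasting (0 min) concentration.
#' @param template Length-4 non-negative shape with `template[1] == 0`.
#' @param noise_sd SD of the multiplicative log-normal shape noise.
#' @return Numeric length-4 curve.
#' @examples
#' build_curve(975, 5) # c(5, 9.1667, 9.1667, 7.0833); AUC exactly 975
#' @export
build_curve <- function(target_auc, fasting, template = c(0, 1, 1, 0.5),
                        noise_sd = 0) {
  if (length(template) != 4L || template[1] != 0 || any(template < 0)) {
    .err("template must be length 4, non-negative, with template[1] = 0",
         "obty_error_shape")
  }
  tn <- template
  if (noise_sd > 0) tn[-1] <- template[-1] * exp(rnorm(3, 0, noise_sd))
  s <- (target_auc - 120 * fasting) / sum(TRAP_WEIGHTS * tn)
  if (is.na(s) || s < 0) {
    .err("unsolvable curve: target AUC below the flat-curve minimum 120*fasting",
         "obty_error_shape")
  }
  fasting + s * tn
}

## vectorized curve construction for a whole cohort; returns n x 4 matrix
.build_curves <- function(auc, fasting, template, noise_sd) {
  n <- length(auc)
  Tn <- matrix(template, n, 4, byrow = TRUE)
  if (noise_sd > 0) {
    Tn[, -1] <- Tn[, -1] * exp(matrix(rnorm(n * 3, 0, noise_sd), n, 3))
  }
  s <- (auc - 120 * fasting) / as.numeric(Tn %*% TRAP_WEIGHTS)
  if (any(s < 0)) .err("unsolvable curve in cohort generation", "obty_error_shape")
  fasting + s * Tn
}

#' Generate a synthetic cohort with known subtype structure
#'
#' Draws each patient's sex, generating subtype (from the mixture weights)
#' and feature vector (per-sex Gaussian component, truncated positive), then
#' constructs OGTT curves whose trapezoid AUCs equal the drawn features
#' exactly, cosmetic demographics (log-normal age with median ~29 y, BMI,
#' HbA1c loosely tied to glucose AUC), and comorbidity flags from the
#' logistic specification given subtype, sex and age (centered at 29 y).
#' If the configuration requests missingness, the stated fraction of records
#' lose the timepoints absent from the pattern. Fully reproducible from the
#' seed.
#'
#' @param config A [default_config()]-style `synthetic_config`.
#' @param seed Integer seed.
#' @return List with `cohort` (a `cohort_table`) and `truth` (data frame
#'   `patient_id`, `sex`, `subtype`, true `glucose_auc`, `insulin_auc`,
#'   `uric_acid` -- retained even for records whose timepoints are removed).
#' @export
generate_cohort <- function(config = default_config(), seed) {
  .validate_config(config)
  set.seed(seed)
  n <- config$n
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(1 - config$sex_ratio, config$sex_ratio))
  subtype <- sample(subtype_levels(), n, replace = TRUE,
                    prob = config$mixture_weights[subtype_levels()])
  feats <- matrix(NA_real_, n, 3, dimnames = list(NULL, FEATURE_VARS))
  for (v in FEATURE_VARS) {
    mu <- vapply(seq_len(n), function(i) config$centers[[sex[i]]][subtype[i], v],
                 numeric(1))
    x <- rnorm(n, mu, config$sds[v])
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- rnorm(sum(bad), mu[bad], config$sds[v])
    }
    feats[, v] <- x
  }
  age <- pmin(pmax(rlnorm(n, config$age$meanlog, config$age$sdlog),
                   config$age$min), config$age$max)
  bmi <- rlnorm(n, config$bmi$meanlog, config$bmi$sdlog)

  ff <- config$fasting_frac
  g_fast <- runif(n, ff$glucose[1], ff$glucose[2]) * feats[, "glucose_auc"] / 120
  i_fast <- runif(n, ff$insulin[1], ff$insulin[2]) * feats[, "insulin_auc"] / 120
  g_curve <- .build_curves(feats[, "glucose_auc"], g_fast,
                           config$templates$glucose, config$curve_noise["glucose"])
  i_curve <- .build_curves(feats[, "insulin_auc"], i_fast,
                           config$templates$insulin, config$curve_noise["insulin"])
  hba1c <- pmax(3.3 + feats[, "glucose_auc"] / 430 + rnorm(n, 0, 0.25), 3.8)

  df <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    sex = sex, age = age, bmi = bmi,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(OGTT_TIMES)) {
    df[[.glu_cols()[j]]] <- g_curve[, j]
    df[[.ins_cols()[j]]] <- i_curve[, j]
  }
  df$uric_acid <- feats[, "uric_acid"]
  df$hba1c <- hba1c
  df$cohort_id <- "synthetic"
  spec <- config$comorbidity_spec
  for (r in seq_len(nrow(spec))) {
    shift <- c(MHO = 0, `HMO-U` = spec$shift_hmo_u[r],
               `HMO-I` = spec$shift_hmo_i[r], LMO = spec$shift_lmo[r])
    eta <- spec$base_logodds[r] + shift[subtype] +
      spec$effect_female[r] * (sex == "female") +
      spec$effect_age[r] * (age - 29)
    df[[spec$name[r]]] <- factor(ifelse(rbinom(n, 1, plogis(eta)) == 1,
                                        "present", "absent"),
                                 levels = c("present", "absent", "unknown"))
  }
  cohort <- as_cohort(df, comorbidities = spec$name, provenance = "synthetic")
  if (config$missingness$fraction > 0) {
    cohort <- apply_missingness(cohort, config$missingness$pattern,
                                config$missingness$fraction,
                                seed = sample.int(.Machine$integer.max, 1))
  }
  truth <- data.frame(patient_id = df$patient_id, sex = sex, subtype = subtype,
                      glucose_auc = feats[, "glucose_auc"],
                      insulin_auc = feats[, "insulin_auc"],
                      uric_acid = feats[, "uric_acid"],
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Remove OGTT timepoints from a fraction of records
#'
#' Emulates cohorts where the four-timepoint OGTT is not routine: the stated
#' fraction of records (sampled with the seed) keep only the timepoints the
#' pattern declares present; all other glucose/insulin cells become missing.
#'
#' @param cohort A `cohort_table`.
#' @param pattern An [availability_pattern()] (what affected records keep).
#' @param fraction Fraction of records affected, in \[0, 1\].
#' @param seed Integer seed.
#' @return The modified `cohort_table`.
#' @export
apply_missingness <- function(cohort, pattern, fraction, seed) {
  if (fraction < 0 || fraction > 1) .err("fraction must be in [0, 1]", "obty_error_validation")
  if (!inherits(pattern, "availability_pattern")) {
    .err("pattern must be an availability_pattern", "obty_error_pattern")
  }
  if (fraction == 0) return(cohort)
  set.seed(seed)
  affected <- sample(seq_len(nrow(cohort)), round(fraction * nrow(cohort)))
  drop_g <- .glu_cols()[!OGTT_TIMES %in% pattern$glucose]
  drop_i <- .ins_cols()[!OGTT_TIMES %in% pattern$insulin]
  for (col in drop_g) cohort[[col]][affected] <- NA_real_
  for (col in drop_i) cohort[[col]][affected] <- NA_real_
  cohort
}
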