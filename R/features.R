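#' Trapezoidal area under a four-point OGTT curve
#'
#' Integrates a concentration curve sampled at 0, 30, 60 and 120 min by the
#' trapezoidal rule, which on this grid reduces to the fixed weights
#' \eqn{15 y_0 + 30 y_{30} + 45 y_{60} + 30 y_{120}}.
#'
#' @param values Numeric vector of length 4 (concentrations at 0, 30, 60,
#'   120 min, in grid order).
#' @return The area in concentration·min.
#' @examples
#' trapezoid_auc(c(5.2, 9.0, 9.0, 7.4)) # 975 mmol/L·min
#' @export
trapezoid_auc <- function(values) {
  if (length(values) != 4L) {
    .err("OGTT curve must have exactly the four grid points 0, 30, 60, 120 min",
         "obty_error_validation")
  }
  if (anyNA(values)) {
    .err("incomplete OGTT curve: missing grid value(s); route through imputation",
         "obty_error_incomplete")
  }
  if (any(values <= 0)) .err("OGTT concentrations must be positive", "obty_error_domain")
  sum(TRAP_WEIGHTS * values)
}

## row-wise trapezoid over an n x 4 matrix (no validation; NA propagates)
.trap_rows <- function(m) as.numeric(m %*% TRAP_WEIGHTS)

.ogtt_complete <- function(cohort) {
  complete.cases(cohort[, c(.glu_cols(), .ins_cols())])
}

#' Derive the three clustering variables from OGTT curves
#'
#' Computes per patient the glucose AUC, insulin AUC (trapezoidal rule over
#' the 0/30/60/120 min grid) and copies uric acid through -- the three
#' variables the subtyping model clusters on.
#'
#' @param cohort A `cohort_table` whose OGTT curves are complete (records with
#'   missing timepoints raise an incomplete-curve error; see
#'   [impute_features()] for partial sampling).
#' @return Data frame with columns `patient_id`, `sex`, `glucose_auc`
#'   (mmol/L·min), `insulin_auc` (mU/L·min), `uric_acid` (\eqn{\mu}mol/L).
#' @export
compute_features <- function(cohort) {
  ok <- .ogtt_complete(cohort)
  if (!all(ok)) {
    .err(sprintf("incomplete OGTT curves for %d record(s) (e.g. %s); use impute_features()",
                 sum(!ok), paste(head(cohort$patient_id[!ok], 5), collapse = ", ")),
         "obty_error_incomplete")
  }
  if (anyNA(cohort$uric_acid)) {
    .err("uric_acid missing for some records", "obty_error_incomplete")
  }
  data.frame(
    patient_id  = cohort$patient_id,
    sex         = cohort$sex,
    glucose_auc = .trap_rows(as.matrix(cohort[, .glu_cols()])),
    insulin_auc = .trap_rows(as.matrix(cohort[, .ins_cols()])),
    uric_acid   = cohort$uric_acid,
    stringsAsFactors = FALSE
  )
}

#' HOMA-IR: homeostatic model assessment of insulin resistance
#'
#' Standard fasting-based index \eqn{g_0 \cdot i_0 / 22.5} with glucose in
#' mmol/L and insulin in mU/L.
#'
#' @param g0 Fasting glucose, mmol/L.
#' @param i0 Fasting insulin, mU/L.
#' @return Dimensionless index (vectorized).
#' @export
homa_ir <- function(g0, i0) {
  if (any(g0 <= 0 | i0 <= 0, na.rm = TRUE)) {
    .err("HOMA-IR requires positive fasting glucose and insulin", "obty_error_domain")
  }
  g0 * i0 / 22.5
}

#' HOMA-beta: homeostasis model assessment of beta-cell function
#'
#' Standard form \eqn{20 i_0 / (g_0 - 3.5)}. The index is undefined at the
#' pole \eqn{g_0 \le 3.5} mmol/L; such records are flagged `NA` rather than
#' aborting a cohort run.
#'
#' @inheritParams homa_ir
#' @return Dimensionless index; `NA` where undefined.
#' @export
homa_beta <- function(g0, i0) {
  out <- ifelse(g0 > 3.5, 20 * i0 / (g0 - 3.5), NA_real_)
  as.numeric(out)
}

#' IGI: insulinogenic index
#'
#' Early-phase secretion index \eqn{(i_{30}-i_0)/(g_{30}-g_0)}; `NA` (flagged
#' undefined) when the glucose increment is zero.
#'
#' @param g0,g30 Glucose at 0 and 30 min, mmol/L.
#' @param i0,i30 Insulin at 0 and 30 min, mU/L.
#' @return Dimensionless index; `NA` where undefined.
#' @export
igi <- function(g0, g30, i0, i30) {
  as.numeric(ifelse(g30 != g0, (i30 - i0) / (g30 - g0), NA_real_))
}

#' WBISI: whole-body (Matsuda) insulin sensitivity index
#'
#' \eqn{10000 / \sqrt{(18 g_0) i_0 (18 \bar g) \bar i}} where the means are
#' taken over the four grid points available here (0, 30, 60, 120 min) and 18
#' converts glucose from mmol/L to mg/dL.
#'
#' @param curve_g Numeric length-4 glucose curve (mmol/L) or n x 4 matrix.
#' @param curve_i Numeric length-4 insulin curve (mU/L) or n x 4 matrix.
#' @return Positive dimensionless index, decreasing in every input value.
#' @export
wbisi <- function(curve_g, curve_i) {
  g <- if (is.matrix(curve_g)) curve_g else matrix(curve_g, nrow = 1)
  i <- if (is.matrix(curve_i)) curve_i else matrix(curve_i, nrow = 1)
  if (ncol(g) != 4L || ncol(i) != 4L) {
    .err("WBISI needs the four grid points 0, 30, 60, 120 min", "obty_error_validation")
  }
  if (anyNA(g) || anyNA(i)) .err("incomplete OGTT curve", "obty_error_incomplete")
  if (any(g <= 0) || any(i <= 0)) .err("OGTT concentrations must be positive", "obty_error_domain")
  out <- 10000 / sqrt(g[, 1] * 18 * i[, 1] * rowMeans(g) * 18 * rowMeans(i))
  as.numeric(out)
}

#' Insulin sensitivity and secretion indices for a cohort
#'
#' Computes the six metabolic indices per patient: HOMA-IR, HOMA-beta, IGI,
#' WBISI and the two disposition indices DI = HOMA-beta/HOMA-IR and
#' DI = IGI × WBISI. Undefined indices (pole cases such as fasting glucose at
#' 3.5 mmol/L) are flagged `NA` per record; the algebraic DI identities hold
#' exactly wherever the parts are defined.
#'
#' The exact formulas are the standard literature forms of these named
#' indices (documented per function); WBISI averages over the four-point grid
#' used throughout rather than Matsuda's original five samples.
#'
#' @param cohort A `cohort_table` with complete OGTT curves.
#' @return Data frame with `patient_id` and columns `homa_ir`, `homa_beta`,
#'   `igi`, `wbisi`, `di_homa`, `di_igi`.
#' @export
compute_indices <- function(cohort) {
  ok <- .ogtt_complete(cohort)
  if (!all(ok)) {
    .err(sprintf("incomplete OGTT curves for %d record(s)", sum(!ok)),
         "obty_error_incomplete")
  }
  g <- as.matrix(cohort[, .glu_cols()])
  i <- as.matrix(cohort[, .ins_cols()])
  hir <- homa_ir(g[, 1], i[, 1])
  hb  <- homa_beta(g[, 1], i[, 1])
  ig  <- igi(g[, 1], g[, 2], i[, 1], i[, 2])
  wb  <- wbisi(g, i)
  data.frame(
    patient_id = cohort$patient_id,
    homa_ir = hir, homa_beta = hb, igi = ig, wbisi = wb,
    di_homa = hb / hir,
    di_igi  = ig * wb,
    stringsAsFactors = FALSE
  )
}
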