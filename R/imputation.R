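#' Availability pattern for partial OGTT sampling
#'
#' Declares which timepoints of the 0/30/60/120 min grid are present for the
#' glucose and insulin curves of a record (or a cohort-wide sampling design).
#'
#' @param glucose,insulin Integer vectors, non-empty subsets of
#'   `c(0, 30, 60, 120)`.
#' @return An `availability_pattern` (list with sorted `glucose` and
#'   `insulin` time vectors).
#' @export
availability_pattern <- function(glucose = OGTT_TIMES, insulin = OGTT_TIMES) {
  check <- function(x, nm) {
    x <- sort(unique(as.integer(x)))
    if (!length(x)) .err(paste0(nm, " pattern must keep at least one timepoint"),
                         "obty_error_pattern")
    if (!all(x %in% OGTT_TIMES)) {
      .err(paste0(nm, " pattern times must be within {0, 30, 60, 120}"),
           "obty_error_pattern")
    }
    x
  }
  structure(list(glucose = check(glucose, "glucose"),
                 insulin = check(insulin, "insulin")),
            class = "availability_pattern")
}

.pattern_key <- function(target, times) {
  paste0(target, "|", paste(sort(times), collapse = ","))
}

.reformulate_y <- function(vars) {
  as.formula(paste(".y ~", if (length(vars)) paste(vars, collapse = " + ") else "1"))
}

#' Stepwise linear regression by partial-F inclusion/exclusion
#'
#' Forward inclusion of the candidate with the smallest partial-F p-value
#' while it is below `p_in`, alternating with backward elimination of the
#' selected predictor with the largest p-value while it exceeds `p_out`,
#' until the selected set is stable. Termination is guaranteed by
#' `p_in < p_out` plus an iteration cap. Rank-deficient selections drop the
#' later-entering collinear predictor with a warning.
#'
#' @param X Numeric matrix or data frame of candidate predictors (no missing
#'   entries).
#' @param y Numeric response vector.
#' @param p_in Inclusion threshold on the partial-F p-value (default 0.05).
#' @param p_out Exclusion threshold (default 0.10).
#' @param max_steps Iteration cap.
#' @return An `imputation_model`: list with `predictors`, `intercept`,
#'   `coef` (named, one per selected predictor), `sigma`.
#' @export
stepwise_fit <- function(X, y, p_in = 0.05, p_out = 0.10, max_steps = 100) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X)))) names(X) <- paste0("x", seq_along(X))
  if (anyNA(X) || anyNA(y)) .err("no missing entries allowed in X or y", "obty_error_validation")
  if (nrow(X) <= ncol(X) + 2L) {
    .err("need more rows than candidate predictors + 2", "obty_error_size")
  }
  if (p_in >= p_out) .err("p_in must be strictly below p_out", "obty_error_validation")
  dat <- cbind(X, .y = y)
  fit_for <- function(vars) lm(.reformulate_y(vars), data = dat)
  # an exactly linear response (e.g. the full-pattern trapezoid identity) is
  # a legitimate input here; silence only summary.lm's perfect-fit notice
  quiet_summary <- function(fit) {
    withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }

  selected <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    candidates <- setdiff(names(X), selected)
    if (length(candidates)) {
      base_fit <- fit_for(selected)
      pv <- vapply(candidates, function(v) {
        a <- anova(base_fit, fit_for(c(selected, v)))
        p <- a$`Pr(>F)`[2]
        if (is.na(p)) 1 else p
      }, numeric(1))
      if (min(pv) < p_in) {
        selected <- c(selected, names(which.min(pv)))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- fit_for(selected)
      cf <- coef(fit)[-1]
      if (anyNA(cf)) {
        drop_var <- selected[max(which(selected %in% names(cf)[is.na(cf)]))]
        warning("dropping collinear predictor ", drop_var)
        selected <- setdiff(selected, drop_var)
        fit <- fit_for(selected)
        changed <- TRUE
      }
      if (length(selected)) {
        sm <- quiet_summary(fit)$coefficients
        pr <- sm[-1, 4]
        names(pr) <- rownames(sm)[-1]
        if (length(pr) && max(pr) > p_out) {
          selected <- setdiff(selected, names(which.max(pr)))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  fit <- fit_for(selected)
  cf <- coef(fit)
  structure(list(
    predictors = selected,
    intercept = unname(cf["(Intercept)"]),
    coef = if (length(selected)) cf[selected] else setNames(numeric(0), character(0)),
    sigma = quiet_summary(fit)$sigma
  ), class = "imputation_model")
}

#' @export
predict.imputation_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  out <- rep(object$intercept, nrow(x))
  for (v in names(object$coef)) out <- out + object$coef[[v]] * x[[v]]
  out
}

## default training patterns: every 1-3 timepoint subset of the grid
.default_time_subsets <- function() {
  subsets <- list()
  for (sz in 1:3) {
    cmb <- combn(OGTT_TIMES, sz)
    for (j in seq_len(ncol(cmb))) subsets[[length(subsets) + 1L]] <- cmb[, j]
  }
  subsets
}

#' Train the AUC imputation suite
#'
#' Fits one stepwise regression per (target AUC, availability pattern):
#' the response is the exact four-point trapezoid AUC of complete-OGTT
#' records, the candidate predictors are the raw concentrations of that
#' analyte at the pattern's present times. The cohort's complete records are
#' split 70/30 (stratified by sex); adjusted R-squared on the held-out 30%
#' is stored per model, computed as \eqn{1-(1-R^2)(n-1)/(n-p-1)} with the
#' test-set n and the selected p (the square root, "adjusted R", is stored
#' alongside).
#'
#' @param cohort A `cohort_table`; records with complete OGTT curves are the
#'   training material.
#' @param patterns List of [availability_pattern()]s, or `NULL` for every
#'   1-3 timepoint subset of the grid for both targets.
#' @param split Training fraction (default 0.70).
#' @param seed Integer seed for the split.
#' @param p_in,p_out Stepwise thresholds.
#' @return An `imputation_suite` (named list of `imputation_model`s keyed by
#'   target and present times).
#' @export
train_imputation_suite <- function(cohort, patterns = NULL, split = 0.70, seed,
                                   p_in = 0.05, p_out = 0.10) {
  complete <- cohort[.ogtt_complete(cohort), , drop = FALSE]
  if (nrow(complete) < 30L) {
    .err(sprintf("too few complete-OGTT records (%d) for a %d/%d split",
                 nrow(complete), round(split * 100), round((1 - split) * 100)),
         "obty_error_size")
  }
  time_subsets <- if (is.null(patterns)) {
    list(glucose_auc = .default_time_subsets(), insulin_auc = .default_time_subsets())
  } else {
    list(glucose_auc = unique(lapply(patterns, `[[`, "glucose")),
         insulin_auc = unique(lapply(patterns, `[[`, "insulin")))
  }
  set.seed(seed)
  train_idx <- unlist(lapply(c("male", "female"), function(s) {
    idx <- which(complete$sex == s)
    sample(idx, round(split * length(idx)))
  }))
  test_idx <- setdiff(seq_len(nrow(complete)), train_idx)

  conc_cols <- list(glucose_auc = setNames(.glu_cols(), OGTT_TIMES),
                    insulin_auc = setNames(.ins_cols(), OGTT_TIMES))
  auc_true <- list(
    glucose_auc = .trap_rows(as.matrix(complete[, .glu_cols()])),
    insulin_auc = .trap_rows(as.matrix(complete[, .ins_cols()]))
  )
  models <- list()
  for (target in c("glucose_auc", "insulin_auc")) {
    for (times in time_subsets[[target]]) {
      cols <- conc_cols[[target]][as.character(sort(times))]
      Xtr <- complete[train_idx, cols, drop = FALSE]
      ytr <- auc_true[[target]][train_idx]
      m <- stepwise_fit(Xtr, ytr, p_in = p_in, p_out = p_out)
      pred <- predict(m, complete[test_idx, cols, drop = FALSE])
      yte <- auc_true[[target]][test_idx]
      sse <- sum((yte - pred)^2)
      sst <- sum((yte - mean(yte))^2)
      r2 <- 1 - sse / sst
      p <- length(m$coef)
      nt <- length(yte)
      adj <- 1 - (1 - r2) * (nt - 1) / (nt - p - 1)
      m$target <- target
      m$times <- sort(times)
      m$r2_test <- r2
      m$adjusted_r2_test <- adj
      m$adjusted_r_test <- sqrt(max(adj, 0))
      m$n_train <- length(train_idx)
      m$n_test <- nt
      models[[.pattern_key(target, times)]] <- m
    }
  }
  structure(list(models = models, split = split), class = "imputation_suite")
}

#' @export
print.imputation_suite <- function(x, ...) {
  cat(sprintf("<imputation_suite> %d models (70/30-style split at %.0f%%)\n",
              length(x$models), 100 * x$split))
  r2 <- vapply(x$models, `[[`, numeric(1), "adjusted_r2_test")
  cat(sprintf("test adjusted R^2: %.3f - %.3f (mean %.3f)\n",
              min(r2), max(r2), mean(r2)))
  invisible(x)
}

#' Derive features for a cohort with partial OGTT sampling
#'
#' Complete records bypass imputation and are identical to
#' [compute_features()] output. For a record with missing timepoints, the
#' matching (target, present-times) model of the suite estimates the AUC;
#' the estimate is flagged in the `glucose_imputed`/`insulin_imputed`
#' columns together with the model's held-out adjusted R-squared, so callers
#' can see which estimates are lower-confidence (fasting-only patterns carry
#' the lowest R-squared). A record whose pattern has no trained model raises
#' an error listing the trained patterns.
#'
#' @param cohort A `cohort_table`.
#' @param suite An `imputation_suite` from [train_imputation_suite()].
#' @return Data frame like [compute_features()] plus imputation provenance
#'   columns `glucose_imputed`, `insulin_imputed`, `glucose_r2`, `insulin_r2`.
#' @export
impute_features <- function(cohort, suite) {
  if (anyNA(cohort$uric_acid)) .err("uric_acid missing for some records", "obty_error_incomplete")
  n <- nrow(cohort)
  out <- data.frame(patient_id = cohort$patient_id, sex = cohort$sex,
                    glucose_auc = NA_real_, insulin_auc = NA_real_,
                    uric_acid = cohort$uric_acid,
                    glucose_imputed = FALSE, insulin_imputed = FALSE,
                    glucose_r2 = NA_real_, insulin_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  specs <- list(
    list(target = "glucose_auc", cols = setNames(.glu_cols(), OGTT_TIMES),
         flag = "glucose_imputed", r2col = "glucose_r2"),
    list(target = "insulin_auc", cols = setNames(.ins_cols(), OGTT_TIMES),
         flag = "insulin_imputed", r2col = "insulin_r2")
  )
  for (sp in specs) {
    m <- as.matrix(cohort[, sp$cols])
    present <- !is.na(m)
    complete <- rowSums(present) == 4L
    out[[sp$target]][complete] <- .trap_rows(m[complete, , drop = FALSE])
    for (i in which(!complete)) {
      times <- OGTT_TIMES[present[i, ]]
      if (!length(times)) {
        .err(sprintf("record %s has no %s measurements at all",
                     cohort$patient_id[i], sp$target), "obty_error_pattern")
      }
      key <- .pattern_key(sp$target, times)
      model <- suite$models[[key]]
      if (is.null(model)) {
        .err(sprintf("no imputation model for pattern %s; trained patterns: %s",
                     key, paste(names(suite$models), collapse = "; ")),
             "obty_error_pattern")
      }
      row <- as.data.frame(t(setNames(m[i, present[i, ]], sp$cols[as.character(times)])))
      out[[sp$target]][i] <- predict(model, row)
      out[[sp$flag]][i] <- TRUE
      out[[sp$r2col]][i] <- model$adjusted_r2_test
    }
  }
  out
}
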