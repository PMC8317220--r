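#' Binary logistic regression with separation reporting
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`stats::glm`, convergence tolerance 1e-8, at most 50 iterations).
#' Complete or quasi-separation is detected (divergent coefficients or
#' fitted probabilities pinned at 0/1) and reported as a flag rather than a
#' crash, so a cohort run survives comorbidities with empty cells.
#'
#' @param outcome Binary (0/1 or logical) vector, no missing values.
#' @param design Data frame of predictors (subtype dummies enter as a factor
#'   with the reference level first).
#' @return A `logistic_fit`: list with `coefficients`, `vcov`, `converged`,
#'   `separation`, and the underlying `glm` object.
#' @export
fit_logistic <- function(outcome, design) {
  y <- as.numeric(outcome)
  if (anyNA(y) || anyNA(design)) {
    .err("missing values in outcome or design", "obty_error_validation")
  }
  if (!all(y %in% c(0, 1))) .err("outcome must be binary", "obty_error_validation")
  dat <- cbind(.y = y, as.data.frame(design))
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separation <- warned || any(abs(coef(fit)) > 15, na.rm = TRUE)
  structure(list(coefficients = coef(fit), vcov = vcov(fit),
                 converged = fit$converged, separation = separation,
                 glm = fit),
            class = "logistic_fit")
}

#' Adjusted odds ratios of comorbidities per subtype
#'
#' For each comorbidity, fits outcome ~ subtype + sex + age by logistic
#' regression with MHO as the reference category (age enters linearly in
#' years) and reports per non-reference subtype the adjusted odds ratio
#' \eqn{e^\beta} with its Wald 95% confidence interval
#' \eqn{e^{\beta \pm 1.96\,SE}} and p-value. Records with unknown
#' comorbidity state are dropped per comorbidity (complete-case). A subtype
#' with zero cases propagates a separation flag (CI reported as (0, Inf)).
#'
#' @param cohort A `cohort_table`.
#' @param partition Partition data frame (`patient_id`, `subtype`) covering
#'   all records, e.g. from [fit_sex_stratified()] or [assign_to_model()].
#' @param comorbidities Comorbidity column names (default: all in the
#'   cohort).
#' @param reference Reference subtype (default `"MHO"`).
#' @return Data frame with one row per (comorbidity, non-reference subtype):
#'   `comorbidity`, `subtype`, `aor`, `ci_low`, `ci_high`, `p`, `separation`,
#'   `n`; attribute `adjusted_for = c("sex", "age")`.
#' @export
aor_table <- function(cohort, partition, comorbidities = comorbidity_names(cohort),
                      reference = "MHO") {
  dat <- merge(as.data.frame(cohort), partition[, c("patient_id", "subtype")],
               by = "patient_id")
  if (nrow(dat) != nrow(cohort) || anyNA(dat$subtype)) {
    .err("partition must label every record exactly once", "obty_error_validation")
  }
  if (anyNA(dat$age) || anyNA(dat$sex)) {
    .err("sex and age must be non-missing for adjustment", "obty_error_validation")
  }
  lv <- c(reference, setdiff(intersect(subtype_levels(), unique(dat$subtype)), reference))
  dat$subtype <- factor(dat$subtype, levels = lv)
  rows <- list()
  for (cm in comorbidities) {
    y <- c(present = 1, absent = 0, unknown = NA)[as.character(dat[[cm]])]
    keep <- !is.na(y)
    fit <- fit_logistic(y[keep],
                        data.frame(subtype = dat$subtype[keep],
                                   sex = dat$sex[keep], age = dat$age[keep]))
    cf <- fit$coefficients
    se <- sqrt(diag(fit$vcov))
    for (sub in lv[-1]) {
      term <- paste0("subtype", sub)
      b <- cf[[term]]; s <- se[[term]]
      rows[[length(rows) + 1L]] <- data.frame(
        comorbidity = cm, subtype = sub,
        aor = exp(b),
        ci_low = if (fit$separation) 0 else exp(b - qnorm(0.975) * s),
        ci_high = if (fit$separation) Inf else exp(b + qnorm(0.975) * s),
        p = 2 * pnorm(-abs(b / s)),
        separation = fit$separation,
        n = sum(keep),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "adjusted_for") <- c("sex", "age")
  out
}

#' Pearson chi-square test of an r x c contingency table
#'
#' \eqn{\sum (O-E)^2/E} with \eqn{(r-1)(c-1)} degrees of freedom, no
#' continuity correction.
#'
#' @param contingency Matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || sum(m) == 0) .err("counts must be non-negative with n > 0",
                                      "obty_error_validation")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    .err("degenerate table: zero row or column marginal", "obty_error_degenerate")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Omnibus and pairwise group comparison of a continuous variable
#'
#' One-way ANOVA (or ANCOVA with covariates entering as linear terms) on an
#' optionally transformed variable, followed by all pairwise subtype
#' contrasts with Bonferroni correction (raw p multiplied by the number of
#' pairs, capped at 1). The transform is configuration, not automated
#' normality testing.
#'
#' @param values Numeric vector, one per patient.
#' @param partition Group labels (subtype per patient).
#' @param covariates Optional data frame of adjustment covariates.
#' @param transform One of `"none"`, `"log"`, `"sqrt"`.
#' @return List with `omnibus_f`, `omnibus_p`, `pairwise` (data frame
#'   `contrast`, `estimate`, `p_adjusted`), `transform`.
#' @export
group_compare <- function(values, partition, covariates = NULL,
                          transform = c("none", "log", "sqrt")) {
  transform <- match.arg(transform)
  group <- factor(as.character(partition))
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    .err("need at least 2 groups with n >= 2 each", "obty_error_size")
  }
  y <- switch(transform,
    none = values,
    log = {
      if (any(values <= 0, na.rm = TRUE)) {
        .err(paste0("log transform on non-positive value(s) at row(s) ",
                    paste(head(which(values <= 0), 5), collapse = ", ")),
             "obty_error_validation")
      }
      log(values)
    },
    sqrt = {
      if (any(values < 0, na.rm = TRUE)) {
        .err(paste0("sqrt transform on negative value(s) at row(s) ",
                    paste(head(which(values < 0), 5), collapse = ", ")),
             "obty_error_validation")
      }
      sqrt(values)
    })
  dat <- data.frame(.y = y, group = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  full <- lm(.y ~ ., data = dat)
  null <- lm(.y ~ . - group, data = dat)
  a <- anova(null, full)
  emm <- emmeans::emmeans(full, "group")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "bonferroni"))
  list(
    omnibus_f = a$F[2],
    omnibus_p = a$`Pr(>F)`[2],
    pairwise = data.frame(contrast = as.character(prs$contrast),
                          estimate = prs$estimate,
                          p_adjusted = prs$p.value,
                          stringsAsFactors = FALSE),
    transform = transform
  )
}
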