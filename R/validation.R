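#' Assign a cohort to a fitted subtype model
#'
#' Maps every patient to the nearest cluster center of the model, in the
#' model's normalized space for the patient's sex stratum: squared Euclidean
#' distance for k-means models, the log-likelihood distance increment for
#' two-step models. Deterministic; ties break toward the lower-index center.
#'
#' @param model A `cluster_model`.
#' @param cohort A `cohort_table`.
#' @param suite Optional imputation suite for records with partial OGTT
#'   sampling (defaults to the suite stored in the model, if any).
#' @param own_normalization Normalize the cohort with its own per-stratum
#'   means/SDs instead of the model's stored parameters (default `FALSE`,
#'   which keeps the model portable).
#' @return Partition data frame: `patient_id`, `sex`, `subtype`, ordered by
#'   patient id.
#' @export
assign_to_model <- function(model, cohort, suite = NULL, own_normalization = FALSE) {
  if (is.null(suite)) suite <- model$imputation_suite
  feats <- if (is.null(suite)) compute_features(cohort) else impute_features(cohort, suite)
  parts <- lapply(c("male", "female"), function(s) {
    sub <- feats[feats$sex == s, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    st <- model$strata[[s]]
    norm <- if (own_normalization) zscore_fit(sub[, FEATURE_VARS]) else st$normalization
    Z <- zscore_apply(norm, as.matrix(sub[, FEATURE_VARS]))
    Cz <- zscore_apply(st$normalization, st$centers)
    idx <- if (identical(model$algorithm, "twostep") && !is.null(st$summaries)) {
      apply(Z, 1, function(x) which.min(.loglik_point_dist(x, st$summaries)))
    } else {
      max.col(-.sqdist(Z, Cz), ties.method = "first")
    }
    data.frame(patient_id = sub$patient_id, sex = s,
               subtype = st$labels[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[order(out$patient_id), ]
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Optimal matching between the labels of two partitions
#'
#' Finds the one-to-one mapping from the `assigned` partition's labels to the
#' `reference` partition's labels that maximizes total agreement, by
#' exhaustive search over the k! permutations of the k x k contingency table
#' (k <= 8).
#'
#' @param reference,assigned Label vectors over the same patients (same
#'   length, same number of distinct labels).
#' @return Named character vector mapping assigned labels (names) to
#'   reference labels (values), with attribute `agreement` (count).
#' @export
match_clusters <- function(reference, assigned) {
  reference <- as.character(reference); assigned <- as.character(assigned)
  if (length(reference) != length(assigned)) {
    .err("partitions must cover the same patients", "obty_error_validation")
  }
  ref_labels <- sort(unique(reference))
  asg_labels <- sort(unique(assigned))
  if (length(ref_labels) != length(asg_labels)) {
    tab <- table(reference, assigned)
    .err(paste0("partitions have different cluster counts (",
                length(ref_labels), " vs ", length(asg_labels), "); contingency:\n",
                paste(capture.output(print(tab)), collapse = "\n")),
         "obty_error_mismatch")
  }
  k <- length(ref_labels)
  if (k > 8L) .err("exhaustive matching supports k <= 8", "obty_error_size")
  tab <- table(factor(reference, ref_labels), factor(assigned, asg_labels))
  perms <- .permutations(seq_len(k))
  agree <- apply(perms, 1, function(p) sum(tab[cbind(p, seq_len(k))]))
  best <- perms[which.max(agree), ]
  structure(setNames(ref_labels[best], asg_labels), agreement = max(agree))
}

#' Agreement metrics between a reference and an assigned partition
#'
#' After optimal label matching, computes the 4 x 4 (k x k) confusion matrix
#' and per-cluster one-vs-rest accuracy \eqn{(TP+TN)/n}, sensitivity
#' \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)} and Jaccard coefficient
#' \eqn{|A \cap B| / |A \cup B|} on member sets, plus their means across
#' clusters. Empty clusters yield `NA` metrics with an explicit flag instead
#' of a division by zero.
#'
#' @param reference,assigned Label vectors over the same patients.
#' @param matching Optional precomputed [match_clusters()] result.
#' @return An `assignment_report`: list with `confusion`, `metrics` (one row
#'   per cluster), `mean_accuracy`, `mean_sensitivity`, `mean_specificity`,
#'   `mean_jaccard`, `matching`, `n`.
#' @export
agreement_report <- function(reference, assigned, matching = NULL) {
  reference <- as.character(reference); assigned <- as.character(assigned)
  if (is.null(matching)) matching <- match_clusters(reference, assigned)
  mapped <- unname(matching[assigned])
  labels <- sort(unique(c(reference, mapped)))
  canon <- intersect(subtype_levels(), labels)
  if (length(canon) == length(labels)) labels <- canon
  n <- length(reference)
  confusion <- table(reference = factor(reference, labels),
                     assigned = factor(mapped, labels))
  metrics <- do.call(rbind, lapply(labels, function(lb) {
    in_ref <- reference == lb
    in_asg <- mapped == lb
    tp <- sum(in_ref & in_asg); fn <- sum(in_ref & !in_asg)
    fp <- sum(!in_ref & in_asg); tn <- sum(!in_ref & !in_asg)
    flag <- (tp + fn) == 0 || (tn + fp) == 0 || (tp + fn + fp) == 0
    data.frame(
      cluster = lb,
      accuracy = (tp + tn) / n,
      sensitivity = if ((tp + fn) > 0) tp / (tp + fn) else NA_real_,
      specificity = if ((tn + fp) > 0) tn / (tn + fp) else NA_real_,
      jaccard = if ((tp + fn + fp) > 0) tp / (tp + fn + fp) else NA_real_,
      empty_flag = flag,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    confusion = confusion,
    metrics = metrics,
    mean_accuracy = mean(metrics$accuracy, na.rm = TRUE),
    mean_sensitivity = mean(metrics$sensitivity, na.rm = TRUE),
    mean_specificity = mean(metrics$specificity, na.rm = TRUE),
    mean_jaccard = mean(metrics$jaccard, na.rm = TRUE),
    matching = matching,
    n = n
  ), class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("<assignment_report> n = %d\n", x$n))
  print(x$confusion)
  print(x$metrics, row.names = FALSE, digits = 3)
  cat(sprintf("means: ACC %.3f, SEN %.3f, SPE %.3f, Jaccard %.3f\n",
              x$mean_accuracy, x$mean_sensitivity, x$mean_specificity,
              x$mean_jaccard))
  invisible(x)
}

#' Full verification run against a fitted model
#'
#' The cross-cohort stability evaluation: clusters the verification cohort
#' independently (same algorithm, sex-stratified -- the reference partition),
#' assigns its patients to the main model's centers (the assigned partition),
#' optimally matches the two, and reports per-cluster
#' accuracy/sensitivity/specificity and Jaccard coefficients.
#'
#' @param model The fitted main `cluster_model`.
#' @param verification_cohort A `cohort_table` (n > 40, both sexes).
#' @param config A [clustering_config()] for the independent clustering.
#' @param seed Integer seed for the independent clustering.
#' @param suite Optional imputation suite.
#' @return List with `report` (an `assignment_report`), `reference` and
#'   `assigned` partitions, and `reference_model`.
#' @export
verification_run <- function(model, verification_cohort,
                             config = clustering_config(), seed, suite = NULL) {
  if (nrow(verification_cohort) <= 40L) {
    .err("verification cohort too small to cluster independently (need n > 40)",
         "obty_error_size")
  }
  ref_model <- fit_sex_stratified(verification_cohort, model$algorithm,
                                  config = config, seed = seed, suite = suite)
  reference <- ref_model$partition
  assigned <- assign_to_model(model, verification_cohort, suite = suite,
                              own_normalization = config$own_normalization)
  stopifnot(identical(reference$patient_id, assigned$patient_id))
  report <- agreement_report(reference$subtype, assigned$subtype)
  list(report = report, reference = reference, assigned = assigned,
       reference_model = ref_model)
}
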