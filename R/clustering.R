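#' Fit z-score normalization parameters
#'
#' Per-variable mean and standard deviation (sample, n-1 denominator, the
#' SPSS convention) of the clustering features, fitted within one sex stratum.
#'
#' @param features Numeric matrix or data frame of clustering variables
#'   (columns `glucose_auc`, `insulin_auc`, `uric_acid`).
#' @return List with numeric vectors `mean` and `sd`, class
#'   `normalization_params`.
#' @export
zscore_fit <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) .err("need at least 2 observations to normalize", "obty_error_size")
  mu <- colMeans(x)
  s  <- apply(x, 2, sd)
  if (any(s <= 0 | !is.finite(s))) {
    .err(paste0("degenerate (zero-SD) variable(s): ",
                paste(colnames(x)[s <= 0 | !is.finite(s)], collapse = ", ")),
         "obty_error_degenerate")
  }
  structure(list(mean = mu, sd = s), class = "normalization_params")
}

#' Apply (or invert) a z-score normalization
#'
#' @param params A `normalization_params` object from [zscore_fit()].
#' @param v Numeric matrix/data frame (rows = observations) or vector.
#' @param inverse If `TRUE`, map z-scores back to raw units (`z * sd + mean`).
#' @return Matrix (or vector) on the transformed scale.
#' @export
zscore_apply <- function(params, v, inverse = FALSE) {
  vec <- is.null(dim(v))
  x <- if (vec) matrix(as.numeric(v), nrow = 1) else as.matrix(v)
  out <- if (inverse) {
    sweep(sweep(x, 2, params$sd, "*"), 2, params$mean, "+")
  } else {
    sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  }
  if (vec) drop(out) else out
}

## squared Euclidean distances, n x k
.sqdist <- function(X, C) {
  out <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  out[out < 0] <- 0
  out
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- .sqdist(X, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L) + 1L) {
    idx <- if (all(d2 <= 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, .sqdist(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

.lloyd <- function(X, centers, max_iter, tol) {
  n <- nrow(X); k <- nrow(centers)
  cluster <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    D <- .sqdist(X, centers)
    cluster <- max.col(-D, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      members <- cluster == j
      if (!any(members)) {
        # empty cluster: re-seed at the point farthest from its own center
        own <- D[cbind(seq_len(n), cluster)]
        newc[j, ] <- X[which.max(own), ]
      } else {
        newc[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol) break
  }
  D <- .sqdist(X, centers)
  cluster <- max.col(-D, ties.method = "first")
  wcss <- sum(D[cbind(seq_len(n), cluster)])
  list(centers = centers, cluster = cluster, wcss = wcss, iterations = it)
}

#' k-means clustering (Lloyd iterations, k-means++ starts)
#'
#' Runs Lloyd's algorithm from `n_init` k-means++-seeded starts and keeps the
#' solution with the lowest within-cluster sum of squares. Iteration stops
#' when the largest center movement falls below `tol` or after `max_iter`
#' iterations (defaults 1e-5 and 30, the settings the subtyping model uses).
#' Empty clusters are re-seeded at the point farthest from its assigned
#' center.
#'
#' @param points Numeric matrix of normalized feature vectors (rows =
#'   observations).
#' @param k Number of clusters (>= 2, < number of points).
#' @param max_iter,tol Lloyd iteration controls.
#' @param n_init Number of random restarts.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return List with `centers` (k x d matrix), `cluster` (integer vector),
#'   `wcss`, `iterations`.
#' @export
kmeans_cluster <- function(points, k, max_iter = 30, tol = 1e-5, n_init = 20,
                           seed = NULL) {
  X <- as.matrix(points)
  if (k < 2L) .err("k must be at least 2", "obty_error_size")
  if (nrow(X) <= k) {
    if (nrow(X) == k) {
      return(list(centers = X, cluster = seq_len(k), wcss = 0, iterations = 0L))
    }
    .err("need more points than clusters", "obty_error_size")
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- .lloyd(X, .kmeanspp_init(X, k), max_iter, tol)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' Mean silhouette width of a partition
#'
#' Per point, \eqn{s_i = (b_i - a_i)/\max(a_i, b_i)} with \eqn{a_i} the mean
#' Euclidean distance to the point's own cluster (excluding itself) and
#' \eqn{b_i} the smallest mean distance to any other cluster; points in
#' singleton clusters contribute 0. Returns the mean over all points.
#'
#' @param points Numeric matrix in the normalized feature space.
#' @param cluster Integer or factor cluster membership.
#' @param d Optional precomputed distance matrix (`as.matrix(dist(points))`).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
mean_silhouette <- function(points, cluster, d = NULL) {
  cl <- as.integer(factor(cluster))
  k <- max(cl)
  if (k < 2L) .err("silhouette is undefined for a single cluster", "obty_error_size")
  if (is.null(d)) d <- as.matrix(dist(as.matrix(points)))
  n <- nrow(d)
  sizes <- tabulate(cl, k)
  # column j of M: summed distance from each point to cluster j
  M <- sapply(seq_len(k), function(j) rowSums(d[, cl == j, drop = FALSE]))
  a <- M[cbind(seq_len(n), cl)] / pmax(sizes[cl] - 1L, 1L)
  Mmean <- sweep(M, 2, sizes, "/")
  Mmean[cbind(seq_len(n), cl)] <- Inf
  b <- apply(Mmean, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[cl] == 1L] <- 0
  mean(s)
}

#' Select the number of clusters by mean silhouette
#'
#' Runs [kmeans_cluster()] for each candidate `k` and returns the one with
#' the largest mean silhouette width (ties broken toward smaller `k`). The
#' silhouette profile is attached as attribute `"silhouette"` so callers can
#' flag "no structure" when even the best value is low.
#'
#' @param points Numeric matrix in the normalized feature space.
#' @param k_range Candidate cluster counts (default 2..8).
#' @param seed Optional integer seed.
#' @param ... Passed to [kmeans_cluster()] (`n_init`, `max_iter`, `tol`).
#' @return Integer `k`, with attribute `silhouette` (named numeric vector).
#' @export
select_k <- function(points, k_range = 2:8, seed = NULL, ...) {
  X <- as.matrix(points)
  if (min(k_range) < 2L || max(k_range) >= nrow(X)) {
    .err("k_range must lie within [2, n)", "obty_error_size")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(dist(X))
  sil <- vapply(k_range, function(k) {
    fit <- kmeans_cluster(X, k, ...)
    mean_silhouette(X, fit$cluster, d = d)
  }, numeric(1))
  names(sil) <- k_range
  k <- k_range[which.max(sil)] # which.max takes the first (smallest k) on ties
  structure(as.integer(k), silhouette = sil)
}

#' Label four cluster centers with the metabolic subtype names
#'
#' Deterministic rule applied to the centers in raw units: the center with
#' the largest glucose AUC is LMO; among the rest, the largest insulin AUC is
#' HMO-I; of the remaining two, the larger uric acid is HMO-U and the last is
#' MHO. Order-invariant; a tie in a deciding variable (practically impossible
#' on continuous data) is an error.
#'
#' @param centers 4 x 3 numeric matrix with columns `glucose_auc`,
#'   `insulin_auc`, `uric_acid`, in raw units.
#' @return Character vector of subtype labels aligned with the center rows.
#' @export
label_subtypes <- function(centers) {
  m <- as.matrix(centers)
  if (nrow(m) != 4L) .err("subtype labeling requires exactly 4 centers", "obty_error_size")
  cols <- FEATURE_VARS
  if (!all(cols %in% colnames(m))) colnames(m) <- cols
  labels <- rep(NA_character_, 4L)
  pick <- function(idx, var) {
    v <- m[idx, var]
    if (sum(v == max(v)) > 1L) {
      .err(paste0("tie in deciding variable ", var), "obty_error_validation")
    }
    idx[which.max(v)]
  }
  rest <- 1:4
  i <- pick(rest, "glucose_auc"); labels[i] <- "LMO";  rest <- setdiff(rest, i)
  i <- pick(rest, "insulin_auc"); labels[i] <- "HMO-I"; rest <- setdiff(rest, i)
  i <- pick(rest, "uric_acid");   labels[i] <- "HMO-U"; rest <- setdiff(rest, i)
  labels[rest] <- "MHO"
  labels
}

#' Clustering configuration
#'
#' @param k_range Candidate cluster counts for model selection.
#' @param n_init k-means restarts.
#' @param max_iter,tol Lloyd iteration controls.
#' @param pooled_normalization Normalize on the pooled cohort instead of per
#'   sex stratum (default `FALSE`: fully separate sub-models).
#' @param own_normalization When assigning an external cohort to a model,
#'   use the cohort's own means/SDs instead of the model's stored parameters
#'   (default `FALSE`: the stored parameters make the model portable).
#' @return A named list, class `clustering_config`.
#' @export
clustering_config <- function(k_range = 2:8, n_init = 20, max_iter = 30,
                              tol = 1e-5, pooled_normalization = FALSE,
                              own_normalization = FALSE) {
  structure(list(k_range = k_range, n_init = n_init, max_iter = max_iter,
                 tol = tol, pooled_normalization = pooled_normalization,
                 own_normalization = own_normalization),
            class = "clustering_config")
}

#' Fit the sex-stratified subtyping model
#'
#' The main model of the package: computes the three clustering features per
#' record (through the imputation suite when OGTT sampling is partial),
#' z-normalizes within each sex stratum, clusters each stratum separately
#' (k-means with silhouette-based selection of k, or two-step with BIC-based
#' selection), de-normalizes the centers back to raw units, pools the two
#' sub-model partitions, and attaches the metabolic subtype labels.
#'
#' If the two strata select different cluster counts, the k chosen on the
#' larger stratum is imposed on both and a warning is emitted (the subtype
#' structure is defined as common across sexes).
#'
#' Records are processed in patient-id order internally, so the fit is
#' invariant to the row order of the cohort at a fixed seed.
#'
#' @param cohort A `cohort_table` with both sexes present (> 10 records each).
#' @param algorithm `"kmeans"` or `"twostep"`.
#' @param config A [clustering_config()].
#' @param seed Integer seed (mandatory: all stochastic steps derive from it).
#' @param suite Optional [train_imputation_suite()] result for records with
#'   partial OGTT sampling.
#' @return A `cluster_model`: list with `algorithm`, `k`, `strata` (per sex:
#'   `normalization`, `centers` in raw units, `labels`, and for two-step the
#'   cluster `summaries`), `mean_silhouette`, `format_version`, and the
#'   training `partition` (data frame `patient_id`, `sex`, `subtype`).
#' @export
fit_sex_stratified <- function(cohort, algorithm = c("kmeans", "twostep"),
                               config = clustering_config(), seed, suite = NULL) {
  algorithm <- match.arg(algorithm)
  if (missing(seed)) .err("seed is a mandatory configuration field", "obty_error_validation")
  feats <- if (is.null(suite)) compute_features(cohort) else impute_features(cohort, suite)
  feats <- feats[order(feats$patient_id), , drop = FALSE]
  counts <- table(feats$sex)
  for (s in c("male", "female")) {
    if (is.na(counts[s]) || counts[s] <= 10L) {
      .err(paste0("missing or undersized sex stratum: ", s), "obty_error_stratum")
    }
  }
  set.seed(seed)
  pooled_norm <- if (isTRUE(config$pooled_normalization)) {
    zscore_fit(feats[, FEATURE_VARS])
  } else NULL

  strata <- list()
  fits <- list()
  for (s in c("male", "female")) {
    sub <- feats[feats$sex == s, , drop = FALSE]
    Xraw <- as.matrix(sub[, FEATURE_VARS])
    norm <- if (is.null(pooled_norm)) zscore_fit(Xraw) else pooled_norm
    Z <- zscore_apply(norm, Xraw)
    if (algorithm == "kmeans") {
      ksel <- select_k(Z, config$k_range, n_init = config$n_init,
                       max_iter = config$max_iter, tol = config$tol)
      fit <- kmeans_cluster(Z, as.integer(ksel), max_iter = config$max_iter,
                            tol = config$tol, n_init = config$n_init)
      fit$k <- as.integer(ksel)
    } else {
      fit <- twostep_cluster(Z, max_k = max(config$k_range))
    }
    fits[[s]] <- list(fit = fit, Z = Z, norm = norm, ids = sub$patient_id)
  }
  ks <- vapply(fits, function(f) f$fit$k, integer(1))
  if (ks["male"] != ks["female"]) {
    larger <- names(which.max(counts))
    k_common <- ks[[larger]]
    warning(sprintf(
      "sex strata selected different k (male %d, female %d); imposing k = %d from the larger stratum (%s)",
      ks["male"], ks["female"], k_common, larger))
    for (s in c("male", "female")) {
      if (fits[[s]]$fit$k != k_common) {
        fits[[s]]$fit <- if (algorithm == "kmeans") {
          c(kmeans_cluster(fits[[s]]$Z, k_common, max_iter = config$max_iter,
                           tol = config$tol, n_init = config$n_init),
            list(k = k_common))
        } else {
          twostep_cluster(fits[[s]]$Z, max_k = max(config$k_range), k = k_common)
        }
      }
    }
  }
  k <- fits[["male"]]$fit$k

  partition <- NULL
  sils <- numeric(0)
  for (s in c("male", "female")) {
    f <- fits[[s]]
    centers_raw <- zscore_apply(f$norm, f$fit$centers, inverse = TRUE)
    colnames(centers_raw) <- FEATURE_VARS
    labels <- if (k == 4L) label_subtypes(centers_raw) else paste0("C", seq_len(k))
    strata[[s]] <- list(
      normalization = f$norm,
      centers = centers_raw,
      labels = labels,
      summaries = if (algorithm == "twostep") {
        .cluster_summaries(f$Z, f$fit$cluster, k)
      } else NULL
    )
    sils[s] <- mean_silhouette(f$Z, f$fit$cluster)
    partition <- rbind(partition, data.frame(
      patient_id = f$ids, sex = s, subtype = labels[f$fit$cluster],
      stringsAsFactors = FALSE))
  }
  if (!setequal(strata$male$labels, strata$female$labels)) {
    .err("cross-sex label sets differ", "obty_error_validation")
  }
  structure(list(
    algorithm = algorithm,
    k = k,
    strata = strata,
    mean_silhouette = unname(mean(sils)),
    format_version = MODEL_FORMAT_VERSION,
    partition = partition[order(partition$patient_id), ]
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> algorithm: %s, k = %d, mean silhouette = %.3f\n",
              x$algorithm, x$k, x$mean_silhouette))
  for (s in names(x$strata)) {
    cat(sprintf("-- %s centers (raw units):\n", s))
    m <- round(x$strata[[s]]$centers)
    rownames(m) <- x$strata[[s]]$labels
    print(m)
  }
  invisible(x)
}
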