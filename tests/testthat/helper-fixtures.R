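# fixtures are built in code; no data files

# one patient row whose OGTT curves integrate exactly to the requested AUCs
make_patient_row <- function(id, sex, gauc, iauc, ua, age = 30, bmi = 35) {
  gc <- build_curve(gauc, fasting = 0.65 * gauc / 120)
  ic <- build_curve(iauc, fasting = 0.16 * iauc / 120,
                    template = c(0, 0.6, 1, 0.7))
  df <- data.frame(patient_id = id, sex = sex, age = age, bmi = bmi,
                   stringsAsFactors = FALSE)
  for (j in 1:4) {
    df[[paste0("glu_", c(0, 30, 60, 120)[j])]] <- gc[j]
    df[[paste0("ins_", c(0, 30, 60, 120)[j])]] <- ic[j]
  }
  df$uric_acid <- ua
  df$hba1c <- 5.5
  df$cohort_id <- "fixture"
  df
}

# cohort of patients placed exactly at the published per-sex cluster centers
make_center_cohort <- function() {
  cfg <- default_config()
  rows <- list()
  for (s in c("male", "female")) {
    cen <- cfg$centers[[s]]
    for (lb in rownames(cen)) {
      rows[[length(rows) + 1L]] <- make_patient_row(
        paste0(s, "-", lb), s, cen[lb, "glucose_auc"],
        cen[lb, "insulin_auc"], cen[lb, "uric_acid"])
    }
  }
  as_cohort(do.call(rbind, rows), provenance = "centers")
}

# a portable model whose centers are the published ones and whose
# normalization comes from a default-config synthetic cohort
make_reference_model <- function(seed = 101) {
  cfg <- default_config()
  g <- generate_cohort(cfg, seed = seed)
  feats <- compute_features(g$cohort)
  strata <- lapply(c(male = "male", female = "female"), function(s) {
    X <- as.matrix(feats[feats$sex == s, c("glucose_auc", "insulin_auc", "uric_acid")])
    centers <- cfg$centers[[s]]
    list(normalization = zscore_fit(X), centers = centers,
         labels = label_subtypes(centers))
  })
  structure(list(algorithm = "kmeans", k = 4L, strata = strata,
                 mean_silhouette = NA_real_, format_version = "1.0"),
            class = "cluster_model")
}

# well-separated Gaussian blobs for clustering tests
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[j, ], each = n_per),
                 sd = sd), n_per, ncol(centers))
  }))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# exhaustive-search k-means oracle: minimum WCSS over all assignments
brute_force_wcss <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    w <- sum(vapply(seq_len(k), function(j) {
      m <- X[a == j, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
    best <- min(best, w)
  }
  best
}
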