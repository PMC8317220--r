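## Two-step clustering in the SPSS tradition, at desk scale: exact
## agglomerative merging from singletons (no CF-tree pre-clustering), with
## the log-likelihood inter-cluster distance
##   d(j, s) = xi_j + xi_s - xi_{j+s},
##   xi_v = -N_v * sum_over_variables 1/2 * log(sigma2_k + sigma2_vk)
## where sigma2_k is the variable's overall (biased, ML) variance -- a
## regularizer that keeps singleton clusters finite -- and sigma2_vk the
## within-cluster ML variance. Schwarz BIC = -2 * sum_v xi_v + m_k * log N
## with m_k = 2 * d * k parameters (a mean and a variance per variable per
## cluster) scores each candidate count; the count is chosen by the
## two-stage rule of the TwoStep tradition (BIC-change ratio, then the
## largest relative jump in the minimum inter-cluster distance), which is
## robust to the marginal overfitting of a raw BIC minimum.

.xi_from_stats <- function(ns, SM, SQ, sigma2) {
  # ns: m-vector, SM/SQ: m x d matrices of per-cluster sums / sums of squares
  mu <- SM / ns
  within <- SQ / ns - mu^2
  within[within < 0] <- 0
  -ns * rowSums(0.5 * log(sweep(within, 2, sigma2, "+")))
}

#' Two-step clustering (log-likelihood distance, Schwarz BIC)
#'
#' Agglomerates from singletons under the log-likelihood inter-cluster
#' distance and selects the number of clusters over candidates up to
#' `max_k` by the two-stage BIC rule: an initial estimate where the
#' BIC-change ratio \eqn{\Delta BIC(J)/\Delta BIC(1)} first drops below
#' 0.04, refined to the candidate with the largest relative jump in the
#' minimum inter-cluster distance (ratio threshold 1.15). The result is
#' floored at 2 clusters (a one-cluster solution is not a usable subtyping,
#' mirroring the silhouette path).
#'
#' @param points Numeric matrix of normalized feature vectors.
#' @param max_k Largest candidate cluster count.
#' @param k Optional forced cluster count (cuts the merge tree at that
#'   level instead of selecting by BIC).
#' @param trace If `TRUE`, record the merge sequence (member-index sets of
#'   the two clusters joined at each step) as element `merges`.
#' @return List with `centers` (k x d means in the normalized space),
#'   `cluster`, `k`, `bic` (named vector over candidate k), `overall_var`,
#'   and optionally `merges`.
#' @export
twostep_cluster <- function(points, max_k = 8, k = NULL, trace = FALSE) {
  Z <- as.matrix(points)
  n <- nrow(Z); d <- ncol(Z)
  if (n < 4L) .err("two-step clustering needs at least 4 points", "obty_error_size")
  keep_max <- max(max_k, if (is.null(k)) 0L else k)
  sigma2 <- apply(Z, 2, function(col) mean((col - mean(col))^2))
  if (any(sigma2 <= 0)) .err("degenerate (zero-variance) variable", "obty_error_degenerate")

  ns <- rep(1, n)
  SM <- Z
  SQ <- Z^2
  xi <- .xi_from_stats(ns, SM, SQ, sigma2)
  xi_all <- .xi_from_stats(n, matrix(colSums(Z), 1), matrix(colSums(Z^2), 1), sigma2)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  assign_vec <- seq_len(n)

  pair_dist <- function(j, idx) {
    # distance from cluster j to each cluster in idx, vectorized
    ns_u <- ns[j] + ns[idx]
    SM_u <- sweep(SM[idx, , drop = FALSE], 2, SM[j, ], "+")
    SQ_u <- sweep(SQ[idx, , drop = FALSE], 2, SQ[j, ], "+")
    xi_u <- .xi_from_stats(ns_u, SM_u, SQ_u, sigma2)
    xi[j] + xi[idx] - xi_u
  }

  D <- matrix(Inf, n, n)
  for (j in seq_len(n - 1L)) {
    idx <- (j + 1L):n
    D[j, idx] <- pair_dist(j, idx)
  }

  snapshots <- list()   # per stored level: list(cluster =, sum_xi =)
  d_at <- numeric(0)    # d_at["m"]: minimum inter-cluster distance of the
                        # m-cluster solution (= cost of the merge m -> m-1)
  merges <- if (trace) vector("list", n - 1L) else NULL
  m <- n
  step <- 0L
  while (m > 2L) {
    step <- step + 1L
    w <- arrayInd(which.min(D), dim(D))
    j <- min(w); s <- max(w)
    d_at[[as.character(m)]] <- D[j, s]
    if (trace) {
      merges[[step]] <- list(a = sort(members[[j]]), b = sort(members[[s]]),
                             d = D[j, s])
    }
    ns[j] <- ns[j] + ns[s]
    SM[j, ] <- SM[j, ] + SM[s, ]
    SQ[j, ] <- SQ[j, ] + SQ[s, ]
    xi[j] <- .xi_from_stats(ns[j], SM[j, , drop = FALSE], SQ[j, , drop = FALSE], sigma2)
    members[[j]] <- c(members[[j]], members[[s]])
    members[[s]] <- integer(0)
    active[s] <- FALSE
    D[s, ] <- Inf; D[, s] <- Inf
    others <- which(active); others <- others[others != j]
    if (length(others)) {
      dd <- pair_dist(j, others)
      lo <- others[others < j]; hi <- others[others > j]
      if (length(lo)) D[lo, j] <- dd[others < j]
      if (length(hi)) D[j, hi] <- dd[others > j]
    }
    m <- m - 1L
    if (m <= keep_max) {
      idx_active <- which(active)
      cl <- integer(n)
      for (ci in seq_along(idx_active)) cl[members[[idx_active[ci]]]] <- ci
      snapshots[[as.character(m)]] <- list(cluster = cl, sum_xi = sum(xi[active]))
    }
  }

  d_at[["2"]] <- min(D) # gap between the final two clusters (merge 2 -> 1)

  levels_avail <- sort(as.integer(names(snapshots)))
  bic <- vapply(levels_avail, function(kk) {
    -2 * snapshots[[as.character(kk)]]$sum_xi + (2 * d * kk) * log(n)
  }, numeric(1))
  names(bic) <- levels_avail
  bic1 <- -2 * xi_all + (2 * d) * log(n)
  k_sel <- if (is.null(k)) {
    bic_asc <- c(setNames(bic1, "1"), bic[as.character(levels_avail[levels_avail <= max_k])])
    max(.twostep_select_k(bic_asc, d_at, max_k), 2L)
  } else {
    if (!as.character(k) %in% names(snapshots)) {
      .err(paste0("no merge level with k = ", k), "obty_error_size")
    }
    as.integer(k)
  }
  cl <- snapshots[[as.character(k_sel)]]$cluster
  centers <- t(vapply(seq_len(k_sel),
                      function(j) colMeans(Z[cl == j, , drop = FALSE]),
                      numeric(d)))
  out <- list(centers = centers, cluster = cl, k = k_sel,
              bic = bic, overall_var = sigma2)
  if (trace) out$merges <- merges[seq_len(step)]
  out
}

## two-stage automatic cluster-count selection on an ascending BIC profile:
## initial estimate where the BIC improvement falls below 4% of the first
## improvement, refined by the largest relative jump in the minimum
## inter-cluster distance (take the runner-up's k when the top two jump
## ratios are within 15% of each other)
.twostep_select_k <- function(bic_asc, d_at, max_k) {
  ks <- as.integer(names(bic_asc))
  dbic <- bic_asc[-length(bic_asc)] - bic_asc[-1]
  if (dbic[1] <= 0) return(1L)
  r1 <- dbic / dbic[1]
  small <- which(r1 < 0.04)
  k_init <- if (length(small)) as.integer(names(dbic)[min(small)]) else max_k
  if (k_init <= 2L) return(k_init)
  cand <- 2:k_init
  r2 <- vapply(cand, function(J) {
    d_at[[as.character(J)]] / d_at[[as.character(J + 1)]]
  }, numeric(1))
  ord <- order(r2, decreasing = TRUE)
  if (length(cand) == 1L || r2[ord[1]] / r2[ord[2]] > 1.15) {
    cand[ord[1]]
  } else {
    max(cand[ord[1]], cand[ord[2]])
  }
}

## per-cluster sufficient statistics (z-space) kept in a fitted two-step
## model so external points can be scored by the same log-likelihood distance
.cluster_summaries <- function(Z, cluster, k) {
  list(
    overall_var = apply(Z, 2, function(col) mean((col - mean(col))^2)),
    clusters = lapply(seq_len(k), function(j) {
      m <- Z[cluster == j, , drop = FALSE]
      list(n = nrow(m), mean = colMeans(m),
           var = apply(m, 2, function(col) mean((col - mean(col))^2)))
    })
  )
}

## log-likelihood distance increment of adding single point x (z-space) to
## each summarized cluster; returns a k-vector
.loglik_point_dist <- function(x, summaries) {
  sigma2 <- summaries$overall_var
  xi_x <- -sum(0.5 * log(sigma2)) # singleton: zero within-variance
  vapply(summaries$clusters, function(cl) {
    nv <- cl$n
    sm <- cl$mean * nv
    sq <- nv * (cl$var + cl$mean^2)
    xi_v <- -nv * sum(0.5 * log(sigma2 + cl$var))
    ns_u <- nv + 1
    mu_u <- (sm + x) / ns_u
    within_u <- pmax((sq + x^2) / ns_u - mu_u^2, 0)
    xi_u <- -ns_u * sum(0.5 * log(sigma2 + within_u))
    xi_v + xi_x - xi_u
  }, numeric(1))
}
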