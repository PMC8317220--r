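MODEL_FORMAT_VERSION <- "1.0"

.named_list <- function(x) as.list(x)

#' Write a fitted subtype model to JSON
#'
#' Serializes a `cluster_model` -- algorithm tag, per-sex normalization
#' parameters and cluster centers (raw units), subtype labels, and for
#' two-step models the per-cluster summary statistics -- to a human-readable
#' JSON document. If the model carries an `imputation_suite`, it is written
#' alongside. The training partition is not serialized (the model is the
#' portable object).
#'
#' @param model A `cluster_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  ser_stratum <- function(st) {
    centers <- lapply(seq_len(nrow(st$centers)), function(i) {
      c(list(label = st$labels[i]), as.list(st$centers[i, ]))
    })
    out <- list(
      normalization = list(mean = as.list(st$normalization$mean),
                           sd = as.list(st$normalization$sd)),
      centers = centers
    )
    if (!is.null(st$summaries)) {
      out$summaries <- list(
        overall_var = as.list(st$summaries$overall_var),
        clusters = lapply(st$summaries$clusters, function(cl) {
          list(n = cl$n, mean = as.list(cl$mean), var = as.list(cl$var))
        })
      )
    }
    out
  }
  doc <- list(
    format_version = model$format_version,
    algorithm = model$algorithm,
    k = model$k,
    mean_silhouette = model$mean_silhouette,
    strata = lapply(model$strata[c("male", "female")], ser_stratum)
  )
  if (!is.null(model$imputation_suite)) {
    doc$imputation_suite <- .serialize_suite(model$imputation_suite)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a subtype model from JSON
#'
#' Strictly validates the document: a version-tag mismatch raises an explicit
#' incompatibility error, a truncated or malformed file raises a parse error
#' (never a partial model), and a model missing one sex stratum is rejected.
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return A `cluster_model`.
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) .err(paste0("cannot parse model file: ",
                                                  conditionMessage(e)),
                                           "obty_error_parse"))
  if (is.null(doc$format_version) || !identical(doc$format_version, MODEL_FORMAT_VERSION)) {
    .err(sprintf("incompatible model format version '%s' (expected '%s')",
                 as.character(doc$format_version %||% "<missing>"), MODEL_FORMAT_VERSION),
         "obty_error_incompat")
  }
  for (s in c("male", "female")) {
    if (is.null(doc$strata[[s]])) {
      .err(paste0("model missing sex stratum: ", s), "obty_error_validation")
    }
  }
  de_stratum <- function(st) {
    centers <- t(vapply(st$centers, function(ct) {
      unlist(ct[FEATURE_VARS])
    }, numeric(3)))
    colnames(centers) <- FEATURE_VARS
    out <- list(
      normalization = structure(
        list(mean = unlist(st$normalization$mean)[FEATURE_VARS],
             sd = unlist(st$normalization$sd)[FEATURE_VARS]),
        class = "normalization_params"),
      centers = centers,
      labels = vapply(st$centers, function(ct) ct$label, character(1))
    )
    if (!is.null(st$summaries)) {
      out$summaries <- list(
        overall_var = unlist(st$summaries$overall_var)[FEATURE_VARS],
        clusters = lapply(st$summaries$clusters, function(cl) {
          list(n = as.numeric(cl$n),
               mean = unlist(cl$mean)[FEATURE_VARS],
               var = unlist(cl$var)[FEATURE_VARS])
        })
      )
    }
    out
  }
  strata <- lapply(doc$strata[c("male", "female")], de_stratum)
  ks <- vapply(strata, function(st) nrow(st$centers), integer(1))
  if (length(unique(ks)) != 1L || ks[1] != doc$k) {
    .err("inconsistent cluster counts across strata", "obty_error_validation")
  }
  if (!setequal(strata$male$labels, strata$female$labels)) {
    .err("cross-sex label sets differ", "obty_error_validation")
  }
  model <- list(
    algorithm = doc$algorithm,
    k = as.integer(doc$k),
    strata = strata,
    mean_silhouette = as.numeric(doc$mean_silhouette),
    format_version = doc$format_version
  )
  if (!is.null(doc$imputation_suite)) {
    model$imputation_suite <- .deserialize_suite(doc$imputation_suite)
  }
  structure(model, class = "cluster_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.serialize_suite <- function(suite) {
  list(
    split = suite$split,
    models = lapply(suite$models, function(m) {
      list(target = m$target, times = as.integer(m$times),
           intercept = m$intercept, coef = as.list(m$coef),
           r2_test = m$r2_test, adjusted_r2_test = m$adjusted_r2_test,
           adjusted_r_test = m$adjusted_r_test,
           n_train = m$n_train, n_test = m$n_test)
    })
  )
}

.deserialize_suite <- function(doc) {
  models <- lapply(doc$models, function(m) {
    structure(list(target = m$target, times = unlist(m$times),
                   intercept = as.numeric(m$intercept),
                   coef = unlist(m$coef),
                   r2_test = as.numeric(m$r2_test),
                   adjusted_r2_test = as.numeric(m$adjusted_r2_test),
                   adjusted_r_test = as.numeric(m$adjusted_r_test),
                   n_train = as.numeric(m$n_train), n_test = as.numeric(m$n_test)),
              class = "imputation_model")
  })
  structure(list(models = models, split = as.numeric(doc$split)),
            class = "imputation_suite")
}
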