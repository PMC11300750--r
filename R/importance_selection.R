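#' Family-native feature importance of one fitted fold model
#'
#' Measures, per family:
#' * `rdf` — two parallel measures from the fitted forest: `mda`
#'   (mean decrease accuracy: per-tree out-of-bag accuracy drop after
#'   permuting the feature, averaged over trees, unscaled) and `mdg`
#'   (mean decrease Gini: total impurity decrease attributed to the
#'   feature across trees).
#' * `svm_poly3` — `weight`: the absolute pseudo-weight
#'   `|sum_j (dual coefficient_j) x_j|` over the support vectors, per
#'   feature (e1071's dual coefficients already carry the label sign).
#' * `logit` — `deviance`: deviance of the model refitted without the
#'   feature minus deviance of the full model, on the same training fold.
#'
#' @param fit A fitted model from the nested LOO engine (for rdf, fitted
#'   with importance).
#' @param family The model family the fit came from.
#' @param x,y The training fold (needed for the logit drop-one refits).
#' @return A feature-by-measure numeric matrix.
#' @export
fold_importance <- function(fit, family, x, y) {
  if (!identical(fit$family, family)) {
    stop(sprintf("family mismatch: fit is '%s', asked for '%s'",
                 fit$family, family))
  }
  feats <- colnames(x)
  if (family == "rdf") {
    imp <- randomForest::importance(fit$model, scale = FALSE)
    out <- cbind(mda = imp[feats, "MeanDecreaseAccuracy"],
                 mdg = imp[feats, "MeanDecreaseGini"])
  } else if (family == "svm_poly3") {
    w <- drop(t(fit$model$coefs) %*% fit$model$SV)
    out <- cbind(weight = abs(w)[feats])
  } else if (family == "logit") {
    full_dev <- fit$deviance
    dev_without <- vapply(seq_along(feats), function(k) {
      xm <- cbind(1, fit$x_std[, -k, drop = FALSE])
      suppressWarnings(
        stats::glm.fit(xm, fit$y_num, family = stats::binomial()))$deviance
    }, numeric(1))
    out <- cbind(deviance = dev_without - full_dev)
  } else {
    stop("unknown family: ", family)
  }
  rownames(out) <- feats
  out
}

#' Distributional feature importance across the external LOO models
#'
#' The outer leave-one-out loop produces one fitted model per lesion; each
#' yields an importance value per feature. Pooling them gives a sample of
#' n importance values per feature — a distribution rather than a point
#' estimate — summarized here by the mean and the interquartile range
#' (Q1/Q3, linear-interpolation quantiles).
#'
#' @param result A [nested_loo_evaluate()] result run with
#'   `importance = TRUE`.
#' @return An object of class `importance_distribution`: per measure a
#'   `summary` data frame (feature, mean, q1, q3, ordered as the feature
#'   table) and a folds-by-features `samples` matrix; plus `n_folds`.
#' @export
distributional_importance <- function(result) {
  stopifnot(inherits(result, "nested_loo_result"))
  imps <- lapply(result$folds, `[[`, "importance")
  if (any(vapply(imps, is.null, logical(1)))) {
    stop("a fold is missing importance values; rerun with importance = TRUE")
  }
  measures <- colnames(imps[[1]])
  feats <- result$feature_names
  per_measure <- lapply(measures, function(m) {
    samples <- t(vapply(imps, function(im) im[feats, m], numeric(length(feats))))
    colnames(samples) <- feats
    q <- apply(samples, 2, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE)
    list(summary = data.frame(feature = feats,
                              mean = colMeans(samples),
                              q1 = q[1, ], q3 = q[2, ],
                              row.names = NULL),
         samples = samples)
  })
  names(per_measure) <- measures
  structure(list(measures = per_measure,
                 measure_names = measures,
                 n_folds = length(imps)),
            class = "importance_distribution")
}

#' @export
print.importance_distribution <- function(x, ...) {
  cat(sprintf("<importance_distribution> %d folds, measures: %s\n",
              x$n_folds, paste(x$measure_names, collapse = ", ")))
  s <- x$measures[[1]]$summary
  s <- s[order(-s$mean), ]
  top <- utils::head(s, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-20s mean %8.4f  IQR [%.4f, %.4f]\n",
                top$feature[i], top$mean[i], top$q1[i], top$q3[i]))
  }
  invisible(x)
}

#' Write distributional importances as a tidy CSV
#' @param dist An [distributional_importance()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(dist, path) {
  stopifnot(inherits(dist, "importance_distribution"))
  rows <- lapply(dist$measure_names, function(m) {
    cbind(measure = m, dist$measures[[m]]$summary)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# Exact 1-D 2-means: enumerate the n - 1 ordered split points and return
# the one minimizing the within-cluster sum of squares (ties -> smallest
# split index, i.e. the smaller lower cluster).
two_means_split_1d <- function(values) {
  o <- order(values)
  v <- values[o]
  n <- length(v)
  best_wss <- Inf
  best_s <- 1L
  for (s in seq_len(n - 1)) {
    lo <- v[seq_len(s)]
    hi <- v[(s + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best_s <- s
    }
  }
  list(split = best_s, order = o, wss = best_wss)
}

#' Split features into most/less relevant by exact 1-D 2-means
#'
#' One-dimensional 2-means on the mean importances, solved exactly by
#' enumerating all ordered split points (no initialization randomness).
#' The cluster with the larger center is the relevant one.
#'
#' @param dist An [distributional_importance()] result, or a named numeric
#'   vector of mean importances.
#' @param measure Which measure to cluster on (default: the first).
#' @return A list with `relevant` (feature names, descending importance)
#'   and `rest` (remaining features, descending importance).
#' @export
cluster_relevant <- function(dist, measure = NULL) {
  if (inherits(dist, "importance_distribution")) {
    if (is.null(measure)) measure <- dist$measure_names[1]
    if (!measure %in% dist$measure_names) {
      stop(sprintf("unknown measure '%s'", measure))
    }
    s <- dist$measures[[measure]]$summary
    means <- stats::setNames(s$mean, s$feature)
  } else {
    means <- dist
    if (is.null(names(means))) stop("mean importances must be named")
  }
  if (length(means) < 2) stop("at least 2 features are required")
  if (length(unique(means)) == 1) {
    stop("all mean importances are identical: no meaningful 2-clustering; ",
         "inspect the importance distribution before selecting")
  }
  sp <- two_means_split_1d(means)
  v <- means[sp$order]
  lower <- names(v)[seq_len(sp$split)]
  upper <- names(v)[(sp$split + 1):length(v)]
  # the upper cluster always has the larger center after sorting
  list(relevant = upper[order(-means[upper])],
       rest = lower[order(-means[lower])])
}

#' Greedy adaptive feature selection on nested LOO AUC
#'
#' Implements the adaptive augmentation procedure: (1) evaluate the full
#' feature set by nested LOO and collect its distributional importance;
#' (2) split the features into most/less relevant with exact 1-D 2-means
#' on the mean importances ([cluster_relevant()]); (3) take the relevant
#' cluster as the seed set and evaluate it; (4) walk the remaining
#' features in descending mean importance, adding each in turn and keeping
#' it only if the external nested-LOO AUC strictly increases. Seed
#' features are accepted wholesale and never pruned. Every AUC in the
#' trace is the pooled external nested-LOO AUC of the recorded feature
#' set under the same master seed, so the trace replays exactly.
#'
#' The ordering/clustering measure defaults to mean decrease accuracy for
#' rdf and the family's single measure otherwise. Because the importance
#' ranking is taken from the full-feature run on all data, the final AUC
#' is an optimistically biased estimate of the selected model's
#' performance: the selection has seen every lesion.
#'
#' @param table A redundancy-corrected [feature_table()] aligned with
#'   `labels`.
#' @param labels A [label_vector()].
#' @param spec A [model_spec()]. With a singleton grid the candidate
#'   evaluations skip threshold calibration (the AUC is unaffected; see
#'   [nested_loo_evaluate()]).
#' @param measure Importance measure for clustering and ordering
#'   (default `"mda"` for rdf).
#' @return An object of class `selection_trace`: `seed_cluster`, `steps`
#'   (data frame feature/auc_before/auc_after/kept), `final_set`,
#'   `final_auc`, `full_auc`, `total_nested_evaluations`, `feature_names`,
#'   `seed`.
#' @export
adaptive_select <- function(table, labels, spec, measure = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_vector"),
            inherits(spec, "model_spec"))
  fast <- grid_size(spec) == 1L

  full <- nested_loo_evaluate(table, labels, spec,
                              calibrate = !fast, importance = TRUE)
  full_auc <- auc_roc(external_scores(full), labels$labels)
  dist <- distributional_importance(full)
  if (is.null(measure)) {
    measure <- if (spec$family == "rdf") "mda" else dist$measure_names[1]
  }
  cl <- cluster_relevant(dist, measure)

  eval_auc <- function(feats) {
    res <- nested_loo_evaluate(subset_features(table, feats), labels, spec,
                               calibrate = !fast, importance = FALSE)
    auc_roc(external_scores(res), labels$labels)
  }

  current <- cl$relevant
  current_auc <- eval_auc(current)
  steps <- data.frame(feature = character(), auc_before = numeric(),
                      auc_after = numeric(), kept = logical(),
                      stringsAsFactors = FALSE)
  for (f in cl$rest) {
    cand_auc <- eval_auc(c(current, f))
    keep <- cand_auc > current_auc
    steps <- rbind(steps, data.frame(feature = f, auc_before = current_auc,
                                     auc_after = cand_auc, kept = keep,
                                     stringsAsFactors = FALSE))
    if (keep) {
      current <- c(current, f)
      current_auc <- cand_auc
    }
  }

  structure(list(seed_cluster = cl$relevant,
                 steps = steps,
                 final_set = current,
                 final_auc = current_auc,
                 full_auc = full_auc,
                 total_nested_evaluations = 2L + length(cl$rest),
                 feature_names = table$feature_names,
                 measure = measure,
                 seed = spec$seed),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> seed cluster {%s} -> final %d features, AUC %.3f (full-set AUC %.3f)\n",
              paste(x$seed_cluster, collapse = ", "),
              length(x$final_set), x$final_auc, x$full_auc))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  %s %-20s %.3f -> %.3f\n",
                  if (x$steps$kept[i]) "+" else "-",
                  x$steps$feature[i], x$steps$auc_before[i], x$steps$auc_after[i]))
    }
  }
  invisible(x)
}
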