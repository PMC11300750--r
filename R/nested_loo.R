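#' Specify a classifier family and its hyperparameter grid
#'
#' Three families are supported: `rdf` (random decision forest, tuned over
#' the number of trees), `svm_poly3` (support vector machine with a
#' degree-3 polynomial kernel, tuned over the cost), and `logit` (binomial
#' generalized linear model, no hyperparameters). Default grids are coarse
#' samplings of the intervals n_t in [50, 250] and c in [1, 10].
#'
#' @param family `"rdf"`, `"svm_poly3"`, or `"logit"`.
#' @param hyper_grid Numeric vector of grid values (`n_t` for rdf, cost for
#'   svm_poly3); ignored for logit. Defaults: `c(50, 100, 150, 200, 250)`
#'   and `c(1, 2, 5, 10)`.
#' @param seed Integer master seed; per-fold seeds are derived from it so
#'   reruns are identical.
#' @param nt_range Allowed range for rdf tree counts.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("rdf", "svm_poly3", "logit"),
                       hyper_grid = NULL, seed = 1L,
                       nt_range = c(50, 250)) {
  family <- match.arg(family)
  if (family == "logit") {
    grid <- NA_real_  # single implicit setting
  } else if (is.null(hyper_grid)) {
    grid <- if (family == "rdf") c(50, 100, 150, 200, 250) else c(1, 2, 5, 10)
  } else {
    grid <- sort(unique(as.numeric(hyper_grid)))
    if (!length(grid) || anyNA(grid)) stop("hyper_grid must be nonempty and numeric")
    if (family == "rdf" && (any(grid < nt_range[1]) || any(grid > nt_range[2]))) {
      stop(sprintf("rdf tree counts must lie in [%g, %g]", nt_range[1], nt_range[2]))
    }
    if (family == "svm_poly3" && any(grid <= 0)) stop("svm cost must be positive")
  }
  structure(list(family = family, hyper_grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

grid_size <- function(spec) {
  if (spec$family == "logit") 1L else length(spec$hyper_grid)
}

# Deterministic per-(fold, internal-point) seed derived from the master
# seed. Keeps every value below 2^31 and exact in double arithmetic.
derive_seed <- function(master, fold, point = 0L) {
  as.integer(((master %% 2147483647) * 69069 + fold * 10007 + point * 101) %%
               2147483629) + 1L
}

#' Rank-based AUC-ROC (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' counting ties as one half: (concordant pairs + ties / 2) / (n+ * n-).
#'
#' @param scores Numeric prediction scores (larger = more malignant).
#' @param labels Binary labels (1 = malignant).
#' @return A fraction in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Calibrate a classification threshold maximizing sensitivity + specificity
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus one candidate below the minimum and one above the
#' maximum (so "call everything" and "call nothing" are reachable). A
#' lesion is called malignant iff its score is at least the threshold. Ties
#' in the objective break toward the smallest threshold.
#'
#' @inheritParams auc_roc
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  s <- sort(unique(scores))
  candidates <- c(s[1] - 1,
                  if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
                  s[length(s)] + 1)
  best <- -Inf
  best_t <- candidates[1]
  for (t in candidates) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    if (sens + spec > best + 1e-12) {
      best <- sens + spec
      best_t <- t
    }
  }
  best_t
}

# Column-standardize train, apply the same transform to test. Constant
# columns map to zero (no information, no NaN).
standardize_pair <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sds <- apply(x_train, 2, stats::sd)
  sds[sds == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sds, `/`),
       test = sweep(sweep(x_test, 2, mu), 2, sds, `/`))
}

# Fit a single model with fixed hyperparameters. randomForest interleaves
# its permutation-importance draws with tree growing, so importance = TRUE
# yields a different (equally valid) forest than importance = FALSE at the
# same seed: internal-loop fits use rdf_importance = FALSE (matching the
# sliced grid evaluation), refits always use rdf_importance = TRUE so
# their scores are identical whether or not importance is requested.
fit_model <- function(family, hyper, x_train, y_train, seed,
                      rdf_importance = FALSE) {
  y <- factor(y_train, levels = c(0L, 1L))
  set.seed(seed)
  if (family == "rdf") {
    model <- randomForest::randomForest(x_train, y, ntree = hyper,
                                        importance = rdf_importance)
    list(family = family, model = model)
  } else if (family == "svm_poly3") {
    st <- standardize_pair(x_train, x_train)
    model <- e1071::svm(st$train, y, kernel = "polynomial", degree = 3,
                        cost = hyper, scale = FALSE)
    list(family = family, model = model,
         mu = colMeans(x_train),
         sds = {s <- apply(x_train, 2, stats::sd); s[s == 0] <- 1; s},
         x_std = st$train, y = y)
  } else {
    st <- standardize_pair(x_train, x_train)
    xm <- cbind(`(Intercept)` = 1, st$train)
    fit <- suppressWarnings(
      stats::glm.fit(xm, y_train, family = stats::binomial()))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0  # aliased columns contribute nothing
    list(family = family, coef = coefs, deviance = fit$deviance,
         mu = colMeans(x_train),
         sds = {s <- apply(x_train, 2, stats::sd); s[s == 0] <- 1; s},
         x_std = st$train, y_num = y_train)
  }
}

score_model <- function(fit, x_test) {
  if (fit$family == "rdf") {
    unname(stats::predict(fit$model, x_test, type = "prob")[, "1"])
  } else if (fit$family == "svm_poly3") {
    z <- sweep(sweep(x_test, 2, fit$mu), 2, fit$sds, `/`)
    pred <- stats::predict(fit$model, z, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 orients the decision value toward the first level of the
    # colname "A/B"; flip if needed so that larger = malignant.
    sgn <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
    unname(sgn * dv[, 1])
  } else {
    z <- sweep(sweep(x_test, 2, fit$mu), 2, fit$sds, `/`)
    eta <- cbind(1, z) %*% fit$coef
    unname(drop(1 / (1 + exp(-eta))))
  }
}

#' Fit one model at fixed hyperparameters and score test rows
#'
#' Scores are on the family's native scale: fraction of trees voting
#' malignant (rdf), signed decision value (svm_poly3), predicted
#' probability (logit). The svm and logit features are z-scored with
#' training-fold statistics only; random forests use the raw features
#' (tree splits are invariant to monotone rescaling).
#'
#' @param family `"rdf"`, `"svm_poly3"`, or `"logit"`.
#' @param hyper The hyperparameter value (`n_t`, cost, or `NA` for logit).
#' @param x_train,y_train Training matrix and 0/1 labels (both classes
#'   required).
#' @param x_test Matrix of rows to score.
#' @param seed Integer seed making the fit deterministic.
#' @return Numeric scores for the rows of `x_test`.
#' @export
fit_and_score <- function(family, hyper, x_train, y_train, x_test, seed = 1L) {
  if (length(unique(y_train)) < 2) {
    stop("degenerate training fold: only one class present")
  }
  fit <- fit_model(family, hyper, x_train, y_train, seed)
  score_model(fit, x_test)
}

# Internal LOO scores for every rdf grid value from a single forest of
# max(n_t) trees: the first n_t trees of a seeded forest are identical to
# a separately seeded n_t-tree fit, so slicing the per-tree votes
# reproduces each grid setting exactly at a fraction of the cost.
rdf_grid_scores <- function(x_train, y_train, x_test, nt_grid, seed) {
  y <- factor(y_train, levels = c(0L, 1L))
  set.seed(seed)
  model <- randomForest::randomForest(x_train, y, ntree = max(nt_grid))
  votes <- stats::predict(model, x_test, predict.all = TRUE)$individual == "1"
  vapply(nt_grid, function(nt) mean(votes[1, seq_len(nt)]), numeric(1))
}

#' Inner leave-one-out grid search with threshold calibration
#'
#' For every hyperparameter setting, each of the m training lesions is in
#' turn held out, the model is fitted on the other m - 1 and scores the
#' held-out lesion; the setting with the best AUC over those m held-out
#' scores wins (ties break toward the simplest model: fewest trees,
#' smallest cost). The classification threshold is then calibrated on the
#' winning setting's m scores by [select_threshold()].
#'
#' @param x,y Training matrix and 0/1 labels (m >= 4, both classes).
#' @param spec A [model_spec()].
#' @param fold Integer index of the enclosing external fold (seeds the
#'   internal fits).
#' @return List with `best_hyper`, `internal_scores` (of the winning
#'   setting), `threshold`, `internal_auc`, `auc_by_setting`, and
#'   `sessions` (number of training sessions performed, `|grid| * m`).
#' @export
internal_loo_optimize <- function(x, y, spec, fold = 0L) {
  m <- nrow(x)
  if (m < 4) stop("internal LOO needs at least 4 training lesions")
  if (length(unique(y)) < 2) stop("internal LOO needs both classes")
  G <- grid_size(spec)
  scores <- matrix(NA_real_, m, G)
  for (j in seq_len(m)) {
    seed_j <- derive_seed(spec$seed, fold, j)
    x_tr <- x[-j, , drop = FALSE]
    y_tr <- y[-j]
    x_te <- x[j, , drop = FALSE]
    if (length(unique(y_tr)) < 2) {
      # at very small m the inner loop can exhaust a class; the only
      # fittable model is the constant (prior) predictor, whose score
      # ties with everything of its kind in the AUC
      scores[j, ] <- mean(y_tr)
      next
    }
    if (spec$family == "rdf") {
      scores[j, ] <- rdf_grid_scores(x_tr, y_tr, x_te, spec$hyper_grid, seed_j)
    } else if (spec$family == "svm_poly3") {
      for (g in seq_len(G)) {
        scores[j, g] <- fit_and_score("svm_poly3", spec$hyper_grid[g],
                                      x_tr, y_tr, x_te, seed_j)
      }
    } else {
      scores[j, 1] <- fit_and_score("logit", NA, x_tr, y_tr, x_te, seed_j)
    }
  }
  aucs <- apply(scores, 2, auc_roc, labels = y)
  best <- which.max(aucs)  # grid sorted ascending: first max = simplest
  list(best_hyper = if (spec$family == "logit") NA_real_ else spec$hyper_grid[best],
       internal_scores = scores[, best],
       threshold = select_threshold(scores[, best], y),
       internal_auc = unname(aucs[best]),
       auc_by_setting = unname(aucs),
       sessions = G * m)
}

#' Nested leave-one-out model evaluation
#'
#' The outer loop holds out each lesion once; on the remaining n - 1 an
#' inner leave-one-out grid search picks the hyperparameters and calibrates
#' the classification threshold ([internal_loo_optimize()]); the winning
#' setting is refitted on all n - 1 lesions and scores the held-out lesion,
#' which is called malignant iff its score reaches the fold's threshold.
#' No information from the held-out lesion enters its fold's
#' standardization, optimization, calibration, or refit.
#'
#' The internal training-session counter follows `|grid| * n * (n - 1)`;
#' the n refits are tallied separately.
#'
#' When the grid is a singleton and neither thresholds nor internal AUCs
#' are needed (`calibrate = FALSE`), the inner loop is skipped: the
#' hyperparameter choice is forced and the pooled external AUC does not
#' depend on the thresholds, so the external scores are identical to the
#' full run (fold records then carry `NA` thresholds and internal AUCs).
#'
#' @param table A [feature_table()] aligned with `labels`.
#' @param labels A [label_vector()].
#' @param spec A [model_spec()].
#' @param calibrate Run the inner loop even when the grid is a singleton
#'   (default `TRUE`; must stay `TRUE` for grids larger than one).
#' @param importance Record per-fold feature importance from the refit
#'   models (default `TRUE`).
#' @param group_by Leave out whole patient groups instead of single lesions
#'   (`"patient"`, requires `labels$groups`); default per-lesion.
#' @return An object of class `nested_loo_result`: `folds` (list of fold
#'   records: `held_out`, `best_hyper`, `threshold`, `score`,
#'   `hard_prediction`, `internal_auc`, `importance`), `model_spec`,
#'   `feature_names`, `lesion_ids`, `labels`, `training_sessions`, `refits`.
#' @export
nested_loo_evaluate <- function(table, labels, spec,
                                calibrate = TRUE, importance = TRUE,
                                group_by = c("lesion", "patient")) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_vector"),
            inherits(spec, "model_spec"))
  group_by <- match.arg(group_by)
  if (!identical(table$lesion_ids, labels$lesion_ids)) {
    stop("table and labels are not aligned; call align_cohort() first")
  }
  x <- table$values
  y <- labels$labels
  n <- nrow(x)
  if (n < 5) stop("nested LOO needs at least 5 lesions")
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("each class needs at least 2 members so every training fold sees both")
  }
  if (group_by == "patient") {
    if (is.null(labels$groups)) stop("group-wise LOO needs labels with groups")
    fold_of <- match(labels$groups, unique(labels$groups))
    fold_ids <- unique(labels$groups)
  } else {
    fold_of <- seq_len(n)
    fold_ids <- labels$lesion_ids
  }
  n_folds <- length(fold_ids)
  G <- grid_size(spec)
  if (!calibrate && G > 1) {
    stop("calibrate = FALSE is only valid for a singleton hyper grid")
  }

  sessions <- 0L
  folds <- vector("list", n_folds)
  for (i in seq_len(n_folds)) {
    test_idx <- which(fold_of == i)
    x_tr <- x[-test_idx, , drop = FALSE]
    y_tr <- y[-test_idx]
    stopifnot(length(unique(y_tr)) == 2)

    if (calibrate) {
      opt <- internal_loo_optimize(x_tr, y_tr, spec, fold = i)
      sessions <- sessions + opt$sessions
      best <- opt$best_hyper
      threshold <- opt$threshold
      internal_auc <- opt$internal_auc
    } else {
      best <- if (spec$family == "logit") NA_real_ else spec$hyper_grid[1]
      threshold <- NA_real_
      internal_auc <- NA_real_
    }

    fit <- fit_model(spec$family, best, x_tr, y_tr,
                     seed = derive_seed(spec$seed, i, 0L),
                     rdf_importance = TRUE)
    sc <- score_model(fit, x[test_idx, , drop = FALSE])
    imp <- if (importance) fold_importance(fit, spec$family, x_tr, y_tr)

    folds[[i]] <- list(held_out = labels$lesion_ids[test_idx],
                       best_hyper = best,
                       threshold = threshold,
                       score = sc,
                       hard_prediction = if (is.na(threshold)) rep(NA_integer_, length(sc))
                                         else as.integer(sc >= threshold),
                       internal_auc = internal_auc,
                       importance = imp)
  }

  structure(list(folds = folds, model_spec = spec,
                 feature_names = table$feature_names,
                 lesion_ids = labels$lesion_ids,
                 labels = y,
                 training_sessions = sessions,
                 refits = n_folds),
            class = "nested_loo_result")
}

#' @export
print.nested_loo_result <- function(x, ...) {
  cat(sprintf("<nested_loo_result> %s, %d folds, %d internal training sessions (+%d refits)\n",
              x$model_spec$family, length(x$folds), x$training_sessions, x$refits))
  cat(sprintf("  pooled external AUC-ROC: %.3f\n",
              auc_roc(external_scores(x), x$labels)))
  invisible(x)
}

#' Pooled external scores of a nested LOO result, in lesion order
#' @param result A [nested_loo_evaluate()] result.
#' @return Named numeric vector of held-out scores.
#' @export
external_scores <- function(result) {
  stopifnot(inherits(result, "nested_loo_result"))
  ids <- unlist(lapply(result$folds, `[[`, "held_out"))
  sc <- unlist(lapply(result$folds, `[[`, "score"))
  stats::setNames(sc, ids)[result$lesion_ids]
}

external_predictions <- function(result) {
  ids <- unlist(lapply(result$folds, `[[`, "held_out"))
  hp <- unlist(lapply(result$folds, `[[`, "hard_prediction"))
  stats::setNames(hp, ids)[result$lesion_ids]
}

#' Performance metrics from a nested LOO result
#'
#' The AUC-ROC pools the n external scores; accuracy, specificity,
#' precision and recall come from the n hard calls made with each fold's
#' own calibrated threshold (positive = malignant). A metric whose
#' denominator is empty (e.g. precision when no lesion is called positive)
#' is returned as `NA` and flagged, never coerced to 0.
#'
#' @param result A [nested_loo_evaluate()] result (run with
#'   `calibrate = TRUE`).
#' @param labels Optional [label_vector()] to check against the stored one.
#' @return An object of class `loo_metrics`: `auc_roc`, `accuracy`,
#'   `specificity`, `precision`, `recall`, `undefined` (names of flagged
#'   metrics), and the confusion counts.
#' @export
compute_metrics <- function(result, labels = NULL) {
  stopifnot(inherits(result, "nested_loo_result"))
  y <- result$labels
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_vector"))
    if (!identical(labels$lesion_ids, result$lesion_ids)) {
      stop("labels do not match the evaluated lesion set")
    }
    y <- labels$labels
  }
  sc <- external_scores(result)
  pred <- external_predictions(result)
  if (anyNA(pred)) {
    stop("hard predictions unavailable: rerun nested_loo_evaluate with calibrate = TRUE")
  }
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  metrics <- list(auc_roc = auc_roc(sc, y),
                  accuracy = (tp + tn) / length(y),
                  specificity = safe_div(tn, tn + fp),
                  precision = safe_div(tp, tp + fp),
                  recall = safe_div(tp, tp + fn))
  undefined <- names(metrics)[vapply(metrics, is.na, logical(1))]
  structure(c(metrics,
              list(undefined = undefined,
                   confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))),
            class = "loo_metrics")
}

#' @export
print.loo_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("AUC-ROC %s | accuracy %s | specificity %s | precision %s | recall %s\n",
              fmt(x$auc_roc), fmt(x$accuracy), fmt(x$specificity),
              fmt(x$precision), fmt(x$recall)))
  invisible(x)
}
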