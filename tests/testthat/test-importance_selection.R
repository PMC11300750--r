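fit_for <- function(family, x, y, hyper = switch(family, rdf = 200, 1),
                    seed = 1) {
  radloo:::fit_model(family, hyper, x, y, seed = seed, rdf_importance = TRUE)
}

test_that("a constant feature carries zero importance in every family", {
  set.seed(51)
  x <- cbind(signal = rnorm(40), flat = rep(1.3, 40), noise = rnorm(40))
  y <- as.integer(x[, "signal"] + rnorm(40, sd = 0.5) > 0)
  y[1:2] <- 0:1
  for (fam in c("rdf", "svm_poly3", "logit")) {
    fit <- fit_for(fam, x, y)
    imp <- fold_importance(fit, fam, x, y)
    expect_equal(unname(imp["flat", 1]), 0, tolerance = 1e-8)
    if (fam == "rdf") expect_equal(unname(imp["flat", "mdg"]), 0)
  }
})

test_that("logit drop-one deviance isolates the predictive feature", {
  set.seed(52)
  n <- 60
  f1 <- rnorm(n)
  f2 <- rnorm(n)  # independent of the label
  y <- as.integer(f1 + rnorm(n, sd = 0.8) > 0)
  y[1:2] <- 0:1
  x <- cbind(f1 = f1, f2 = f2)
  fit <- fit_for("logit", x, y)
  imp <- fold_importance(fit, "logit", x, y)
  expect_gt(imp["f1", 1], imp["f2", 1])
  expect_gt(imp["f1", 1], 10)     # strong signal: large deviance change
  expect_lt(imp["f2", 1], 6.6)    # ~ chi-square(1) under the null (99th pct)
})

test_that("forest mean decrease accuracy matches an independent permutation oracle", {
  set.seed(53)
  n <- 60
  x <- cbind(signal = c(rnorm(n / 2, 1.8), rnorm(n / 2, -1.8)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c(1L, 0L), each = n / 2)
  set.seed(99)
  rf <- randomForest::randomForest(x, factor(y, levels = c("0", "1")),
                                   ntree = 300, importance = TRUE,
                                   keep.inbag = TRUE)
  # oracle: per tree, OOB accuracy before vs after permuting one feature,
  # with our own permutation draws; averaged over trees
  ind <- predict(rf, x, predict.all = TRUE)$individual
  oracle <- vapply(colnames(x), function(feat) {
    set.seed(7)
    drops <- vapply(seq_len(rf$ntree), function(t) {
      oob <- which(rf$inbag[, t] == 0)
      if (!length(oob)) return(NA_real_)
      acc0 <- mean(ind[oob, t] == as.character(y[oob]))
      xp <- x
      xp[oob, feat] <- x[sample(oob), feat]
      indp <- predict(rf, xp[oob, , drop = FALSE],
                      predict.all = TRUE)$individual[, t]
      acc0 - mean(indp == as.character(y[oob]))
    }, numeric(1))
    mean(drops, na.rm = TRUE)
  }, numeric(1))
  mda <- randomForest::importance(rf, scale = FALSE)[, "MeanDecreaseAccuracy"]
  expect_equal(unname(mda["signal"]), unname(oracle["signal"]),
               tolerance = 0.05)
  expect_lt(abs(mda["noise1"] - oracle["noise1"]), 0.02)
  expect_lt(abs(mda["noise2"] - oracle["noise2"]), 0.02)
  expect_gt(mda["signal"], mda["noise1"])
})

test_that("svm pseudo-weights vanish for an empty column and find the signal", {
  set.seed(54)
  x <- cbind(signal = c(rnorm(20, 2), rnorm(20, -2)), noise = rnorm(40))
  y <- rep(c(1L, 0L), each = 20)
  fit <- fit_for("svm_poly3", x, y)
  imp <- fold_importance(fit, "svm_poly3", x, y)
  expect_gt(imp["signal", "weight"], imp["noise", "weight"])
  expect_error(fold_importance(fit, "rdf", x, y), "family mismatch")
})

test_that("distributional importance summarizes per-fold samples", {
  res <- fake_loo_result(c(1, 1, 0, 0, 1, 0), c(1, 1, 0, 0, 1, 0))
  imp <- cbind(deviance = c(f1 = 2, f2 = 0.5))
  res$folds <- lapply(res$folds, function(f) { f$importance <- imp; f })
  res$feature_names <- c("f1", "f2")
  dist <- distributional_importance(res)
  s <- dist$measures$deviance$summary
  expect_equal(s$mean, c(2, 0.5))
  expect_equal(s$q1, s$mean)   # identical folds: degenerate distribution
  expect_equal(s$q3, s$mean)
  expect_true(all(s$q1 <= s$q3))

  res$folds[[2]]$importance <- NULL
  expect_error(distributional_importance(res), "missing importance")
})

test_that("a dominant planted feature tops the importance ranking", {
  firsts <- vapply(1:5, function(seed) {
    co <- generate_cohort(signal_cohort_config(n = 30, d = 3, n_geometric = 2,
                                               n_texture = 4, seed = seed,
                                               informative = c(sphericity = NA)))
    al <- aligned_reference(co)
    res <- nested_loo_evaluate(al$table, al$labels,
                               model_spec("rdf", 100, seed = seed),
                               calibrate = FALSE)
    s <- distributional_importance(res)$measures$mda$summary
    s$feature[which.max(s$mean)]
  }, character(1))
  expect_true(all(firsts == "sphericity"))
})

test_that("exact 1-D 2-means separates clear clusters and matches brute force", {
  cl <- cluster_relevant(c(a = 10, b = 9, c = 0.1, d = 0.2))
  expect_setequal(cl$relevant, c("a", "b"))
  expect_identical(cl$relevant, c("a", "b"))  # descending importance
  expect_identical(cl$rest, c("d", "c"))

  cl <- cluster_relevant(c(a = 5, b = 5, c = 1))
  expect_setequal(cl$relevant, c("a", "b"))

  set.seed(55)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    v <- setNames(round(rnorm(n), 2), paste0("f", seq_len(n)))
    if (length(unique(v)) == 1) next
    cl <- cluster_relevant(v)
    oracle <- brute_two_means(v)
    expect_identical(sort(cl$relevant), oracle$upper)
    expect_identical(sort(cl$rest), oracle$lower)
  }
  expect_error(cluster_relevant(c(a = 1, b = 1, c = 1)), "identical")
})

test_that("adaptive selection obeys the strict-improvement rule and replays exactly", {
  co <- generate_cohort(signal_cohort_config(n = 24, d = 2, n_geometric = 2,
                                             n_texture = 4, seed = 56,
                                             informative = c(sphericity = NA,
                                                             entropy = NA)))
  al <- aligned_reference(co)
  spec <- model_spec("rdf", 50, seed = 13)
  trace <- adaptive_select(al$table, al$labels, spec)

  n_feat <- length(al$table$feature_names)
  expect_equal(trace$total_nested_evaluations,
               2L + (n_feat - length(trace$seed_cluster)))
  expect_equal(nrow(trace$steps), n_feat - length(trace$seed_cluster))
  kept <- trace$steps$kept
  expect_true(all(trace$steps$auc_after[kept] > trace$steps$auc_before[kept]))
  expect_true(all(trace$steps$auc_after[!kept] <= trace$steps$auc_before[!kept]))
  expect_setequal(trace$final_set,
                  c(trace$seed_cluster, trace$steps$feature[kept]))

  # the final AUC never falls below the seed-cluster AUC
  seed_eval <- nested_loo_evaluate(subset_features(al$table, trace$seed_cluster),
                                   al$labels, spec, calibrate = FALSE,
                                   importance = FALSE)
  seed_auc <- auc_roc(external_scores(seed_eval), al$labels$labels)
  expect_gte(trace$final_auc, seed_auc)

  # replay: re-evaluating the recorded final set reproduces the recorded AUC
  replay <- nested_loo_evaluate(subset_features(al$table, trace$final_set),
                                al$labels, spec, calibrate = FALSE,
                                importance = FALSE)
  expect_equal(auc_roc(external_scores(replay), al$labels$labels),
               trace$final_auc)
})
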