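test_that("AUC-ROC matches exhaustive pair counting", {
  expect_equal(auc_roc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # one tie across classes
  s <- c(0.2, 0.5, 0.5, 0.9, 0.1)
  y <- c(0, 0, 1, 1, 0)
  expect_equal(auc_roc(s, y), brute_auc(s, y))
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)  # rounding forces occasional ties
    expect_equal(auc_roc(s, y), brute_auc(s, y))
  }
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC-ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1
  s <- rnorm(40)
  expect_equal(auc_roc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("threshold calibration maximizes sensitivity plus specificity", {
  # perfect separation: the sum reaches 2 and the threshold sits in the gap
  s <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  t <- select_threshold(s, y)
  expect_gt(t, 0.2); expect_lte(t, 0.8)
  pred <- s >= t
  expect_equal(mean(pred[y == 1]) + mean(!pred[y == 0]), 2)

  # anti-separated scores: an extreme candidate wins
  s <- c(0.9, 0.8, 0.1, 0.2)
  expect_equal(select_threshold(s, y), brute_threshold(s, y))

  set.seed(33)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- rnorm(n)
    expect_equal(select_threshold(s, y), brute_threshold(s, y))
  }
})

test_that("fit_and_score is deterministic and directionally sane", {
  set.seed(34)
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- as.integer(x[, 1] > 0)  # linearly separated on feature 1
  y[1] <- 1L - y[1]            # keep it non-degenerate but informative
  xt <- matrix(c(3, 0, -3, 0), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  for (fam in c("rdf", "svm_poly3", "logit")) {
    hyper <- switch(fam, rdf = 50, svm_poly3 = 1, logit = NA)
    s1 <- fit_and_score(fam, hyper, x, y, xt, seed = 5)
    s2 <- fit_and_score(fam, hyper, x, y, xt, seed = 5)
    expect_identical(s1, s2)
    expect_gt(s1[1], s1[2])  # clearly positive row outranks negative row
  }
  sl <- fit_and_score("logit", NA, x, y, xt, seed = 5)
  expect_gt(sl[1], 0.5)
  expect_error(fit_and_score("logit", NA, x, rep(1L, 15), xt),
               "one class")
})

test_that("internal LOO grid search matches a longhand re-run", {
  co <- generate_cohort(signal_cohort_config(n = 10, d = 1.5, n_geometric = 2,
                                             n_texture = 4, seed = 41,
                                             informative = c(sphericity = NA)))
  al <- aligned_reference(co)
  x <- al$table$values
  y <- al$labels$labels
  spec <- model_spec("rdf", c(50, 100), seed = 17)
  opt <- internal_loo_optimize(x, y, spec, fold = 3)

  # longhand: per grid setting, an explicit LOO loop over fit_and_score
  scores <- matrix(NA_real_, nrow(x), 2)
  for (g in 1:2) {
    for (j in seq_len(nrow(x))) {
      scores[j, g] <- fit_and_score("rdf", spec$hyper_grid[g],
                                    x[-j, , drop = FALSE], y[-j],
                                    x[j, , drop = FALSE],
                                    seed = radloo:::derive_seed(17, 3, j))
    }
  }
  aucs <- apply(scores, 2, auc_roc, labels = y)
  expect_equal(opt$auc_by_setting, unname(aucs))
  expect_equal(opt$internal_auc, max(aucs))
  expect_equal(opt$best_hyper, spec$hyper_grid[which.max(aucs)])
  expect_equal(opt$internal_scores, scores[, which.max(aucs)])
  expect_equal(opt$threshold,
               select_threshold(scores[, which.max(aucs)], y))
  expect_equal(opt$sessions, 2 * nrow(x))
})

test_that("logit has a single implicit setting and duplicated grids deduplicate", {
  spec <- model_spec("logit", seed = 2)
  expect_equal(radloo:::grid_size(spec), 1L)
  co <- generate_cohort(null_cohort_config(n = 8, n_geometric = 2,
                                           n_texture = 2, seed = 42))
  al <- aligned_reference(co)
  opt <- internal_loo_optimize(al$table$values, al$labels$labels, spec)
  expect_true(is.na(opt$best_hyper))
  expect_false(is.na(opt$threshold))

  expect_identical(model_spec("rdf", c(100, 50, 100))$hyper_grid,
                   model_spec("rdf", c(50, 100))$hyper_grid)
  expect_error(model_spec("rdf", c(10, 100)), "must lie in")
})

test_that("training-session accounting follows |grid| * n * (n - 1)", {
  co <- generate_cohort(null_cohort_config(n = 6, n_geometric = 2,
                                           n_texture = 2, seed = 43))
  al <- aligned_reference(co)
  res <- nested_loo_evaluate(al$table, al$labels,
                             model_spec("svm_poly3", c(1, 5), seed = 3),
                             importance = FALSE)
  expect_equal(res$training_sessions, 2 * 6 * 5)
  expect_equal(res$refits, 6)
})

test_that("the held-out lesion cannot influence its own fold's model", {
  co <- generate_cohort(signal_cohort_config(n = 10, d = 1, n_geometric = 2,
                                             n_texture = 3, seed = 44,
                                             informative = c(sphericity = NA)))
  al <- aligned_reference(co)
  spec <- model_spec("logit", seed = 6)
  clean <- nested_loo_evaluate(al$table, al$labels, spec)
  for (i in c(1, 5, 10)) {
    poisoned <- al$table
    poisoned$values[i, ] <- 1e9  # sentinel row
    poisoned <- feature_table(poisoned$values,
                              feature_class = poisoned$feature_class)
    dirty <- nested_loo_evaluate(poisoned, al$labels, spec)
    for (field in c("best_hyper", "threshold", "internal_auc", "importance")) {
      expect_identical(dirty$folds[[i]][[field]], clean$folds[[i]][[field]])
    }
  }
})

test_that("nested LOO results are reproducible and every lesion is held out once", {
  co <- generate_cohort(signal_cohort_config(n = 12, d = 1, n_geometric = 2,
                                             n_texture = 3, seed = 45,
                                             informative = c(sphericity = NA)))
  al <- aligned_reference(co)
  spec <- model_spec("rdf", 50, seed = 7)
  a <- nested_loo_evaluate(al$table, al$labels, spec)
  b <- nested_loo_evaluate(al$table, al$labels, spec)
  expect_identical(external_scores(a), external_scores(b))
  expect_setequal(unlist(lapply(a$folds, `[[`, "held_out")),
                  al$labels$lesion_ids)
  for (f in a$folds) {
    expect_equal(f$hard_prediction, as.integer(f$score >= f$threshold))
  }
})

test_that("the singleton-grid shortcut reproduces the calibrated external scores", {
  co <- generate_cohort(signal_cohort_config(n = 10, d = 1, n_geometric = 2,
                                             n_texture = 3, seed = 46,
                                             informative = c(sphericity = NA)))
  al <- aligned_reference(co)
  spec <- model_spec("rdf", 100, seed = 8)
  full <- nested_loo_evaluate(al$table, al$labels, spec, calibrate = TRUE)
  fast <- nested_loo_evaluate(al$table, al$labels, spec, calibrate = FALSE)
  expect_identical(external_scores(fast), external_scores(full))
  expect_true(all(is.na(vapply(fast$folds, `[[`, numeric(1), "threshold"))))
  expect_error(nested_loo_evaluate(al$table, al$labels,
                                   model_spec("rdf", c(50, 100), seed = 8),
                                   calibrate = FALSE),
               "singleton")
})

test_that("group-wise LOO leaves out whole patients", {
  co <- generate_cohort(null_cohort_config(n = 10, n_geometric = 2,
                                           n_texture = 2, seed = 47))
  al <- aligned_reference(co)
  groups <- rep(sprintf("pat%d", 1:5), each = 2)
  labels <- label_vector(al$labels$lesion_ids, al$labels$labels,
                         groups = groups)
  res <- nested_loo_evaluate(al$table, labels, model_spec("logit", seed = 9),
                             group_by = "patient")
  expect_length(res$folds, 5)
  expect_setequal(unlist(lapply(res$folds, `[[`, "held_out")),
                  labels$lesion_ids)
  expect_length(res$folds[[1]]$score, 2)
})

test_that("metrics reproduce confusion-matrix arithmetic and flag empty denominators", {
  # 8 folds with TP=3, FP=1, TN=3, FN=1
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 0, 0, 1)
  res <- fake_loo_result(y, pred)
  m <- compute_metrics(res)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 0.75)
  expect_equal(unname(m$confusion), c(3L, 1L, 3L, 1L))

  all_correct <- fake_loo_result(y, y, scores = y)
  m <- compute_metrics(all_correct)
  expect_equal(m$auc_roc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$recall, 1)

  all_negative <- fake_loo_result(y, rep(0, 8))
  m <- compute_metrics(all_negative)
  expect_equal(m$recall, 0)
  expect_true(is.na(m$precision))
  expect_identical(m$undefined, "precision")
})
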