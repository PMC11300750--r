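# Shared fixtures and independent oracles.

# Hand-built extraction set: 2 patients, 3 variants (reference + 2), one
# feature whose values are easy to sum by hand.
tiny_extraction_set <- function(f_ref = c(2, 10),
                                f_v1 = c(3, 9),
                                f_v2 = c(4, 14),
                                feature = "f1") {
  mk <- function(v) {
    feature_table(matrix(v, ncol = 1,
                         dimnames = list(paste0("P", seq_along(v)), feature)))
  }
  extraction_set(list("standard:25" = mk(f_ref),
                      "reduced:25" = mk(f_v1),
                      "increased:25" = mk(f_v2)),
                 reference = extraction_variant("standard", 25))
}

# Longhand evaluation of the instability double sum, written independently
# of the package implementation.
longhand_delta <- function(es, feature) {
  ref_key <- variant_key(es$reference)
  ref <- es$variants[[ref_key]]$values[, feature]
  rng <- max(ref) - min(ref)
  V <- length(es$variants)
  np <- length(ref)
  total <- 0
  for (k in names(es$variants)) {
    v <- es$variants[[k]]$values[, feature]
    for (p in seq_len(np)) {
      total <- total + abs(v[p] - ref[p]) / rng
    }
  }
  unname(total / (V * np))
}

# Exhaustive pair-counting AUC.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold scan with the same candidate construction as the
# contract (midpoints plus one candidate beyond each extreme), ties toward
# the smallest threshold.
brute_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
             s[length(s)] + 1)
  obj <- vapply(cands, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0)
  }, numeric(1))
  cands[which(obj >= max(obj) - 1e-12)[1]]
}

# Exhaustive 1-D 2-means: every ordered split point, ties toward the
# smallest lower cluster.
brute_two_means <- function(values) {
  o <- order(values)
  v <- values[o]
  n <- length(v)
  wss <- vapply(seq_len(n - 1), function(s) {
    sum((v[1:s] - mean(v[1:s]))^2) + sum((v[(s + 1):n] - mean(v[(s + 1):n]))^2)
  }, numeric(1))
  s <- which(wss <= min(wss) + 1e-12)[1]
  list(lower = sort(names(values)[o[1:s]]),
       upper = sort(names(values)[o[(s + 1):n]]))
}

# Small label-balanced cohort without planted structure.
null_cohort_config <- function(n = 40, n_geometric = 2, n_texture = 8,
                               seed = 1) {
  cohort_config(n_lesions = n, prevalence = 0.5,
                n_geometric = n_geometric, n_texture = n_texture,
                informative = c(sphericity = 0),
                redundant_pairs = data.frame(source = character(),
                                             clone = character(),
                                             r = numeric()),
                seed = seed)
}

# Cohort with planted class signal and no redundancy.
signal_cohort_config <- function(n = 69, d = 1.5, n_geometric = 5,
                                 n_texture = 15, seed = 1,
                                 informative = c(sphericity = NA,
                                                 glszm_sae = NA,
                                                 glszm_lalgle = NA)) {
  informative[] <- d
  cohort_config(n_lesions = n, n_geometric = n_geometric,
                n_texture = n_texture, informative = informative,
                redundant_pairs = data.frame(source = character(),
                                             clone = character(),
                                             r = numeric()),
                seed = seed)
}

aligned_reference <- function(cohort) {
  align_cohort(reference_table(cohort$extraction_set), cohort$labels)
}

# A synthetic nested_loo_result with prescribed hard predictions, for
# metric and concordance arithmetic.
fake_loo_result <- function(labels, predictions, scores = NULL,
                            family = "logit") {
  n <- length(labels)
  ids <- sprintf("L%03d", seq_len(n))
  if (is.null(scores)) scores <- predictions + 0.1
  folds <- lapply(seq_len(n), function(i) {
    list(held_out = ids[i], best_hyper = NA_real_, threshold = 0.5,
         score = scores[i], hard_prediction = as.integer(predictions[i]),
         internal_auc = NA_real_, importance = NULL)
  })
  structure(list(folds = folds,
                 model_spec = model_spec(family, seed = 1),
                 feature_names = c("f1", "f2"),
                 lesion_ids = ids,
                 labels = as.integer(labels),
                 training_sessions = 0L, refits = n),
            class = "nested_loo_result")
}
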