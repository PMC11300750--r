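#' Perturbation instability score of one feature
#'
#' For a feature f over an extraction grid with reference variant `ref`, the
#' instability score is
#'
#'   Delta = 1 / (V * n_p) * sum over variants v, patients p of
#'           |f(v, p) - f(ref, p)| / (max_p f(ref, p) - min_p f(ref, p))
#'
#' where V is the number of grid variants (reference included — its terms
#' are zero) and n_p the number of patients. The denominator is the cohort
#' range of the feature at the reference extraction, so Delta is invariant
#' under affine rescaling of the feature and under patient permutation.
#' With the canonical 3-mask x 5-bin-width grid the prefactor is 1/(15 n_p).
#'
#' A feature that is constant at the reference extraction has an undefined
#' score (zero range): it is returned as `NA` and flagged, never silently 0
#' or infinite.
#'
#' @param es An [extraction_set()].
#' @param feature A feature name present in `es`.
#' @return A single non-negative number, or `NA` if the reference range is
#'   zero.
#' @export
instability_score <- function(es, feature) {
  stopifnot(inherits(es, "extraction_set"))
  ref <- reference_table(es)
  if (!feature %in% ref$feature_names) {
    stop(sprintf("unknown feature '%s'", feature))
  }
  rep <- stability_table(es, features = feature)
  unname(rep$delta[feature])
}

#' Per-variant deviation table and instability scores
#'
#' Computes the full feature-by-variant matrix of patient-averaged
#' normalized absolute deviations from the reference extraction (the
#' heatmap content of a stability figure) together with the per-feature
#' instability score, which is the row mean of that matrix.
#'
#' @param es An [extraction_set()].
#' @param features Feature names to score (default: all).
#' @return An object of class `stability_report`: `delta` (named vector, NA
#'   where undefined), `undefined` (named logical), `per_variant_deviation`
#'   (feature x variant matrix), `reference`, `n_patients`.
#' @export
stability_table <- function(es, features = NULL) {
  stopifnot(inherits(es, "extraction_set"))
  ref <- reference_table(es)
  if (is.null(features)) features <- ref$feature_names
  unknown <- setdiff(features, ref$feature_names)
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  n_p <- nrow(ref$values)
  if (n_p < 2) stop("at least 2 patients are required (reference range undefined)")

  ref_vals <- ref$values[, features, drop = FALSE]
  rng <- apply(ref_vals, 2, function(v) max(v) - min(v))
  undefined <- rng == 0

  keys <- names(es$variants)
  dev <- matrix(NA_real_, length(features), length(keys),
                dimnames = list(features, keys))
  for (k in keys) {
    vals <- es$variants[[k]]$values[, features, drop = FALSE]
    dev[, k] <- colMeans(abs(vals - ref_vals)) / rng
  }
  dev[undefined, ] <- NA_real_
  dev[, variant_key(es$reference)] <- ifelse(undefined, NA_real_, 0)

  delta <- rowMeans(dev)
  structure(list(delta = delta,
                 undefined = stats::setNames(undefined, features),
                 per_variant_deviation = dev,
                 reference = es$reference,
                 n_patients = n_p),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d features x %d variants (reference %s)\n",
              nrow(x$per_variant_deviation), ncol(x$per_variant_deviation),
              variant_key(x$reference)))
  ord <- order(x$delta, na.last = TRUE)
  show <- utils::head(ord, 5)
  for (i in show) {
    cat(sprintf("  %-20s Delta = %s\n", names(x$delta)[i],
                format(x$delta[i], digits = 4)))
  }
  if (length(ord) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a stability report as a tidy CSV
#'
#' One row per feature: the per-variant deviations, the feature class, and
#' the instability score. Diffable replacement for a heatmap figure.
#'
#' @param report A [stability_table()] result.
#' @param table The reference [feature_table()] (for the feature classes).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(report, table, path) {
  stopifnot(inherits(report, "stability_report"))
  df <- data.frame(feature = rownames(report$per_variant_deviation),
                   feature_class = table$feature_class[rownames(report$per_variant_deviation)],
                   report$per_variant_deviation,
                   delta = report$delta,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Drop the less stable member of each highly correlated feature pair
#'
#' All pairwise Pearson correlations are computed on the reference-variant
#' table. Pairs with `|r| > r_threshold` are processed once, in descending
#' `|r|`: if both members are still present, the one with the larger
#' instability score is dropped (an undefined score counts as larger than
#' any defined one; ties drop the lexicographically later name). Correlations
#' are not recomputed after a drop. The number of principal components
#' needed for `variance_threshold` cumulative variance is reported before
#' and after as a redundancy sanity check.
#'
#' @param table The reference-variant [feature_table()].
#' @param delta Named instability scores covering every feature of `table`
#'   (a [stability_table()] `delta` vector, NA where undefined).
#' @param r_threshold Absolute-correlation threshold (default 0.95).
#' @param variance_threshold Cumulative-variance fraction for the PCA check
#'   (default 0.99).
#' @return An object of class `redundancy_result`: `kept`, `dropped` (data
#'   frame with columns dropped/retained/correlation),
#'   `pca_components_before`, `pca_components_after`, `r_threshold`,
#'   `variance_threshold`.
#' @export
redundancy_correction <- function(table, delta, r_threshold = 0.95,
                                  variance_threshold = 0.99) {
  stopifnot(inherits(table, "feature_table"))
  feats <- table$feature_names
  missing <- setdiff(feats, names(delta))
  if (length(missing)) {
    stop("delta missing feature(s): ", paste(missing, collapse = ", "))
  }
  delta <- delta[feats]
  cm <- suppressWarnings(stats::cor(table$values))
  pairs <- which(upper.tri(cm) & abs(cm) > r_threshold & !is.na(cm),
                 arr.ind = TRUE)
  dropped <- data.frame(dropped = character(), retained = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    r_abs <- abs(cm[pairs])
    a <- feats[pairs[, 1]]
    b <- feats[pairs[, 2]]
    ord <- order(-r_abs, pmin(a, b), pmax(a, b))
    gone <- character()
    for (i in ord) {
      f1 <- a[i]; f2 <- b[i]
      if (f1 %in% gone || f2 %in% gone) next
      d1 <- delta[[f1]]; d2 <- delta[[f2]]
      v1 <- if (is.na(d1)) Inf else d1
      v2 <- if (is.na(d2)) Inf else d2
      drop <- if (v1 > v2) f1
              else if (v2 > v1) f2
              else max(f1, f2)  # tie: lexicographically later name
      keep <- setdiff(c(f1, f2), drop)
      gone <- c(gone, drop)
      dropped <- rbind(dropped,
                       data.frame(dropped = drop, retained = keep,
                                  correlation = cm[pairs[i, 1], pairs[i, 2]],
                                  stringsAsFactors = FALSE))
    }
  }
  kept <- setdiff(feats, dropped$dropped)
  before <- pca_component_count(table, variance_threshold)
  after <- pca_component_count(subset_features(table, kept), variance_threshold)
  structure(list(kept = kept, dropped = dropped,
                 pca_components_before = before,
                 pca_components_after = after,
                 r_threshold = r_threshold,
                 variance_threshold = variance_threshold),
            class = "redundancy_result")
}

#' @export
print.redundancy_result <- function(x, ...) {
  cat(sprintf("<redundancy_result> kept %d, dropped %d (|r| > %s); PCA@%s%%: %d -> %d components\n",
              length(x$kept), nrow(x$dropped), format(x$r_threshold),
              format(100 * x$variance_threshold),
              x$pca_components_before, x$pca_components_after))
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %-20s (kept %s, r = %.3f)\n",
                  x$dropped$dropped[i], x$dropped$retained[i],
                  x$dropped$correlation[i]))
    }
  }
  invisible(x)
}

#' Principal components needed to reach a cumulative-variance threshold
#'
#' Columns are standardized to unit variance; zero-variance columns are
#' excluded from the decomposition and count as contributing no variance.
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param variance_threshold Cumulative explained-variance fraction
#'   (default 0.99).
#' @return Integer component count.
#' @export
pca_component_count <- function(table, variance_threshold = 0.99) {
  m <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (ncol(m) < 2) stop("at least 2 features are required")
  if (nrow(m) < 3) stop("at least 3 patients are required")
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all feature columns are constant")
  z <- scale(m[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  as.integer(which(varfrac >= variance_threshold - 1e-12)[1])
}
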