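#' Construct a feature table
#'
#' A feature table is the basic container of the package: a numeric
#' lesion-by-feature matrix together with lesion identifiers and a
#' geometric/texture class label for every feature. Radiomic feature values
#' are treated as unitless.
#'
#' @param values Numeric matrix, one row per lesion, one column per feature.
#' @param lesion_ids Character vector of unique lesion identifiers
#'   (row names of `values`).
#' @param feature_names Character vector of unique feature names
#'   (column names of `values`).
#' @param feature_class Named character vector mapping every feature name to
#'   `"geometric"` or `"texture"`. If `NULL`, all features are classed as
#'   `"texture"`: geometric status must be declared explicitly because the
#'   texture-only analysis mode depends on it, and guessing silently would be
#'   worse than a conservative default.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, lesion_ids = rownames(values),
                          feature_names = colnames(values),
                          feature_class = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature values must be numeric")
  }
  lesion_ids <- as.character(lesion_ids)
  feature_names <- as.character(feature_names)
  if (length(lesion_ids) != nrow(values)) {
    stop("length(lesion_ids) must equal nrow(values)")
  }
  if (length(feature_names) != ncol(values)) {
    stop("length(feature_names) must equal ncol(values)")
  }
  if (anyDuplicated(lesion_ids)) {
    stop("duplicate lesion_ids: ",
         paste(unique(lesion_ids[duplicated(lesion_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature_names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("missing feature values, e.g. lesion '%s', feature '%s'",
                 lesion_ids[idx[1, 1]], feature_names[idx[1, 2]]))
  }
  if (is.null(feature_class)) {
    feature_class <- stats::setNames(rep("texture", length(feature_names)),
                                     feature_names)
  }
  missing_class <- setdiff(feature_names, names(feature_class))
  if (length(missing_class)) {
    stop("feature_class missing for: ", paste(missing_class, collapse = ", "))
  }
  feature_class <- feature_class[feature_names]
  if (!all(feature_class %in% c("geometric", "texture"))) {
    stop("feature_class values must be 'geometric' or 'texture'")
  }
  dimnames(values) <- list(lesion_ids, feature_names)
  structure(list(values = values,
                 lesion_ids = lesion_ids,
                 feature_names = feature_names,
                 feature_class = feature_class),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d lesions x %d features (%d geometric, %d texture)\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_class == "geometric"),
              sum(x$feature_class == "texture")))
  invisible(x)
}

#' Restrict a feature table to a subset of features
#'
#' @param table A [feature_table()].
#' @param features Character vector of feature names to keep (order kept).
#' @return A `feature_table` with the selected columns.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(features, table$feature_names)
  if (length(missing)) {
    stop("unknown features: ", paste(missing, collapse = ", "))
  }
  feature_table(table$values[, features, drop = FALSE],
                lesion_ids = table$lesion_ids,
                feature_names = features,
                feature_class = table$feature_class[features])
}

#' Describe an extraction variant
#'
#' An extraction variant identifies one re-extraction of the feature set:
#' which perturbed segmentation mask was used (`reduced`, `standard`, or
#' `increased`) and the gray-level discretization bin width.
#'
#' @param mask One of `"reduced"`, `"standard"`, `"increased"`.
#' @param bin_width Positive number, the gray-level bin width.
#' @return An object of class `extraction_variant`.
#' @export
extraction_variant <- function(mask, bin_width) {
  mask <- match.arg(mask, c("reduced", "standard", "increased"))
  bin_width <- as.numeric(bin_width)
  if (length(bin_width) != 1 || !is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  structure(list(mask = mask, bin_width = bin_width),
            class = "extraction_variant")
}

#' Key string for an extraction variant, e.g. "standard:25"
#' @param variant An [extraction_variant()].
#' @return A single string `"mask:bin_width"`.
#' @export
variant_key <- function(variant) {
  paste0(variant$mask, ":", format(variant$bin_width, trim = TRUE))
}

#' Parse a "mask:bin_width" key into an extraction variant
#' @param key String such as `"standard:25"`.
#' @return An [extraction_variant()].
#' @export
parse_variant <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("variant key must look like 'standard:25'")
  extraction_variant(parts[1], as.numeric(parts[2]))
}

#' Bundle feature tables over a perturbation grid
#'
#' An extraction set holds one [feature_table()] per extraction variant plus
#' a designated reference variant (the radiologist's standard mask at the
#' default bin width in the original study design). It is the domain of the
#' instability score: every non-reference table is compared against the
#' reference one.
#'
#' @param tables Named list of `feature_table`s, keyed by [variant_key()].
#' @param reference An [extraction_variant()] whose key must be present in
#'   `tables`.
#' @return An object of class `extraction_set`.
#' @export
extraction_set <- function(tables, reference) {
  stopifnot(inherits(reference, "extraction_variant"))
  if (!length(tables)) stop("extraction set needs at least one variant")
  ref_key <- variant_key(reference)
  if (!ref_key %in% names(tables)) {
    stop(sprintf("reference variant absent: '%s' not among extracted variants", ref_key))
  }
  ref <- tables[[ref_key]]
  for (key in names(tables)) {
    tab <- tables[[key]]
    if (!inherits(tab, "feature_table")) stop("all variants must be feature_tables")
    if (!identical(tab$lesion_ids, ref$lesion_ids)) {
      extra <- setdiff(tab$lesion_ids, ref$lesion_ids)
      miss <- setdiff(ref$lesion_ids, tab$lesion_ids)
      stop(sprintf(
        "inconsistent lesion sets: variant '%s' vs reference '%s' (missing: %s; extra: %s)",
        key, ref_key,
        if (length(miss)) paste(miss, collapse = ", ") else "none",
        if (length(extra)) paste(extra, collapse = ", ") else
          "none (order differs)"))
    }
    if (!identical(tab$feature_names, ref$feature_names)) {
      stop(sprintf("variant '%s' does not share the reference feature names", key))
    }
  }
  structure(list(variants = tables, reference = reference),
            class = "extraction_set")
}

#' @export
print.extraction_set <- function(x, ...) {
  ref <- reference_table(x)
  cat(sprintf("<extraction_set> %d variants (reference %s), %d lesions x %d features\n",
              length(x$variants), variant_key(x$reference),
              nrow(ref$values), ncol(ref$values)))
  invisible(x)
}

#' Feature table of the reference variant
#' @param es An [extraction_set()].
#' @return The reference [feature_table()].
#' @export
reference_table <- function(es) {
  stopifnot(inherits(es, "extraction_set"))
  es$variants[[variant_key(es$reference)]]
}

#' Construct a binary label vector
#'
#' Malignant is always the positive class. Both classes must be present:
#' every downstream stage (AUC, threshold calibration, model fitting)
#' requires a two-class cohort.
#'
#' @param lesion_ids Character vector of unique lesion identifiers.
#' @param labels Integer/logical vector (1/TRUE = malignant) or a character
#'   vector of `"benign"`/`"malignant"` tokens (case-insensitive).
#' @param groups Optional character vector of group (patient) identifiers,
#'   enabling group-wise leave-one-out.
#' @return An object of class `label_vector` with integer 0/1 labels.
#' @export
label_vector <- function(lesion_ids, labels, groups = NULL) {
  lesion_ids <- as.character(lesion_ids)
  if (anyDuplicated(lesion_ids)) {
    stop("duplicate lesion_ids: ",
         paste(unique(lesion_ids[duplicated(lesion_ids)]), collapse = ", "))
  }
  if (is.character(labels) || is.factor(labels)) {
    tok <- tolower(as.character(labels))
    bad <- setdiff(unique(tok), c("benign", "malignant"))
    if (length(bad)) {
      stop("unknown label token(s): ", paste(bad, collapse = ", "))
    }
    labels <- as.integer(tok == "malignant")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
  }
  if (length(labels) != length(lesion_ids)) {
    stop("labels and lesion_ids lengths differ")
  }
  if (length(unique(labels)) < 2) {
    stop("both classes (benign and malignant) must be present")
  }
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != length(lesion_ids)) {
      stop("groups and lesion_ids lengths differ")
    }
  }
  structure(list(lesion_ids = lesion_ids, labels = labels, groups = groups),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> %d lesions, %d malignant / %d benign%s\n",
              length(x$labels), sum(x$labels), sum(1 - x$labels),
              if (is.null(x$groups)) "" else
                sprintf(", %d patient groups", length(unique(x$groups)))))
  invisible(x)
}

#' Read a long-format extraction CSV into an extraction set
#'
#' The expected layout is one row per (lesion, mask, bin width) with columns
#' `lesion_id`, `mask`, `bin_width` followed by one numeric column per
#' feature. Feature classes come from a sidecar YAML file mapping each
#' feature name to `list(class = "geometric"|"texture")`; without it all
#' features are classed as texture. Lesion order is canonicalized by sorting
#' `lesion_id` so that downstream fold indexing does not depend on input row
#' order.
#'
#' @param path Path to the features CSV.
#' @param reference The reference [extraction_variant()]; must be present in
#'   the file.
#' @param meta_path Optional path to the feature-class YAML sidecar.
#' @return A validated [extraction_set()].
#' @export
read_extraction_set <- function(path,
                                reference = extraction_variant("standard", 25),
                                meta_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("lesion_id", "mask", "bin_width")
  if (!all(required %in% names(df))) {
    stop("features CSV must have columns lesion_id, mask, bin_width")
  }
  feat_cols <- setdiff(names(df), required)
  if (!length(feat_cols)) stop("features CSV has no feature columns")
  for (fc in feat_cols) {
    v <- df[[fc]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric feature value at row %d, column '%s': '%s'",
                     bad[1], fc, v[bad[1]]))
      }
      df[[fc]] <- num
    }
  }

  feature_class <- NULL
  if (!is.null(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    feature_class <- vapply(meta, function(m) m$class, character(1))
  }

  key <- paste0(df$mask, ":", format(df$bin_width, trim = TRUE))
  all_lesions <- sort(unique(df$lesion_id))
  tables <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (anyDuplicated(sub$lesion_id)) {
      stop(sprintf("duplicate lesion rows in variant '%s': %s", k,
                   paste(unique(sub$lesion_id[duplicated(sub$lesion_id)]),
                         collapse = ", ")))
    }
    miss <- setdiff(all_lesions, sub$lesion_id)
    if (length(miss)) {
      stop(sprintf("lesion(s) %s absent from variant '%s' but present elsewhere",
                   paste(miss, collapse = ", "), k))
    }
    sub <- sub[order(sub$lesion_id), , drop = FALSE]
    m <- as.matrix(sub[, feat_cols, drop = FALSE])
    tables[[k]] <- feature_table(m, lesion_ids = sub$lesion_id,
                                 feature_names = feat_cols,
                                 feature_class = feature_class)
  }
  extraction_set(tables, reference)
}

#' Write an extraction set back to the long CSV layout
#'
#' Inverse of [read_extraction_set()] up to row order.
#'
#' @param es An [extraction_set()].
#' @param path Output CSV path.
#' @param meta_path Optional path for the feature-class YAML sidecar.
#' @return `path`, invisibly.
#' @export
write_extraction_set <- function(es, path, meta_path = NULL) {
  stopifnot(inherits(es, "extraction_set"))
  rows <- lapply(names(es$variants), function(k) {
    v <- parse_variant(k)
    tab <- es$variants[[k]]
    data.frame(lesion_id = tab$lesion_ids,
               mask = v$mask,
               bin_width = v$bin_width,
               as.data.frame(tab$values),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    fc <- reference_table(es)$feature_class
    yaml::write_yaml(lapply(as.list(fc), function(cl) list(class = cl)),
                     meta_path)
  }
  invisible(path)
}

#' Read a labels CSV
#'
#' Expects columns `lesion_id` and `label` (`benign`/`malignant`,
#' case-insensitive) and an optional `patient_id` column for group-wise
#' leave-one-out.
#'
#' @param path Path to the labels CSV.
#' @return A [label_vector()] with malignant as the positive class.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lesion_id", "label") %in% names(df))) {
    stop("labels CSV must have columns lesion_id, label")
  }
  label_vector(df$lesion_id, df$label,
               groups = if ("patient_id" %in% names(df)) df$patient_id)
}

#' Align a feature table with a label vector
#'
#' Restricts both to their common lesions in a common (sorted) order. The
#' labels may cover extra lesions, which are dropped with a message; a table
#' lesion without a label is an error.
#'
#' @param table A [feature_table()].
#' @param labels A [label_vector()].
#' @return A list with elements `table` and `labels`, identically ordered.
#' @export
align_cohort <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"), inherits(labels, "label_vector"))
  unlabeled <- setdiff(table$lesion_ids, labels$lesion_ids)
  if (length(unlabeled)) {
    stop("lesion(s) without a label: ", paste(unlabeled, collapse = ", "))
  }
  common <- sort(intersect(table$lesion_ids, labels$lesion_ids))
  if (!length(common)) stop("empty intersection between table and labels")
  extra <- setdiff(labels$lesion_ids, common)
  if (length(extra)) {
    message("dropping ", length(extra), " labeled lesion(s) absent from the table: ",
            paste(extra, collapse = ", "))
  }
  tab <- feature_table(table$values[common, , drop = FALSE],
                       lesion_ids = common,
                       feature_names = table$feature_names,
                       feature_class = table$feature_class)
  idx <- match(common, labels$lesion_ids)
  lab <- label_vector(common, labels$labels[idx],
                      groups = if (!is.null(labels$groups)) labels$groups[idx])
  list(table = tab, labels = lab)
}
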