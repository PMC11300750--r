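#' Configure the synthetic radiomic cohort generator
#'
#' The generator emulates the shape of a medium-sized breast-lesion radiomic
#' study: by default 69 lesions with a malignant-majority split (35/69), 25
#' features per modality (6 geometric, 19 texture), a couple of near-duplicate
#' feature pairs, geometric features that are insensitive to the gray-level
#' bin width, and class separation driven by a small planted subset of
#' features. All structural choices are configurable; the defaults are the
#' study conditions the package's validation simulations run under.
#'
#' @param n_lesions Number of lesions (default 69).
#' @param prevalence Malignant fraction in (0, 1); exactly
#'   `floor(prevalence * n_lesions)` lesions are labeled malignant (default
#'   35/69).
#' @param n_geometric,n_texture Feature counts per class (defaults 6 and 19).
#' @param informative Named numeric vector: feature name -> effect size `d`
#'   (standardized mean shift added to the malignant class).
#' @param redundant_pairs Data frame with columns `source`, `clone`, `r`:
#'   each clone column is regenerated as an `r`-mixture of its source plus
#'   independent noise, hitting Pearson correlation `r` in expectation.
#' @param instability Named numeric vector: feature name -> `sigma_pert`, the
#'   scale of additive mask-perturbation noise relative to the feature's
#'   cohort SD. Unnamed features default to 0.05 (geometric) / 0.3 (texture).
#' @param bw_sensitivity Named numeric vector: feature name -> slope of the
#'   bin-width response per unit deviation from the reference bin width
#'   (again relative to cohort SD). Geometric features must be 0 — bin width
#'   only enters texture computations. Unnamed texture features default to
#'   0.02.
#' @param masks Mask variants of the perturbation grid.
#' @param bin_widths Bin widths of the perturbation grid.
#' @param reference Reference [extraction_variant()] (default standard:25).
#' @param seed Integer seed; same config + seed reproduces the cohort
#'   exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_lesions = 69,
                          prevalence = 35 / 69,
                          n_geometric = 6,
                          n_texture = 19,
                          informative = c(sphericity = 1.5,
                                          glszm_sae = 1.0,
                                          ngtdm_strength = 0.8),
                          redundant_pairs = data.frame(
                            source = c("volume", "rms"),
                            clone = c("total_energy", "median_intensity"),
                            r = c(0.99, 0.97)),
                          instability = NULL,
                          bw_sensitivity = NULL,
                          masks = c("reduced", "standard", "increased"),
                          bin_widths = c(15, 20, 25, 30, 35),
                          reference = extraction_variant("standard", 25),
                          seed = 1L) {
  if (n_lesions < 4) stop("n_lesions must be at least 4")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  n_pos <- floor(prevalence * n_lesions)
  if (n_pos < 1 || n_pos >= n_lesions) {
    stop("prevalence produces an empty class at this n_lesions")
  }

  geo_pool <- c("volume", "sphericity", "elongation", "surface_area",
                "compactness", "flatness", "maximum_diameter", "mesh_volume")
  tex_pool <- c("energy", "total_energy", "entropy", "uniformity",
                "median_intensity", "rms", "glszm_sae", "glszm_lae",
                "glszm_lalgle", "glszm_lglze", "glszm_salgle", "glszm_hglze",
                "glszm_sahgle", "glszm_zp", "glszm_ze", "ngtdm_coarseness",
                "ngtdm_strength", "ngtdm_contrast", "ngtdm_busyness",
                "glcm_contrast", "glcm_correlation", "glrlm_sre", "glrlm_lre")
  if (n_geometric > length(geo_pool) || n_texture > length(tex_pool)) {
    geo <- if (n_geometric <= length(geo_pool)) geo_pool[seq_len(n_geometric)]
           else c(geo_pool, sprintf("geom_%02d", seq_len(n_geometric - length(geo_pool))))
    tex <- if (n_texture <= length(tex_pool)) tex_pool[seq_len(n_texture)]
           else c(tex_pool, sprintf("tex_%02d", seq_len(n_texture - length(tex_pool))))
  } else {
    geo <- geo_pool[seq_len(n_geometric)]
    tex <- tex_pool[seq_len(n_texture)]
  }
  feature_names <- c(geo, tex)
  feature_class <- stats::setNames(rep(c("geometric", "texture"),
                                       c(n_geometric, n_texture)),
                                   feature_names)

  check_known <- function(x, what) {
    unknown <- setdiff(names(x), feature_names)
    if (length(unknown)) {
      stop(sprintf("%s refers to unknown feature(s): %s", what,
                   paste(unknown, collapse = ", ")))
    }
  }
  check_known(informative, "informative")
  if (any(!is.finite(informative))) stop("effect sizes must be finite")

  if (nrow(redundant_pairs)) {
    if (!all(c("source", "clone", "r") %in% names(redundant_pairs))) {
      stop("redundant_pairs needs columns source, clone, r")
    }
    check_known(stats::setNames(redundant_pairs$r, redundant_pairs$source),
                "redundant_pairs$source")
    check_known(stats::setNames(redundant_pairs$r, redundant_pairs$clone),
                "redundant_pairs$clone")
    if (any(redundant_pairs$r <= 0 | redundant_pairs$r > 1)) {
      stop("target correlations must lie in (0, 1]")
    }
    if (length(intersect(redundant_pairs$clone, redundant_pairs$source)) ||
        anyDuplicated(redundant_pairs$clone)) {
      stop("clone features must be distinct from sources and from each other")
    }
  }

  sig <- stats::setNames(ifelse(feature_class == "geometric", 0.05, 0.3),
                         feature_names)
  if (!is.null(instability)) {
    check_known(instability, "instability")
    if (any(instability < 0)) stop("sigma_pert must be >= 0")
    sig[names(instability)] <- instability
  }
  bws <- stats::setNames(ifelse(feature_class == "geometric", 0, 0.02),
                         feature_names)
  if (!is.null(bw_sensitivity)) {
    check_known(bw_sensitivity, "bw_sensitivity")
    bws[names(bw_sensitivity)] <- bw_sensitivity
  }
  if (any(bws[feature_class == "geometric"] != 0)) {
    stop("geometric features must have bw_sensitivity 0 (bin width does not enter shape computations)")
  }

  ref_key <- variant_key(reference)
  grid_keys <- as.vector(outer(masks, bin_widths,
                               function(m, b) paste0(m, ":", format(b, trim = TRUE))))
  if (!ref_key %in% grid_keys) {
    stop("reference variant must lie on the masks x bin_widths grid")
  }

  structure(list(n_lesions = as.integer(n_lesions), prevalence = prevalence,
                 n_positive = as.integer(n_pos),
                 feature_names = feature_names, feature_class = feature_class,
                 informative = informative, redundant_pairs = redundant_pairs,
                 instability = sig, bw_sensitivity = bws,
                 masks = masks, bin_widths = bin_widths,
                 reference = reference, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Baseline (reference-variant) features are independent standard normal
#' draws; informative features receive a `+d` mean shift in the malignant
#' class; clone features are regenerated as correlation-`r` mixtures of
#' their sources. Every non-reference variant `(m, bw)` is the reference
#' matrix plus `mask_offset(m) * sigma_pert * sd * eps` plus
#' `bw_sensitivity * (bw - bw_ref) * sd * eta` with fresh unit normal noise,
#' where `mask_offset` is 0 for the standard mask and 1 for the
#' reduced/increased masks. The reference variant reproduces the baseline
#' matrix exactly.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `extraction_set`, `labels`
#'   (a [label_vector()]), and `truth` (class `cohort_truth`: the planted
#'   informative set, clone map, per-feature `sigma_pert` and
#'   `bw_sensitivity`, and the realized seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_lesions
  p <- length(config$feature_names)
  lesion_ids <- sprintf("L%03d", seq_len(n))

  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  labels <- integer(n)
  labels[sample.int(n, config$n_positive)] <- 1L

  base <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(lesion_ids, config$feature_names))
  for (f in names(config$informative)) {
    base[labels == 1L, f] <- base[labels == 1L, f] + config$informative[[f]]
  }
  if (nrow(config$redundant_pairs)) {
    for (i in seq_len(nrow(config$redundant_pairs))) {
      src <- config$redundant_pairs$source[i]
      clone <- config$redundant_pairs$clone[i]
      r <- config$redundant_pairs$r[i]
      s <- stats::sd(base[, src])
      base[, clone] <- r * base[, src] +
        sqrt(1 - r^2) * s * stats::rnorm(n)
    }
  }

  sd_ref <- apply(base, 2, stats::sd)
  ref_key <- variant_key(config$reference)
  bw_ref <- config$reference$bin_width

  tables <- list()
  for (m in config$masks) {
    for (bw in config$bin_widths) {
      key <- paste0(m, ":", format(bw, trim = TRUE))
      if (key == ref_key) {
        vals <- base
      } else {
        mask_off <- if (m == "standard") 0 else 1
        eps <- matrix(stats::rnorm(n * p), n, p)
        eta <- matrix(stats::rnorm(n * p), n, p)
        vals <- base +
          mask_off * sweep(eps, 2, config$instability * sd_ref, `*`) +
          (bw - bw_ref) * sweep(eta, 2, config$bw_sensitivity * sd_ref, `*`)
      }
      tables[[key]] <- feature_table(vals, lesion_ids = lesion_ids,
                                     feature_names = config$feature_names,
                                     feature_class = config$feature_class)
    }
  }

  truth <- structure(list(informative = config$informative,
                          redundant = stats::setNames(
                            as.character(config$redundant_pairs$source),
                            config$redundant_pairs$clone),
                          sigma_pert = config$instability,
                          bw_sensitivity = config$bw_sensitivity,
                          feature_names = config$feature_names,
                          seed = config$seed),
                     class = "cohort_truth")

  list(extraction_set = extraction_set(tables, config$reference),
       labels = label_vector(lesion_ids, labels),
       truth = truth)
}

#' Score a selection trace against the generator's ground truth
#'
#' Precision and recall of the finally selected feature set with respect to
#' the planted informative set, plus a flag for informative features that
#' were discarded as redundant before selection ever saw them.
#'
#' @param trace A [adaptive_select()] trace.
#' @param truth The `cohort_truth` from [generate_cohort()].
#' @param dropped_redundant Optional character vector of features removed by
#'   [redundancy_correction()] before selection.
#' @return A list with `precision`, `recall`, `selected`, `informative`, and
#'   `informative_dropped_as_redundant`.
#' @export
recovery_report <- function(trace, truth, dropped_redundant = character()) {
  stopifnot(inherits(trace, "selection_trace"), inherits(truth, "cohort_truth"))
  universe <- union(trace$feature_names, dropped_redundant)
  if (length(setdiff(universe, truth$feature_names))) {
    stop("trace and truth cover different feature universes: ",
         paste(setdiff(universe, truth$feature_names), collapse = ", "))
  }
  informative <- names(truth$informative)
  selected <- trace$final_set
  hit <- intersect(selected, informative)
  list(precision = if (length(selected)) length(hit) / length(selected) else NA_real_,
       recall = if (length(informative)) length(hit) / length(informative) else NA_real_,
       selected = selected,
       informative = informative,
       informative_dropped_as_redundant = intersect(dropped_redundant, informative))
}

# Seed-scoped RNG: sets the seed, returns a restorer for the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Write a generated cohort to disk
#'
#' Produces the on-disk layout the readers expect: `features.csv` (long
#' format), `features.meta.yaml` (feature classes), `labels.csv`, and
#' `truth.json` (the planted ground truth).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_extraction_set(cohort$extraction_set,
                       file.path(dir, "features.csv"),
                       file.path(dir, "features.meta.yaml"))
  utils::write.csv(data.frame(lesion_id = cohort$labels$lesion_ids,
                              label = ifelse(cohort$labels$labels == 1L,
                                             "malignant", "benign")),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(informative = as.list(tr$informative),
                            redundant = as.list(tr$redundant),
                            sigma_pert = as.list(tr$sigma_pert),
                            bw_sensitivity = as.list(tr$bw_sensitivity),
                            seed = tr$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
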