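#' Default extraction configuration
#'
#' The feature bank is the cross product of image transforms and feature
#' classes: 10 transforms x (18 first-order + 24 GLCM + 16 GLRLM +
#' 16 GLSZM + 14 GLDM + 5 NGTDM) = 930 features under the defaults.
#' Transforms are computed on the ROI bounding box padded by `pad` pixels
#' (localizing wavelet/gradient context), then restricted to the mask.
#'
#' @param transforms character vector of transform kinds
#'   (see [apply_transform()]).
#' @param classes subset of `c("firstorder", "glcm", "glrlm", "glszm",
#'   "gldm", "ngtdm")`.
#' @param discretization arguments for [discretize()].
#' @param distance,angles GLCM/GLRLM geometry.
#' @param pad bounding-box padding in pixels.
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(transforms = c("original", "wavelet_LL",
                                          "wavelet_LH", "wavelet_HL",
                                          "wavelet_HH", "square",
                                          "squareroot", "logarithm",
                                          "exponential", "gradient"),
                           classes = c("firstorder", "glcm", "glrlm",
                                       "glszm", "gldm", "ngtdm"),
                           discretization = list(mode = "fixed_bin_width",
                                                 bin_width = 5),
                           distance = 1, angles = c(0, 45, 90, 135),
                           pad = 8) {
  structure(list(transforms = transforms, classes = classes,
                 discretization = discretization, distance = distance,
                 angles = angles, pad = pad),
            class = "extract_config")
}

class_feature_names <- function(class) {
  switch(class,
         firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                        "10Percentile", "90Percentile", "Maximum", "Mean",
                        "Median", "InterquartileRange", "Range",
                        "MeanAbsoluteDeviation",
                        "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                        "Skewness", "Kurtosis", "Variance", "Uniformity"),
         glcm = glcm_feature_names,
         glrlm = glrlm_feature_names,
         glszm = glszm_feature_names,
         gldm = gldm_feature_names,
         ngtdm = ngtdm_feature_names,
         stop("unknown feature class: ", class))
}

#' The feature registry
#'
#' Enumerates every feature name of a configuration in fixed order
#' `<transform>_<class>_<Feature>`, e.g.
#' `square_glrlm_ShortRunLowGrayLevelEmphasis`.
#'
#' @param config an [extract_config()].
#' @return Character vector of feature names.
#' @export
feature_registry <- function(config = extract_config()) {
  unlist(lapply(config$transforms, function(tr)
    unlist(lapply(config$classes, function(cl)
      paste(tr, cl, class_feature_names(cl), sep = "_")))))
}

#' Extract the full feature vector of one candidate region
#'
#' Crops the slice to the padded ROI bounding box, applies each configured
#' transform, discretizes, and computes every configured feature class.
#' Non-finite values are replaced by 0 (and counted in attribute
#' `n_nonfinite`) so downstream tables stay rectangular.
#'
#' @param slice [image_slice()] or matrix.
#' @param mask logical ROI mask.
#' @param config an [extract_config()].
#' @return Named numeric vector, `length(feature_registry(config))`.
#' @export
extract_all <- function(slice, mask, config = extract_config()) {
  slice <- as_slice(slice)
  mask <- roi_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1, min(idx[, 1]) - config$pad)
  r1 <- min(nrow(mask), max(idx[, 1]) + config$pad)
  c0 <- max(1, min(idx[, 2]) - config$pad)
  c1 <- min(ncol(mask), max(idx[, 2]) + config$pad)
  sub <- image_slice(slice$values[r0:r1, c0:c1, drop = FALSE], slice$spacing)
  msk <- mask[r0:r1, c0:c1, drop = FALSE]
  out <- numeric(0)
  for (tr in config$transforms) {
    tv <- apply_transform(sub, msk, tr)
    d <- do.call(discretize, c(list(slice = tv, mask = msk),
                               config$discretization))
    for (cl in config$classes) {
      vals <- switch(cl,
        firstorder = first_order_features(tv, msk, config$discretization),
        glcm = glcm_features(d$levels, d$ng, config$distance, config$angles),
        glrlm = glrlm_features(d$levels, d$ng, config$angles),
        glszm = glszm_features(d$levels, d$ng),
        gldm = gldm_features(d$levels, d$ng),
        ngtdm = ngtdm_features(d$levels, d$ng))
      names(vals) <- paste(tr, cl, names(vals), sep = "_")
      out <- c(out, vals)
    }
  }
  bad <- !is.finite(out)
  if (any(bad)) {
    msg("extract_all: ", sum(bad), " non-finite feature value(s) set to 0")
    out[bad] <- 0
  }
  attr(out, "n_nonfinite") <- sum(bad)
  out
}

#' Build labeled feature tables for the three study pairings
#'
#' Runs midline estimation, ROI mirroring and feature extraction over a
#' cohort, then assembles the three comparisons the separability analysis
#' is built on:
#' \describe{
#'   \item{lesion_vs_mirror}{lesion regions vs their contralateral mirrors
#'     (one pair per lesion subject).}
#'   \item{normal_vs_mirror}{normal-subject regions vs their mirrors (three
#'     pairs per normal subject) — the null comparison.}
#'   \item{lesion_vs_normal}{lesion regions vs one normal region per
#'     control subject, at comparable locations.}
#' }
#'
#' @param cohort a `ct_cohort`.
#' @param config an [extract_config()].
#' @param use_true_midline use the generator's midline instead of
#'   estimating it from the image (tests only).
#' @return A list of three `labeled_feature_table` objects.  Each is a
#'   data.frame of features with attributes `y` (1 = infarct-side region),
#'   `pairing_id`, `label` and `subject_id`.
#' @export
extract_cohort_features <- function(cohort, config = extract_config(),
                                    use_true_midline = FALSE) {
  regions <- list()
  for (sub in cohort$subjects) {
    ml <- if (use_true_midline)
      midline_params(sub$true_midline["offset"], sub$true_midline["angle"])
    else NULL
    pairs <- make_candidate_pairs(sub, midline = ml)
    for (p in pairs) for (r in p) regions[[length(regions) + 1]] <- r
  }
  reg_names <- feature_registry(config)
  X <- matrix(NA_real_, length(regions), length(reg_names),
              dimnames = list(NULL, reg_names))
  meta <- data.frame(subject_id = character(length(regions)),
                     label = character(length(regions)),
                     pairing_id = character(length(regions)),
                     slice_idx = integer(length(regions)))
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    X[k, ] <- extract_all(r$slice, r$mask, config)
    meta$subject_id[k] <- r$subject_id
    meta$label[k] <- r$label
    meta$pairing_id[k] <- r$pairing_id
  }
  make_table <- function(rows, y) {
    tb <- as.data.frame(X[rows, , drop = FALSE])
    structure(tb, y = as.integer(y), pairing_id = meta$pairing_id[rows],
              label = meta$label[rows], subject_id = meta$subject_id[rows],
              class = c("labeled_feature_table", class(tb)))
  }
  lab <- meta$label
  # pairing C: lesion regions vs the first normal region of each control
  first_norm <- lab == "normal" & !duplicated(paste(meta$subject_id, lab))
  list(
    lesion_vs_mirror = make_table(which(lab %in% c("lesion", "mirror")),
                                  lab[lab %in% c("lesion", "mirror")] == "lesion"),
    normal_vs_mirror = make_table(which(lab %in% c("normal", "normal_mirror")),
                                  lab[lab %in% c("normal", "normal_mirror")] == "normal"),
    lesion_vs_normal = make_table(which(lab == "lesion" | first_norm),
                                  lab[lab == "lesion" | first_norm] == "lesion"))
}

#' Write a labeled feature table as CSV
#'
#' First columns are `subject_id`, `label`, `pairing_id`, `y`; the rest is
#' the regions-by-features matrix.
#'
#' @param table a `labeled_feature_table`.
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  n <- nrow(table)
  out <- cbind(data.frame(
    subject_id = attr(table, "subject_id") %||% rep(NA_character_, n),
    label = attr(table, "label") %||% rep(NA_character_, n),
    pairing_id = attr(table, "pairing_id") %||% rep(NA_character_, n),
    y = attr(table, "y")),
    as.data.frame(table))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the feature registry as JSON
#' @param config an [extract_config()].
#' @param path output JSON path.
#' @export
write_registry <- function(config, path) {
  entries <- lapply(config$transforms, function(tr)
    lapply(config$classes, function(cl)
      list(transform = tr, class = cl,
           features = class_feature_names(cl))))
  jsonlite::write_json(list(n_features = length(feature_registry(config)),
                            bank = entries),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
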