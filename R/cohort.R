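#' Generate a synthetic cohort of lesion and normal subjects
#'
#' Emulates the study layout the analysis assumes: `n_lesion` subjects
#' contribute one slice each with a unilateral lesion, and `n_normal`
#' control subjects contribute three slices each, onto which lesion-shaped
#' ROIs resampled from the lesion subjects' mask library are projected (so
#' "normal" regions are interrogated at lesion-plausible locations, exactly
#' as DWI-derived labels would be projected onto control CTs).
#'
#' Each subject's head carries a small random pose (in-plane rotation and
#' horizontal shift), recorded as `true_midline`, so the midline estimator
#' downstream has something honest to recover.  Everything is a pure
#' function of `seed`.
#'
#' @param n_lesion,n_normal subject counts (>= 1).
#' @param spec a [phantom_spec()].
#' @param lesion_dist list describing the lesion population:
#'   `radius_range` (px), `irregularity`, `delta_hu` (HU), `smooth_sigma`
#'   (px).  `delta_hu = 0, smooth_sigma = 0` gives the null cohort used for
#'   calibration.
#' @param seed integer master seed.
#' @param max_tries placement retries for a sampled ROI before erroring.
#' @return An object of class `ct_cohort`: list of subjects, each with
#'   `subject_id`, `group` (`"lesion"`/`"normal"`), `true_midline`
#'   (offset px, angle deg), and `slices`, a list of records holding
#'   `slice`, `mask`, `brain`.
#' @export
generate_cohort <- function(n_lesion = 38, n_normal = 18,
                            spec = phantom_spec(),
                            lesion_dist = list(radius_range = c(10, 20),
                                               irregularity = 0.3,
                                               delta_hu = -6,
                                               smooth_sigma = 1.5),
                            seed = 1L, max_tries = 50L) {
  stopifnot(n_lesion >= 1, n_normal >= 1)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  cxm <- (nc - 1) / 2
  subjects <- vector("list", n_lesion + n_normal)
  mask_library <- list()   # canonical-frame lesion masks, for projection

  sample_pose <- function(s) with_seed(s, c(offset = runif(1, -8, 8),
                                            angle = runif(1, -4, 4)))

  place_blob <- function(brain, lspec, s) {
    # retries sample a fresh centre (and shape) inside a random hemisphere
    for (try in seq_len(max_tries)) {
      st <- derive_seed(s, try)
      ctr <- with_seed(st, {
        side <- sample(c(-1, 1), 1)
        margin <- lspec$mean_radius * (1 + lspec$boundary_irregularity) + 4
        hi <- 0.33 * nc - margin - 4        # keep the blob inside the brain
        if (hi <= margin + 2)
          stop("lesion radius too large for this image size")
        cc <- cxm + 1 + side * runif(1, margin + 2, hi)
        rr <- nrow(brain) / 2 + runif(1, -0.22, 0.22) * nrow(brain)
        c(rr, cc)
      })
      lspec$center <- ctr
      m <- try(sample_lesion_roi(brain, lspec, midline_col = cxm, seed = st),
               silent = TRUE)
      if (!inherits(m, "try-error")) return(list(mask = m, spec = lspec))
    }
    stop("could not place an ROI inside the brain after ", max_tries,
         " tries")
  }

  pose_warp <- function(rec, pose) {
    # rotating the image by -angle tilts the (vertical) generating midline
    # by +angle in the midline_params convention, so true_midline can be
    # compared directly against estimate_midline() output
    pp <- affine_params(tx = pose["offset"], ty = 0, theta = -pose["angle"])
    bg <- spec$tissue_means["background"]
    list(slice = image_slice(warp_affine(rec$slice$values, pp,
                                         interp = "bilinear", fill = bg),
                             rec$slice$spacing),
         mask = transform_mask(rec$mask, pp),
         brain = warp_affine(rec$brain * 1, pp, interp = "nearest",
                             fill = 0) > 0.5)
  }

  for (i in seq_len(n_lesion)) {
    s <- derive_seed(seed, i)
    head <- generate_head_slice(spec, seed = s)
    lspec <- with_seed(derive_seed(s, 2), lesion_spec(
      mean_radius = runif(1, lesion_dist$radius_range[1],
                          lesion_dist$radius_range[2]),
      boundary_irregularity = lesion_dist$irregularity,
      delta_hu = lesion_dist$delta_hu,
      smooth_sigma = lesion_dist$smooth_sigma, seed = derive_seed(s, 3)))
    blob <- place_blob(head$brain, lspec, derive_seed(s, 4))
    mask_library[[length(mask_library) + 1]] <- blob$mask
    lesioned <- inject_lesion(head$slice, blob$mask, blob$spec)
    pose <- sample_pose(derive_seed(s, 5))
    rec <- pose_warp(list(slice = lesioned, mask = blob$mask,
                          brain = head$brain), pose)
    subjects[[i]] <- structure(
      list(subject_id = sprintf("L%03d", i), group = "lesion",
           true_midline = pose, slices = list(rec)),
      class = "synthetic_subject")
  }

  for (j in seq_len(n_normal)) {
    s <- derive_seed(seed, 10000 + j)
    pose <- sample_pose(derive_seed(s, 5))
    recs <- vector("list", 3)
    for (k in 1:3) {
      sk <- derive_seed(s, 20 + k)
      head <- generate_head_slice(spec, seed = sk)
      # project a lesion-shaped mask from the library onto this slice
      lib_mask <- with_seed(derive_seed(sk, 1),
                            mask_library[[sample.int(length(mask_library), 1)]])
      ctr0 <- mask_centroid(lib_mask)            # (x, y), 0-based
      placed <- NULL
      for (try in seq_len(max_tries)) {
        st <- derive_seed(sk, 100 + try)
        rad <- sqrt(sum(lib_mask) / pi)
        tgt <- with_seed(st, {
          side <- sample(c(-1, 1), 1)
          hi <- max(rad + 10, 0.33 * nc - rad - 8)
          c(x = cxm + side * runif(1, rad + 6, hi),
            y = nr / 2 + runif(1, -0.22, 0.22) * nr)
        })
        cand <- try(transform_mask(lib_mask,
                                   affine_params(tx = tgt["x"] - ctr0["x"],
                                                 ty = tgt["y"] - ctr0["y"])),
                    silent = TRUE)
        if (inherits(cand, "try-error")) next
        xs <- which(cand, arr.ind = TRUE)[, 2] - 1
        crosses <- min(xs) < cxm && max(xs) > cxm
        if (!crosses && all(head$brain[cand])) { placed <- cand; break }
      }
      if (is.null(placed))
        stop("could not place a projected ROI inside normal brain of ",
             sprintf("N%03d", j))
      recs[[k]] <- pose_warp(list(slice = head$slice, mask = placed,
                                  brain = head$brain), pose)
    }
    subjects[[n_lesion + j]] <- structure(
      list(subject_id = sprintf("N%03d", j), group = "normal",
           true_midline = pose, slices = recs),
      class = "synthetic_subject")
  }
  structure(list(subjects = subjects, spec = spec, lesion_dist = lesion_dist,
                 seed = seed),
            class = "ct_cohort")
}

#' @export
print.ct_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  nsl <- sum(vapply(x$subjects, function(s) length(s$slices), 0L))
  cat(sprintf("<ct_cohort> %d lesion + %d normal subjects, %d (slice, mask) records, seed %d\n",
              sum(groups == "lesion"), sum(groups == "normal"), nsl, x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Slices and masks go out as NIfTI (`.nii.gz`) and 16-bit PNG; a JSON
#' manifest records subject ids, groups, file paths and the master seed.
#'
#' @param cohort a `ct_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cohort$seed, subjects = list())
  for (sub in cohort$subjects) {
    entry <- list(subject_id = sub$subject_id, group = sub$group,
                  true_midline = as.list(sub$true_midline), slices = list())
    for (k in seq_along(sub$slices)) {
      rec <- sub$slices[[k]]
      stem <- file.path(dir, sprintf("%s_s%d", sub$subject_id, k))
      RNifti::writeNifti(rec$slice$values, paste0(stem, "_ct.nii.gz"))
      RNifti::writeNifti(rec$mask * 1L, paste0(stem, "_roi.nii.gz"))
      v <- rec$slice$values
      png::writePNG((v - min(v)) / max(1e-9, diff(range(v))),
                    paste0(stem, "_ct.png"))
      entry$slices[[k]] <- list(ct = paste0(stem, "_ct.nii.gz"),
                                roi = paste0(stem, "_roi.nii.gz"))
    }
    manifest$subjects[[length(manifest$subjects) + 1]] <- entry
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
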