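#' Specification of a synthetic head-CT phantom
#'
#' Describes the geometry and statistics of a 2D axial head phantom: an
#' elliptical skull ring around a brain compartment with a cortical
#' gray-matter band and a white-matter interior, overlaid with spatially
#' correlated Gaussian noise.  The phantom is bilaterally symmetric about a
#' vertical midline up to a small per-subject left/right attenuation jitter,
#' which is what keeps "normal" hemispheres from being trivially
#' mirror-identical.
#'
#' Default tissue attenuations are typical head-CT values (HU): air
#' background -1000, white matter 25, gray matter 38, skull 700.  The
#' default noise SD (6 HU) is deliberately of the same magnitude as the
#' default lesion attenuation drop, so injected lesions are near-invisible
#' to the eye.
#'
#' @param image_shape integer (rows, cols); default 512 x 512, the standard
#'   CT reconstruction matrix.
#' @param pixel_spacing mm per pixel (isotropic).
#' @param tissue_means named numeric: `background`, `skull`, `white`, `gray`
#'   attenuations in HU; must satisfy background < white < gray < skull.
#' @param noise_sd SD of the additive noise field, HU.
#' @param noise_corr_len Gaussian smoothing scale of the noise field, pixels.
#' @param asymmetry_jitter SD of the random left/right hemispheric mean
#'   offset, HU.
#' @param seed default seed used when an operation is not given one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(512L, 512L),
                         pixel_spacing = 0.45,
                         tissue_means = c(background = -1000, skull = 700,
                                          white = 25, gray = 38),
                         noise_sd = 6,
                         noise_corr_len = 2,
                         asymmetry_jitter = 2,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape <= 0))
    stop("image_shape must be two positive integers")
  stopifnot(noise_sd >= 0, noise_corr_len >= 0, asymmetry_jitter >= 0,
            pixel_spacing > 0)
  tm <- tissue_means
  if (!all(c("background", "skull", "white", "gray") %in% names(tm)))
    stop("tissue_means needs background, skull, white, gray")
  if (!(tm["background"] < tm["white"] && tm["white"] < tm["gray"] &&
        tm["gray"] < tm["skull"]))
    stop("tissue means must be ordered background < white < gray < skull")
  structure(list(image_shape = image_shape, pixel_spacing = pixel_spacing,
                 tissue_means = tm, noise_sd = noise_sd,
                 noise_corr_len = noise_corr_len,
                 asymmetry_jitter = asymmetry_jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of an injectable ischemic-like lesion
#'
#' A blob-shaped unilateral lesion whose two effects mimic early infarction
#' on CT: a small mean attenuation decrease (`delta_hu`, negative) and a
#' local loss of texture modelled as extra Gaussian smoothing
#' (`smooth_sigma`).  Both effects are feathered at the lesion edge so no
#' step edge is created.
#'
#' @param center lesion centre as (row, col), 1-based; `NULL` means the
#'   caller will sample one inside a hemisphere.
#' @param mean_radius mean blob radius, pixels.
#' @param boundary_irregularity dimensionless raggedness of the blob
#'   boundary (0 gives an exact disk).
#' @param delta_hu mean attenuation change inside the lesion, HU (<= 0).
#' @param smooth_sigma extra smoothing inside the lesion, pixels.
#' @param seed seed for blob-shape randomness.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center = NULL, mean_radius = 15,
                        boundary_irregularity = 0.3,
                        delta_hu = -6, smooth_sigma = 1.5, seed = 1L) {
  stopifnot(mean_radius > 0, boundary_irregularity >= 0, delta_hu <= 0,
            smooth_sigma >= 0)
  structure(list(center = center, mean_radius = mean_radius,
                 boundary_irregularity = boundary_irregularity,
                 delta_hu = delta_hu, smooth_sigma = smooth_sigma,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

gaussian_smooth <- function(values, sigma) {
  if (sigma <= 0) return(values)
  as.matrix(EBImage::gblur(values, sigma = sigma))
}

# Spatially correlated Gaussian noise with unit-normalized sample SD.
correlated_noise <- function(shape, sd, corr_len) {
  z <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  if (corr_len > 0) z <- gaussian_smooth(z, corr_len)
  z / stats::sd(z) * sd
}

#' Generate one synthetic head slice
#'
#' Builds the noise-free symmetric phantom described by `spec`, applies the
#' hemispheric jitter (as a smooth left/right ramp so no artificial midline
#' edge appears), and adds the correlated noise field.  Deterministic for a
#' fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A list with elements `slice` ([image_slice()]) and `brain`
#'   (logical brain mask, skull excluded).
#' @export
generate_head_slice <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  tm <- spec$tissue_means
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  ax <- 0.33 * nc; ay <- 0.42 * nr            # head semi-axes, x across
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - cx
  y <- matrix(rep(0:(nr - 1), times = nc), nr, nc) - cy
  r <- sqrt((x / ax)^2 + (y / ay)^2)          # normalized elliptical radius
  base <- matrix(tm["background"], nr, nc)
  base[r <= 1] <- tm["skull"]
  base[r <= 0.92] <- tm["gray"]               # CSF-thin rim folded into gray
  base[r <= 0.88] <- tm["gray"]
  base[r <= 0.70] <- tm["white"]
  # deep gray nuclei: two mirror-symmetric ellipses in the white matter
  dg <- ((abs(x) - 0.28 * ax) / (0.14 * ax))^2 + (y / (0.30 * ay))^2 <= 1
  base[dg & r <= 0.70] <- tm["gray"]
  # lateral ventricles: paired CSF slivers tilted toward the midline; their
  # orientation anchors the rotational part of midline estimation, exactly
  # as on real axial slices
  csf <- tm["white"] - 15
  for (s in c(-1, 1)) {
    u <- x - s * 0.10 * ax
    w <- y + 0.05 * ay
    phi <- s * 20 * pi / 180
    u2 <- u * cos(phi) + w * sin(phi)
    w2 <- -u * sin(phi) + w * cos(phi)
    vent <- (u2 / (0.05 * ax))^2 + (w2 / (0.25 * ay))^2 <= 1
    base[vent & r <= 0.70] <- csf
  }
  brain <- r <= 0.88
  with_seed(seed, {
    if (spec$asymmetry_jitter > 0) {
      jit <- rnorm(1, 0, spec$asymmetry_jitter)
      base <- base + brain * (jit / 2) * tanh(x / 6)
    }
    if (spec$noise_sd > 0)
      base <- base + correlated_noise(c(nr, nc), spec$noise_sd,
                                      spec$noise_corr_len)
  })
  list(slice = image_slice(base, rep(spec$pixel_spacing, 2)), brain = brain)
}

#' Sample a blob-shaped lesion ROI inside one hemisphere
#'
#' Draws a connected blob whose boundary radius is the mean radius modulated
#' by random low-order angular harmonics.  With zero irregularity the blob
#' degenerates to the rasterized disk of radius `mean_radius`.  Errors if
#' the blob would cross the midline column or leave the brain.
#'
#' @param brain_mask logical brain mask.
#' @param spec a [lesion_spec()] with non-`NULL` `center`.
#' @param midline_col x (0-based column) of the symmetry axis; defaults to
#'   the image centre column.
#' @param seed seed for the harmonic amplitudes; defaults to `spec$seed`.
#' @return logical lesion mask.
#' @export
sample_lesion_roi <- function(brain_mask, spec, midline_col = NULL,
                              seed = spec$seed) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (is.null(spec$center)) stop("lesion_spec$center must be set")
  nr <- nrow(brain_mask); nc <- ncol(brain_mask)
  if (is.null(midline_col)) midline_col <- (nc - 1) / 2
  cr <- spec$center[1]; cc <- spec$center[2]
  x <- matrix(rep(1:nc, each = nr), nr, nc) - cc
  y <- matrix(rep(1:nr, times = nc), nr, nc) - cr
  d <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  pert <- 0
  if (spec$boundary_irregularity > 0) {
    amp <- with_seed(seed, rnorm(3))
    psi <- with_seed(derive_seed(seed, 7), runif(3, 0, 2 * pi))
    h <- sweep(outer(c(phi), 2:4), 2, psi, "+")
    pert <- matrix(cos(h) %*% (amp / sqrt(sum(amp^2))), nr, nc) *
      spec$boundary_irregularity
  }
  mask <- d <= spec$mean_radius * (1 + pert)
  if (!any(mask)) stop("degenerate lesion: empty blob")
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1
  if (min(xs) < midline_col && max(xs) > midline_col)
    stop("lesion blob crosses the midline")
  if (any(!brain_mask[mask])) stop("lesion blob exits the brain")
  mask
}

#' Inject a lesion into a slice
#'
#' Inside the ROI the image is blended with a smoothed copy of itself
#' (texture loss) and shifted down in attenuation; the blend weight is a
#' feathered version of the mask so the lesion has no step edge, and the
#' attenuation shift is normalized so the ROI mean moves by exactly
#' `delta_hu`.  Pixels outside the ROI are untouched.
#'
#' @param slice an [image_slice()] (or matrix).
#' @param roi logical lesion mask aligned to `slice`.
#' @param spec a [lesion_spec()].
#' @return An [image_slice()] with the lesion applied.
#' @export
inject_lesion <- function(slice, roi, spec) {
  slice <- as_slice(slice)
  roi <- roi_mask(roi)
  if (!all(dim(roi) == dim(slice$values)))
    stop("ROI shape does not match slice")
  v <- slice$values
  w <- gaussian_smooth(roi * 1, 1.0)
  w <- w * roi                                 # feather strictly inside ROI
  w <- w / max(w)
  out <- v
  if (spec$smooth_sigma > 0) {
    sm <- gaussian_smooth(v, spec$smooth_sigma)
    out <- v + w * (sm - v)
  }
  if (spec$delta_hu != 0 || spec$smooth_sigma > 0) {
    drift <- mean(out[roi]) - mean(v[roi])
    out <- out + (spec$delta_hu - drift) * w / mean(w[roi])
  }
  image_slice(out, slice$spacing)
}
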