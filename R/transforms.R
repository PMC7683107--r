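#' Image transforms of the radiomic feature bank
#'
#' Each transform produces a derived image on which every texture class is
#' recomputed, multiplying the feature bank.  Pointwise transforms
#' (square, squareroot, logarithm, exponential) are taken after shifting
#' ROI intensities to be >= 1 (CT attenuations are negative) and scaling to
#' (0, 1], so the logarithm is defined and the exponential cannot overflow;
#' wavelet transforms are the four subbands of a single-level 2D Haar DWT
#' upsampled back to the input shape; gradient is the central-difference
#' magnitude.
#'
#' With `rescale = TRUE` (the default used during extraction) the
#' transformed ROI values are mapped linearly back onto the original ROI
#' intensity range, so one fixed-bin-width discretization remains
#' meaningful across all transforms.
#'
#' @param slice [image_slice()] or matrix.
#' @param mask logical ROI mask (nonempty), same shape.
#' @param kind one of `original`, `wavelet_LL`, `wavelet_LH`, `wavelet_HL`,
#'   `wavelet_HH`, `square`, `squareroot`, `logarithm`, `exponential`,
#'   `gradient`.
#' @param rescale map transformed ROI values back to the input ROI range.
#' @return An [image_slice()] of the same shape.
#' @export
apply_transform <- function(slice, mask, kind = "original", rescale = TRUE) {
  slice <- as_slice(slice)
  mask <- roi_mask(mask)
  v <- slice$values
  kinds <- c("original", "wavelet_LL", "wavelet_LH", "wavelet_HL",
             "wavelet_HH", "square", "squareroot", "logarithm",
             "exponential", "gradient")
  if (!kind %in% kinds) stop("unknown transform kind: ", kind)
  if (kind == "original") return(slice)
  if (startsWith(kind, "wavelet")) {
    out <- haar_subband(v, sub = sub("wavelet_", "", kind))
  } else if (kind == "gradient") {
    nr <- nrow(v); nc <- ncol(v)
    gy <- (v[c(2:nr, nr), ] - v[c(1, 1:(nr - 1)), ]) / (2 * slice$spacing[1])
    gx <- (v[, c(2:nc, nc)] - v[, c(1, 1:(nc - 1))]) / (2 * slice$spacing[2])
    out <- sqrt(gx^2 + gy^2)
  } else {
    s <- v - min(v[mask]) + 1            # >= 1 inside the ROI
    s <- s / max(s[mask])                # (0, 1] inside the ROI
    out <- switch(kind,
                  square      = s^2,
                  squareroot  = sqrt(pmax(s, 0)),
                  logarithm   = log(pmax(s, .Machine$double.eps)),
                  exponential = exp(s))
  }
  if (rescale) {
    rin <- range(v[mask]); rout <- range(out[mask])
    out <- if (diff(rout) == 0) matrix(rin[1], nrow(v), ncol(v))
           else (out - rout[1]) / diff(rout) * diff(rin) + rin[1]
  }
  image_slice(out, slice$spacing)
}

# Single-level 2D Haar DWT subband, upsampled back to the input shape by
# 2x2 pixel replication (odd trailing row/col handled by edge padding).
haar_subband <- function(v, sub = c("LL", "LH", "HL", "HH")) {
  sub <- match.arg(sub)
  nr <- nrow(v); nc <- ncol(v)
  vp <- v
  if (nr %% 2 == 1) vp <- rbind(vp, vp[nr, , drop = FALSE])
  if (nc %% 2 == 1) vp <- cbind(vp, vp[, ncol(vp), drop = FALSE])
  a <- vp[seq(1, nrow(vp), 2), seq(1, ncol(vp), 2), drop = FALSE]
  b <- vp[seq(1, nrow(vp), 2), seq(2, ncol(vp), 2), drop = FALSE]
  c_ <- vp[seq(2, nrow(vp), 2), seq(1, ncol(vp), 2), drop = FALSE]
  d <- vp[seq(2, nrow(vp), 2), seq(2, ncol(vp), 2), drop = FALSE]
  # orthonormal Haar: L = (p+q)/sqrt(2), H = (p-q)/sqrt(2), applied to
  # columns then rows; first letter = row filter, second = column filter
  band <- switch(sub,
                 LL = (a + b + c_ + d) / 2,
                 LH = (a - b + c_ - d) / 2,
                 HL = (a + b - c_ - d) / 2,
                 HH = (a - b - c_ + d) / 2)
  up <- band[rep(seq_len(nrow(band)), each = 2),
             rep(seq_len(ncol(band)), each = 2), drop = FALSE]
  up[1:nr, 1:nc, drop = FALSE]
}

#' Discretize ROI intensities to gray levels 1..Ng
#'
#' Gray-level matrices require integer levels; this maps ROI intensities to
#' levels either by fixed bin width (`level = floor((v - min) / width) + 1`,
#' robust to ROI-size differences, the package default at 5 HU) or by a
#' fixed number of equal-width bins spanning the ROI range.
#'
#' @param slice [image_slice()] or matrix.
#' @param mask logical ROI mask.
#' @param mode `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param bin_width bin width in intensity units (mode `fixed_bin_width`).
#' @param bin_count number of bins (mode `fixed_bin_count`).
#' @param max_levels safety cap on Ng.
#' @return A list: `levels` (integer matrix, NA outside the mask) and `ng`.
#'   A constant ROI yields `ng = 1`.
#' @export
discretize <- function(slice, mask, mode = c("fixed_bin_width",
                                             "fixed_bin_count"),
                       bin_width = 5, bin_count = 32, max_levels = 64) {
  mode <- match.arg(mode)
  slice <- as_slice(slice)
  mask <- roi_mask(mask)
  v <- slice$values
  vals <- v[mask]
  lev <- matrix(NA_integer_, nrow(v), ncol(v))
  if (diff(range(vals)) == 0) {
    lev[mask] <- 1L
    return(list(levels = lev, ng = 1L))
  }
  if (mode == "fixed_bin_width") {
    stopifnot(bin_width > 0)
    l <- floor((vals - min(vals)) / bin_width) + 1
    if (max(l) > max_levels)  # degrade gracefully on huge ranges
      l <- floor((l - 1) * (max_levels / max(l))) + 1
  } else {
    stopifnot(bin_count >= 1)
    edges <- seq(min(vals), max(vals), length.out = bin_count + 1)
    l <- pmin(bin_count, findInterval(vals, edges, rightmost.closed = TRUE))
  }
  lev[mask] <- as.integer(l)
  list(levels = lev, ng = as.integer(max(l)))
}
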