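#' CT-like image slices and ROI masks
#'
#' An `image_slice` is the unit of all image math in this package: a numeric
#' matrix of attenuation values in Hounsfield units (HU) plus an in-plane
#' pixel spacing in millimetres.  An ROI mask is an ordinary logical matrix of
#' the same shape; helper [roi_mask()] validates one.
#'
#' Pixel coordinates are row-major and 0-based in the geometry helpers:
#' `x` runs along columns, `y` along rows, and all affine transforms are
#' taken about the image centre `((ncol-1)/2, (nrow-1)/2)`.
#'
#' @param values numeric matrix of attenuation values (HU); must be finite.
#' @param spacing numeric length-2, mm per pixel along (row, col).
#' @return An object of class `image_slice`.
#' @export
image_slice <- function(values, spacing = c(0.45, 0.45)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("slice values must be finite numerics")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  stopifnot(length(spacing) == 2, all(spacing > 0))
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice> %d x %d px, %.3g x %.3g mm/px, HU range [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname image_slice
#' @param mask logical (or 0/1) matrix.
#' @param require_nonempty error when the mask has no foreground pixel.
#' @export
roi_mask <- function(mask, require_nonempty = TRUE) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (require_nonempty && !any(mask)) stop("ROI mask is empty")
  mask
}

as_slice <- function(x) {
  if (inherits(x, "image_slice")) x else image_slice(x)
}

#' Affine transform parameters
#'
#' Parameters of a 2D affine map applied about the image centre in the fixed
#' composition order scale, then rotate, then translate:
#' `p' = R(theta) %*% diag(sx, sy) %*% p + (tx, ty)` for a point
#' `p = (x, y)` relative to the centre (x along columns, y along rows).
#'
#' @param tx,ty translation in pixels (x = columns, y = rows).
#' @param theta rotation in degrees, counter-clockwise in (x, y).
#' @param sx,sy strictly positive scale factors.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(tx = 0, ty = 0, theta = 0, sx = 1, sy = 1) {
  stopifnot(sx > 0, sy > 0)
  structure(list(tx = tx, ty = ty, theta = theta, sx = sx, sy = sy),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("<affine> t = (%.3f, %.3f) px, theta = %.3f deg, s = (%.4f, %.4f)\n",
              x$tx, x$ty, x$theta, x$sx, x$sy))
  invisible(x)
}

# 2x3 forward matrix [A | b] mapping centre-relative (x, y).
affine_matrix <- function(p) {
  th <- p$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% diag(c(p$sx, p$sy))
  cbind(A, c(p$tx, p$ty))
}

#' @rdname affine_params
#' @param p an `affine_params` object.
#' @export
affine_invert <- function(p) {
  M <- affine_matrix(p)
  A <- M[, 1:2]; b <- M[, 3]
  Ai <- solve(A)
  bi <- -Ai %*% b
  th <- atan2(Ai[2, 1] / sqrt(sum(Ai[, 1]^2)), Ai[1, 1] / sqrt(sum(Ai[, 1]^2)))
  # exact for rigid and isotropic-scale members; with sx != sy the inverse of
  # a scale-rotate-translate map lies outside the family and this is the
  # closest member (sufficient for the round-trip guarantees, which are
  # stated for rigid transforms)
  affine_params(tx = bi[1], ty = bi[2], theta = th * 180 / pi,
                sx = 1 / p$sx, sy = 1 / p$sy)
}

centre_xy <- function(dim2) c((dim2[2] - 1) / 2, (dim2[1] - 1) / 2)

# Inverse-mapping affine warp.  For every output pixel the inverse transform
# locates its source in `values`; `interp` is "bilinear" for images and
# "nearest" for masks.  Out-of-field pixels take `fill`.
warp_affine <- function(values, params, target_shape = dim(values),
                        interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  M <- affine_matrix(params)
  Ai <- solve(M[, 1:2])
  b <- M[, 3]
  nr <- target_shape[1]; nc <- target_shape[2]
  c_out <- centre_xy(target_shape); c_in <- centre_xy(dim(values))
  xo <- rep(0:(nc - 1), each = nr) - c_out[1]
  yo <- rep(0:(nr - 1), times = nc) - c_out[2]
  xs <- Ai[1, 1] * (xo - b[1]) + Ai[1, 2] * (yo - b[2]) + c_in[1]
  ys <- Ai[2, 1] * (xo - b[1]) + Ai[2, 2] * (yo - b[2]) + c_in[2]
  out <- rep(as.numeric(fill), nr * nc)
  if (interp == "nearest") {
    ri <- round(ys) + 1; ci <- round(xs) + 1
    ok <- ri >= 1 & ri <= nrow(values) & ci >= 1 & ci <= ncol(values)
    out[ok] <- values[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(ys); c0 <- floor(xs)
    fr <- ys - r0; fc <- xs - c0
    ok <- r0 >= 0 & r0 <= nrow(values) - 2 & c0 >= 0 & c0 <= ncol(values) - 2
    r0 <- r0[ok] + 1; c0 <- c0[ok] + 1; fr <- fr[ok]; fc <- fc[ok]
    v00 <- values[cbind(r0, c0)];     v01 <- values[cbind(r0, c0 + 1)]
    v10 <- values[cbind(r0 + 1, c0)]; v11 <- values[cbind(r0 + 1, c0 + 1)]
    out[ok] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
      fr * ((1 - fc) * v10 + fc * v11)
  }
  matrix(out, nr, nc)
}

#' Resample an ROI mask under an affine transform
#'
#' Applies `params` to a binary mask by nearest-neighbour inverse mapping, so
#' the output stays binary.  Errors when the transformed mask leaves the
#' field of view entirely.
#'
#' @param mask logical matrix (nonempty).
#' @param params an [affine_params()] object.
#' @param target_shape output (rows, cols); defaults to the input shape.
#' @return logical matrix of shape `target_shape`.
#' @export
transform_mask <- function(mask, params, target_shape = dim(mask)) {
  mask <- roi_mask(mask)
  out <- warp_affine(mask * 1, params, target_shape, interp = "nearest",
                     fill = 0) > 0.5
  if (!any(out)) stop("transformed mask is empty: ROI left the field of view")
  out
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}
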