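#' Normalized mutual information between two slices
#'
#' NMI = (H(A) + H(B)) / H(A, B) on a joint intensity histogram, the
#' standard similarity metric for cross-modality alignment.  Pixels where
#' either image is undefined (NA, e.g. outside a warped field of view) are
#' ignored.  Degenerate inputs (constant overlap) score 0.
#'
#' @param a,b numeric matrices of equal shape.
#' @param bins number of intensity bins per image.
#' @return NMI value (>= 0; 2 for identical non-constant images).
#' @export
nmi <- function(a, b, bins = 32) {
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(0)
  av <- a[ok]; bv <- b[ok]
  cut_idx <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(1L, length(v)))
    pmin(bins, pmax(1L, as.integer(floor((v - r[1]) / diff(r) * bins)) + 1L))
  }
  ai <- cut_idx(av); bi <- cut_idx(bv)
  joint <- tabulate(ai + bins * (bi - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  hfun <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  pj <- matrix(p, bins, bins)
  hab <- hfun(p)
  if (hab == 0) return(0)
  (hfun(rowSums(pj)) + hfun(colSums(pj))) / hab
}

#' Coarse rotational registration
#'
#' Emulates the reconstruct-to-a-consistent-angle step of cross-modality
#' alignment, reduced to an in-plane rotation search: the moving slice is
#' rotated over an angle grid and the angle maximizing NMI against the
#' fixed slice is returned.  Ties break toward the smallest |angle|.
#'
#' @param fixed,moving [image_slice()] objects or matrices.
#' @param angle_grid candidate rotations, degrees.
#' @param bins histogram bins for [nmi()].
#' @return Best angle in degrees.
#' @export
coarse_register <- function(fixed, moving, angle_grid = seq(-15, 15, by = 1),
                            bins = 32) {
  if (length(angle_grid) == 0) stop("empty angle grid")
  f <- as_slice(fixed)$values; m <- as_slice(moving)$values
  if (length(f) == 0 || length(m) == 0) stop("empty slice")
  angle_grid <- angle_grid[order(abs(angle_grid))]
  sc <- vapply(angle_grid, function(a) {
    w <- warp_affine(m, affine_params(theta = a), target_shape = dim(f),
                     fill = NA)
    nmi(f, w, bins)
  }, 0)
  angle_grid[which.max(sc)]
}

#' Fine affine registration
#'
#' Local derivative-free optimization of NMI over translation, rotation and
#' anisotropic scale, starting from `init`.  The returned parameters are
#' those of the best metric seen, so the metric never decreases relative to
#' the initialization; failure to converge within the iteration cap returns
#' the best-so-far with `converged = FALSE` and a warning.
#'
#' @param fixed,moving slices.
#' @param init an [affine_params()] starting point.
#' @param max_iter Nelder-Mead iteration cap.
#' @param bins histogram bins for [nmi()].
#' @return An [affine_params()] with attributes `metric` and `converged`.
#' @export
fine_register <- function(fixed, moving, init = affine_params(),
                          max_iter = 500, bins = 32) {
  f <- as_slice(fixed)$values; m <- as_slice(moving)$values
  objective <- function(p) {
    if (p[4] <= 0.2 || p[5] <= 0.2) return(1e6)
    w <- warp_affine(m, affine_params(p[1], p[2], p[3], p[4], p[5]),
                     target_shape = dim(f), fill = NA)
    -nmi(f, w, bins)
  }
  p0 <- c(init$tx, init$ty, init$theta, init$sx, init$sy)
  f0 <- objective(p0)
  fit <- optim(p0, objective, method = "Nelder-Mead",
               control = list(maxit = max_iter, reltol = 1e-10,
                              parscale = c(1, 1, 1, 0.02, 0.02)))
  # one restart from the incumbent guards against premature simplex collapse
  fit2 <- optim(fit$par, objective, method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = 1e-10,
                               parscale = c(0.5, 0.5, 0.5, 0.01, 0.01)))
  best <- if (fit2$value < fit$value) fit2 else fit
  converged <- best$convergence == 0
  if (!converged) warning("fine_register: iteration cap reached, returning best-so-far")
  par <- if (best$value <= f0) best$par else p0
  out <- affine_params(par[1], par[2], par[3], par[4], par[5])
  attr(out, "metric") <- -min(best$value, f0)
  attr(out, "converged") <- converged
  out
}

#' One-call two-stage registration
#'
#' Convenience wrapper reproducing the coarse-then-fine pipeline: grid
#' rotation search, translation initialization from foreground centroids,
#' then [fine_register()].
#'
#' @inheritParams fine_register
#' @param angle_grid grid for the coarse stage.
#' @return An [affine_params()], as from [fine_register()].
#' @export
register_slices <- function(fixed, moving, angle_grid = seq(-15, 15, by = 1),
                            bins = 32) {
  f <- as_slice(fixed)$values; m <- as_slice(moving)$values
  th0 <- coarse_register(f, m, angle_grid, bins)
  fg <- function(v) {
    thr <- quantile(v, 0.75)
    mask_centroid(v > thr)
  }
  cf <- fg(f); cm <- fg(m)
  init <- affine_params(tx = cf["x"] - cm["x"], ty = cf["y"] - cm["y"],
                        theta = th0)
  fine_register(f, m, init, bins = bins)
}

#' Serialize affine parameters to JSON
#' @param params an [affine_params()].
#' @param path output file.
#' @export
write_affine <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
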