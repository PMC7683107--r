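# Offsets for the standard 2D angle set; distance d scales the unit step.
angle_offsets <- function(angles, distance = 1) {
  lapply(angles, function(a) {
    switch(as.character(a),
           "0"   = c(dr = 0, dc = 1),
           "45"  = c(dr = -1, dc = 1),
           "90"  = c(dr = -1, dc = 0),
           "135" = c(dr = -1, dc = -1),
           stop("unsupported angle: ", a)) * distance
  })
}

# Symmetrized, normalized co-occurrence matrix for one offset.
glcm_matrix <- function(levels, ng, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  r0 <- max(1, 1 - dr):min(nr, nr - dr)
  c0 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  counts <- tabulate(a[ok] + ng * (b[ok] - 1L), nbins = ng * ng)
  P <- matrix(counts, ng, ng)
  P <- P + t(P)
  P / sum(P)
}

glcm_feature_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "IMC1", "IMC2", "IDM", "IDMN", "ID", "IDN", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(rep(1:ng, times = ng), ng, ng)   # row level
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sdx <- sqrt(sum(((1:ng) - mux)^2 * px)); sdy <- sqrt(sum(((1:ng) - muy)^2 * py))
  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), 0)
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(P)
  eps <- .Machine$double.eps
  hxy1 <- -sum(P * log2(outer(px, py) + eps))
  hxy2 <- { o <- outer(px, py); o <- o[o > 0]; -sum(o * log2(o)) }
  hx <- ent(px); hy <- ent(py)
  da <- sum((0:(ng - 1)) * pxy_dif)
  corr <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 1
  mcc <- if (ng == 1) 1 else {
    Q <- matrix(0, ng, ng)
    nz <- px > 0
    Pn <- P
    for (k in 1:ng) {
      if (py[k] <= 0) next
      Q <- Q + (Pn[, k] %o% Pn[, k]) / py[k]
    }
    Q[nz, ] <- Q[nz, ] / px[nz]
    Q[!nz, ] <- 0
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, if (length(ev) >= 2) ev[2] else 1)))
  }
  setNames(c(
    sum(i * j * P),
    mux,
    sum((i + j - mux - muy)^4 * P),
    sum((i + j - mux - muy)^3 * P),
    sum((i + j - mux - muy)^2 * P),
    sum((i - j)^2 * P),
    corr,
    da,
    ent(pxy_dif),
    sum(((0:(ng - 1)) - da)^2 * pxy_dif),
    sum(P^2),
    hxy,
    if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    sum(P / (1 + (i - j)^2)),
    sum(P / (1 + ((i - j) / ng)^2)),
    sum(P / (1 + abs(i - j))),
    sum(P / (1 + abs(i - j) / ng)),
    sum(P[i != j] / (i[i != j] - j[i != j])^2),
    max(P),
    sum((2:(2 * ng)) * pxy_sum),
    ent(pxy_sum),
    sum((i - mux)^2 * P),
    mcc), glcm_feature_names)
}

#' Gray-level co-occurrence matrix features
#'
#' Co-occurrence counts are accumulated per angle at the given distance,
#' symmetrized and normalized to sum 1; the 24 standard GLCM features are
#' computed per angle and averaged over angles.  On a single-level ROI,
#' `Contrast` is 0 and `Correlation` is defined as 1 by convention.
#'
#' @param levels integer level matrix (NA outside the ROI), as produced by
#'   [discretize()].
#' @param ng number of gray levels.
#' @param distance pixel offset distance.
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, ng, distance = 1,
                          angles = c(0, 45, 90, 135)) {
  offs <- angle_offsets(angles, distance)
  per <- vapply(offs, function(o) {
    glcm_features_one(glcm_matrix(levels, ng, o["dr"], o["dc"]))
  }, numeric(length(glcm_feature_names)))
  rowMeans(per)
}
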