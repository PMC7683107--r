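# 8-connected components of equal-level in-mask pixels (zone labeling).
# Returns a data.frame with one row per zone: level, size.
label_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  idx <- which(!is.na(levels))
  if (length(idx) == 0) return(data.frame(level = integer(), size = integer()))
  vid <- match(seq_len(nr * nc), idx)     # pixel -> vertex id (NA outside)
  edges <- list()
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r0 <- max(1, 1 - dr):min(nr, nr - dr)
    c0 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- levels[r0, c0, drop = FALSE]
    b <- levels[r0 + dr, c0 + dc, drop = FALSE]
    same <- !is.na(a) & !is.na(b) & a == b
    if (!any(same)) next
    ia <- outer(r0, (c0 - 1) * nr, "+")[same]
    ib <- outer(r0 + dr, (c0 + dc - 1) * nr, "+")[same]
    edges[[length(edges) + 1]] <- cbind(vid[ia], vid[ib])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  data.frame(level = levels[idx][match(seq_len(comp$no), comp$membership)],
             size = as.integer(comp$csize))
}

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of equal gray level inside the mask;
#' the zone-count matrix P(level, size) feeds the 16 standard GLSZM
#' features.  Size zones are orientation-free, so there is no angle
#' averaging.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, ng) {
  z <- label_zones(levels)
  np <- sum(!is.na(levels))
  ns <- max(z$size, 1L)
  P <- matrix(0, ng, ns)
  if (nrow(z) > 0) {
    counts <- tabulate(z$level + ng * (z$size - 1L), nbins = ng * ns)
    P <- matrix(counts, ng, ns)
  }
  size_distribution_features(P, np, glszm_feature_names)
}

gldm_feature_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

# All 8 neighbour offsets.
neigh8 <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
               c(1, -1), c(1, 0), c(1, 1))

shift_levels <- function(levels, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  out <- matrix(NA_integer_, nr, nc)
  r0 <- max(1, 1 + dr):min(nr, nr + dr)
  c0 <- max(1, 1 + dc):min(nc, nc + dc)
  out[r0, c0] <- levels[r0 - dr, c0 - dc]
  out
}

#' Gray-level dependence matrix features
#'
#' The dependence size of a pixel is one plus the number of its in-mask
#' 8-neighbours whose gray level differs by at most `alpha` (default 0,
#' i.e. equal level).  The matrix P(level, dependence size) feeds the 14
#' standard GLDM features.
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on the level difference.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, ng, alpha = 0) {
  dep <- matrix(0L, nrow(levels), ncol(levels))
  for (o in neigh8) {
    nb <- shift_levels(levels, o[1], o[2])
    dep <- dep + (!is.na(nb) & !is.na(levels) & abs(nb - levels) <= alpha)
  }
  inmask <- !is.na(levels)
  k <- dep[inmask] + 1L
  i <- levels[inmask]
  nd <- max(k)
  P <- matrix(tabulate(i + ng * (k - 1L), nbins = ng * nd), ng, nd)
  nz <- sum(P)
  ii <- matrix(rep(1:ng, times = nd), ng, nd)
  kk <- matrix(rep(1:nd, each = ng), ng, nd)
  p <- P / nz
  gi <- rowSums(P); dj <- colSums(P)
  mu_i <- sum(ii * p); mu_k <- sum(kk * p)
  pe <- p[p > 0]
  setNames(c(
    sum(P / kk^2) / nz,
    sum(P * kk^2) / nz,
    sum(gi^2) / nz,
    sum(dj^2) / nz,
    sum(dj^2) / nz^2,
    sum((ii - mu_i)^2 * p),
    sum((kk - mu_k)^2 * p),
    -sum(pe * log2(pe)),
    sum(P / ii^2) / nz,
    sum(P * ii^2) / nz,
    sum(P / (ii^2 * kk^2)) / nz,
    sum(P * ii^2 / kk^2) / nz,
    sum(P * kk^2 / ii^2) / nz,
    sum(P * ii^2 * kk^2) / nz), gldm_feature_names)
}

ngtdm_feature_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                         "Strength")

#' Neighbourhood gray-tone difference matrix features
#'
#' For every in-mask pixel with at least one in-mask 8-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per gray level; the 5 standard NGTDM features
#' follow.  `Coarseness` is capped at 1e6 when its denominator vanishes.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels, ng) {
  nbsum <- matrix(0, nrow(levels), ncol(levels))
  nbcnt <- matrix(0L, nrow(levels), ncol(levels))
  for (o in neigh8) {
    nb <- shift_levels(levels, o[1], o[2])
    has <- !is.na(nb)
    nbsum <- nbsum + ifelse(has, nb, 0)
    nbcnt <- nbcnt + has
  }
  valid <- !is.na(levels) & nbcnt > 0
  abar <- nbsum[valid] / nbcnt[valid]
  lv <- levels[valid]
  nvp <- sum(valid)
  n_i <- tabulate(lv, nbins = ng)
  s_i <- vapply(1:ng, function(g) sum(abs(g - abar[lv == g])), 0)
  p_i <- n_i / nvp
  act <- which(n_i > 0)
  ngp <- length(act)
  coarse <- { d <- sum(p_i * s_i); if (d > 0) min(1 / d, 1e6) else 1e6 }
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) *
           outer(act, act, function(a, b) (a - b)^2)) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  cplx <- if (nvp > 0 && ngp > 1) {
    tot <- 0
    for (a in act) for (b in act) {
      tot <- tot + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    }
    tot / nvp
  } else 0
  strength <- if (sum(s_i) > 0 && ngp > 1) {
    tot <- 0
    for (a in act) for (b in act)
      tot <- tot + (p_i[a] + p_i[b]) * (a - b)^2
    tot / sum(s_i)
  } else 0
  setNames(c(coarse, contrast, busyness, cplx, strength),
           ngtdm_feature_names)
}
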