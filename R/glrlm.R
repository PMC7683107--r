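# Extract the pixel sequences of an image along one of the four standard
# directions; out-of-mask pixels (NA) break runs naturally.
direction_lines <- function(levels, angle) {
  nr <- nrow(levels); nc <- ncol(levels)
  switch(as.character(angle),
         "0"   = lapply(seq_len(nr), function(r) levels[r, ]),
         "90"  = lapply(seq_len(nc), function(c_) levels[, c_]),
         "45"  = { # anti-diagonals, stepping (-1, +1)
           split(levels[order(row(levels) + col(levels),
                              -row(levels))],
                 sort(c(row(levels) + col(levels))))
         },
         "135" = { # main diagonals, stepping (-1, -1): traverse reversed
           split(levels[order(col(levels) - row(levels),
                              -row(levels))],
                 sort(c(col(levels) - row(levels))))
         },
         stop("unsupported angle: ", angle))
}

# Run-length matrix P[level, run length] for one direction.
glrlm_matrix <- function(levels, ng, angle) {
  lines <- direction_lines(levels, angle)
  maxlen <- max(nrow(levels), ncol(levels))
  runs <- lapply(lines, function(ln) {
    r <- rle(as.vector(ln))
    keep <- !is.na(r$values)
    cbind(r$values[keep], r$lengths[keep])
  })
  runs <- do.call(rbind, runs)
  P <- matrix(0, ng, maxlen)
  if (!is.null(runs) && nrow(runs) > 0) {
    counts <- tabulate(runs[, 1] + ng * (pmin(runs[, 2], maxlen) - 1),
                       nbins = ng * maxlen)
    P <- matrix(counts, ng, maxlen)
  }
  P
}

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

size_distribution_features <- function(P, np, names, run_names = TRUE) {
  # shared formula set for run-length-style matrices: rows = gray level i,
  # cols = size/length s
  ng <- nrow(P); ns <- ncol(P)
  nr_tot <- sum(P)
  if (nr_tot == 0) return(setNames(rep(0, length(names)), names))
  i <- matrix(rep(1:ng, times = ns), ng, ns)
  s <- matrix(rep(1:ns, each = ng), ng, ns)
  p <- P / nr_tot
  gi <- rowSums(P); sj <- colSums(P)
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  pe <- p[p > 0]
  setNames(c(
    sum(P / s^2) / nr_tot,
    sum(P * s^2) / nr_tot,
    sum(gi^2) / nr_tot,
    sum(gi^2) / nr_tot^2,
    sum(sj^2) / nr_tot,
    sum(sj^2) / nr_tot^2,
    nr_tot / np,
    sum((i - mu_i)^2 * p),
    sum((s - mu_s)^2 * p),
    -sum(pe * log2(pe)),
    sum(P / i^2) / nr_tot,
    sum(P * i^2) / nr_tot,
    sum(P / (i^2 * s^2)) / nr_tot,
    sum(P * i^2 / s^2) / nr_tot,
    sum(P * s^2 / i^2) / nr_tot,
    sum(P * i^2 * s^2) / nr_tot), names)
}

#' Gray-level run-length matrix features
#'
#' Maximal runs of equal gray level are enumerated along each direction
#' (restricted to the mask, which breaks runs), tallied into a level-by-
#' length matrix, and the 16 standard GLRLM features are computed per angle
#' then averaged over angles.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, ng, angles = c(0, 45, 90, 135)) {
  np <- sum(!is.na(levels))
  per <- vapply(angles, function(a) {
    size_distribution_features(glrlm_matrix(levels, ng, a), np,
                               glrlm_feature_names)
  }, numeric(length(glrlm_feature_names)))
  rowMeans(per)
}
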