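#' Equal-frequency binning of a continuous feature
#'
#' Information gain needs discrete symbols; continuous feature values are
#' assigned to at most `k` equal-frequency bins (quantile cuts).  Ties at a
#' bin edge go to the lower bin; a constant feature collapses to a single
#' bin.
#'
#' @param values numeric vector.
#' @param k maximum number of bins (>= 2).
#' @return Integer vector of bin symbols.
#' @export
bin_feature <- function(values, k = 10) {
  stopifnot(k >= 2)
  if (length(unique(values)) <= 1) return(rep(1L, length(values)))
  cuts <- unique(quantile(values, probs = seq(0, 1, length.out = k + 1),
                          names = FALSE, type = 7))
  if (length(cuts) <= 2) {
    # quantiles collapsed (heavily tied data): split at the median value
    return(as.integer(values > cuts[1]) + 1L)
  }
  as.integer(cut(values, breaks = cuts, include.lowest = TRUE, right = TRUE))
}

#' Shannon entropy of a label vector (bits)
#'
#' `H = -sum p log2 p` over the empirical distribution, with `0 log 0 = 0`.
#'
#' @param labels vector of discrete labels (any type).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  stopifnot(length(labels) > 0)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discrete feature about the class label
#'
#' `IG(X, Y) = H(Y) - H(Y | X)` with `H(Y | X) = sum_x p(x) H(Y | X = x)`:
#' the reduction in uncertainty about class membership once the binned
#' feature value is known.  Bounded in `[0, H(Y)]`; tiny negatives from
#' floating-point rounding are clipped to 0.
#'
#' @param binned_feature discrete feature symbols (see [bin_feature()]).
#' @param labels class labels, same length.
#' @return Information gain in bits.
#' @export
information_gain <- function(binned_feature, labels) {
  stopifnot(length(binned_feature) == length(labels))
  n <- length(labels)
  hy <- entropy_bits(labels)
  cond <- 0
  for (x in unique(binned_feature)) {
    sel <- binned_feature == x
    cond <- cond + sum(sel) / n * entropy_bits(labels[sel])
  }
  max(0, hy - cond)
}

#' Screen a feature table by information gain
#'
#' Computes IG for every feature (after equal-frequency binning) and counts
#' how many features exceed each threshold strictly.
#'
#' @param table a `labeled_feature_table` (or plain data.frame/matrix with
#'   `y` passed separately).
#' @param thresholds numeric thresholds (bits).
#' @param k_bins bins for [bin_feature()].
#' @param y binary labels; defaults to `attr(table, "y")`.
#' @return An `ig_screen` object: `ig` (named, input order), `ordering`
#'   (feature names by decreasing IG), `counts_by_threshold`, `selected`
#'   (feature names per threshold), `h_y`.
#' @export
screen_features <- function(table, thresholds = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                            k_bins = 10, y = attr(table, "y")) {
  X <- as.matrix(table)
  stopifnot(!is.null(y), length(y) == nrow(X), length(unique(y)) == 2)
  ig <- apply(X, 2, function(col) information_gain(bin_feature(col, k_bins), y))
  counts <- vapply(thresholds, function(t) sum(ig > t), 0L)
  names(counts) <- format(thresholds)
  selected <- lapply(thresholds, function(t) names(ig)[ig > t])
  names(selected) <- format(thresholds)
  structure(list(ig = ig, ordering = names(sort(ig, decreasing = TRUE)),
                 counts_by_threshold = counts, selected = selected,
                 thresholds = thresholds, k_bins = k_bins,
                 h_y = entropy_bits(y)),
            class = "ig_screen")
}

#' @export
print.ig_screen <- function(x, ...) {
  cat(sprintf("<ig_screen> %d features, H(Y) = %.4f bits\n", length(x$ig),
              x$h_y))
  cat("features above threshold (strict):\n")
  print(x$counts_by_threshold)
  cat("top features:\n")
  top <- head(x$ordering, 3)
  for (f in top) cat(sprintf("  %-60s %.4f\n", f, x$ig[f]))
  invisible(x)
}

#' Write an IG screen as CSV plus a JSON threshold-count summary
#'
#' @param screen an `ig_screen`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_ig_screen <- function(screen, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    nm <- names(screen$ig)
    pat <- "^(.*)_(firstorder|glcm|glrlm|glszm|gldm|ngtdm)_(.*)$"
    df <- data.frame(feature = nm,
                     transform = sub(pat, "\\1", nm),
                     class = sub(pat, "\\2", nm),
                     ig = as.numeric(screen$ig))
    df <- df[order(-df$ig), ]
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(as.list(screen$counts_by_threshold), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(screen)
}
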