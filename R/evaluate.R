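#' Cross-validation configuration
#'
#' @param folds number of CV folds (>= 2).
#' @param repeats number of repetitions of the whole CV.
#' @param seed integer seed controlling splits and classifier randomness.
#' @param paired_split keep a region and its mirror (same `pairing_id`) in
#'   the same fold — splitting siblings across folds leaks subject
#'   identity and inflates accuracy.
#' @export
cv_config <- function(folds = 4, repeats = 100, seed = 1L,
                      paired_split = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed),
                 paired_split = paired_split),
            class = "cv_config")
}

# Fold assignment: stratified by class, or by pairing group when paired.
# Returns an integer fold id per row.
assign_folds <- function(y, pairing_id, folds, paired) {
  n <- length(y)
  fold <- integer(n)
  if (paired && !is.null(pairing_id)) {
    groups <- unique(pairing_id)
    gf <- sample(rep(seq_len(folds), length.out = length(groups)))
    fold <- gf[match(pairing_id, groups)]
  } else {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  }
  fold
}

#' Repeated k-fold cross-validated accuracy of one classifier
#'
#' Features are standardized per training fold (statistics fitted on the
#' training rows only, applied to the test rows); accuracy is the pooled
#' fraction correct per fold, averaged over all folds of all repeats.
#' Deterministic for a fixed `config$seed`.  Degenerate splits (a training
#' fold containing a single class) are re-drawn.
#'
#' @param table a `labeled_feature_table`.
#' @param feature_set character vector of feature columns to use.
#' @param classifier one element of [classifier_registry()].
#' @param config a [cv_config()].
#' @param y,pairing_id defaults taken from the table attributes.
#' @return Named numeric: `accuracy` and (as an extension to the plain
#'   metric) `balanced_accuracy`.
#' @export
run_cv <- function(table, feature_set, classifier, config = cv_config(),
                   y = attr(table, "y"),
                   pairing_id = attr(table, "pairing_id")) {
  stopifnot(length(feature_set) > 0)
  X <- as.matrix(table)[, feature_set, drop = FALSE]
  stopifnot(length(unique(y)) == 2)
  accs <- baccs <- numeric(0)
  for (rep_i in seq_len(config$repeats)) {
    set.seed(derive_seed(config$seed, rep_i))
    fold <- assign_folds(y, pairing_id, config$folds, config$paired_split)
    for (tries in 1:10) {
      bad <- any(vapply(seq_len(config$folds), function(f)
        length(unique(y[fold != f])) < 2 || sum(fold == f) == 0, TRUE))
      if (!bad) break
      msg("run_cv: degenerate fold, redrawing split")
      fold <- assign_folds(y, pairing_id, config$folds, config$paired_split)
    }
    for (f in seq_len(config$folds)) {
      tr <- fold != f; te <- !tr
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
      set.seed(derive_seed(config$seed, rep_i * 1000 + f))
      model <- classifier$fit(Xtr, y[tr])
      pred <- classifier$predict(model, Xte)
      accs <- c(accs, mean(pred == y[te]))
      cls <- sort(unique(y))
      pc <- vapply(cls, function(cl) {
        sel <- y[te] == cl
        if (!any(sel)) NA_real_ else mean(pred[sel] == cl)
      }, 0)
      baccs <- c(baccs, mean(pc, na.rm = TRUE))
    }
  }
  c(accuracy = mean(accs), balanced_accuracy = mean(baccs))
}

#' Classifier-by-threshold accuracy grid
#'
#' For every IG threshold, restricts the table to the surviving features
#' and runs every classifier through [run_cv()].  Thresholds with no
#' surviving feature are skipped (NA cells), mirroring how sparse screens
#' leave blank report cells.
#'
#' @param table a `labeled_feature_table`.
#' @param screen an `ig_screen` for this table.
#' @param thresholds numeric thresholds to evaluate (default: the screen's).
#' @param classifiers a [classifier_registry()] subset.
#' @param config a [cv_config()].
#' @return A `cv_report`: accuracy and balanced-accuracy grids, feature
#'   counts, per-threshold means, overall aggregations, and the best cell.
#' @export
run_matrix <- function(table, screen, thresholds = screen$thresholds,
                       classifiers = classifier_registry(),
                       config = cv_config()) {
  grid <- matrix(NA_real_, length(classifiers), length(thresholds),
                 dimnames = list(names(classifiers), format(thresholds)))
  bgrid <- grid
  counts <- integer(length(thresholds))
  for (ti in seq_along(thresholds)) {
    feats <- names(screen$ig)[screen$ig > thresholds[ti]]
    counts[ti] <- length(feats)
    if (length(feats) == 0) {
      msg("run_matrix: no features above IG ", thresholds[ti], ", skipped")
      next
    }
    for (ci in seq_along(classifiers)) {
      r <- run_cv(table, feats, classifiers[[ci]], config)
      grid[ci, ti] <- r["accuracy"]
      bgrid[ci, ti] <- r["balanced_accuracy"]
    }
  }
  per_thr <- colMeans(grid, na.rm = TRUE)
  per_thr[counts == 0] <- NA_real_
  filled <- !is.na(grid)
  best_idx <- if (any(filled)) which(grid == max(grid, na.rm = TRUE),
                                     arr.ind = TRUE)[1, ] else NULL
  structure(list(
    accuracy = grid, balanced_accuracy = bgrid,
    feature_counts = setNames(counts, format(thresholds)),
    thresholds = thresholds,
    per_threshold_mean = per_thr,
    # the three aggregations a single "average accuracy" could mean:
    mean_over_cells = mean(grid, na.rm = TRUE),
    mean_of_threshold_means = mean(per_thr, na.rm = TRUE),
    mean_over_classifiers = rowMeans(grid, na.rm = TRUE),
    best = if (is.null(best_idx)) NULL else list(
      accuracy = max(grid, na.rm = TRUE),
      classifier = rownames(grid)[best_idx[1]],
      threshold = thresholds[best_idx[2]]),
    config = config), class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat("<cv_report> classifier x IG-threshold accuracy\n")
  print(round(x$accuracy, digits))
  cat("features surviving:", paste(x$feature_counts, collapse = " / "), "\n")
  cat(sprintf("per-threshold mean: %s\n",
              paste(round(x$per_threshold_mean, digits), collapse = " / ")))
  cat(sprintf("overall mean %.4f", x$mean_over_cells))
  if (!is.null(x$best))
    cat(sprintf("; best %.4f (%s at IG > %s)", x$best$accuracy,
                x$best$classifier, format(x$best$threshold)))
  cat("\n")
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object, ...)
  cat("balanced accuracy (extension):\n")
  print(round(object$balanced_accuracy, 4))
  invisible(object)
}

#' Run the three separability experiments of the analysis
#'
#' Pairing A: lesion regions vs their contralateral mirrors.  Pairing B:
#' normal regions vs their mirrors (should not separate).  Pairing C:
#' lesion regions vs normal regions.  Each pairing gets its own IG screen
#' and classifier-by-threshold grid; A and B use paired splitting.
#'
#' @param tables output of [extract_cohort_features()] (or a `ct_cohort`,
#'   which is extracted first).
#' @param config a [cv_config()].
#' @param thresholds IG thresholds for the screen's survival counts.
#' @param cv_thresholds thresholds at which the classifier grid is actually
#'   evaluated (defaults to `thresholds`; counting is cheap, classification
#'   is not, so the two may differ).
#' @param k_bins equal-frequency bins for the IG screen.
#' @param classifiers a [classifier_registry()] subset.
#' @param extract_cfg an [extract_config()] when `tables` is a cohort.
#' @return A `sep_experiments` object: per pairing, the `ig_screen`, the
#'   `cv_report`, and the row count.
#' @export
run_three_experiments <- function(tables, config = cv_config(),
                                  thresholds = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                  cv_thresholds = thresholds,
                                  k_bins = 10,
                                  classifiers = classifier_registry(),
                                  extract_cfg = extract_config()) {
  if (inherits(tables, "ct_cohort"))
    tables <- extract_cohort_features(tables, extract_cfg)
  out <- list()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    paired <- nm != "lesion_vs_normal"
    cfg <- config; cfg$paired_split <- paired
    screen <- screen_features(tb, thresholds = thresholds, k_bins = k_bins)
    report <- run_matrix(tb, screen, cv_thresholds, classifiers, cfg)
    out[[nm]] <- list(screen = screen, report = report, n = nrow(tb))
  }
  structure(out, class = "sep_experiments")
}

#' @export
print.sep_experiments <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, sprintf("(n = %d regions)\n", x[[nm]]$n))
    print(x[[nm]]$screen$counts_by_threshold)
    print(x[[nm]]$report)
    cat("\n")
  }
  invisible(x)
}

#' End-to-end separability run
#'
#' Generates a cohort, extracts the feature bank, screens by information
#' gain, evaluates the classifier grid for the three pairings, and
#' (optionally) writes a JSON report plus CSV tables.  A pure function of
#' its two seeds.
#'
#' @param n_lesion,n_normal cohort sizes.
#' @param spec a [phantom_spec()].
#' @param lesion_dist lesion population, as in [generate_cohort()].
#' @param seed cohort generation seed.
#' @param cv_seed classifier/CV seed (defaults to `seed`).
#' @param repeats,folds CV settings.
#' @param thresholds IG thresholds.
#' @param classifiers classifier subset.
#' @param extract_cfg an [extract_config()].
#' @param out_dir when non-`NULL`, reports are written here.
#' @return A list: `cohort`, `tables`, `experiments`, and `json` (the
#'   serialized report as text).
#' @export
run_all <- function(n_lesion = 38, n_normal = 18, spec = phantom_spec(),
                    lesion_dist = list(radius_range = c(10, 20),
                                       irregularity = 0.3, delta_hu = -6,
                                       smooth_sigma = 1.5),
                    seed = 1L, cv_seed = seed, repeats = 10, folds = 4,
                    thresholds = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                    cv_thresholds = thresholds,
                    classifiers = classifier_registry(),
                    extract_cfg = extract_config(), out_dir = NULL) {
  cohort <- generate_cohort(n_lesion, n_normal, spec, lesion_dist, seed)
  tables <- extract_cohort_features(cohort, extract_cfg)
  cfg <- cv_config(folds = folds, repeats = repeats, seed = cv_seed)
  exps <- run_three_experiments(tables, cfg, thresholds, cv_thresholds,
                                classifiers = classifiers)
  json <- report_json(exps, seed = seed, cv_seed = cv_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(out_dir, "report.json"))
    writeLines(format_text_report(exps),
               file.path(out_dir, "report.txt"))
    for (nm in names(tables))
      write_feature_table(tables[[nm]],
                          file.path(out_dir, paste0(nm, "_features.csv")))
  }
  list(cohort = cohort, tables = tables, experiments = exps, json = json)
}

# Deterministic JSON serialization of a sep_experiments object.
report_json <- function(exps, seed = NA, cv_seed = NA) {
  payload <- list(seed = seed, cv_seed = cv_seed, pairings = lapply(
    unclass(exps), function(e) list(
      n_regions = e$n,
      ig_counts = as.list(e$screen$counts_by_threshold),
      accuracy = apply(e$report$accuracy, 1, as.list),
      per_threshold_mean = as.list(e$report$per_threshold_mean),
      mean_over_cells = e$report$mean_over_cells,
      best = e$report$best)))
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

# Human-readable screen-counts + accuracy tables.
format_text_report <- function(exps) {
  out <- character(0)
  for (nm in names(exps)) {
    e <- exps[[nm]]
    out <- c(out, sprintf("== %s (n = %d regions)", nm, e$n),
             "features above IG threshold:",
             paste(capture.output(print(e$screen$counts_by_threshold)),
                   collapse = "\n"),
             "accuracy grid:",
             paste(capture.output(print(round(e$report$accuracy, 4))),
                   collapse = "\n"), "")
  }
  out
}
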