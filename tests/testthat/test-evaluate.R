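cfgq <- cv_config(folds = 4, repeats = 2, seed = 3, paired_split = FALSE)

test_that("a label-copy feature gives perfect decision-tree accuracy", {
  tb <- toy_table(n = 40)
  reg <- classifier_registry("decision_tree")
  r <- run_cv(tb, "perfect1", reg$decision_tree, cfgq)
  expect_equal(r[["accuracy"]], 1)
})

test_that("cross-validated accuracy is deterministic per seed", {
  tb <- toy_table(n = 32)
  reg <- classifier_registry(c("random_forest", "multilayer_perceptron",
                               "k_nearest_neighbor"))
  for (cl in reg) {
    a <- run_cv(tb, names(tb)[1:10], cl, cfgq)
    b <- run_cv(tb, names(tb)[1:10], cl, cfgq)
    expect_identical(a, b)
  }
})

test_that("pure-noise features stay in the binomial null band", {
  set.seed(10)
  n <- 50
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("n", 1:8)
  tb <- as.data.frame(X); attr(tb, "y") <- y
  reg <- classifier_registry(c("support_vector_machine", "decision_tree",
                               "gaussian_naive_bayes"))
  for (cl in reg) {
    r <- run_cv(tb, colnames(X), cl, cv_config(repeats = 5, seed = 11,
                                               paired_split = FALSE))
    expect_gte(r[["accuracy"]], 0.38 - 0.06)  # 5x repeats tighten the SE
    expect_lte(r[["accuracy"]], 0.62 + 0.06)
  }
})

test_that("paired splitting keeps mirror siblings in one fold", {
  y <- rep(c(0L, 1L), 12)
  pid <- rep(1:12, each = 2)
  set.seed(1)
  fold <- strokesep:::assign_folds(y, pid, 4, paired = TRUE)
  for (g in unique(pid))
    expect_length(unique(fold[pid == g]), 1)
  strat <- strokesep:::assign_folds(y, NULL, 4, paired = FALSE)
  for (f in 1:4) expect_equal(sum(strat == f & y == 1), 3)
})

test_that("the accuracy grid bookkeeping is complete and best dominates", {
  tb <- toy_table(n = 32)
  sc <- screen_features(tb, thresholds = c(0.0, 0.5))
  reg <- classifier_registry(c("decision_tree", "k_nearest_neighbor"))
  rep_ <- run_matrix(tb, sc, thresholds = c(0.0, 0.5), classifiers = reg,
                     config = cfgq)
  expect_identical(dim(rep_$accuracy), c(2L, 2L))
  expect_equal(sum(!is.na(rep_$accuracy)), 4)
  expect_length(rep_$per_threshold_mean, 2)
  expect_gte(rep_$best$accuracy, max(rep_$accuracy, na.rm = TRUE) - 1e-12)
  # label copies survive 0.5 and give a perfect best cell
  expect_equal(rep_$best$accuracy, 1)
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1, na.rm = TRUE))
})

test_that("thresholds with no surviving features are skipped as NA", {
  set.seed(5)
  X <- matrix(rnorm(24 * 5), 24, 5); colnames(X) <- paste0("n", 1:5)
  tb <- as.data.frame(X); attr(tb, "y") <- rep(0:1, 12)
  sc <- screen_features(tb, thresholds = c(0, 0.95))
  reg <- classifier_registry("decision_tree")
  rep_ <- run_matrix(tb, sc, thresholds = c(0, 0.95), classifiers = reg,
                     config = cfgq)
  expect_true(is.na(rep_$accuracy[1, 2]))
  expect_true(is.na(rep_$per_threshold_mean[2]))
})

test_that("three-experiment run respects the region bookkeeping", {
  co <- generate_cohort(4, 2, small_spec(), small_dist(), seed = 21)
  tabs <- extract_cohort_features(co, extract_config(
    transforms = c("original", "square"),
    classes = c("firstorder", "glrlm")))
  expect_equal(nrow(tabs$lesion_vs_mirror), 8)      # 4 pairs
  expect_equal(nrow(tabs$normal_vs_mirror), 12)     # 2 subjects x 3 slices
  expect_equal(nrow(tabs$lesion_vs_normal), 6)      # 4 lesions + 2 normals
  expect_equal(sum(attr(tabs$lesion_vs_normal, "y")), 4)
  exps <- run_three_experiments(tabs, cv_config(repeats = 1, seed = 2),
                                thresholds = 0.1,
                                classifiers = classifier_registry(
                                  c("decision_tree", "k_nearest_neighbor")))
  expect_named(exps, c("lesion_vs_mirror", "normal_vs_mirror",
                       "lesion_vs_normal"))
  for (e in exps) expect_s3_class(e$report, "cv_report")
})

test_that("label permutation after fitting destroys measured accuracy", {
  # no-leakage check: a perfectly learnable table scored against permuted
  # test labels must fall to the null band
  tb <- toy_table(n = 40)
  reg <- classifier_registry("decision_tree")
  r_true <- run_cv(tb, "perfect1", reg$decision_tree, cfgq)
  set.seed(8)
  yp <- sample(attr(tb, "y"))
  r_perm <- run_cv(tb, "perfect1", reg$decision_tree, cfgq, y = yp)
  expect_equal(r_true[["accuracy"]], 1)
  expect_lt(r_perm[["accuracy"]], 0.75)
})
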