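# AdaBoost.M1 with depth-1 decision stumps.  Written here because no
# boosting package with the classic discrete-AdaBoost contract is among the
# dependencies.  The stump search is exhaustive and fully vectorized: the
# per-feature sort orders are precomputed once, and each round evaluates
# the weighted error of every (feature, split, polarity) candidate with a
# handful of matrix operations.
fit_adaboost <- function(X, y, rounds = 50) {
  n <- nrow(X); p <- ncol(X)
  ord <- apply(X, 2, order)                    # n x p index matrix
  Xs <- matrix(X[cbind(c(ord), rep(seq_len(p), each = n))], n, p)
  distinct <- rbind(Xs[-n, , drop = FALSE] < Xs[-1, , drop = FALSE],
                    rep(FALSE, p))
  ys <- matrix(y[ord], n, p)                   # labels in sorted order
  w <- rep(1 / n, n)
  stumps <- list()
  for (m in seq_len(rounds)) {
    ws <- matrix(w[ord], n, p)
    colcumsum <- function(M) {
      cs <- matrix(cumsum(M), n, p)
      if (p > 1) cs + rep(c(0, -cs[n, -p]), each = n) else cs
    }
    wy1 <- colcumsum(ws * (ys == 1))
    wy0 <- colcumsum(ws * (ys == 0))
    # stump "predict 1 when x > split after position k":
    # err = (weight of y=1 at or below k) + (weight of y=0 above k)
    errs <- wy1 + (sum(w[y == 0]) - wy0)
    errs[!distinct] <- Inf
    flip <- 1 - errs                           # opposite polarity
    flip[!distinct] <- Inf
    i1 <- which.min(errs); i2 <- which.min(flip)
    if (!is.finite(errs[i1]) && !is.finite(flip[i2])) break
    if (errs[i1] <= flip[i2]) {
      err <- errs[i1]; pol <- 1L; idx <- i1
    } else {
      err <- flip[i2]; pol <- -1L; idx <- i2
    }
    k <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    thr <- (Xs[k, j] + Xs[k + 1, j]) / 2
    err_c <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err_c) / err_c)
    stumps[[m]] <- c(j = j, thr = thr, pol = pol, alpha = alpha)
    h <- as.integer(X[, j] > thr)
    if (pol < 0) h <- 1L - h
    w <- w * exp(-alpha * (2 * h - 1) * (2 * y - 1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(stumps = stumps), class = "ada_stumps")
}

predict_adaboost <- function(model, X) {
  F_ <- rep(0, nrow(X))
  for (s in model$stumps) {
    h <- as.integer(X[, s["j"]] > s["thr"])
    if (s["pol"] < 0) h <- 1L - h
    F_ <- F_ + s["alpha"] * (2 * h - 1)
  }
  as.integer(F_ > 0)
}

# Bagged decision trees: bootstrap aggregation of unrestricted trees is a
# random forest whose per-split candidate set is every feature, so ranger
# with mtry = p provides it directly.
fit_bagging <- function(X, y, n_bags = 10) {
  ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                 num.trees = n_bags, mtry = ncol(X), replace = TRUE,
                 num.threads = 1, seed = sample.int(.Machine$integer.max, 1))
}

predict_bagging <- function(model, X) {
  as.integer(predict(model, data = as.data.frame(X),
                     num.threads = 1)$predictions) - 1L
}

# Median-binarization for Bernoulli naive Bayes; medians come from the
# training fold.
binarize <- function(X, med) {
  out <- as.data.frame(lapply(seq_len(ncol(X)), function(j)
    factor(as.integer(X[, j] > med[j]), levels = c(0, 1))))
  names(out) <- colnames(X)
  out
}

#' The ten-classifier registry
#'
#' Fixed, documented hyperparameter defaults for the ten families used by
#' the separability harness: multilayer perceptron (single hidden layer of
#' 4 units, weight decay 0.1), decision tree (CART), random forest
#' (100 trees), AdaBoost (50 stump rounds), gradient boosting (xgboost,
#' 100 rounds, depth 3, eta 0.1), bagging (10 bootstrapped CART trees),
#' Bernoulli naive Bayes (on median-binarized features, Laplace 1),
#' Gaussian naive Bayes, RBF support vector machine (cost 1), and
#' k-nearest neighbours (k = 5).  All operate on features standardized per
#' training fold by the harness.
#'
#' @param families optional subset of family names.
#' @return Named list; each element has `fit(X, y)` and `predict(model, X)`
#'   returning integer 0/1 labels.
#' @export
classifier_registry <- function(families = NULL) {
  reg <- list(
    multilayer_perceptron = list(
      # nnet optimizes by BFGS, whose per-iteration cost is quadratic in
      # the weight count; with feature banks in the hundreds a compact
      # hidden layer is what keeps the perceptron usable
      fit = function(X, y) nnet::nnet(x = X, y = y, size = 4, decay = 0.1,
                                      maxit = 60, entropy = TRUE,
                                      trace = FALSE, MaxNWts = 50000),
      predict = function(m, X) as.integer(predict(m, X) > 0.5)),
    decision_tree = list(
      fit = function(X, y) {
        df <- as.data.frame(X); df$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(.y ~ ., data = df,
                     control = rpart::rpart.control(xval = 0,
                                                    maxcompete = 0,
                                                    maxsurrogate = 0,
                                                    usesurrogate = 0))
      },
      predict = function(m, X)
        as.integer(predict(m, as.data.frame(X), type = "class")) - 1L),
    random_forest = list(
      fit = function(X, y) ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
        num.trees = 100, num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1)),
      predict = function(m, X)
        as.integer(predict(m, data = as.data.frame(X),
                           num.threads = 1)$predictions) - 1L),
    adaboost = list(
      fit = function(X, y) fit_adaboost(X, y),
      predict = predict_adaboost),
    gradient_boosting = list(
      fit = function(X, y) xgboost::xgboost(
        X, factor(y, levels = c(0, 1)), nrounds = 100, max_depth = 3,
        learning_rate = 0.1, nthreads = 1, verbosity = 0),
      predict = function(m, X) as.integer(predict(m, X) > 0.5)),
    bagging = list(
      fit = function(X, y) fit_bagging(X, y),
      predict = predict_bagging),
    bernoulli_naive_bayes = list(
      fit = function(X, y) {
        med <- apply(X, 2, median)
        m <- e1071::naiveBayes(binarize(X, med),
                               factor(y, levels = c(0, 1)), laplace = 1)
        list(nb = m, med = med)
      },
      predict = function(m, X)
        as.integer(predict(m$nb, binarize(X, m$med))) - 1L),
    gaussian_naive_bayes = list(
      fit = function(X, y) {
        m <- e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
        # floor class-conditional SDs so degenerate features cannot yield
        # NaN densities
        m$tables <- lapply(m$tables, function(tb) {
          tb[, 2] <- pmax(tb[, 2], 1e-6); tb
        })
        m
      },
      predict = function(m, X)
        as.integer(predict(m, as.data.frame(X))) - 1L),
    support_vector_machine = list(
      fit = function(X, y) e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                                      kernel = "radial", cost = 1,
                                      scale = FALSE),
      predict = function(m, X) as.integer(predict(m, X)) - 1L),
    k_nearest_neighbor = list(
      fit = function(X, y) list(X = X, y = factor(y, levels = c(0, 1))),
      predict = function(m, X)
        as.integer(class::knn(m$X, X, m$y, k = min(5, nrow(m$X)))) - 1L)
  )
  if (!is.null(families)) {
    missing <- setdiff(families, names(reg))
    if (length(missing) > 0) stop("unknown classifier(s): ",
                                  paste(missing, collapse = ", "))
    reg <- reg[families]
  }
  reg
}
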