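# Boosted decision-tree classification of functional-test error labels.
#
# The ensemble is discrete (SAMME, two-class) AdaBoost over depth-bounded
# trees grown by weighted Gini impurity on a per-round random feature
# subset. Numerical determinism contract for split selection, shared by the
# tests' independent reference: candidate thresholds are midpoints between
# consecutive distinct sorted feature values; impurities are compared at
# 1e-9 resolution; ties break toward the lower feature index, then the lower
# threshold; leaf labels are the weighted majority with ties going to class
# 0 (non-faulty).

IMPURITY_RESOLUTION <- 1e-9

#' Boosting hyper-parameters
#'
#' Defaults follow the study configuration: 50 weak learners, learning rate
#' 0.1, tree depth at most 3, `floor(sqrt(d))` candidate features per
#' learner, random state 42, and an 80/15/5 train/validation/test partition.
#'
#' @param n_learners Number of boosting rounds (>= 1).
#' @param learning_rate Shrinkage applied to each learner's weight (> 0).
#' @param max_depth Maximum tree depth (1 = decision stump).
#' @param feature_subset `"sqrt"` (default: `floor(sqrt(d))` features drawn
#'   per round) or `"all"` (exhaustive; used e.g. for stump-reference
#'   comparisons).
#' @param seed Random state driving the per-round feature-subset schedule and
#'   the data partition.
#' @param split Train/validation/test fractions summing to 1.
#' @return A `boost_params` list.
#' @export
boost_params <- function(n_learners = 50, learning_rate = 0.1, max_depth = 3,
                         feature_subset = c("sqrt", "all"), seed = 42,
                         split = c(0.80, 0.15, 0.05)) {
  feature_subset <- match.arg(feature_subset)
  if (n_learners < 1) ms_stop("bad_argument", "n_learners must be >= 1")
  if (learning_rate <= 0) ms_stop("bad_argument", "learning_rate must be > 0")
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3)
    ms_stop("bad_argument", "split must be 3 fractions summing to 1")
  structure(list(n_learners = as.integer(n_learners),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 feature_subset = feature_subset,
                 seed = as.integer(seed), split = split),
            class = "boost_params")
}

# ---- weighted decision tree ------------------------------------------------

weighted_gini <- function(w1, w0) {
  tot <- w1 + w0
  if (tot <= 0) return(0)
  1 - (w1 / tot)^2 - (w0 / tot)^2
}

# Best (feature, threshold) over the candidate pool by weighted Gini of the
# children; NULL when no split strictly improves impurity.
best_split <- function(X, y, w, pool) {
  parent <- weighted_gini(sum(w[y == 1]), sum(w[y == 0]))
  best <- NULL
  best_imp <- round(parent / IMPURITY_RESOLUTION) * IMPURITY_RESOLUTION
  wtot <- sum(w)
  for (j in pool) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
    cw1 <- cumsum(ws * (ys == 1)); cw0 <- cumsum(ws * (ys == 0))
    n <- length(xs)
    distinct <- which(xs[-n] < xs[-1])
    if (length(distinct) == 0) next
    for (i in distinct) {
      thr <- (xs[i] + xs[i + 1]) / 2
      wl <- cw1[i] + cw0[i]
      imp <- (wl * weighted_gini(cw1[i], cw0[i]) +
              (wtot - wl) * weighted_gini(cw1[n] - cw1[i], cw0[n] - cw0[i])) / wtot
      imp <- round(imp / IMPURITY_RESOLUTION) * IMPURITY_RESOLUTION
      if (imp < best_imp ||
          (!is.null(best) && imp == best_imp &&
           (j < best$feature || (j == best$feature && thr < best$threshold)))) {
        best <- list(feature = j, threshold = thr)
        best_imp <- imp
      }
    }
  }
  best
}

leaf_node <- function(y, w) {
  w1 <- sum(w[y == 1]); w0 <- sum(w[y == 0])
  list(leaf = TRUE, class = if (w1 > w0) 1L else 0L)  # tie -> class 0
}

fit_tree <- function(X, y, w, pool, max_depth, depth = 0L) {
  if (depth >= max_depth || length(unique(y)) == 1)
    return(leaf_node(y, w))
  sp <- best_split(X, y, w, pool)
  if (is.null(sp)) return(leaf_node(y, w))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = fit_tree(X[left, , drop = FALSE], y[left], w[left],
                       pool, max_depth, depth + 1L),
       right = fit_tree(X[!left, , drop = FALSE], y[!left], w[!left],
                        pool, max_depth, depth + 1L))
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  if (node$leaf) return(rep(node$class, n))
  out <- integer(n)
  left <- X[, node$feature] <= node$threshold
  if (any(left)) out[left] <- predict_tree(node$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$right, X[!left, , drop = FALSE])
  out
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

# ---- boosting --------------------------------------------------------------

#' Train a discrete AdaBoost ensemble
#'
#' Sample weights start uniform at `1/n`. Each round draws a feature subset
#' (per the schedule keyed to `(seed, round)`), fits a depth-bounded tree by
#' weighted Gini, computes the weighted error `eps`, assigns the learner
#' weight `alpha = learning_rate * log((1 - eps) / eps)`, multiplies the
#' weights of misclassified samples by `exp(alpha)` and renormalizes. A
#' perfect round (`eps = 0`) keeps the learner with a large capped weight and
#' stops; a failing round (`eps >= 0.5`) redraws the feature subset once and
#' stops after the retry.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels, 1 = faulty (positive class), 0 = non-faulty.
#' @param params A [boost_params()].
#' @return An `adaboost_model`: `learners` (tree node records), `alphas`,
#'   `features` (column names seen at fit), `params`.
#' @export
train_adaboost <- function(X, y, params = boost_params()) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) ms_stop("bad_argument", "need >= 2 training samples")
  if (length(unique(y)) < 2)
    ms_stop("degenerate_labels", "training labels contain a single class")
  m <- if (params$feature_subset == "all") d else max(1L, floor(sqrt(d)))
  draw_pool <- function(t, retry = FALSE) {
    if (m == d) return(seq_len(d))
    with_seed(derive_seed(params$seed, t + if (retry) 100000L else 0L),
              sort(sample.int(d, m)))
  }
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  eps_min <- 1e-10
  for (t in seq_len(params$n_learners)) {
    pool <- draw_pool(t)
    tree <- fit_tree(X, y, w, pool, params$max_depth)
    pred <- predict_tree(tree, X)
    eps <- sum(w[pred != y])
    if (eps >= 0.5) {
      pool <- draw_pool(t, retry = TRUE)
      tree <- fit_tree(X, y, w, pool, params$max_depth)
      pred <- predict_tree(tree, X)
      eps <- sum(w[pred != y])
      if (eps >= 0.5) break
      alpha <- params$learning_rate * log((1 - max(eps, eps_min)) / max(eps, eps_min))
      learners[[length(learners) + 1L]] <- tree
      alphas <- c(alphas, alpha)
      break
    }
    eps_c <- max(eps, eps_min)
    alpha <- params$learning_rate * log((1 - eps_c) / eps_c)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (eps == 0) break
    mis <- pred != y
    w[mis] <- w[mis] * exp(alpha)
    w <- w / sum(w)
  }
  if (length(learners) == 0)
    ms_stop("training_failure", "no weak learner achieved error < 0.5")
  structure(list(learners = learners, alphas = alphas,
                 features = colnames(X), n_features = d, params = params),
            class = "adaboost_model")
}

#' Predict binary labels with a boosted ensemble
#'
#' Weighted vote `sum(alpha_t * (2 * h_t(x) - 1))`; positive score gives
#' class 1 (faulty), ties break toward class 0 (non-faulty).
#'
#' @param object An `adaboost_model`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Ignored.
#' @return Integer vector of 0/1 labels.
#' @export
predict.adaboost_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    ms_stop("shape_error", "model expects %d features, got %d",
            object$n_features, ncol(X))
  score <- rep(0, nrow(X))
  for (t in seq_along(object$learners))
    score <- score + object$alphas[t] * (2 * predict_tree(object$learners[[t]], X) - 1)
  as.integer(score > 0)
}

# ---- data partition --------------------------------------------------------

largest_remainder <- function(total, fractions) {
  ideal <- total * fractions
  base <- floor(ideal)
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(-(ideal - base), seq_along(fractions))  # ties -> earlier split
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test partition
#'
#' Splits samples into disjoint, exhaustive index sets. Split sizes are the
#' largest-remainder rounding of `n * fractions` (remainder ties break toward
#' the earlier split: train, validation, test), and within those sizes class
#' proportions are preserved per split up to the same rounding. Deterministic
#' for a fixed seed. If the test split ends up without one of the classes, a
#' warning is raised and the validation split absorbs the test split.
#'
#' @param labels Binary label vector (both classes must be present).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Random state.
#' @param merge_degenerate_test Apply the absorb rule above (default `TRUE`).
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.80, 0.15, 0.05), seed = 42,
                             merge_degenerate_test = TRUE) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    ms_stop("degenerate_labels", "both classes must be present")
  if (abs(sum(fractions) - 1) > 1e-8)
    ms_stop("bad_argument", "fractions must sum to 1")
  target <- largest_remainder(length(labels), fractions)
  n_c <- vapply(classes, function(cl) sum(labels == cl), 0L)
  alloc <- t(vapply(n_c, largest_remainder, integer(3), fractions = fractions))
  # repair column sums to the total targets, moving units of the class most
  # over-represented in the oversized split (ties -> lower class)
  repeat {
    colsum <- colSums(alloc)
    if (all(colsum == target)) break
    s_over <- which(colsum > target)[1]
    s_under <- which(colsum < target)[1]
    excess <- alloc[, s_over] - n_c * fractions[s_over]
    excess[alloc[, s_over] == 0] <- -Inf
    cl <- which.max(excess)
    alloc[cl, s_over] <- alloc[cl, s_over] - 1L
    alloc[cl, s_under] <- alloc[cl, s_under] + 1L
  }
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- idx[with_seed(derive_seed(seed, classes[ci]), sample.int(length(idx)))]
    bounds <- cumsum(alloc[ci, ])
    parts$train <- c(parts$train, idx[seq_len(alloc[ci, 1])])
    parts$validation <- c(parts$validation, idx[seq_len(alloc[ci, 2]) + bounds[1]])
    parts$test <- c(parts$test, idx[seq_len(alloc[ci, 3]) + bounds[2]])
  }
  parts <- lapply(parts, sort)
  if (merge_degenerate_test && length(parts$test) > 0 &&
      length(unique(labels[parts$test])) < length(classes)) {
    warning("test split lacks a class; merging it into validation")
    parts$validation <- sort(c(parts$validation, parts$test))
    parts$test <- integer(0)
  }
  parts
}

# ---- evaluation ------------------------------------------------------------

#' Confusion matrix and screening metrics
#'
#' Positive class is 1 = faulty (error present), so sensitivity is the rate
#' at which executed errors are detected and specificity the rate at which
#' correct executions are recognized. Metrics with a zero denominator are
#' reported as `NaN` and flagged in `undefined`, never silently zero.
#'
#' @param y_true,y_pred Binary vectors of equal, positive length.
#' @return List with `confusion` (`TP`, `FP`, `TN`, `FN`), `sensitivity`,
#'   `specificity`, `accuracy`, `undefined` (character vector of flagged
#'   metrics).
#' @export
evaluate_classifier <- function(y_true, y_pred) {
  if (length(y_true) == 0)
    ms_stop("bad_argument", "empty test set")
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  undefined <- c(if (is.nan(sens)) "sensitivity", if (is.nan(spec)) "specificity")
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y_true),
       undefined = undefined %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validated boosting
#'
#' Partitions samples into `k` stratified folds, trains on each complement
#' and predicts the held-out fold, then evaluates the pooled out-of-fold
#' predictions. Used for cohort-scale validation, where a 5% test split of a
#' 46-subject cohort would hold only two subjects.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param params A [boost_params()].
#' @param k Number of folds (default 5).
#' @return List with `predictions` (out-of-fold, aligned to rows of `X`),
#'   `folds`, and the [evaluate_classifier()] report under `metrics`.
#' @export
cross_validate_adaboost <- function(X, y, params = boost_params(), k = 5) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  folds <- integer(n)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[with_seed(derive_seed(params$seed, 500L + cl), sample.int(length(idx)))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  preds <- integer(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- train_adaboost(X[!hold, , drop = FALSE], y[!hold], params)
    preds[hold] <- predict(model, X[hold, , drop = FALSE])
  }
  list(predictions = preds, folds = folds,
       metrics = evaluate_classifier(y, preds))
}

# ---- serialization ---------------------------------------------------------

#' Write a boosted model as JSON
#'
#' Trees are stored as nested node records (`feature` as a 0-based column
#' index, `threshold`, `left`/`right` children, or a `class` leaf).
#'
#' @param model An `adaboost_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  encode <- function(node) {
    if (node$leaf) list(class = jsonlite::unbox(node$class))
    else list(feature = jsonlite::unbox(node$feature - 1L),
              threshold = jsonlite::unbox(node$threshold),
              left = encode(node$left), right = encode(node$right))
  }
  obj <- list(alphas = model$alphas,
              n_features = jsonlite::unbox(model$n_features),
              features = model$features,
              learners = lapply(model$learners, encode))
  jsonlite::write_json(obj, path, digits = I(17), null = "null")
  invisible(path)
}

#' Read a boosted model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return An `adaboost_model` usable with [predict.adaboost_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  decode <- function(node) {
    if (!is.null(node$class)) list(leaf = TRUE, class = as.integer(node$class))
    else list(leaf = FALSE, feature = as.integer(node$feature) + 1L,
              threshold = as.numeric(node$threshold),
              left = decode(node$left), right = decode(node$right))
  }
  structure(list(learners = lapply(obj$learners, decode),
                 alphas = as.numeric(unlist(obj$alphas)),
                 features = as.character(unlist(obj$features)),
                 n_features = as.integer(obj$n_features),
                 params = NULL),
            class = "adaboost_model")
}
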