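## Morphological feature selection (RFE with a linear SVM, SFM with
## random-forest importances), stratified splitting, normalization and
## modality fusion.

svm_ovr_importance <- function(X, y, cost = 1) {
  ## one-vs-rest linear SVMs; importance = sum over classes of |weight|
  y <- factor(y)
  imp <- rep(0, ncol(X))
  for (cl in levels(y)) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)
    if (!all(is.finite(w)))
      abort_input("non-finite SVM coefficients; check standardization of ",
                  paste(colnames(X), collapse = ", "))
    imp <- imp + abs(as.numeric(w))
  }
  imp
}

cv_accuracy_svm <- function(X, y, folds, cost = 1) {
  correct <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Recursive feature elimination with a linear SVM base model
#'
#' Fits one-vs-rest linear SVMs (`C = 1`) on the standardized matrix,
#' measures each feature's importance as the summed absolute
#' coefficients, eliminates the single least-important feature per
#' iteration (ties broken by dropping the lower column index first), and
#' records the cross-validated accuracy of every subset size. Returns
#' the full elimination ranking and the accuracy-maximizing subset (ties
#' toward the smaller subset), or the top `n_keep` of the ranking when
#' `n_keep` is given.
#'
#' @param X samples x features matrix (standardized internally).
#' @param y class labels.
#' @param n_keep optional forced subset size.
#' @param cv number of cross-validation folds (default 5).
#' @param seed integer seed (fold assignment).
#' @return list with `ranking` (feature names, best first), `kept`
#'   (selected feature names), `cv_curve` (accuracy by subset size,
#'   names = size), `importances` (final-iteration importances of all
#'   features on the full set).
#' @export
rfe_select <- function(X, y, n_keep = NULL, cv = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)
  if (!is.null(n_keep) && n_keep > p)
    abort_input("n_keep must be <= number of features")
  sds <- apply(X, 2, sd); sds[sds < 1e-12] <- 1
  Xs <- scale(X, scale = sds)
  y <- factor(y)
  with_seed(seed, {
    folds <- numeric(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(cv), length.out = length(idx)))
    }
    active <- seq_len(p)
    eliminated <- integer(0)
    cv_curve <- setNames(rep(NA_real_, p), as.character(seq_len(p)))
    full_imp <- NULL
    while (length(active) >= 1) {
      Xa <- Xs[, active, drop = FALSE]
      cv_curve[as.character(length(active))] <-
        cv_accuracy_svm(Xa, y, folds)
      if (length(active) == 1) break
      imp <- svm_ovr_importance(Xa, y)
      if (is.null(full_imp))
        full_imp <- setNames(imp, colnames(Xa))
      ## ties: drop the lower column index first
      drop_local <- which(imp == min(imp))[1]
      eliminated <- c(active[drop_local], eliminated)
      active <- active[-drop_local]
    }
    ranking <- colnames(X)[c(active, eliminated)]
    if (is.null(n_keep)) {
      sizes <- as.integer(names(cv_curve))
      best_acc <- max(cv_curve)
      k_best <- min(sizes[cv_curve >= best_acc - 1e-15])
    } else {
      k_best <- n_keep
    }
    list(ranking = ranking, kept = sort(ranking[seq_len(k_best)]),
         cv_curve = cv_curve, importances = full_imp)
  })
}

#' Importance-threshold feature selection (select-from-model)
#'
#' Fits a random forest (200 trees) and keeps the features whose
#' normalized impurity importance is at least `threshold`. The default
#' `"mean"` threshold keeps features with above-average importance. If
#' nothing clears the threshold the single top feature is kept with a
#' warning.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param threshold `"mean"` or a numeric cutoff on the normalized
#'   importances (which sum to 1).
#' @param n_trees forest size.
#' @param seed integer seed.
#' @return list with `kept` (feature names) and `importances`
#'   (normalized, named).
#' @export
sfm_select <- function(X, y, threshold = "mean", n_trees = 200, seed = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort_input("X must be finite")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  with_seed(seed, {
    fit <- randomForest::randomForest(X, factor(y), ntree = n_trees)
    imp <- fit$importance[, "MeanDecreaseGini"]
    imp <- imp / sum(imp)
    thr <- if (identical(threshold, "mean")) mean(imp) else
      as.numeric(threshold)
    kept <- names(imp)[imp >= thr]
    if (length(kept) == 0) {
      warning("no feature importance reached the threshold; keeping the ",
              "single top feature", call. = FALSE)
      kept <- names(which.max(imp))
    }
    list(kept = kept, importances = imp)
  })
}

#' Stratified train/test split
#'
#' Splits sample indices class by class at the given training ratio.
#' Per-class training counts use largest-remainder rounding so the
#' overall training size equals `round(ratio * n)` exactly (e.g. 260
#' samples at 7:3 give 182/78).
#'
#' @param y class labels.
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(y, ratio = 0.7, seed = 1) {
  y <- factor(y)
  n <- length(y)
  n_train <- round(ratio * n)
  counts <- table(y)
  quota <- floor(ratio * counts)
  rem <- ratio * counts - quota
  short <- n_train - sum(quota)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    quota[add] <- quota[add] + 1
  }
  with_seed(seed, {
    train <- integer(0)
    for (ci in seq_along(levels(y))) {
      idx <- which(y == levels(y)[ci])
      train <- c(train, sample(idx, quota[ci]))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Fuse selected morphological and spectral feature blocks
#'
#' Z-scores every column using statistics computed on the training rows
#' only (no leakage), then concatenates the morphological block ahead of
#' the spectral block. Reports the dimensionality reduction of each
#' modality as `100 * (1 - kept / original)` when the original widths
#' are supplied.
#'
#' @param morph samples x kept-morphological-features matrix (may have 0
#'   columns for spectral-only mode).
#' @param bands samples x kept-bands matrix.
#' @param y class labels.
#' @param train integer indices of the training rows used for the
#'   normalization statistics (default: all rows).
#' @param morph_total,bands_total original feature counts before
#'   selection, for the reduction report (optional).
#' @param sample_id optional ids checked for alignment between blocks.
#' @return object of class `fused_dataset`: `X` (normalized), `y`,
#'   `feature_names`, `blocks` (column counts per modality), `center`/
#'   `scale` (training statistics), `reduction_pct`.
#' @export
fuse_features <- function(morph, bands, y, train = NULL,
                          morph_total = NULL, bands_total = NULL,
                          sample_id = NULL) {
  morph <- as.matrix(morph); bands <- as.matrix(bands)
  if (nrow(morph) > 0 && ncol(morph) > 0 && nrow(morph) != nrow(bands))
    abort_input("morph and bands row counts differ: ", nrow(morph),
                " vs ", nrow(bands))
  if (!is.null(sample_id)) {
    ids_m <- rownames(morph); ids_b <- rownames(bands)
    if (!is.null(ids_m) && !is.null(ids_b) && !identical(ids_m, ids_b)) {
      bad <- which(ids_m != ids_b)
      abort_input("sample-id mismatch between blocks at rows: ",
                  paste(head(bad, 10), collapse = ", "))
    }
  }
  if (ncol(morph) == 0) {
    X <- bands
  } else {
    X <- cbind(morph, bands)
  }
  if (anyNA(X)) abort_input("fused matrix contains NA")
  nm <- colnames(X)
  if (anyDuplicated(nm)) abort_input("feature names must be unique")
  train <- train %||% seq_len(nrow(X))
  ctr <- colMeans(X[train, , drop = FALSE])
  scl <- apply(X[train, , drop = FALSE], 2, sd)
  scl[scl < 1e-12] <- 1
  Xn <- scale(X, center = ctr, scale = scl)
  attr(Xn, "scaled:center") <- NULL
  attr(Xn, "scaled:scale") <- NULL
  red <- c(morph = if (is.null(morph_total)) NA_real_ else
             100 * (1 - ncol(morph) / morph_total),
           bands = if (is.null(bands_total)) NA_real_ else
             100 * (1 - ncol(bands) / bands_total))
  structure(list(X = Xn, y = factor(y), feature_names = nm,
                 blocks = c(morph = ncol(morph), bands = ncol(bands)),
                 center = ctr, scale = scl, reduction_pct = red),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(sprintf(
    "fused_dataset: %d samples, %d morphological + %d spectral features\n",
    nrow(x$X), x$blocks["morph"], x$blocks["bands"]))
  if (!all(is.na(x$reduction_pct)))
    cat(sprintf("  dimensionality reduction: morph %.2f%%, bands %.2f%%\n",
                x$reduction_pct["morph"], x$reduction_pct["bands"]))
  invisible(x)
}

#' Split a fused dataset back into its modality blocks
#'
#' @param fd a [fuse_features()] result.
#' @return list with matrices `morph` and `bands`.
#' @export
unfuse <- function(fd) {
  stopifnot(inherits(fd, "fused_dataset"))
  k <- fd$blocks["morph"]
  list(morph = fd$X[, seq_len(k), drop = FALSE],
       bands = fd$X[, k + seq_len(fd$blocks["bands"]), drop = FALSE])
}
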