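## Random-forest hyperparameter tuning driven by the ORBMO optimizer,
## plus confusion-matrix based evaluation.
##
## The tuned box is dim = 3: number of trees in [10, 300], maximum tree
## depth in [3, 30], and the per-split feature count in [2, 20]
## (clipped to the available feature count at fit time).

#' Default hyperparameter search space for the random forest
#'
#' @return a [search_space()] with bounds `lb = c(10, 3, 2)`,
#'   `ub = c(300, 30, 20)` over (`n_estimators`, `max_depth`,
#'   `max_features`).
#' @export
rf_search_space <- function() {
  search_space(c(10, 3, 2), c(300, 30, 20),
               names = c("n_estimators", "max_depth", "max_features"))
}

#' Decode a continuous optimizer position into RF hyperparameters
#'
#' Rounds half away from zero to integers and clips into the search box.
#'
#' @param position numeric 3-vector.
#' @param space the hyperparameter [search_space()].
#' @return named integer vector (`n_estimators`, `max_depth`,
#'   `max_features`).
#' @export
decode_params <- function(position, space = rf_search_space()) {
  stopifnot(length(position) == space$dim)
  v <- trunc(abs(position) + 0.5) * sign(position)  # round half away from zero
  v <- pmin(pmax(v, ceiling(space$lb)), floor(space$ub))
  setNames(as.integer(v), space$names)
}

fit_rf <- function(X, y, params, seed) {
  ranger::ranger(
    x = as.data.frame(X), y = factor(y),
    num.trees = params[["n_estimators"]],
    max.depth = params[["max_depth"]],
    mtry = min(params[["max_features"]], ncol(X)),
    seed = seed, num.threads = 1)
}

## majority-vote ties are broken with the prediction seed, so it must be
## pinned for reproducible reports
predict_rf <- function(fit, X) {
  predict(fit, as.data.frame(X), seed = 1L, num.threads = 1)$predictions
}

stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  small <- names(which(table(y) < k))
  if (length(small) > 0)
    abort_input("class(es) with fewer than ", k, " members: ",
                paste(small, collapse = ", "))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Cross-validated error-rate fitness of RF hyperparameters
#'
#' `fitness = 1 - mean stratified k-fold accuracy`, the quantity the
#' optimizer minimizes. Fully seeded, so identical inputs give identical
#' fitness.
#'
#' @param params decoded hyperparameters ([decode_params()]).
#' @param X,y training data.
#' @param k folds (default 5); every class needs at least `k` members.
#' @param seed integer seed (fold assignment and forests).
#' @return error rate in \[0, 1\].
#' @export
cv_fitness <- function(params, X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  folds <- stratified_folds(y, k, seed)
  correct <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_rf(X[tr, , drop = FALSE], y[tr], params,
                  seed = seed + f)
    pred <- predict_rf(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  1 - correct / length(y)
}

#' Tune random-forest hyperparameters with ORBMO
#'
#' Wraps [cv_fitness()] as the objective of [orbmo_optimize()] over the
#' hyperparameter box. Because decoded positions are integer triples,
#' fitness values are memoized per triple, which removes most repeated
#' forest fits late in the run.
#'
#' @param X,y training data (typically a fused feature table).
#' @param space hyperparameter [search_space()].
#' @param n,t_max optimizer population size and iteration budget.
#' @param cfg an [orbmo_config()].
#' @param k cross-validation folds for the fitness.
#' @param seed integer seed for the whole tuning run.
#' @return list with `params` (decoded best), `fitness` (best CV error),
#'   `history` (best fitness per iteration), `evaluations`
#'   (distinct hyperparameter triples evaluated).
#' @export
tune_rf <- function(X, y, space = rf_search_space(), n = 30, t_max = 100,
                    cfg = orbmo_config(), k = 5, seed = 1) {
  X <- as.matrix(X)
  cache <- new.env(parent = emptyenv())
  n_distinct <- 0L
  objective <- function(pos) {
    par <- decode_params(pos, space)
    key <- paste(par, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_fitness(par, X, y, k = k, seed = derive_seed(seed, 1))
    cache[[key]] <- val
    n_distinct <<- n_distinct + 1L
    val
  }
  res <- orbmo_optimize(objective, space, n = n, t_max = t_max, cfg = cfg,
                        seed = derive_seed(seed, 2))
  list(params = decode_params(res$best, space),
       fitness = res$best_fitness, history = res$history,
       evaluations = n_distinct)
}

#' Train a random forest with given hyperparameters
#'
#' @param X,y training data.
#' @param params decoded hyperparameters.
#' @param seed integer seed.
#' @return a fitted `ranger` model.
#' @export
train_rf <- function(X, y, params, seed = 1) {
  fit_rf(as.matrix(X), y, params, seed)
}

#' Confusion-matrix classification report
#'
#' Builds the C x C confusion matrix (rows = actual, columns =
#' predicted) and computes accuracy plus per-class precision, recall and
#' F1 from one-vs-rest TP/FP/FN counts: `P = TP / (TP + FP)`,
#' `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`. Aggregates are
#' support-weighted averages, under which weighted recall equals
#' accuracy exactly. A class never predicted gets precision 0 with a
#' warning.
#'
#' @param actual,predicted class labels (equal length).
#' @param levels optional class level set (defaults to the union).
#' @return object of class `classification_report`: `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1`, `per_class` (data frame
#'   with class, support, precision, recall, f1).
#' @export
classification_report <- function(actual, predicted, levels = NULL) {
  levels <- levels %||% sort(unique(c(as.character(actual),
                                      as.character(predicted))))
  actual <- factor(as.character(actual), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  if (length(actual) != length(predicted))
    abort_input("actual and predicted must have equal length")
  cm <- table(actual = actual, predicted = predicted)
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  never_pred <- colSums(cm) == 0 & support > 0
  if (any(never_pred))
    warning("class(es) absent from predictions: ",
            paste(levels[never_pred], collapse = ", "),
            "; precision defined as 0", call. = FALSE)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / n
  structure(list(
    confusion = unclass(cm),
    accuracy = sum(tp) / n,
    precision = sum(w * prec),
    recall = sum(w * rec),
    f1 = sum(w * f1),
    per_class = data.frame(class = levels, support = as.integer(support),
                           precision = as.numeric(prec),
                           recall = as.numeric(rec),
                           f1 = as.numeric(f1))),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | weighted precision %.4f recall %.4f F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on test data
#'
#' @param model a fitted `ranger` model.
#' @param X_test,y_test aligned test data.
#' @return a [classification_report()].
#' @export
evaluate_model <- function(model, X_test, y_test) {
  pred <- predict_rf(model, as.matrix(X_test))
  classification_report(y_test, pred,
                        levels = levels(factor(y_test)))
}
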