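test_that("positions decode to rounded, clipped integer hyperparameters", {
  expect_equal(decode_params(c(10, 3, 2)),
               c(n_estimators = 10L, max_depth = 3L, max_features = 2L))
  expect_equal(decode_params(c(300.49, 30.2, 19.7)),
               c(n_estimators = 300L, max_depth = 30L,
                 max_features = 20L))
  expect_equal(decode_params(c(155.5, 16.5, 11.5)),
               c(n_estimators = 156L, max_depth = 17L,
                 max_features = 12L))
})

test_that("cross-validated fitness separates signal from chance", {
  ## two clusters 10 sigma apart: near-zero error
  set.seed(21)
  X <- rbind(matrix(rnorm(100 * 3), 100), matrix(rnorm(100 * 3, 10), 100))
  y <- rep(1:2, each = 100)
  par <- c(n_estimators = 50L, max_depth = 10L, max_features = 2L)
  expect_lte(cv_fitness(par, X, y, seed = 1), 0.05)
  ## shuffled labels, 4 balanced classes: chance error ~ 0.75
  set.seed(22)
  Xr <- matrix(rnorm(200 * 5), 200)
  yr <- sample(rep(1:4, each = 50))
  f <- cv_fitness(par, Xr, yr, seed = 2)
  expect_equal(f, 0.75, tolerance = 0.08 / 0.75)
  ## determinism
  expect_identical(cv_fitness(par, Xr, yr, seed = 2), f)
  expect_error(cv_fitness(par, Xr[1:8, ], yr[1:8], k = 5),
               "fewer than")
})

test_that("tuning returns in-bounds parameters with a non-increasing history", {
  set.seed(23)
  X <- rbind(matrix(rnorm(60 * 4), 60), matrix(rnorm(60 * 4, 3), 60))
  y <- rep(1:2, each = 60)
  res <- tune_rf(X, y, n = 5, t_max = 6, seed = 3)
  sp <- rf_search_space()
  expect_true(all(res$params >= sp$lb & res$params <= sp$ub))
  expect_true(all(diff(res$history) <= 0))
  expect_gt(res$evaluations, 0)
})

test_that("tuned forests are no worse than default forests on held-out data", {
  accs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    spec <- fixture_spec("medium", samples_per_class = 30, wl_step = 10)
    task <- make_fused_task(spec, seed = s, cars_runs = 20)
    tr <- task$split$train; te <- task$split$test
    tuned <- tune_rf(task$fused$X[tr, ], task$fused$y[tr], n = 6,
                     t_max = 10, seed = s)
    m1 <- train_rf(task$fused$X[tr, ], task$fused$y[tr], tuned$params,
                   seed = s)
    m0 <- train_rf(task$fused$X[tr, ], task$fused$y[tr],
                   c(n_estimators = 100L, max_depth = 30L,
                     max_features = 4L), seed = s)
    accs[s, 1] <- evaluate_model(m1, task$fused$X[te, ],
                                 task$fused$y[te])$accuracy
    accs[s, 2] <- evaluate_model(m0, task$fused$X[te, ],
                                 task$fused$y[te])$accuracy
  }
  expect_gte(mean(accs[, 1]), mean(accs[, 2]) - 0.02)
})

test_that("binary confusion arithmetic matches the metric definitions", {
  ## TP=50 TN=40 FP=5 FN=5 on the positive class
  actual <- c(rep("pos", 55), rep("neg", 45))
  predicted <- c(rep("pos", 50), rep("neg", 5),
                 rep("pos", 5), rep("neg", 40))
  rep_ <- classification_report(actual, predicted,
                                levels = c("pos", "neg"))
  expect_equal(rep_$accuracy, 0.9)
  pc <- rep_$per_class
  expect_equal(pc$precision[pc$class == "pos"], 50 / 55,
               tolerance = 1e-12)
  expect_equal(pc$recall[pc$class == "pos"], 50 / 55, tolerance = 1e-12)
  expect_equal(pc$f1[pc$class == "pos"], 0.909091, tolerance = 1e-6)
})

test_that("perfect predictions give a diagonal confusion and unit metrics", {
  y <- rep(c("a", "b", "c"), times = c(5, 7, 3))
  rep_ <- classification_report(y, y)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$f1, 1)
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 0)
})

test_that("weighted recall equals accuracy on arbitrary predictions", {
  for (s in 1:5) {
    set.seed(s)
    actual <- sample(letters[1:4], 120, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1))
    predicted <- sample(letters[1:4], 120, replace = TRUE)
    rep_ <- suppressWarnings(classification_report(actual, predicted))
    expect_equal(rep_$recall, rep_$accuracy, tolerance = 1e-12)
    expect_equal(sum(rep_$confusion), 120)
    ## per-class F1 is the harmonic mean of per-class P and R
    pc <- rep_$per_class
    nz <- pc$precision + pc$recall > 0
    expect_equal(pc$f1[nz], 2 * pc$precision[nz] * pc$recall[nz] /
                   (pc$precision[nz] + pc$recall[nz]),
                 tolerance = 1e-12)
  }
})

test_that("report metrics are invariant to class relabelling", {
  set.seed(31)
  actual <- sample(1:3, 90, replace = TRUE)
  predicted <- ifelse(runif(90) < 0.8, actual, sample(1:3, 90, TRUE))
  r1 <- classification_report(actual, predicted)
  perm <- c(3, 1, 2)
  r2 <- classification_report(perm[actual], perm[predicted])
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$precision, r2$precision)
  expect_equal(r1$f1, r2$f1)
})

test_that("a class absent from predictions yields zero precision and a warning", {
  actual <- c("a", "a", "b", "b")
  predicted <- c("a", "a", "a", "a")
  expect_warning(rep_ <- classification_report(actual, predicted),
                 "absent")
  expect_equal(rep_$per_class$precision[rep_$per_class$class == "b"], 0)
})
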