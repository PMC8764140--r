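# Undersampling, splitting, folding, grid-searched fits, prediction.

test_that("undersampling yields an exact 1:1 ratio keeping all positives", {
  set.seed(61)
  lab <- c(rep("positive", 10), rep("negative", 100))
  x <- matrix(rnorm(110 * 3), 110, 3, dimnames = list(NULL, c("a","b","c")))
  fm <- kcr_features(x, lab)
  bal <- undersample_balance(fm, seed = 5)
  expect_identical(sum(bal$label == "positive"), 10L)
  expect_identical(sum(bal$label == "negative"), 10L)
  expect_true(all(fm$sample_id[fm$label == "positive"] %in% bal$sample_id))

  # already balanced: unchanged
  fm2 <- fm[1:20, ]
  expect_identical(undersample_balance(fm2, 1)$sample_id, fm2$sample_id)

  # determinism contract
  expect_identical(undersample_balance(fm, 5)$sample_id,
                   undersample_balance(fm, 5)$sample_id)
  expect_false(identical(undersample_balance(fm, 5)$sample_id,
                         undersample_balance(fm, 6)$sample_id))

  expect_error(undersample_balance(fm[fm$label == "negative", ], 1),
               "both classes")
})

test_that("train/test split is stratified, disjoint and exhaustive", {
  fm <- toy_features(n = 100, p = 3, seed = 7)
  sp <- train_test_split(fm, 0.8, seed = 3)
  expect_identical(nrow(sp$train$x), 80L)
  expect_identical(nrow(sp$test$x), 20L)
  expect_identical(sort(c(sp$train$sample_id, sp$test$sample_id)),
                   sort(fm$sample_id))
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  # class proportion within one sample of the input proportion
  for (part in sp) {
    expect_lte(abs(sum(part$label == "positive") -
                   0.5 * length(part$label)), 1)
  }
  expect_error(train_test_split(fm[c(1, 2, 4), ], 0.8, 1), "fewer than 2")
})

test_that("k-fold indices partition the samples with near-equal sizes", {
  f <- kfold_indices(10, 5, seed = 1)
  expect_identical(lengths(f), rep(2L, 5))
  f <- kfold_indices(11, 5, seed = 1)
  expect_identical(sort(lengths(f), decreasing = TRUE),
                   c(3L, 2L, 2L, 2L, 2L))
  expect_identical(sort(unlist(f)), 1:11)
  expect_error(kfold_indices(3, 5), "exceeds")
})

test_that("grid search picks the single point of a one-point grid", {
  fm <- toy_features(n = 40, p = 4, seed = 8)
  fit <- kcr_fit(fm, "svm", grid = data.frame(C = 4, gamma = 0.25),
                 k = 4, seed = 2)
  expect_identical(fit$best$C, 4)
  expect_identical(fit$best$gamma, 0.25)
})

test_that("separable toy data is fit perfectly by every classifier", {
  fm <- toy_features(n = 60, p = 4, seed = 9, signal = 6)
  for (cl in c("svm", "rf", "lr")) {
    grid <- switch(cl, svm = data.frame(C = c(1, 16), gamma = 0.1),
                   rf = data.frame(num_trees = 300), lr = NULL)
    fit <- kcr_fit(fm, cl, grid = grid, k = 3, seed = 4)
    lab <- predict(fit, fm, type = "label")
    expect_identical(as.character(lab), as.character(fm$label))
    s <- predict(fit, fm)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all((s >= 0.5) == (fm$label == "positive")))
  }
})

test_that("chosen point is invariant to grid enumeration order modulo ties", {
  fm <- toy_features(n = 50, p = 4, seed = 10, signal = 1)
  g1 <- expand.grid(gamma = c(0.01, 0.1), C = c(1, 8))[, c("C", "gamma")]
  fit1 <- kcr_fit(fm, "svm", grid = g1, k = 5, seed = 6)
  # exhaustive re-evaluation: best mean CV AUC equals the fit's choice
  best_cv <- max(fit1$cv)
  expect_equal(fit1$cv[fit1$best_index], best_cv)
  expect_identical(fit1$best_index, which.max(fit1$cv))
})

test_that("prediction enforces the training column contract", {
  fm <- toy_features(n = 40, p = 4, seed = 11)
  fit <- kcr_fit(fm, "lr", k = 4, seed = 1)
  # permuted columns are fine
  x2 <- fm$x[, rev(colnames(fm$x))]
  expect_equal(predict(fit, x2), predict(fit, fm$x), tolerance = 1e-12)
  expect_error(predict(fit, fm$x[, 1:3]), "missing")
  x3 <- cbind(fm$x, junk = 1)
  expect_error(predict(fit, x3), "extra")
  # identical rows get identical scores
  s <- predict(fit, fm$x[c(1, 1), ])
  expect_identical(s[1], s[2])
})

test_that("fits are deterministic under fixed seeds", {
  fm <- toy_features(n = 50, p = 4, seed = 12)
  for (cl in c("svm", "rf", "lr")) {
    grid <- switch(cl, svm = data.frame(C = 2, gamma = 0.1),
                   rf = data.frame(num_trees = 200), lr = NULL)
    f1 <- kcr_fit(fm, cl, grid = grid, k = 5, seed = 3)
    f2 <- kcr_fit(fm, cl, grid = grid, k = 5, seed = 3)
    expect_identical(f1$cv, f2$cv)
    expect_identical(predict(f1, fm), predict(f2, fm))
  }
})

test_that("single-class folds are rejected with advice", {
  lab <- c(rep("positive", 3), rep("negative", 37))
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  fm <- kcr_features(x, lab)
  expect_error(kcr_fit(fm, "lr", k = 10, seed = 1), "smaller k")
})
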