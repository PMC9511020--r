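test_that("stratified split hits the per-group 20% quota within one subject", {
  man <- make_manifest(c(172, 152, 154, 160))
  plan <- stratified_split(man, ratio = 0.2, seed = 17)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_setequal(c(plan$train_ids, plan$test_ids), man$subject_id)
  test_counts <- table(man$group[man$subject_id %in% plan$test_ids])
  expect_true(test_counts[["young"]] %in% 34:35)
  expect_true(test_counts[["adult"]] %in% 30:31)
  expect_true(test_counts[["middle_old"]] %in% 30:31)
  expect_identical(unname(test_counts[["old"]]), 32L)
  # sex stays balanced within each group's test quota
  sex_tab <- table(man$sex[man$subject_id %in% plan$test_ids])
  expect_lt(abs(sex_tab[["F"]] - sex_tab[["M"]]), 6)
})

test_that("stratified split is deterministic and validates group sizes", {
  man <- make_manifest(c(10, 10, 10, 10))
  a <- stratified_split(man, seed = 18)
  b <- stratified_split(man, seed = 18)
  expect_identical(a$test_ids, b$test_ids)

  one_group <- data.frame(subject_id = paste0("s", 1:10), age = 25,
                          group = factor(rep("young", 10)))
  plan <- stratified_split(one_group, ratio = 0.2, seed = 19)
  expect_length(plan$test_ids, 2)

  tiny <- data.frame(subject_id = c("a", "b"), age = c(25, 75),
                     group = factor(c("young", "old")))
  expect_error(stratified_split(tiny), "fewer than 2")
})

test_that("cv folds partition subjects with balanced class counts", {
  man <- make_manifest(c(40, 41, 39, 43))
  folds <- cv_folds(man, k = 5, seed = 20)
  expect_setequal(unlist(folds), man$subject_id)
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  for (g in age_group_levels()) {
    per_fold <- vapply(folds, function(f)
      sum(man$group[man$subject_id %in% f] == g), numeric(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_identical(cv_folds(man, k = 5, seed = 20), folds)

  # k = 2 on 8 balanced subjects: one subject per class per fold
  man8 <- make_manifest(c(2, 2, 2, 2))
  folds2 <- cv_folds(man8, k = 2, seed = 21)
  expect_identical(lengths(folds2), c(4L, 4L))
  for (f in folds2)
    expect_equal(as.vector(table(man8$group[man8$subject_id %in% f])),
                 rep(1L, 4))
})

test_that("classification metrics count correctly", {
  lv <- age_group_levels()
  y <- factor(rep(lv, each = 2), levels = lv)
  expect_equal(evaluate_classification(y, y)$accuracy, 100)
  constant <- factor(rep("young", 8), levels = lv)
  expect_equal(evaluate_classification(constant, y)$accuracy, 25)
  five_right <- y
  five_right[c(4, 6, 8)] <- "young"  # break 3 of 8
  expect_equal(evaluate_classification(five_right, y)$accuracy, 62.5)
  m <- evaluate_classification(five_right, y)
  expect_identical(unname(rowSums(m$confusion)), rep(2, 4))
  expect_error(evaluate_classification(factor(character(0)),
                                       factor(character(0))), "empty")
})

test_that("regression metrics match hand computations", {
  m <- evaluate_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mae, m$rmse, m$r2), c(0, 0, 1))
  m <- evaluate_regression(c(5, 5), c(0, 10))
  expect_equal(c(m$mae, m$rmse, m$r2), c(5, 5, 0))
  m <- evaluate_regression(c(2, 3, 4), c(1, 2, 3))
  expect_equal(c(m$mae, m$rmse, m$r2), c(1, 1, -0.5))
  expect_error(evaluate_regression(c(1, 2), c(5, 5)), "zero variance")
  expect_error(evaluate_regression(1, 1), "at least 2")
})

test_that("rmse dominates mae on random prediction vectors", {
  set.seed(22)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    y <- rnorm(n, 50, 20)
    yhat <- y + rnorm(n, sd = runif(1, 0.1, 10))
    m <- evaluate_regression(yhat, y)
    expect_gte(m$rmse, m$mae)
    expect_gte(m$mae, 0)
    expect_lte(m$r2, 1)
  }
})

test_that("zero-epoch fits return the untouched initialization", {
  x <- array(rnorm(16 * 16 * 12), c(16, 16, 12))
  y <- factor(rep(age_group_levels(), 3))
  fit <- ayu_net(x, y, architecture = "vgg5", epochs = 0, seed = 23)
  ref <- build_model("vgg5", p = 16, task = "classification",
                     n_classes = 4, seed = 23,
                     class_levels = age_group_levels())
  expect_identical(fit$model$params, ref$params)
  expect_length(fit$loss_trace, 0)
})

test_that("training is reproducible and reduces the loss on planted signal", {
  cohort <- generate_cohort(sim_config(n_subjects = 48L, p = 16L,
                                       n_timepoints = 120L), seed = 24)
  x <- cohort_sfc(cohort)
  y <- cohort$manifest$group
  fit1 <- ayu_net(x, y, architecture = "vgg5", epochs = 4, seed = 25)
  fit2 <- ayu_net(x, y, architecture = "vgg5", epochs = 4, seed = 25)
  expect_identical(fit1$model$params, fit2$model$params)
  fit3 <- ayu_net(x, y, architecture = "vgg5", epochs = 4, seed = 26)
  expect_false(identical(fit3$model$params, fit1$model$params))
  expect_lt(tail(fit1$loss_trace, 1), fit1$loss_trace[1])
})

test_that("predictions are deterministic, labelled, and shape-checked", {
  cohort <- generate_cohort(sim_config(n_subjects = 24L, p = 16L,
                                       n_timepoints = 60L), seed = 27)
  x <- cohort_sfc(cohort)
  fit <- ayu_net(x, cohort$manifest$group, architecture = "vgg5",
                 epochs = 2, seed = 28)
  p1 <- predict(fit, x, type = "prob")
  p2 <- predict(fit, x, type = "prob")
  expect_identical(p1, p2)
  expect_identical(colnames(p1), age_group_levels())
  cls <- predict(fit, x, type = "class")
  expect_true(all(cls %in% age_group_levels()))
  # batch independence through the scaler + forward stack
  single <- predict(fit, x[, , 3], type = "prob")
  expect_lt(max(abs(single - p1[3, ])), 1e-6)
  expect_error(predict(fit, array(rnorm(8 * 8 * 2), c(8, 8, 2))),
               "fitted for p")
  lam <- attr(predict(fit, x[, , 1:5], attention_weights = TRUE),
              "attention")
  for (l in lam) {
    expect_true(all(l >= 0))
    expect_lt(max(abs(colSums(l) - 1)), 1e-6)
  }
})

test_that("cross-validation averages fold metrics and is seeded", {
  cohort <- generate_cohort(sim_config(n_subjects = 32L, p = 16L,
                                       n_timepoints = 60L), seed = 29)
  x <- cohort_sfc(cohort)
  y <- cohort$manifest$group
  cv <- cross_validate(x, y, k = 2, seed = 30, architecture = "vgg5",
                       epochs = 1)
  expect_identical(rownames(cv$folds), c("fold1", "fold2", "mean"))
  expect_equal(cv$folds["mean", "accuracy"],
               mean(cv$folds[1:2, "accuracy"]), tolerance = 1e-9)
  cv2 <- cross_validate(x, y, k = 2, seed = 30, architecture = "vgg5",
                        epochs = 1)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$folds, cv2$folds)
})
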