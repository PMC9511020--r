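#' Stratified train/test split
#'
#' Splits subjects 80:20 (by default) within each age group (and, when a
#' `sex` column is present, within each age-group x sex cell), so that the
#' test fraction of every group deviates from the target ratio by at most
#' one subject.  Deterministic under `seed`.
#'
#' @param manifest Data frame with `subject_id` and `group` (and optionally
#'   `sex`) columns, e.g. from [read_manifest()] or [generate_cohort()].
#' @param ratio Test fraction (default 0.2).
#' @param seed Integer seed.
#' @return List of class `split_plan` with `train_ids`, `test_ids`,
#'   `ratio`, `seed`.
#' @export
stratified_split <- function(manifest, ratio = 0.2, seed = 1L) {
  if (!all(c("subject_id", "group") %in% names(manifest)))
    stop("manifest needs subject_id and group columns")
  sizes <- table(manifest$group)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  strata <- if ("sex" %in% names(manifest))
    interaction(manifest$group, manifest$sex, drop = TRUE)
  else factor(manifest$group)
  test_ids <- character(0L)
  for (g in levels(factor(manifest$group))) {
    in_g <- manifest$group == g
    n_test <- round(ratio * sum(in_g))
    # fill the group's quota stratum by stratum, largest first, so sex
    # stays balanced while the per-group count is exact
    ids_by_stratum <- split(manifest$subject_id[in_g],
                            droplevels(strata[in_g]))
    ids_by_stratum <- ids_by_stratum[order(-lengths(ids_by_stratum))]
    sizes_s <- lengths(ids_by_stratum)
    alloc <- floor(n_test * sizes_s / sum(sizes_s))
    rem <- n_test - sum(alloc)
    if (rem > 0)
      alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    for (k in seq_along(ids_by_stratum)) {
      ids <- ids_by_stratum[[k]]
      test_ids <- c(test_ids, sample(ids, min(alloc[k], length(ids))))
    }
  }
  structure(list(train_ids = setdiff(manifest$subject_id, test_ids),
                 test_ids = test_ids, ratio = ratio, seed = seed),
            class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Assigns subjects to `k` folds so that each fold's class counts differ
#' from a perfect partition by at most one subject per class.
#'
#' @inheritParams stratified_split
#' @param k Number of folds (default 5).
#' @return List of `k` character vectors of subject ids (the held-out set
#'   of each fold).
#' @export
cv_folds <- function(manifest, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- vector("list", k)
  for (g in levels(factor(manifest$group))) {
    ids <- sample(manifest$subject_id[manifest$group == g])
    fi <- rep_len(seq_len(k), length(ids))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], ids[fi == f])
  }
  folds
}

#' Classification metrics
#'
#' @param predicted Factor (or character) of predicted group labels.
#' @param truth Factor of true labels.
#' @return List of class `ayu_metrics` with `accuracy` (percent) and the
#'   `confusion` table (rows = truth).
#' @export
evaluate_classification <- function(predicted, truth) {
  if (length(truth) == 0L) stop("empty test set")
  if (length(predicted) != length(truth))
    stop("prediction/truth length mismatch")
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  acc <- 100 * mean(predicted == truth, na.rm = FALSE)
  structure(list(accuracy = acc,
                 confusion = table(truth = truth, predicted = predicted),
                 n = length(truth)),
            class = "ayu_metrics")
}

#' Regression metrics
#'
#' Mean absolute error, root-mean-square error, and the coefficient of
#' determination `r2 = 1 - SS_res / SS_tot` (which can be negative).  The
#' squared Pearson correlation is reported alongside as `r2_pearson` since
#' the two are often conflated.
#'
#' @param predicted Numeric predicted ages.
#' @param truth Numeric true ages (must have positive variance, `n >= 2`).
#' @return List of class `ayu_metrics` with `mae`, `rmse`, `r2`,
#'   `r2_pearson`, `n`.
#' @export
evaluate_regression <- function(predicted, truth) {
  if (length(truth) < 2L) stop("need at least 2 observations")
  if (length(predicted) != length(truth))
    stop("prediction/truth length mismatch")
  predicted <- as.numeric(predicted)
  truth <- as.numeric(truth)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("r2 undefined: zero variance in true values")
  err <- predicted - truth
  structure(list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 r2 = 1 - sum(err^2) / ss_tot,
                 r2_pearson = suppressWarnings(stats::cor(predicted,
                                                          truth))^2,
                 n = length(truth)),
            class = "ayu_metrics")
}

#' @export
print.ayu_metrics <- function(x, ...) {
  if (!is.null(x$accuracy)) {
    cat(sprintf("accuracy: %.3f%% (n = %d)\n", x$accuracy, x$n))
    print(x$confusion)
  } else {
    cat(sprintf("mae %.3f  rmse %.3f  r2 %.3f  (n = %d)\n",
                x$mae, x$rmse, x$r2, x$n))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of a network configuration
#'
#' Trains a fresh, freshly initialized network per fold and evaluates it on
#' the held-out fold; the `mean` row is the arithmetic mean of the fold
#' rows.
#'
#' @param x `p x p x n` array of connectivity matrices.
#' @param y Labels (factor) or ages (numeric).
#' @param groups Stratification labels; defaults to `y` for classification
#'   and to [assign_age_group()] of `y` for regression.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and per-fold training (fold `f`
#'   trains with `seed + f`).
#' @param ... Passed to [ayu_net()] (architecture, attention, epochs, ...).
#' @return List with `folds` (data frame of per-fold metrics plus the mean
#'   row) and `assignments`.
#' @export
cross_validate <- function(x, y, groups = NULL, k = 5L, seed = 1L, ...) {
  x <- as_sfc_array(x)
  n <- dim(x)[3L]
  task <- if (is.factor(y) || is.character(y)) "classification"
          else "regression"
  if (is.null(groups))
    groups <- if (task == "classification") factor(y)
              else assign_age_group(y)
  manifest <- data.frame(subject_id = as.character(seq_len(n)),
                         group = groups)
  folds <- cv_folds(manifest, k = k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- as.integer(folds[[f]])
    train_idx <- setdiff(seq_len(n), test_idx)
    if (task == "classification" &&
        !all(levels(factor(y)) %in% unique(y[train_idx])))
      stop("fold ", f, " is missing a class in its training partition")
    fit <- ayu_net(x[, , train_idx, drop = FALSE], y[train_idx],
                   seed = seed + f, ...)
    pred <- predict(fit, x[, , test_idx, drop = FALSE])
    m <- if (task == "classification")
      evaluate_classification(pred, y[test_idx])
    else evaluate_regression(pred, y[test_idx])
    rows[[f]] <- if (task == "classification")
      data.frame(fold = f, accuracy = m$accuracy, n = m$n)
    else data.frame(fold = f, mae = m$mae, rmse = m$rmse, r2 = m$r2,
                    n = m$n)
  }
  df <- do.call(rbind, rows)
  mean_row <- df[1L, , drop = FALSE]
  mean_row$fold <- NA
  for (cn in setdiff(names(df), "fold"))
    mean_row[[cn]] <- mean(df[[cn]])
  out <- rbind(df, mean_row)
  rownames(out) <- c(paste0("fold", seq_len(k)), "mean")
  list(folds = out, assignments = folds)
}
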