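#' Fit an attention-augmented convolutional network on connectivity matrices
#'
#' The package's central estimator.  Takes a stack of static
#' functional-connectivity matrices and either age-group labels
#' (classification, softmax head with cross-entropy loss) or chronological
#' ages (regression, linear head with squared-error loss), standardizes each
#' matrix entry across the training subjects, and trains a VGG5 or ResNet5
#' trunk with optional attention blocks by mini-batch Adam.  Everything is
#' seeded: two calls with identical inputs and `seed` return identical
#' weights.
#'
#' @param x `p x p x n` array of connectivity matrices (e.g. from
#'   [cohort_sfc()]), or a list of `p x p` matrices.
#' @param y Factor of group labels (classification) or numeric ages
#'   (regression).
#' @param task `"classification"` or `"regression"`; inferred from `y`
#'   when missing.
#' @param architecture `"resnet5"` (default) or `"vgg5"`.
#' @param attention Logical; `FALSE` gives the unaugmented ablation
#'   (uniform attention weights, no attention parameters).
#' @param epochs Training epochs (default 100); `epochs = 0` returns the
#'   Kaiming-initialized network untouched.
#' @param batch_size Mini-batch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed covering initialization and batch shuffling.
#' @param scale `"edge"` (default): per-edge z-scoring with training
#'   moments, applied identically at prediction time; `"none"`: raw
#'   correlations.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `ayu_net`: the trained model, its scaler, the
#'   per-epoch `loss_trace`, and the call configuration.  Methods:
#'   [predict.ayu_net()], `print`, `summary`, `coef` (list of weight
#'   arrays), `plot` (loss trace), `residuals` (regression).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(sim_config(n_subjects = 60, p = 16,
#'                                      n_timepoints = 100), seed = 1)
#' x <- cohort_sfc(cohort)
#' fit <- ayu_net(x, cohort$manifest$group, architecture = "vgg5",
#'                epochs = 2, seed = 1)
#' print(fit)
#' }
#' @export
ayu_net <- function(x, y, task = NULL,
                    architecture = c("resnet5", "vgg5"), attention = TRUE,
                    epochs = 100L, batch_size = 16L, lr = 1e-3, seed = 1L,
                    scale = c("edge", "none"), verbose = FALSE) {
  architecture <- match.arg(architecture)
  scale <- match.arg(scale)
  x <- as_sfc_array(x)
  n <- dim(x)[3L]
  p <- dim(x)[1L]
  if (length(y) != n) stop("length(y) does not match number of matrices")
  if (is.null(task))
    task <- if (is.factor(y) || is.character(y)) "classification"
            else "regression"
  task <- match.arg(task, c("classification", "regression"))
  if (task == "classification") {
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    levels_y <- levels(y)
    yi <- as.integer(y)
    n_out <- length(levels_y)
    if (n_out < 2L) stop("classification needs at least 2 classes")
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop("missing values in y")
    levels_y <- NULL
    n_out <- 1L
  }

  scaler <- if (scale == "edge") {
    std <- standardize_features(x)
    x <- std$train
    list(center = matrix(std$center, p, p), scale = matrix(std$scale, p, p),
         zero_variance = matrix(std$zero_variance, p, p))
  }

  net <- build_model(architecture, p = p, task = task, n_classes = n_out,
                     attention = attention, seed = seed,
                     class_levels = levels_y)

  loss_trace <- numeric(0L)
  if (epochs > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed + 1L)
    opt <- adam_state(net$params, lr = lr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        nb <- length(idx)
        xb <- array(x[, , idx], dim = c(p, p, 1L, nb))
        fwd <- nn_forward(net, xb, want_cache = TRUE)
        if (task == "classification") {
          pb <- fwd$prob
          li <- -log(pmax(pb[cbind(seq_len(nb), yi[idx])], 1e-12))
          loss <- mean(li)
          dz <- pb
          dz[cbind(seq_len(nb), yi[idx])] <-
            dz[cbind(seq_len(nb), yi[idx])] - 1
          dz <- dz / nb
        } else {
          err <- fwd$z[, 1L] - y[idx]
          loss <- mean(err^2)
          dz <- matrix(2 * err / nb, ncol = 1L)
        }
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               " (batch starting at ", b0, "); try a smaller learning rate")
        bwd <- nn_backward(net, fwd, dz)
        upd <- adam_step(opt, net$params, bwd$grads)
        net$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + loss * nb
      }
      loss_trace[ep] <- ep_loss / n
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f", ep, loss_trace[ep]))
    }
  }

  structure(list(model = net, scaler = scaler, task = task,
                 architecture = architecture, attention = attention,
                 loss_trace = loss_trace,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, seed = seed, scale = scale),
                 class_levels = levels_y, p = p, n_train = n),
            class = "ayu_net")
}

as_sfc_array <- function(x) {
  if (is.list(x) && !is.array(x)) {
    p <- nrow(x[[1L]])
    x <- array(unlist(lapply(x, unclass), use.names = FALSE),
               dim = c(p, p, length(x)))
  }
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("x must be a p x p x n array or a list of p x p matrices")
  if (dim(x)[1L] != dim(x)[2L]) stop("matrices must be square")
  unclass(x)
}

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (name in names(params)) {
    g <- grads[[name]]
    if (is.null(g)) next
    state$m[[name]] <- state$beta1 * state$m[[name]] + (1 - state$beta1) * g
    state$v[[name]] <- state$beta2 * state$v[[name]] +
      (1 - state$beta2) * g^2
    params[[name]] <- params[[name]] - state$lr *
      (state$m[[name]] / bc1) / (sqrt(state$v[[name]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

apply_scaler <- function(fit, x) {
  if (is.null(fit$scaler)) return(x)
  n <- dim(x)[3L]
  ctr <- as.vector(fit$scaler$center)
  scl <- as.vector(fit$scaler$scale)
  m <- matrix(x, length(ctr), n)
  array((m - ctr) / scl, dim = dim(x))
}

#' Predict from a fitted network
#'
#' Deterministic given the fitted weights, and batch-size independent: the
#' same subjects give the same outputs whether fed singly or together.
#'
#' @param object An [ayu_net()] fit.
#' @param newdata `p x p x n` array, list of matrices, or a single `p x p`
#'   matrix.
#' @param type `"class"` (default for classification), `"prob"` for class
#'   probabilities, `"response"` for the regression output (default for
#'   regression) or the probability matrix.
#' @param attention_weights If `TRUE`, attach the per-layer attention
#'   weight matrices as an attribute.
#' @param batch_size Internal forward batch size.
#' @param ... Unused.
#' @return Factor, probability matrix, or numeric vector.
#' @export
predict.ayu_net <- function(object, newdata, type = NULL,
                            attention_weights = FALSE, batch_size = 64L,
                            ...) {
  if (is.matrix(newdata) && length(dim(newdata)) == 2L)
    newdata <- array(unclass(newdata), dim = c(dim(newdata), 1L))
  x <- as_sfc_array(newdata)
  if (dim(x)[1L] != object$p)
    stop("input matrices are ", dim(x)[1L], " x ", dim(x)[1L],
         " but the model was fitted for p = ", object$p)
  if (is.null(type))
    type <- if (object$task == "classification") "class" else "response"
  type <- match.arg(type, c("class", "prob", "response"))
  x <- apply_scaler(object, x)
  n <- dim(x)[3L]
  p <- object$p
  zs <- NULL
  lam <- list()
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    xb <- array(x[, , idx], dim = c(p, p, 1L, length(idx)))
    fwd <- nn_forward(object$model, xb, want_cache = FALSE)
    zs <- rbind(zs, fwd$z)
    if (attention_weights) lam[[length(lam) + 1L]] <- fwd$lambda
  }
  out <- if (object$task == "classification") {
    pb <- softmax_rows(zs)
    colnames(pb) <- object$class_levels
    switch(type,
           class = factor(object$class_levels[max.col(pb, "first")],
                          levels = object$class_levels),
           prob = pb,
           response = pb)
  } else {
    if (type == "prob") stop("type = 'prob' is only for classification")
    as.vector(zs)
  }
  if (attention_weights) {
    merged <- lapply(names(lam[[1L]]), function(id)
      do.call(cbind, lapply(lam, `[[`, id)))
    names(merged) <- names(lam[[1L]])
    attr(out, "attention") <- merged
  }
  out
}

#' @export
print.ayu_net <- function(x, ...) {
  cat(sprintf("ayu %s (%s%s), p = %d, task = %s\n",
              x$architecture,
              if (x$attention) "with attention" else "no attention",
              "", x$p, x$task))
  cat(sprintf("  %d parameters, trained %d epoch(s) on %d subjects\n",
              model_param_count(x$model), length(x$loss_trace), x$n_train))
  if (length(x$loss_trace))
    cat(sprintf("  final training loss %.4f\n", utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.ayu_net <- function(object, ...) {
  print(object)
  cat("  layers:\n")
  for (name in names(object$model$params)) {
    p <- object$model$params[[name]]
    cat(sprintf("    %-10s %s\n", name,
                paste(if (is.matrix(p)) dim(p) else length(p),
                      collapse = " x ")))
  }
  invisible(object)
}

#' @export
coef.ayu_net <- function(object, ...) object$model$params

#' @export
plot.ayu_net <- function(x, ...) {
  if (!length(x$loss_trace)) stop("no training epochs to plot")
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b", xlab = "epoch",
       ylab = "training loss",
       main = sprintf("%s (%s)", x$architecture,
                      if (x$attention) "attention" else "no attention"), ...)
  invisible(x)
}

#' @export
residuals.ayu_net <- function(object, newdata, y, ...) {
  if (object$task != "regression")
    stop("residuals are defined for regression fits")
  predict(object, newdata) - as.numeric(y)
}
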