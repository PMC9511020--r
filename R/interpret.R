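#' Integrated-gradients quadrature along a straight path
#'
#' Low-level Riemann-sum approximation of the path integral: for each
#' feature `i`,
#' `attr_i = (x_i - x'_i) * (1/m) * sum_k grad_i(x' + (k/m) (x - x'))`,
#' with `k = 1..m`.  For a model with constant gradient (a linear model)
#' the quadrature is exact for any `m >= 1`.
#'
#' @param grad_fn Function mapping an input (same shape as `x`) to the
#'   gradient of the scalar model output at that input.
#' @param x Input (numeric vector or matrix).
#' @param baseline Baseline `x'`, defaults to all zeros.
#' @param steps Number of interpolation steps `m`.
#' @return Attributions, same shape as `x`.
#' @export
integrated_gradients_path <- function(grad_fn, x, baseline = NULL,
                                      steps = 50L) {
  if (steps < 1L) stop("steps must be >= 1")
  if (is.null(baseline)) baseline <- x * 0
  acc <- x * 0
  for (k in seq_len(steps)) {
    g <- grad_fn(baseline + (k / steps) * (x - baseline))
    if (any(!is.finite(g)))
      stop("non-finite gradient at interpolation step ", k)
    acc <- acc + g
  }
  (x - baseline) * acc / steps
}

#' Integrated-gradient attribution of a fitted network
#'
#' Attributes the model's scalar output — the softmax probability of the
#' predicted (or a chosen) class, optionally its pre-softmax logit, or the
#' regression output — to every entry of the input connectivity matrix, by
#' integrating the input gradient along the straight path from an all-zero
#' baseline matrix to the input.  The path runs in the network's input
#' space: with the default per-edge scaling, the all-zero baseline is the
#' training-mean connectome (every edge at its average value), which keeps
#' the interpolated inputs inside the distribution the network was trained
#' on.  A user-supplied `baseline` is given in the same units as `x` and
#' standardized the same way, so passing a zero matrix reproduces the
#' literal raw-zero baseline; with `scale = "none"` fits the two readings
#' coincide.  The raw attribution is folded to a symmetric matrix: the
#' upper and lower contributions of each undirected edge are summed and
#' mirrored.
#'
#' The completeness property (attributions summing to
#' `F(x) - F(baseline)`) is checked; if the relative error exceeds
#' `completeness_tol` the number of steps is doubled, up to `max_steps`.
#'
#' @param model An [ayu_net()] fit.
#' @param x A single `p x p` connectivity matrix (raw correlations).
#' @param target For classification, the class (label or index) to
#'   attribute; default the model's predicted class.
#' @param output `"prob"` (default) attributes the softmax probability,
#'   `"logit"` the pre-softmax score; ignored for regression.
#' @param baseline Baseline matrix in the units of `x`; default `NULL`
#'   means all zeros in the network's input space (see Details above).
#' @param steps Interpolation steps `m` (default 50).
#' @param completeness_tol Relative completeness tolerance triggering step
#'   escalation (default 0.05); set to `Inf` to disable.
#' @param max_steps Escalation ceiling (default 800).
#' @return `p x p` symmetric attribution matrix of class
#'   `attribution_matrix`, with attributes `target`, `steps`, `sum`
#'   (total attribution) and `delta_F` (`F(x) - F(baseline)`).
#' @export
integrated_gradients <- function(model, x, target = NULL,
                                 output = c("prob", "logit"),
                                 baseline = NULL, steps = 50L,
                                 completeness_tol = 0.05,
                                 max_steps = 800L) {
  output <- match.arg(output)
  stopifnot(inherits(model, "ayu_net"))
  x <- unclass(as.matrix(x))
  p <- nrow(x)
  if (p != model$p) stop("matrix dimension does not match the model")

  # move input and baseline into the network's input space
  std1 <- function(m)
    apply_scaler(model, array(unclass(as.matrix(m)),
                              dim = c(p, p, 1L)))[, , 1L]
  xs <- std1(x)
  bs <- if (is.null(baseline)) matrix(0, p, p) else std1(baseline)

  if (model$task == "classification") {
    cls <- if (is.null(target)) {
      as.character(predict(model, x, type = "class"))
    } else if (is.numeric(target)) model$class_levels[target]
    else as.character(target)
    ci <- match(cls, model$class_levels)
    if (is.na(ci)) stop("unknown target class: ", cls)
  } else {
    ci <- NA_integer_
    cls <- "regression"
  }

  # gradient of F wrt the network input, batched over interpolation steps
  grad_batch <- function(mats) {
    nm <- length(mats)
    xb <- array(unlist(mats, use.names = FALSE), dim = c(p, p, 1L, nm))
    fwd <- nn_forward(model$model, xb, want_cache = TRUE)
    dz <- if (model$task == "regression") {
      matrix(1, nm, 1L)
    } else if (output == "logit") {
      dzm <- matrix(0, nm, length(model$class_levels))
      dzm[, ci] <- 1
      dzm
    } else {
      pb <- fwd$prob
      dzm <- -pb * pb[, ci]
      dzm[, ci] <- dzm[, ci] + pb[, ci]
      dzm
    }
    bwd <- nn_backward(model$model, fwd, dz)
    array(bwd$dx, dim = c(p, p, nm))
  }

  run_ig <- function(m_steps) {
    alphas <- seq_len(m_steps) / m_steps
    # keep forward batches moderate
    acc <- matrix(0, p, p)
    for (chunk in split(alphas, ceiling(seq_along(alphas) / 64L))) {
      mats <- lapply(chunk, function(a) bs + a * (xs - bs))
      g <- grad_batch(mats)
      if (any(!is.finite(g)))
        stop("non-finite gradient during integrated-gradients steps")
      acc <- acc + rowSums(g, dims = 2L)
    }
    (xs - bs) * acc / m_steps
  }

  Fx <- ig_scalar_output(model, xs, ci, output)
  F0 <- ig_scalar_output(model, bs, ci, output)
  m_use <- as.integer(steps)
  repeat {
    attr_raw <- run_ig(m_use)
    total <- sum(attr_raw)
    rel_err <- if (abs(Fx - F0) > 1e-12)
      abs(total - (Fx - F0)) / abs(Fx - F0) else 0
    if (rel_err <= completeness_tol || m_use >= max_steps) break
    m_use <- min(max_steps, m_use * 2L)
  }

  folded <- attr_raw + t(attr_raw)
  diag(folded) <- diag(attr_raw)
  dimnames(folded) <- dimnames(x)
  structure(folded, class = c("attribution_matrix", "matrix", "array"),
            target = cls, steps = m_use, sum = total, delta_F = Fx - F0)
}

# scalar model output on an already-standardized input matrix
ig_scalar_output <- function(model, m, ci, output) {
  fwd <- nn_forward(model$model,
                    array(m, dim = c(model$p, model$p, 1L, 1L)),
                    want_cache = FALSE)
  if (model$task == "regression") return(fwd$z[1L, 1L])
  if (output == "logit") fwd$z[1L, ci] else fwd$prob[1L, ci]
}

#' Group-mean attribution (or connectivity) matrices
#'
#' Elementwise arithmetic mean of per-subject matrices within each age
#' group.
#'
#' @param matrices List (or `p x p x n` array) of symmetric matrices.
#' @param groups Factor of group labels, one per matrix; every level must
#'   be non-empty.
#' @return Named list of group-mean matrices, one per level.
#' @export
mean_group_attribution <- function(matrices, groups) {
  if (is.array(matrices) && length(dim(matrices)) == 3L) {
    matrices <- lapply(seq_len(dim(matrices)[3L]),
                       function(i) matrices[, , i])
  }
  if (!is.factor(groups)) groups <- factor(groups)
  if (length(matrices) != length(groups))
    stop("matrices/groups length mismatch")
  out <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty group: ", g)
    out[[g]] <- Reduce(`+`, matrices[idx]) / length(idx)
  }
  out
}

#' Signed node strength of an attribution matrix
#'
#' For each ROI, sums the positive and the negative attributions of its
#' incident edges (diagonal excluded); `net = positive + negative`.
#' Summing `net` over all nodes equals twice the sum of the per-edge
#' attributions, since every edge is incident to two nodes.
#'
#' @param attr Symmetric `p x p` matrix (attributions or any edge
#'   strengths).
#' @return Data frame with `roi`, `positive`, `negative`, `net`.
#' @export
node_strength <- function(attr) {
  attr <- as.matrix(attr)
  if (nrow(attr) != ncol(attr)) stop("attribution matrix must be square")
  off <- attr
  diag(off) <- 0
  pos <- rowSums(pmax(off, 0))
  neg <- rowSums(pmin(off, 0))
  rois <- rownames(attr)
  if (is.null(rois)) rois <- paste0("ROI_", seq_len(nrow(attr)))
  data.frame(roi = rois, positive = pos, negative = neg, net = pos + neg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge contribution table across age groups
#'
#' One row per undirected edge with one strength column per age group;
#' edges whose absolute strength stays below `threshold` in every group
#' are omitted (the printed-table omission rule).
#'
#' @param group_mats Named list of symmetric `p x p` strength matrices,
#'   one per age group, on a common parcellation.
#' @param atlas Optional atlas lookup ([read_atlas()] format); every ROI
#'   label must resolve, and network columns are added.
#' @param threshold Omission threshold (default 0.2).
#' @return Data frame with `roi1`, `roi2`, one column per group, and
#'   (with an atlas) `network1`, `network2`.
#' @export
edge_contribution_table <- function(group_mats, atlas = NULL,
                                    threshold = 0.2) {
  stopifnot(is.list(group_mats), length(group_mats) >= 1L)
  p <- nrow(group_mats[[1L]])
  rois <- rownames(group_mats[[1L]])
  if (is.null(rois)) rois <- paste0("ROI_", seq_len(p))
  if (!is.null(atlas)) {
    unknown <- setdiff(rois, atlas$roi_label)
    if (length(unknown))
      stop("unknown ROI label(s): ", paste(unknown, collapse = ", "))
  }
  map <- lower_triangle_index(p)
  vals <- vapply(group_mats, function(m) as.matrix(m)[map],
                 numeric(nrow(map)))
  keep <- apply(abs(as.matrix(vals)) >= threshold, 1L, any)
  df <- data.frame(roi1 = rois[map[keep, 1L]], roi2 = rois[map[keep, 2L]],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(as.matrix(vals)[keep, , drop = FALSE]))
  if (!is.null(atlas)) {
    df$network1 <- atlas$network[match(df$roi1, atlas$roi_label)]
    df$network2 <- atlas$network[match(df$roi2, atlas$roi_label)]
  }
  rownames(df) <- NULL
  df
}

#' Classify a 4-point age trajectory
#'
#' Given one value per age group (young, adult, middle-old, old, in that
#' order), labels the profile:
#'
#' * `decreasing` — every successive step decreases, or increases by at
#'   most `tau`, and the total drop from young to old exceeds `tau`;
#' * `inverted_U` — the maximum sits at adult or middle-old, both ends are
#'   below the peak, and the overall range exceeds `tau`;
#' * `flat` — everything else (range within `tau`, or profiles such as a
#'   monotone increase that fit neither label).
#'
#' @param values Numeric vector of 4 ordered group values, or a matrix
#'   with 4 columns (one row per ROI).
#' @param tau Tolerance (default 0.01) below which differences are treated
#'   as no change.
#' @return Character label(s) in `{"decreasing", "inverted_U", "flat"}`.
#' @export
trajectory_classification <- function(values, tau = 0.01) {
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != 4L) stop("need exactly 4 ordered group values")
    return(apply(values, 1L, trajectory_classification, tau = tau))
  }
  if (length(values) != 4L) stop("need exactly 4 ordered group values")
  if (anyNA(values)) stop("missing group value")
  steps <- diff(values)
  rng <- max(values) - min(values)
  if (all(steps <= tau) && (values[1L] - values[4L]) > tau)
    return("decreasing")
  pk <- which.max(values)
  if (rng > tau && pk %in% c(2L, 3L) && values[pk] > values[1L] &&
      values[pk] > values[4L])
    return("inverted_U")
  "flat"
}

#' Per-network, per-group distribution summary
#'
#' Summarizes connectivity or attribution values within each (network,
#' age-group) cell: mean, SD, quartiles, and count, plus a per-network age
#' direction obtained by running [trajectory_classification()] on the cell
#' means.  Cells with fewer than 2 values are flagged, not fatal.
#'
#' @param values Numeric vector of values.
#' @param network Factor/character of network assignments, same length.
#' @param group Factor of age-group labels, same length (levels in young
#'   -> old order).
#' @param tau Tolerance forwarded to [trajectory_classification()].
#' @return List with `cells` (data frame: network, group, n, mean, sd,
#'   q25, median, q75, flagged) and `direction` (per-network label).
#' @export
group_density_summary <- function(values, network, group, tau = 0.01) {
  group <- factor(group)
  network <- factor(network)
  grid <- expand.grid(network = levels(network), group = levels(group),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- values[network == grid$network[i] & group == grid$group[i]]
    if (length(v) < 2L)
      data.frame(grid[i, ], n = length(v), mean = if (length(v)) mean(v)
                 else NA_real_, sd = NA_real_, q25 = NA_real_,
                 median = NA_real_, q75 = NA_real_, flagged = TRUE)
    else
      data.frame(grid[i, ], n = length(v), mean = mean(v),
                 sd = stats::sd(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 median = unname(stats::median(v)),
                 q75 = unname(stats::quantile(v, 0.75)), flagged = FALSE)
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  direction <- vapply(levels(network), function(nw) {
    m <- cells$mean[cells$network == nw]
    if (anyNA(m) || length(m) != 4L) return(NA_character_)
    trajectory_classification(m, tau = tau)
  }, character(1L))
  list(cells = cells, direction = direction)
}

#' Group-level attribution analysis of a fitted classifier
#'
#' The pipeline's interpretation stage: computes the group-mean
#' connectivity matrix of each age group, attributes the model's
#' prediction on it via [integrated_gradients()], and derives edge and
#' node-strength tables.  Two notions of "strength" are available:
#'
#' * `"masked_fc"` (default) — the group-mean correlation of every edge
#'   whose attribution magnitude reaches `mask_rel` of the maximum in any
#'   group (attribution-selected connectivity, on the correlation scale);
#' * `"attribution"` — the raw integrated-gradient attributions.
#'
#' @param model A fitted classification [ayu_net()].
#' @param x `p x p x n` array of raw connectivity matrices.
#' @param groups Factor of age-group labels per subject.
#' @param steps Integrated-gradient steps.
#' @param mode Strength definition, see above.
#' @param mask_rel Relative attribution threshold for the mask
#'   (default 0.2).
#' @param ... Passed to [integrated_gradients()].
#' @return List with `attribution` (per-group attribution matrices),
#'   `strength` (per-group strength matrices under `mode`), `mean_fc`,
#'   `node_strength` (per-group signed node strengths), and
#'   `node_trajectory` (per-ROI label from the net node strengths).
#' @export
group_attribution_analysis <- function(model, x, groups, steps = 50L,
                                       mode = c("masked_fc", "attribution"),
                                       mask_rel = 0.2, ...) {
  mode <- match.arg(mode)
  stopifnot(model$task == "classification")
  x <- as_sfc_array(x)
  mean_fc <- mean_group_attribution(x, groups)
  attribution <- lapply(mean_fc, function(m)
    integrated_gradients(model, m, steps = steps, ...))
  strength <- if (mode == "attribution") {
    lapply(attribution, function(a) unclass(a))
  } else {
    amax <- do.call(pmax, lapply(attribution, abs))
    mask <- amax >= mask_rel * max(amax)
    diag(mask) <- FALSE
    lapply(mean_fc, function(m) m * mask)
  }
  ns <- lapply(strength, node_strength)
  net_mat <- vapply(ns, `[[`, numeric(nrow(ns[[1L]])), "net")
  traj <- trajectory_classification(net_mat)
  names(traj) <- ns[[1L]]$roi
  list(attribution = attribution, strength = strength, mean_fc = mean_fc,
       node_strength = ns, node_trajectory = traj)
}
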