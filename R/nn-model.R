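# Network internals.  Tensors are (H, W, C, N) arrays; convolution and
# max-pooling kernels live in src/nn_ops.cpp, everything else is base R on
# BLAS.  Forward passes cache what backward needs; backward propagates all
# the way to the input (required by integrated gradients).

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv1x1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  out <- xm %*% W
  out <- sweep(out, 2L, b, "+")
  aperm(array(out, c(d[1L], d[2L], d[4L], ncol(W))), c(1L, 2L, 4L, 3L))
}

conv1x1_backward <- function(x, W, dout) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  dm <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), nrow(xm), ncol(W))
  dx <- aperm(array(dm %*% t(W), c(d[1L], d[2L], d[4L], d[3L])),
              c(1L, 2L, 4L, 3L))
  list(dx = dx, dW = crossprod(xm, dm), db = colSums(dm))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

trunk_plan <- function(architecture) {
  if (architecture == "resnet5") {
    list(list(op = "conv", w = "stem"),
         list(op = "pool"),
         list(op = "res", w = "b1", proj = FALSE),
         list(op = "pool"),
         list(op = "res", w = "b2", proj = TRUE),
         list(op = "pool"),
         list(op = "res", w = "b3", proj = TRUE),
         list(op = "tap", id = "att3"),
         list(op = "res", w = "b4", proj = FALSE),
         list(op = "tap", id = "att4"),
         list(op = "pool"))
  } else if (architecture == "vgg5") {
    list(list(op = "conv", w = "c1"),
         list(op = "pool"),
         list(op = "conv", w = "c2"),
         list(op = "pool"),
         list(op = "conv", w = "c3"),
         list(op = "tap", id = "att3"),
         list(op = "conv", w = "c4"),
         list(op = "tap", id = "att4"),
         list(op = "pool"))
  } else stop("unknown architecture: ", architecture)
}

trunk_channels <- function(architecture) {
  if (architecture == "resnet5")
    c(stem = 32L, b1 = 32L, b2 = 64L, b3 = 128L, b4 = 128L)
  else
    c(c1 = 32L, c2 = 64L, c3 = 128L, c4 = 128L)
}

#' Build an attention-augmented convolutional network
#'
#' Constructs an untrained VGG5 or ResNet5 for `p x p` single-channel
#' connectivity-matrix inputs.  Both trunks use 3x3 kernels and ReLU;
#' ResNet5 is a stem convolution (32 channels) followed by four residual
#' blocks at 32/64/128/128 channels, VGG5 is four convolutions at
#' 32/64/128/128 with interleaved max-pooling.  Attention blocks attach to
#' layers 3 and 4 before their pooling, with channel-reduction ratios 1/2
#' and 1/4; their softmax weights pool each tapped feature map into a
#' descriptor that is concatenated with the flattened trunk output before
#' the fully-connected head.  The classification head ends in a softmax
#' over the age groups, the regression head in a single linear unit.
#' Weights are Kaiming-initialized (see [kaiming_init()]).
#'
#' @param architecture `"resnet5"` or `"vgg5"`.
#' @param p Input matrix dimension (number of ROIs).
#' @param task `"classification"` or `"regression"`.
#' @param n_classes Number of classes for classification (default 4).
#' @param attention Logical; if `FALSE`, no attention parameters are
#'   created and the attention weights are forced uniform (plain
#'   average pooling of the tapped maps), giving the unaugmented ablation.
#' @param seed Integer seed for the weight initialization.
#' @param class_levels Optional class labels.
#' @return A list of class `ayu_model` with `spec` and `params`.
#' @export
build_model <- function(architecture = c("resnet5", "vgg5"),
                        p, task = c("classification", "regression"),
                        n_classes = 4L, attention = TRUE, seed = 1L,
                        class_levels = NULL) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  if (p < 8L) stop("input dimension p must be at least 8")
  plan <- trunk_plan(architecture)
  ch <- trunk_channels(architecture)
  n_out <- if (task == "classification") as.integer(n_classes) else 1L
  if (task == "classification" && is.null(class_levels))
    class_levels <- age_group_levels()[seq_len(n_out)]

  shapes <- list()
  add <- function(name, nr, nc, fan_in)
    shapes[[name]] <<- list(nr = nr, nc = nc, fan_in = fan_in)

  h <- p
  cin <- 1L
  tap_info <- list()
  for (st in plan) {
    if (st$op == "conv") {
      co <- ch[[st$w]]
      add(paste0(st$w, "_W"), 9L * cin, co, 9L * cin)
      add(paste0(st$w, "_b"), co, 1L, NA)
      cin <- co
    } else if (st$op == "res") {
      co <- ch[[st$w]]
      add(paste0(st$w, "a_W"), 9L * cin, co, 9L * cin)
      add(paste0(st$w, "a_b"), co, 1L, NA)
      add(paste0(st$w, "b_W"), 9L * co, co, 9L * co)
      add(paste0(st$w, "b_b"), co, 1L, NA)
      if (st$proj) {
        add(paste0(st$w, "p_W"), cin, co, cin)
        add(paste0(st$w, "p_b"), co, 1L, NA)
      }
      cin <- co
    } else if (st$op == "pool") {
      if (h >= 2L) h <- h %/% 2L
    } else if (st$op == "tap") {
      tap_info[[st$id]] <- list(c = cin, S = h * h)
    }
  }
  Df <- h * h * cin
  ratios <- c(att3 = 1 / 2, att4 = 1 / 4)
  if (attention) {
    for (id in names(tap_info)) {
      cc <- tap_info[[id]]$c
      dd <- max(1L, as.integer(round(ratios[[id]] * cc)))
      tap_info[[id]]$d <- dd
      add(paste0(id, "_Wm"), cc, dd, cc)
      add(paste0(id, "_Wn"), cc, dd, cc)
      add(paste0(id, "_Wg"), Df, dd, Df)
    }
  }
  Dh <- Df + sum(vapply(tap_info, function(t) t$c, integer(1L)))
  add("fc_W", Dh, 64L, Dh)
  add("fc_b", 64L, 1L, NA)
  add("out_W", 64L, n_out, 64L)
  add("out_b", n_out, 1L, NA)

  net <- structure(
    list(spec = list(architecture = architecture, task = task, p = as.integer(p),
                     n_out = n_out, attention = attention, plan = plan,
                     channels = ch, taps = tap_info, Df = Df, Dh = Dh,
                     shapes = shapes, class_levels = class_levels,
                     conv_kernel = c(3L, 3L)),
         params = NULL),
    class = "ayu_model")
  kaiming_init(net, seed = seed)
}

#' Kaiming (He) initialization
#'
#' Draws every convolutional, linear, and attention-projection weight from
#' a zero-mean normal with variance `2 / fan_in` (the ReLU gain); all
#' biases start at zero.  Fully reproducible under `seed`.
#'
#' @param net An `ayu_model` from [build_model()].
#' @param seed Integer seed.
#' @return The model with freshly initialized parameters.
#' @export
kaiming_init <- function(net, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- list()
  for (name in names(net$spec$shapes)) {
    sh <- net$spec$shapes[[name]]
    if (grepl("_b$", name)) {
      params[[name]] <- numeric(sh$nr)
    } else {
      params[[name]] <- matrix(
        stats::rnorm(sh$nr * sh$nc, sd = sqrt(2 / sh$fan_in)), sh$nr, sh$nc)
    }
  }
  net$params <- params
  net
}

#' Attention pooling over feature-map positions
#'
#' Implements the attention block used at layers 3 and 4: local features at
#' each spatial position are projected by `W_m` and `W_n`, pairwise
#' compatibility scores are reduced over the second position index (by
#' averaging), a projection of the global feature `g` is added, and a
#' softmax over positions yields the attention weights `lambda`
#' (nonnegative, summing to 1).  The score vector is standardized (mean 0,
#' unit scale) before the softmax so the attention starts in a responsive,
#' non-saturated regime whatever the trunk's activation scale; a saturated
#' softmax would zero the gradients of `W_m` and `W_n` at initialization.
#' The attended descriptor is the lambda-weighted sum of the original
#' local features.
#'
#' @param features `S x c` matrix of local feature vectors (one row per
#'   spatial position).
#' @param g Global feature vector (length matching `nrow(W_g)`), ignored
#'   when `block` is `NULL`.
#' @param block List with `W_m` (`c x d`), `W_n` (`c x d`), `W_g`
#'   (`length(g) x d`), or `NULL` for the ablated block (uniform lambda).
#' @return List with `descriptor` (length `c`) and `lambda` (length `S`).
#' @export
attention_forward <- function(features, g = NULL, block = NULL) {
  features <- as.matrix(features)
  S <- nrow(features)
  if (is.null(block)) {
    lambda <- rep(1 / S, S)
  } else {
    if (ncol(features) != nrow(block$W_m))
      stop("feature channel dimension does not match attention block")
    M <- features %*% block$W_m
    Nn <- features %*% block$W_n
    # pairwise scores averaged over the second position index
    v <- colMeans(Nn)
    if (!is.null(block$W_g)) {
      if (length(g) != nrow(block$W_g))
        stop("global feature dimension does not match attention block")
      v <- v + as.vector(g %*% block$W_g)
    }
    s <- score_standardize(as.vector(M %*% v))$s
    e <- exp(s - max(s))
    lambda <- e / sum(e)
  }
  list(descriptor = as.vector(crossprod(features, lambda)), lambda = lambda)
}

# parameter-free standardization of the compatibility scores before the
# softmax: keeps the attention responsive whatever the trunk's activation
# scale (a saturated softmax would freeze the attention parameters at
# initialization)
score_standardize <- function(s, eps = 1e-8) {
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2) + eps)
  list(s = (s - mu) / sigma, sigma = sigma)
}

score_standardize_backward <- function(s_std, sigma, ds_std) {
  (ds_std - mean(ds_std) - s_std * mean(ds_std * s_std)) / sigma
}

# forward through the convolutional trunk; returns final map, taps, caches
trunk_forward <- function(net, x, want_cache = TRUE) {
  pr <- net$params
  plan <- net$spec$plan
  caches <- vector("list", length(plan))
  taps <- list()
  for (si in seq_along(plan)) {
    st <- plan[[si]]
    if (st$op == "conv") {
      pre <- .conv3x3_forward(x, pr[[paste0(st$w, "_W")]],
                              pr[[paste0(st$w, "_b")]])
      y <- relu(pre)
      if (want_cache) caches[[si]] <- list(x = x, mask = pre > 0)
      x <- y
    } else if (st$op == "res") {
      w <- st$w
      a_pre <- .conv3x3_forward(x, pr[[paste0(w, "a_W")]],
                                pr[[paste0(w, "a_b")]])
      a <- relu(a_pre)
      b_pre <- .conv3x3_forward(a, pr[[paste0(w, "b_W")]],
                                pr[[paste0(w, "b_b")]])
      s <- if (st$proj)
        conv1x1_forward(x, pr[[paste0(w, "p_W")]], pr[[paste0(w, "p_b")]])
      else x
      # variance-preserving merge: without any normalization layers the
      # residual sum would inflate activation scale block by block
      y_pre <- (b_pre + s) / sqrt(2)
      y <- relu(y_pre)
      if (want_cache)
        caches[[si]] <- list(x = x, a = a, mask_a = a_pre > 0,
                             mask_y = y_pre > 0)
      x <- y
    } else if (st$op == "pool") {
      if (dim(x)[1L] >= 2L) {
        pooled <- .maxpool2_forward(x)
        if (want_cache)
          caches[[si]] <- list(which = pooled$which, H = dim(x)[1L],
                               W = dim(x)[2L])
        x <- pooled$out
      } else if (want_cache) caches[[si]] <- list(skip = TRUE)
    } else if (st$op == "tap") {
      taps[[st$id]] <- x
    }
  }
  list(out = x, taps = taps, caches = caches)
}

trunk_backward <- function(net, caches, dy, tap_grads) {
  pr <- net$params
  plan <- net$spec$plan
  grads <- list()
  for (si in rev(seq_along(plan))) {
    st <- plan[[si]]
    ca <- caches[[si]]
    if (st$op == "conv") {
      dpre <- dy * ca$mask
      r <- .conv3x3_backward(ca$x, pr[[paste0(st$w, "_W")]], dpre)
      grads[[paste0(st$w, "_W")]] <- r$dW
      grads[[paste0(st$w, "_b")]] <- r$db
      dy <- r$dx
    } else if (st$op == "res") {
      w <- st$w
      dpre <- dy * ca$mask_y / sqrt(2)
      rb <- .conv3x3_backward(ca$a, pr[[paste0(w, "b_W")]], dpre)
      grads[[paste0(w, "b_W")]] <- rb$dW
      grads[[paste0(w, "b_b")]] <- rb$db
      da <- rb$dx * ca$mask_a
      ra <- .conv3x3_backward(ca$x, pr[[paste0(w, "a_W")]], da)
      grads[[paste0(w, "a_W")]] <- ra$dW
      grads[[paste0(w, "a_b")]] <- ra$db
      dx <- ra$dx
      if (st$proj) {
        rp <- conv1x1_backward(ca$x, pr[[paste0(w, "p_W")]], dpre)
        grads[[paste0(w, "p_W")]] <- rp$dW
        grads[[paste0(w, "p_b")]] <- rp$db
        dx <- dx + rp$dx
      } else dx <- dx + dpre
      dy <- dx
    } else if (st$op == "pool") {
      if (is.null(ca$skip))
        dy <- .maxpool2_backward(ca$which, dy, ca$H, ca$W)
    } else if (st$op == "tap") {
      if (!is.null(tap_grads[[st$id]])) dy <- dy + tap_grads[[st$id]]
    }
  }
  list(grads = grads, dx = dy)
}

# full forward: trunk + attention + head
nn_forward <- function(net, x, want_cache = TRUE) {
  spec <- net$spec
  pr <- net$params
  tr <- trunk_forward(net, x, want_cache = want_cache)
  N <- dim(x)[4L]
  Tm <- t(matrix(tr$out, spec$Df, N))
  desc <- list()
  att <- list()
  for (id in names(spec$taps)) {
    ti <- spec$taps[[id]]
    farr <- tr$taps[[id]]
    S <- ti$S
    dm <- matrix(0, N, ti$c)
    lam <- matrix(0, S, N)
    Ms <- Ns <- vector("list", N)
    if (spec$attention) {
      block <- list(W_m = pr[[paste0(id, "_Wm")]],
                    W_n = pr[[paste0(id, "_Wn")]],
                    W_g = pr[[paste0(id, "_Wg")]])
      for (n in seq_len(N)) {
        Xf <- matrix(farr[, , , n], S, ti$c)
        fwd <- attention_forward(Xf, Tm[n, ], block)
        dm[n, ] <- fwd$descriptor
        lam[, n] <- fwd$lambda
      }
    } else {
      for (n in seq_len(N)) {
        Xf <- matrix(farr[, , , n], S, ti$c)
        dm[n, ] <- colMeans(Xf)
        lam[, n] <- 1 / S
      }
    }
    desc[[id]] <- dm
    att[[id]] <- lam
  }
  h <- do.call(cbind, c(list(Tm), desc))
  fc_pre <- sweep(h %*% pr$fc_W, 2L, pr$fc_b, "+")
  fc <- relu(fc_pre)
  z <- sweep(fc %*% pr$out_W, 2L, pr$out_b, "+")
  res <- list(z = z, lambda = att)
  if (spec$task == "classification") res$prob <- softmax_rows(z)
  if (want_cache)
    res$cache <- list(trunk = tr, Tm = Tm, desc = desc, h = h, fc = fc,
                      x = x)
  res
}

# backward from dz (N x n_out); returns parameter grads and input gradient
nn_backward <- function(net, fwd, dz) {
  spec <- net$spec
  pr <- net$params
  ca <- fwd$cache
  grads <- list()
  grads$out_W <- crossprod(ca$fc, dz)
  grads$out_b <- colSums(dz)
  dfc <- dz %*% t(pr$out_W)
  dfc_pre <- dfc * (ca$fc > 0)
  grads$fc_W <- crossprod(ca$h, dfc_pre)
  grads$fc_b <- colSums(dfc_pre)
  dh <- dfc_pre %*% t(pr$fc_W)
  N <- nrow(dh)
  dTm <- dh[, seq_len(spec$Df), drop = FALSE]
  offset <- spec$Df
  tap_grads <- list()
  for (id in names(spec$taps)) {
    ti <- spec$taps[[id]]
    S <- ti$S
    ddesc_all <- dh[, offset + seq_len(ti$c), drop = FALSE]
    offset <- offset + ti$c
    farr <- ca$trunk$taps[[id]]
    dfarr <- array(0, dim(farr))
    if (spec$attention) {
      Wm <- pr[[paste0(id, "_Wm")]]
      Wn <- pr[[paste0(id, "_Wn")]]
      Wg <- pr[[paste0(id, "_Wg")]]
      dWm <- matrix(0, nrow(Wm), ncol(Wm))
      dWn <- matrix(0, nrow(Wn), ncol(Wn))
      dWg <- matrix(0, nrow(Wg), ncol(Wg))
      for (n in seq_len(N)) {
        Xf <- matrix(farr[, , , n], S, ti$c)
        ddesc <- ddesc_all[n, ]
        lam <- fwd$lambda[[id]][, n]
        # recompute small intermediates
        M <- Xf %*% Wm
        Nn <- Xf %*% Wn
        v <- colMeans(Nn) + as.vector(ca$Tm[n, ] %*% Wg)
        std <- score_standardize(as.vector(M %*% v))
        dlam <- as.vector(Xf %*% ddesc)
        dXf <- tcrossprod(lam, ddesc)
        ds_std <- lam * (dlam - sum(lam * dlam))
        ds <- score_standardize_backward(std$s, std$sigma, ds_std)
        dM <- tcrossprod(ds, v)
        dv <- as.vector(crossprod(M, ds))
        dWm <- dWm + crossprod(Xf, dM)
        dXf <- dXf + dM %*% t(Wm)
        dNn <- matrix(dv / S, S, length(dv), byrow = TRUE)
        dWn <- dWn + crossprod(Xf, dNn)
        dXf <- dXf + dNn %*% t(Wn)
        dWg <- dWg + tcrossprod(ca$Tm[n, ], dv)
        dTm[n, ] <- dTm[n, ] + as.vector(Wg %*% dv)
        dfarr[, , , n] <- dXf
      }
      grads[[paste0(id, "_Wm")]] <- dWm
      grads[[paste0(id, "_Wn")]] <- dWn
      grads[[paste0(id, "_Wg")]] <- dWg
    } else {
      for (n in seq_len(N))
        dfarr[, , , n] <- matrix(ddesc_all[n, ] / S, S, ti$c, byrow = TRUE)
    }
    tap_grads[[id]] <- dfarr
  }
  dtrunk <- array(t(dTm), dim = dim(ca$trunk$out))
  tb <- trunk_backward(net, ca$trunk$caches, dtrunk, tap_grads)
  list(grads = c(grads, tb$grads), dx = tb$dx)
}

model_param_count <- function(net) {
  sum(vapply(net$params, length, numeric(1L)))
}
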