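# Architecture contracts that do not require training.

rand_input <- function(p, n, seed = 1) {
  set.seed(seed)
  array(rnorm(p * p * n), c(p, p, n))
}

test_that("classification outputs are softmax-normalized for both trunks", {
  for (arch in c("resnet5", "vgg5")) {
    net <- build_model(arch, p = 16, task = "classification", seed = 3)
    x <- array(rand_input(16, 5, seed = 4), c(16, 16, 1, 5))
    fwd <- ayu:::nn_forward(net, x, want_cache = FALSE)
    expect_true(all(fwd$prob >= 0))
    expect_lt(max(abs(rowSums(fwd$prob) - 1)), 1e-6)
  }
})

test_that("regression head produces one finite scalar per input", {
  net <- build_model("vgg5", p = 16, task = "regression", seed = 3)
  x <- array(rand_input(16, 4, seed = 5), c(16, 16, 1, 4))
  fwd <- ayu:::nn_forward(net, x, want_cache = FALSE)
  expect_identical(dim(fwd$z), c(4L, 1L))
  expect_true(all(is.finite(fwd$z)))
})

test_that("attention adds exactly the projection parameters at layers 3 and 4", {
  count <- function(net) sum(vapply(net$params, length, numeric(1)))
  on_ <- build_model("resnet5", p = 32, task = "classification", seed = 1,
                     attention = TRUE)
  off <- build_model("resnet5", p = 32, task = "classification", seed = 1,
                     attention = FALSE)
  # channel schedule: both attention layers see c = 128; the trunk output
  # for p = 32 flattens to 128 channels x 2 x 2 positions; ratios 1/2, 1/4
  Df <- 512
  expected <- (128 * 64 + 128 * 64 + Df * 64) +   # W_m, W_n, W_g at layer 3
              (128 * 32 + 128 * 32 + Df * 32)     # and at layer 4
  expect_equal(count(on_) - count(off), expected)
})

test_that("ablating attention changes outputs but keeps head dimensions", {
  x <- array(rand_input(16, 3, seed = 6), c(16, 16, 1, 3))
  on_ <- build_model("resnet5", p = 16, task = "classification", seed = 2,
                     attention = TRUE)
  off <- build_model("resnet5", p = 16, task = "classification", seed = 2,
                     attention = FALSE)
  expect_identical(dim(on_$params$fc_W), dim(off$params$fc_W))
  zo <- ayu:::nn_forward(on_, x, want_cache = FALSE)$z
  zf <- ayu:::nn_forward(off, x, want_cache = FALSE)$z
  expect_gt(max(abs(zo - zf)), 1e-8)
  # ablated attention weights are exactly uniform
  lam <- ayu:::nn_forward(off, x, want_cache = FALSE)$lambda
  for (l in lam) expect_true(all(abs(l - 1 / nrow(l)) < 1e-15))
})

test_that("attention weights are a proper distribution over positions", {
  set.seed(7)
  S <- 16; cc <- 8
  block <- list(W_m = matrix(rnorm(cc * 4), cc, 4),
                W_n = matrix(rnorm(cc * 4), cc, 4),
                W_g = matrix(rnorm(6 * 4), 6, 4))
  g <- rnorm(6)
  f <- matrix(rnorm(S * cc), S, cc)
  att <- attention_forward(f, g, block)
  expect_true(all(att$lambda >= 0))
  expect_lt(abs(sum(att$lambda) - 1), 1e-6)
  expect_equal(att$descriptor, as.vector(crossprod(f, att$lambda)),
               tolerance = 1e-12)

  # all-equal features give uniform attention regardless of g
  f_const <- matrix(1.5, S, cc)
  att_c <- attention_forward(f_const, g, block)
  expect_equal(att_c$lambda, rep(1 / S, S), tolerance = 1e-12)

  # a single spatial position degenerates to lambda = 1
  att_1 <- attention_forward(f[1, , drop = FALSE], g, block)
  expect_equal(att_1$lambda, 1)
  expect_equal(att_1$descriptor, f[1, ], tolerance = 1e-12)

  expect_error(attention_forward(f[, 1:3], g, block), "channel")
  expect_error(attention_forward(f, g[1:2], block), "global")
})

test_that("Kaiming initialization has the stated moments and is seeded", {
  net <- build_model("vgg5", p = 32, task = "classification", seed = 10)
  w <- as.vector(net$params$fc_W)  # fan_in 2304, > 1e5 weights
  fan_in <- nrow(net$params$fc_W)
  expect_gt(length(w), 1e5)
  expect_lt(abs(mean(w)), 0.01)
  expect_lt(abs(var(w) - 2 / fan_in) / (2 / fan_in), 0.1)
  # conv layers too, pooled across tensors of equal fan-in
  w4 <- as.vector(net$params$c4_W)  # fan_in 1152
  expect_lt(abs(var(w4) - 2 / 1152) / (2 / 1152), 0.1)
  expect_true(all(net$params$fc_b == 0))

  again <- kaiming_init(net, seed = 10)
  expect_identical(net$params, again$params)
  other <- kaiming_init(net, seed = 11)
  expect_false(identical(net$params, other$params))
})

test_that("forward passes are deterministic and batch-size independent", {
  net <- build_model("resnet5", p = 16, task = "classification", seed = 12)
  xs <- rand_input(16, 3, seed = 13)
  batch <- array(xs, c(16, 16, 1, 3))
  z_batch <- ayu:::nn_forward(net, batch, want_cache = FALSE)$z
  z_again <- ayu:::nn_forward(net, batch, want_cache = FALSE)$z
  expect_identical(z_batch, z_again)
  for (i in 1:3) {
    zi <- ayu:::nn_forward(net, array(xs[, , i], c(16, 16, 1, 1)),
                           want_cache = FALSE)$z
    expect_lt(max(abs(zi - z_batch[i, , drop = FALSE])), 1e-6)
  }
})

test_that("one training step moves every trainable tensor", {
  # p = 32 keeps both attention layers on multi-position feature maps
  cohort <- generate_cohort(sim_config(n_subjects = 16L, p = 32L,
                                       n_timepoints = 60L), seed = 14)
  x <- cohort_sfc(cohort)
  fit0 <- ayu_net(x, cohort$manifest$group, architecture = "resnet5",
                  epochs = 0, seed = 15)
  fit1 <- ayu_net(x, cohort$manifest$group, architecture = "resnet5",
                  epochs = 1, batch_size = 16, seed = 15)
  for (nm in names(fit0$model$params)) {
    delta <- max(abs(fit1$model$params[[nm]] - fit0$model$params[[nm]]))
    expect_gt(delta, 0)
  }
})

test_that("build_model rejects invalid specifications", {
  expect_error(build_model("alexnet", p = 32, task = "classification"))
  expect_error(build_model("resnet5", p = 4, task = "classification"),
               "at least 8")
})
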