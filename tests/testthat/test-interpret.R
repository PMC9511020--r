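test_that("the path quadrature is exact for linear models at any step count", {
  set.seed(61)
  for (m in c(1L, 7L, 50L)) {
    w <- rnorm(30)
    x <- rnorm(30)
    attr_ <- integrated_gradients_path(function(z) w, x, steps = m)
    expect_lt(max(abs(attr_ - w * x)), 1e-8)
  }
  # matrix-shaped inputs work the same way
  w <- matrix(rnorm(16), 4, 4)
  x <- matrix(rnorm(16), 4, 4)
  expect_lt(max(abs(integrated_gradients_path(function(z) w, x, steps = 3) -
                    w * x)), 1e-8)
})

test_that("attributions vanish when the input equals the baseline", {
  x <- matrix(rnorm(25), 5, 5)
  attr_ <- integrated_gradients_path(function(z) matrix(rnorm(25), 5, 5),
                                     x, baseline = x, steps = 10)
  expect_identical(attr_, x * 0)
})

test_that("non-finite gradients abort with the step index", {
  expect_error(
    integrated_gradients_path(function(z) c(NA_real_, 1), c(1, 2),
                              steps = 4),
    "step 1")
})

test_that("group means average matrices within each age group", {
  lv <- age_group_levels()
  a <- matrix(1, 3, 3)
  mats <- list(a, -a, 2 * a, 2 * a, 3 * a, 0 * a, a, a)
  groups <- factor(rep(lv, each = 2), levels = lv)
  gm <- mean_group_attribution(mats, groups)
  expect_equal(gm$young, 0 * a)          # A and -A cancel
  expect_equal(gm$adult, 2 * a)          # two identical matrices
  expect_equal(gm$middle_old, 1.5 * a)
  expect_equal(gm$old, a)
  expect_error(mean_group_attribution(mats[1:6],
                                      factor(rep(lv[1:3], each = 2),
                                             levels = lv)), "empty group")
  # single subject per group: the mean is that subject's matrix
  gm1 <- mean_group_attribution(mats[c(1, 3, 5, 7)],
                                factor(lv, levels = lv))
  expect_equal(gm1$young, a)
})

test_that("node strength decomposes incident edges by sign", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.5
  ns <- node_strength(m)
  expect_equal(ns$positive[ns$roi %in% c("a", "b")], c(0.5, 0.5))
  expect_equal(ns$positive[ns$roi %in% c("c", "d")], c(0, 0))
  expect_equal(ns$net, ns$positive + ns$negative)

  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- -0.3
  ns2 <- node_strength(m2)
  expect_equal(ns2$negative[1:2], c(-0.3, -0.3))

  m3 <- matrix(0, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 0.2
  m3[1, 3] <- m3[3, 1] <- -0.1
  expect_equal(node_strength(m3)$net[1], 0.1)
})

test_that("net node strength sums to twice the total edge attribution", {
  set.seed(62)
  for (i in 1:50) {
    p <- sample(3:20, 1)
    a <- matrix(rnorm(p * p), p, p)
    a <- a + t(a)
    ns <- node_strength(a)
    edge_total <- sum(a[lower.tri(a)])
    expect_lt(abs(sum(ns$net) - 2 * edge_total), 1e-9)
  }
})

test_that("edge tables apply the omission threshold across groups", {
  lv <- age_group_levels()
  rois <- paste("ROI", 1:4)
  mk <- function(v12, v34) {
    m <- matrix(0, 4, 4, dimnames = list(rois, rois))
    m[1, 2] <- m[2, 1] <- v12
    m[3, 4] <- m[4, 3] <- v34
    m
  }
  mats <- list(young = mk(0.19, 0.61), adult = mk(0.19, 0.56),
               middle_old = mk(0.19, 0.57), old = mk(0.19, 0.49))
  tab <- edge_contribution_table(mats, threshold = 0.2)
  expect_equal(nrow(tab), 1L)  # the 0.19-everywhere edge is omitted
  expect_identical(c(tab$roi1, tab$roi2), c("ROI 4", "ROI 3"))
  expect_equal(unlist(tab[1, lv], use.names = FALSE),
               c(0.61, 0.56, 0.57, 0.49))

  # 0.21 in a single group is enough to retain an edge
  mats21 <- lapply(c(0.21, 0.1, 0.1, 0.1), function(v) mk(v, 0))
  names(mats21) <- lv
  expect_equal(nrow(edge_contribution_table(mats21, threshold = 0.2)), 1L)

  empty <- edge_contribution_table(lapply(mats, function(m) m * 0),
                                   threshold = 0.2)
  expect_equal(nrow(empty), 0L)

  atlas <- data.frame(roi_label = rois[1:3], network = "Default",
                      hemisphere = "LH")
  expect_error(edge_contribution_table(mats, atlas = atlas), "ROI 4")
})

test_that("age trajectories classify with the documented tolerance rule", {
  # near-monotone profile with a sub-tolerance bump counts as decreasing
  expect_identical(trajectory_classification(c(0.632, 0.551, 0.556, 0.512),
                                             tau = 0.01), "decreasing")
  # peak at middle-old with both ends lower
  expect_identical(trajectory_classification(c(0.324, 0.341, 0.370, 0.364),
                                             tau = 0.01), "inverted_U")
  expect_identical(trajectory_classification(c(0.5, 0.5, 0.5, 0.5)), "flat")
  # monotone increase fits neither label
  expect_identical(trajectory_classification(c(0.1, 0.2, 0.3, 0.4)), "flat")
  m <- rbind(c(0.6, 0.5, 0.4, 0.3), c(0.2, 0.5, 0.6, 0.1))
  expect_identical(trajectory_classification(m),
                   c("decreasing", "inverted_U"))
  expect_error(trajectory_classification(c(0.1, 0.2, 0.3)), "4 ordered")
  expect_error(trajectory_classification(c(0.1, NA, 0.3, 0.2)), "missing")
})

test_that("density summaries report cell moments and age direction", {
  lv <- age_group_levels()
  df <- expand.grid(network = c("Default", "Vis"), group = lv,
                    rep = 1:4, stringsAsFactors = FALSE)
  base <- c(Default = 0.4, Vis = 0.3)
  eff <- c(young = 0, adult = 0.05, middle_old = 0.06, old = 0.01)
  values <- base[df$network] + eff[df$group]
  s <- group_density_summary(values, df$network,
                             factor(df$group, levels = lv))
  cell <- s$cells[s$cells$network == "Default" &
                  s$cells$group == "young", ]
  expect_equal(cell$sd, 0)          # identical values in the cell
  expect_equal(cell$q25, cell$q75)
  expect_identical(unname(s$direction["Default"]), "inverted_U")
  expect_identical(unname(s$direction["Vis"]), "inverted_U")

  s2 <- group_density_summary(c(1, 2, 3, 4), rep("Default", 4),
                              factor(rep(lv, 1), levels = lv))
  # one value per cell: flagged, not fatal
  expect_true(all(s2$cells$flagged))
  s3 <- group_density_summary(c(1, 2, 3, 4), rep("Default", 4),
                              factor(rep("young", 4), levels = lv))
  cell3 <- s3$cells[s3$cells$group == "young", ]
  expect_equal(cell3$mean, 2.5)
  expect_equal(cell3$median, 2.5)
})
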