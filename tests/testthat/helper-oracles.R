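# Independent oracles used to cross-check the implementation.

# textbook per-pair Pearson correlation, double loop over columns
brute_pearson <- function(x) {
  p <- ncol(x)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# manifest with given per-group sizes and uniform ages inside each bin
make_manifest <- function(sizes, seed = 1) {
  set.seed(seed)
  bounds <- list(c(20, 40), c(41, 55), c(56, 69), c(70, 88))
  age <- unlist(lapply(1:4, function(g)
    runif(sizes[g], bounds[[g]][1], bounds[[g]][2])))
  data.frame(subject_id = sprintf("s%04d", seq_len(sum(sizes))),
             age = age, sex = rep_len(c("F", "M"), sum(sizes)),
             group = factor(rep(age_group_levels(), sizes),
                            levels = age_group_levels()))
}
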