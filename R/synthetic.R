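#' Synthetic cohort configuration
#'
#' Defines a multi-subject resting-state cohort in which inter-regional
#' correlations follow planted age trajectories.  Three disjoint edge sets
#' are planted in an otherwise unstructured correlation matrix:
#'
#' * `E_dec` — correlation declines linearly from `dec_hi` at age 20 to
#'   `dec_lo` at age 88 (the linear-decline trajectory seen in prefrontal,
#'   somatosensory and default-mode regions),
#' * `E_invU` — correlation follows an inverted-U, peaking at `peak_age`
#'   (default 60, inside the middle-old bin) at `invu_peak` and falling to
#'   `invu_end` at both ends of the age range (visual / ventral-attention
#'   style trajectory),
#' * `E_null` — age-constant correlation `null_r`, an uninformative control.
#'
#' Signal is planted in the correlation structure, not in mean amplitude,
#' because every downstream feature is a Pearson correlation.
#'
#' @param n_subjects Number of subjects (default 600).
#' @param p Number of regions (default 32; use 100 for the
#'   reference-shape preset).
#' @param n_timepoints Timepoints per subject (default 200).
#' @param age_range Closed age range sampled uniformly (default 20-88).
#' @param edges_dec,edges_invU,edges_null Two-column integer matrices of
#'   planted edges (defaults plant 5/5/3 edges among the first 24 regions,
#'   including shared-node triangles so the PSD repair is exercised).
#' @param dec_hi,dec_lo Endpoints of the declining trajectory.
#' @param invu_peak,invu_end,peak_age Inverted-U parameters.
#' @param null_r Constant correlation of null edges.
#' @param noise_sd SD of independent observation noise added on top of the
#'   correlated signal (attenuates all correlations by `1/(1+noise_sd^2)`).
#' @param group_sizes Optional integer vector of 4 per-group subject counts;
#'   overrides the uniform age draw (the reference preset uses the
#'   172/152/154/160 split of a well-known aging cohort).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 600L, p = 32L, n_timepoints = 200L,
                       age_range = c(20, 88),
                       edges_dec = default_edges("dec", p),
                       edges_invU = default_edges("invU", p),
                       edges_null = default_edges("null", p),
                       dec_hi = 0.75, dec_lo = 0.05,
                       invu_peak = 0.75, invu_end = 0.15, peak_age = 60,
                       null_r = 0.45, noise_sd = 0.2,
                       group_sizes = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects), p = as.integer(p),
              n_timepoints = as.integer(n_timepoints), age_range = age_range,
              edges_dec = edges_dec, edges_invU = edges_invU,
              edges_null = edges_null,
              dec_hi = dec_hi, dec_lo = dec_lo, invu_peak = invu_peak,
              invu_end = invu_end, peak_age = peak_age, null_r = null_r,
              noise_sd = noise_sd, group_sizes = group_sizes)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_edges <- function(set = c("dec", "invU", "null"), p = 32L) {
  set <- match.arg(set)
  if (p >= 24L) {
    switch(set,
      dec  = cbind(c(1L, 2L, 1L, 4L, 6L), c(2L, 3L, 3L, 5L, 7L)),
      invU = cbind(c(9L, 10L, 9L, 12L, 14L), c(10L, 11L, 11L, 13L, 15L)),
      null = cbind(c(17L, 19L, 21L), c(18L, 20L, 22L)))
  } else if (p >= 8L) {
    # compact sets for small test parcellations
    switch(set,
      dec  = cbind(c(1L, 2L, 1L), c(2L, 3L, 3L)),
      invU = cbind(c(4L, 5L, 4L), c(5L, 6L, 6L)),
      null = cbind(7L, 8L))
  } else stop("default planted edges need p >= 8; pass edge sets explicitly")
}

validate_sim_config <- function(cfg) {
  all_edges <- rbind(cfg$edges_dec, cfg$edges_invU, cfg$edges_null)
  if (max(all_edges) > cfg$p) stop("planted edge index exceeds p")
  if (any(all_edges[, 1L] == all_edges[, 2L])) stop("self-edge planted")
  key <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  keys <- c(key(cfg$edges_dec), key(cfg$edges_invU), key(cfg$edges_null))
  if (anyDuplicated(keys)) stop("planted edge sets must be disjoint")
  targets <- c(cfg$dec_hi, cfg$dec_lo, cfg$invu_peak, cfg$invu_end, cfg$null_r)
  if (any(abs(targets) >= 0.95))
    stop("target correlations must lie in (-0.95, 0.95)")
  invisible(cfg)
}

#' Planted target correlation at a given age
#'
#' @param age Age in years, within the configured range.
#' @param edge_class One of `"dec"`, `"invU"`, `"null"`.
#' @param config A [sim_config()].
#' @return Target Pearson correlation for an edge of that class.
#' @export
target_correlation <- function(age, edge_class = c("dec", "invU", "null"),
                               config = sim_config()) {
  edge_class <- match.arg(edge_class)
  lo <- config$age_range[1L]
  hi <- config$age_range[2L]
  switch(edge_class,
    dec = config$dec_hi + (age - lo) / (hi - lo) * (config$dec_lo -
                                                      config$dec_hi),
    invU = {
      # piecewise quadratic peaking at peak_age, reaching invu_end at both
      # ends of the age range (the two sides need different curvatures
      # unless the peak is centred)
      a_left <- (config$invu_peak - config$invu_end) /
        (config$peak_age - lo)^2
      a_right <- (config$invu_peak - config$invu_end) /
        (hi - config$peak_age)^2
      a <- ifelse(age <= config$peak_age, a_left, a_right)
      config$invu_peak - a * (age - config$peak_age)^2
    },
    null = rep_len(config$null_r, length(age)))
}

#' Age-specific target correlation matrix
#'
#' Identity plus the planted edges at their age-specific targets, repaired
#' to the nearest valid correlation matrix by eigenvalue clipping at 1e-6
#' followed by rescaling to unit diagonal.
#'
#' @inheritParams target_correlation
#' @return `p x p` correlation matrix (positive semidefinite).
#' @export
target_correlation_matrix <- function(age, config = sim_config()) {
  p <- config$p
  m <- diag(p)
  put <- function(edges, vals) {
    if (nrow(edges)) {
      m[edges] <<- vals
      m[edges[, c(2L, 1L), drop = FALSE]] <<- vals
    }
  }
  put(config$edges_dec, target_correlation(age, "dec", config))
  put(config$edges_invU, target_correlation(age, "invU", config))
  put(config$edges_null, target_correlation(age, "null", config))
  nearest_psd_corr(m)
}

#' Nearest-PSD repair of a correlation matrix
#'
#' Clips eigenvalues below `eps`, reassembles, and rescales to unit
#' diagonal.  Deterministic.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor.
#' @return Positive-semidefinite correlation matrix.
#' @export
nearest_psd_corr <- function(m, eps = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= eps)) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  if (any(!is.finite(d)) || any(d <= 0))
    stop("PSD repair failed: non-positive diagonal")
  out <- out / outer(d, d)
  (out + t(out)) / 2
}

#' Sample one subject's ROI time series
#'
#' Draws `n_timepoints` multivariate-normal observations with the
#' age-specific target correlation (unit variances) and adds independent
#' Gaussian observation noise.
#'
#' @param age Subject age in years.
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @param subject_id Identifier for the returned series.
#' @return An [roi_timeseries()].
#' @export
sample_subject <- function(age, config = sim_config(), seed = 1L,
                           subject_id = "subject") {
  sigma <- target_correlation_matrix(age, config)
  ch <- tryCatch(chol(sigma + diag(1e-9, config$p)),
                 error = function(e) stop("PSD repair failed: ",
                                          conditionMessage(e)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(config$n_timepoints * config$p),
              config$n_timepoints, config$p)
  x <- z %*% ch
  if (config$noise_sd > 0)
    x <- x + config$noise_sd * matrix(stats::rnorm(length(x)), nrow(x))
  roi_timeseries(x, subject_id = subject_id,
                 roi_labels = synthetic_atlas(config$p)$roi_label)
}

#' Synthetic atlas lookup
#'
#' ROI labels with synthetic network and hemisphere assignments in the
#' style of a 17-network parcellation lookup; regions hosting planted
#' declining edges map to "Default"/"SomMot"-style networks and inverted-U
#' hosts to "Vis"/"SalVentAttn", mirroring the trajectory/network pairing
#' reported for aging cohorts.
#'
#' @param p Number of regions.
#' @return Data frame with `roi_label`, `network`, `hemisphere`.
#' @export
synthetic_atlas <- function(p = 32L) {
  nets <- c("Default", "SomMot", "Vis", "SalVentAttn", "Limbic", "Cont",
            "DorsAttn", "TempPar")
  network <- nets[((seq_len(p) - 1L) %/% 4L) %% length(nets) + 1L]
  hemisphere <- ifelse(seq_len(p) %% 2L == 1L, "LH", "RH")
  within_net <- stats::ave(seq_len(p), paste(hemisphere, network),
                           FUN = seq_along)
  data.frame(roi_label = sprintf("%s %s %d", hemisphere, network, within_net),
             network = network, hemisphere = hemisphere,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` ages (uniform over the configured range, or matching
#' `group_sizes` when given), samples each subject's time series, and
#' optionally writes the cohort to disk in the package's TSV dialects
#' (per-subject time series, manifest, atlas, ground-truth JSON).
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory; created if missing.
#' @return A list of class `synthetic_cohort` with elements `manifest`
#'   (subject_id, age, sex, group), `timeseries` (named list of
#'   [roi_timeseries()]), `atlas`, `ground_truth` (planted edges and their
#'   classes), and `config`.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L,
                            out_dir = NULL) {
  n <- config$n_subjects
  if (n < 8L)
    warning("fewer than 8 subjects: a 4-group stratified split downstream ",
            "will fail")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (!is.null(config$group_sizes)) {
    stopifnot(length(config$group_sizes) == 4L)
    bounds <- list(c(20, 40), c(41, 55), c(56, 69), c(70, 88))
    ages <- unlist(lapply(seq_len(4L), function(g)
      stats::runif(config$group_sizes[g], bounds[[g]][1L], bounds[[g]][2L])))
    ages <- sample(ages)
  } else {
    ages <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  }
  n <- length(ages)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("sub-%04d", seq_len(n))
  manifest <- data.frame(subject_id = ids, age = round(ages, 2), sex = sex,
                         stringsAsFactors = FALSE)
  manifest$group <- assign_age_group(manifest$age)
  ts <- lapply(seq_len(n), function(i)
    sample_subject(manifest$age[i], config, seed = subject_seeds[i],
                   subject_id = ids[i]))
  names(ts) <- ids
  edge_df <- function(edges, cls)
    if (nrow(edges)) data.frame(roi1 = edges[, 1L], roi2 = edges[, 2L],
                                class = cls, stringsAsFactors = FALSE)
  gt <- rbind(edge_df(config$edges_dec, "dec"),
              edge_df(config$edges_invU, "invU"),
              edge_df(config$edges_null, "null"))
  atlas <- synthetic_atlas(config$p)
  cohort <- structure(list(manifest = manifest, timeseries = ts,
                           atlas = atlas, ground_truth = gt, config = config),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @rdname generate_cohort
#' @param cohort A `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.tsv"))
  ts_dir <- file.path(out_dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  for (id in names(cohort$timeseries))
    write_timeseries(cohort$timeseries[[id]],
                     file.path(ts_dir, paste0(id, ".tsv")))
  jsonlite::write_json(
    list(ground_truth = cohort$ground_truth,
         config = cohort$config[setdiff(names(cohort$config),
                                        c("edges_dec", "edges_invU",
                                          "edges_null", "group_sizes"))]),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Stack a cohort's connectivity matrices
#'
#' Convenience step from a cohort to the array consumed by [ayu_net()]:
#' one sFC matrix per subject.
#'
#' @param cohort A `synthetic_cohort` (or list with `timeseries`).
#' @return `p x p x n` array, subject order matching the manifest.
#' @export
cohort_sfc <- function(cohort) {
  mats <- lapply(cohort$timeseries, compute_sfc)
  arr <- array(unlist(mats, use.names = FALSE),
               dim = c(dim(mats[[1L]]), length(mats)))
  dimnames(arr) <- c(dimnames(mats[[1L]]), list(names(cohort$timeseries)))
  arr
}
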