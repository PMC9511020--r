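#' Parcellated ROI time series
#'
#' Lightweight container for one subject's region-averaged BOLD signal:
#' a numeric matrix with timepoints in rows and regions (ROIs) in columns.
#'
#' @param values Numeric matrix, `T x p` (timepoints x regions), no missing
#'   values, at least 3 timepoints.
#' @param subject_id Character scalar identifying the subject.
#' @param roi_labels Character vector of `p` unique ROI labels; defaults to
#'   the column names of `values`.
#' @return An object of class `roi_timeseries`: the matrix with ROI labels as
#'   column names and a `subject_id` attribute.
#' @export
roi_timeseries <- function(values, subject_id = "subject",
                           roi_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L)
    stop("time series needs at least 3 timepoints, got ", nrow(values))
  if (anyNA(values) || !all(is.finite(values)))
    stop("time series contains missing or non-finite values")
  if (is.null(roi_labels))
    roi_labels <- paste0("ROI_", seq_len(ncol(values)))
  if (length(roi_labels) != ncol(values))
    stop("roi_labels length does not match number of regions")
  if (anyDuplicated(roi_labels))
    stop("duplicate ROI labels: ",
         paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  colnames(values) <- roi_labels
  structure(values, subject_id = as.character(subject_id),
            class = c("roi_timeseries", "matrix", "array"))
}

#' Static functional connectivity from an ROI time series
#'
#' Computes the full `p x p` matrix of pairwise Pearson correlations between
#' region time courses — the static functional connectivity (sFC) matrix that
#' every downstream consumer (vectorized machine-learning features and the
#' full-matrix network input) is built from.
#'
#' @param ts An [roi_timeseries()] or a plain `T x p` numeric matrix with at
#'   least 3 rows.
#' @param min_max Logical; if `TRUE`, each column is min-max rescaled to
#'   `[0, 1]` before correlation.  Pearson correlation is invariant under
#'   positive affine maps, so this cannot change the result; the flag exists
#'   only to mirror preprocessing pipelines that log such a step.
#' @return A symmetric `p x p` correlation matrix of class
#'   `connectivity_matrix` with unit diagonal and ROI labels as dimnames.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(200 * 8), 200, 8), "s01")
#' cm <- compute_sfc(ts)
#' range(cm)
#' @export
compute_sfc <- function(ts, min_max = FALSE) {
  x <- unclass(as.matrix(ts))
  storage.mode(x) <- "double"
  if (nrow(x) < 3L)
    stop("Pearson correlation needs at least 3 timepoints, got ", nrow(x))
  if (anyNA(x) || !all(is.finite(x)))
    stop("time series contains missing or non-finite values")
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s): ",
         paste(labels[sds == 0], collapse = ", "))
  if (min_max) {
    rng <- apply(x, 2L, range)
    x <- sweep(sweep(x, 2L, rng[1L, ], "-"), 2L, rng[2L, ] - rng[1L, ], "/")
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(labels, labels)
  class(r) <- c("connectivity_matrix", "matrix", "array")
  r
}

#' Validate a square matrix as a connectivity matrix
#'
#' @param m Square numeric matrix.
#' @param tol Symmetry/diagonal tolerance.
#' @return `m` with class `connectivity_matrix`.
#' @export
as_connectivity <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix is asymmetric: worst cell (%d, %d), |delta| = %g",
                 ij[1L], ij[2L], max(asym)))
  }
  m <- (m + t(m)) / 2
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("ROI_", seq_len(nrow(m))),
                        paste0("ROI_", seq_len(nrow(m))))
  class(m) <- c("connectivity_matrix", "matrix", "array")
  m
}

#' Lower-triangle feature vector of a connectivity matrix
#'
#' Linearizes the strictly lower triangle (no diagonal) in a frozen,
#' row-major order: row 2 first (`(2,1)`), then row 3 (`(3,1)`, `(3,2)`),
#' and so on — `p(p-1)/2` values for a `p x p` matrix (4950 for the
#' 100-region parcellation, 2016 for the 64-region one).
#'
#' @param cm Symmetric connectivity matrix (validated via [as_connectivity()]).
#' @param tol Symmetry tolerance forwarded to the validator.
#' @return Numeric vector of length `p(p-1)/2` with an `index_map` attribute:
#'   an integer matrix of (row, col) pairs, `row > col`, in extraction order.
#' @export
vectorize_lower_triangle <- function(cm, tol = 1e-8) {
  cm <- as_connectivity(cm, tol = tol)
  p <- nrow(cm)
  map <- lower_triangle_index(p)
  v <- cm[map]
  names(v) <- paste(rownames(cm)[map[, 1L]], colnames(cm)[map[, 2L]],
                    sep = "~")
  attr(v, "index_map") <- map
  v
}

#' @rdname vectorize_lower_triangle
#' @param p Matrix dimension.
#' @export
lower_triangle_index <- function(p) {
  ij <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  dimnames(ij) <- list(NULL, c("row", "col"))
  ij
}

#' Rebuild a symmetric matrix from a lower-triangle feature vector
#'
#' Inverse of [vectorize_lower_triangle()]: places the values back in the
#' frozen row-major lower-triangle order, mirrors them, and sets the
#' diagonal.
#'
#' @param v Numeric vector of length `p(p-1)/2`.
#' @param diag_value Diagonal fill, 1 for correlation matrices (default).
#' @param roi_labels Optional ROI labels.
#' @return A `p x p` symmetric matrix.
#' @export
matrix_from_lower_triangle <- function(v, diag_value = 1, roi_labels = NULL) {
  len <- length(v)
  p <- (1 + sqrt(1 + 8 * len)) / 2
  if (p != round(p))
    stop("length ", len, " is not p(p-1)/2 for any integer p")
  p <- as.integer(round(p))
  m <- matrix(diag_value, p, p)
  map <- lower_triangle_index(p)
  m[map] <- v
  m[map[, c(2L, 1L), drop = FALSE]] <- v
  if (!is.null(roi_labels)) dimnames(m) <- list(roi_labels, roi_labels)
  m
}

#' Standardize features with training-set moments
#'
#' Z-scores each feature (column) to mean 0, SD 1 using moments estimated on
#' the training set only; any held-out data is transformed with those same
#' parameters.  Zero-variance features are passed through unscaled and
#' reported, not errored.
#'
#' @param train Numeric matrix, samples in rows and features in columns
#'   (e.g. stacked lower-triangle vectors), or a 3-d array `p x p x n` of
#'   connectivity matrices (each matrix entry is then one feature).
#' @param apply_to Optional data of the same kind, transformed with the
#'   training parameters.
#' @return List with `train`, `apply_to` (or `NULL`), `center`, `scale`, and
#'   `zero_variance` (logical per feature).
#' @export
standardize_features <- function(train, apply_to = NULL) {
  to_mat <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L) {
      d <- dim(x)
      t(matrix(x, d[1L] * d[2L], d[3L]))
    } else as.matrix(x)
  }
  shape <- if (is.array(train) && length(dim(train)) == 3L) dim(train) else NULL
  tm <- to_mat(train)
  if (nrow(tm) == 0L) stop("training set is empty")
  center <- colMeans(tm)
  # population SD (divide by n), the standardization convention of
  # machine-learning scalers
  scale <- sqrt(colMeans(sweep(tm, 2L, center, "-")^2))
  zero_var <- !is.finite(scale) | scale == 0
  center[zero_var] <- 0
  scale[zero_var] <- 1
  tf <- function(m) sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
  back <- function(m) {
    if (!is.null(shape)) array(t(m), dim = c(shape[1L], shape[2L], nrow(m)))
    else m
  }
  out_train <- back(tf(tm))
  out_apply <- if (!is.null(apply_to)) back(tf(to_mat(apply_to)))
  list(train = out_train, apply_to = out_apply, center = center,
       scale = scale, zero_variance = zero_var)
}

#' Age-group labels
#'
#' The four closed age bins used throughout the pipeline: young (20-40),
#' adult (41-55), middle-old (56-69), and old (70-88) years.  Ages outside
#' 20-88 are excluded by design and raise an error.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `young`, `adult`, `middle_old`, `old`.
#' @examples
#' assign_age_group(c(40, 41, 69, 70))
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age)))
    stop("non-finite age")
  if (any(age < 20 | age > 88))
    stop("age out of the 20-88 range: subjects below 20 or above 88 years ",
         "are excluded (", paste(age[age < 20 | age > 88], collapse = ", "),
         ")")
  cut(age, breaks = c(20, 40, 55, 69, 88), labels = age_group_levels(),
      include.lowest = TRUE, right = TRUE)
}

#' @rdname assign_age_group
#' @export
age_group_levels <- function() c("young", "adult", "middle_old", "old")
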