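#' Tabular file dialect
#'
#' All on-disk artifacts are tab-delimited text with a header row and
#' fixed 6-decimal formatting of numeric cells, so that re-running a stage
#' with the same inputs and seed reproduces byte-identical files.
#' @name ayu-io
NULL

fmt_num <- function(x, digits = 6L) {
  formatC(x, format = "f", digits = digits)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  body <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(body) != length(header))
    stop("ragged header in ", path)
  body
}

#' Read / write ROI time series
#'
#' Time-series files are TSV with one header row of ROI labels and one row
#' per timepoint.
#'
#' @param path File path.
#' @param subject_id Subject id attached to the parsed series (defaults to
#'   the file name without extension).
#' @return [read_timeseries()] returns an [roi_timeseries()];
#'   `write_timeseries` invisibly returns `path`.
#' @export
read_timeseries <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop("time-series file has no data rows: ", path)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(labels))
    stop("duplicate ROI labels in header of ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  p <- length(labels)
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != p))
    stop("ragged row at line ", which(widths != p)[1L] + 1L, " of ", path,
         ": expected ", p, " cells, found ", widths[widths != p][1L])
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("non-numeric cell at line ", (bad - 1L) %/% p + 2L, " of ", path)
  }
  m <- matrix(vals, ncol = p, byrow = TRUE)
  colnames(m) <- labels
  roi_timeseries(m, subject_id = subject_id)
}

#' @rdname read_timeseries
#' @param ts An [roi_timeseries()] or numeric matrix with ROI column names.
#' @export
write_timeseries <- function(ts, path) {
  m <- unclass(as.matrix(ts))
  lines <- c(paste(colnames(m), collapse = "\t"),
             apply(m, 1L, function(r) paste(fmt_num(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write connectivity (or attribution) matrices
#'
#' Matrix files carry ROI labels as both the header row and the first
#' column; symmetry is validated on read.
#'
#' @param path File path.
#' @param tol Symmetry tolerance on read.
#' @return [read_matrix()] returns a `connectivity_matrix`.
#' @export
read_matrix <- function(path, tol = 1e-8) {
  df <- read_tsv_checked(path)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric cell in matrix file ", path)
  if (!identical(labels, colnames(m)))
    stop("row labels do not match column labels in ", path)
  rownames(m) <- labels
  as_connectivity(m, tol = tol)
}

#' @rdname read_matrix
#' @param cm Square matrix with dimnames.
#' @export
write_matrix <- function(cm, path) {
  m <- unclass(as.matrix(cm))
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("ROI_", seq_len(nrow(m))),
                        paste0("ROI_", seq_len(ncol(m))))
  lines <- c(paste(c("roi", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject manifest
#'
#' Expects columns `subject_id`, `age`, `sex`.  Subjects outside the 20-88
#' age range are rejected (dropped with a message), mirroring the cohort's
#' exclusion rule; retained subjects get a `group` column via
#' [assign_age_group()].
#'
#' @param path File path.
#' @return Data frame with `subject_id`, `age`, `sex`, `group`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  df$age <- as.numeric(df$age)
  bad <- !is.finite(df$age) | df$age < 20 | df$age > 88
  if (any(bad)) {
    message("excluding ", sum(bad), " subject(s) with age outside 20-88: ",
            paste(df$subject_id[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df$group <- assign_age_group(df$age)
  rownames(df) <- NULL
  df
}

#' @rdname read_manifest
#' @param manifest Data frame with at least `subject_id`, `age`, `sex`.
#' @export
write_manifest <- function(manifest, path) {
  cols <- intersect(c("subject_id", "age", "sex", "group"), names(manifest))
  utils::write.table(manifest[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an atlas lookup
#'
#' Expects columns `roi_label`, `network`, `hemisphere`; labels must be
#' unique.
#'
#' @param path File path.
#' @return Data frame lookup.
#' @export
read_atlas <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("roi_label", "network", "hemisphere")
  if (!all(need %in% names(df)))
    stop("atlas must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$roi_label))
    stop("duplicate ROI label(s) in atlas: ",
         paste(unique(df$roi_label[duplicated(df$roi_label)]),
               collapse = ", "))
  df
}

#' @rdname read_atlas
#' @param atlas Data frame with `roi_label`, `network`, `hemisphere`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
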