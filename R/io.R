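#' Read an ROI time-series table
#'
#' Delimited text, header row of region labels, one row per volume (TR).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Numeric T x N matrix with region labels as column names.
#' @export
read_timeseries <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a square connectivity matrix
#'
#' Delimited text with a header row and a leading label column; the row and
#' column label sets must match.
#'
#' @inheritParams read_timeseries
#' @return Numeric N x N matrix with node labels as dimnames.
#' @export
read_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!setequal(rownames(m), colnames(m))) {
    stop("row and column labels differ in ", path)
  }
  m[, rownames(m), drop = FALSE]
}

#' Write a square matrix with labels
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_matrix <- function(m, path, sep = ",") {
  utils::write.table(as.data.frame(unclass(m)), path, sep = sep,
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a node-to-network map
#'
#' Two-column delimited text `node_label,network_name`.
#'
#' @inheritParams read_timeseries
#' @return Named character vector (node label -> network name).
#' @export
read_network_map <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("network map needs two columns: node_label, network_name")
  out <- as.character(df[[2]])
  names(out) <- as.character(df[[1]])
  out
}

#' Read a subject covariate / cognition table
#'
#' One row per subject-occasion:
#' `subject, occasion, age_baseline, gender, education, fd, speed_T, memory_T`.
#' Gender is coded 1 = female, 0 = male; education is ordinal 1-3; fd is the
#' mean framewise displacement across occasions (mm); cognitive scores are
#' T-scores (baseline M = 50, SD = 10).
#'
#' @inheritParams read_timeseries
#' @return Data frame.
#' @export
read_covariates <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("subject", "occasion")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("covariate table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(df[vapply(df, is.numeric, TRUE)])))) {
    stop("covariate table contains non-finite values")
  }
  df
}

#' Load one subject's multilayer network from per-occasion matrix files
#'
#' Subjects without all `n_layers` occasion files are rejected: the temporal
#' analysis requires complete longitudinal data.
#'
#' @param paths Character vector of matrix file paths in occasion order.
#' @param network_map Named character vector from [read_network_map()].
#' @param mode `"positive"` (treat files as ready nonnegative weights) or
#'   `"raw_correlation"` (apply Fisher z + positivize).
#' @param sep Field separator.
#' @return A [assemble_multilayer()] result.
#' @export
load_subject_network <- function(paths, network_map,
                                 mode = c("positive", "raw_correlation"),
                                 sep = ",") {
  mode <- match.arg(mode)
  if (length(paths) < 2) stop("need at least 2 occasion files")
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("incomplete longitudinal data; missing occasion file(s): ",
         paste(missing_files, collapse = ", "))
  }
  layers <- lapply(paths, function(p) {
    m <- read_matrix(p, sep = sep)
    if (mode == "raw_correlation") positivize(fisher_z(m)) else connectivity_layer(m)
  })
  assemble_multilayer(layers, network_map)
}
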