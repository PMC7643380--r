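#' @useDynLib longnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt p.adjust
NULL

# Canonical resting-state network names (Yeo-7 scheme).
YEO7_NETWORKS <- c("FPCN", "DMN", "DAN", "SVAN", "LIMB", "SM", "VIS")

#' Construct a connectivity layer
#'
#' A connectivity layer is one measurement occasion's weighted functional
#' connectivity graph: a nonnegative, symmetric `N x N` matrix with a zero
#' diagonal, with node labels attached. All downstream machinery (multilayer
#' modularity, temporal metrics, null models) assumes exactly these
#' invariants, so they are validated here rather than trusted.
#'
#' @param weights Square numeric matrix of edge weights.
#' @param node_labels Character vector of region labels; defaults to the
#'   matrix dimnames if present.
#' @return An object of class `connectivity_layer`: the weight matrix with
#'   `dimnames` set to the node labels.
#' @export
connectivity_layer <- function(weights, node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop("`weights` must be square")
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
  }
  if (is.null(node_labels)) {
    node_labels <- paste0("n", seq_len(nrow(weights)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(weights)) {
    stop("`node_labels` length must equal the matrix dimension")
  }
  if (anyDuplicated(node_labels)) {
    stop("node labels must be unique")
  }
  if (anyNA(weights)) {
    stop("`weights` contains missing values")
  }
  if (!isSymmetric(unname(weights), tol = 1e-10)) {
    stop("`weights` must be symmetric")
  }
  if (any(diag(weights) != 0)) {
    stop("`weights` must have an exactly zero diagonal")
  }
  if (any(weights < 0)) {
    stop("`weights` must be nonnegative; apply positivize() first")
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(weights, class = c("connectivity_layer", "matrix", "array"))
}

#' @export
print.connectivity_layer <- function(x, ...) {
  n <- nrow(x)
  dens <- mean(x[upper.tri(x)] > 0)
  cat(sprintf("<connectivity_layer> %d nodes, density %.3f, total weight %.3f\n",
              n, dens, sum(x) / 2))
  invisible(x)
}

#' Assemble per-occasion layers into a multilayer network
#'
#' Layers are joined by node label, not by position: each layer is re-indexed
#' to the label order of the first layer, so input files whose rows are
#' permuted across occasions still line up. Every node must carry exactly one
#' resting-state network label.
#'
#' @param layers List of [connectivity_layer()] objects in occasion order
#'   (baseline first).
#' @param network_map Named character vector or two-column data frame
#'   (`node_label`, `network_name`) mapping every node to a network.
#' @param networks Character vector of admissible network names.
#' @return An object of class `multilayer_network` with elements `layers`
#'   (list of N x N matrices), `node_labels`, `network_labels` (named
#'   character vector), `n_nodes`, `n_layers`.
#' @export
assemble_multilayer <- function(layers, network_map,
                                networks = YEO7_NETWORKS) {
  if (length(layers) < 2) {
    stop("a multilayer network needs at least 2 layers")
  }
  layers <- lapply(layers, function(l) {
    if (!inherits(l, "connectivity_layer")) l <- connectivity_layer(l)
    l
  })
  ref <- rownames(layers[[1]])
  aligned <- vector("list", length(layers))
  aligned[[1]] <- layers[[1]]
  for (i in seq_along(layers)[-1]) {
    lab <- rownames(layers[[i]])
    if (!setequal(lab, ref)) {
      missing_here <- setdiff(ref, lab)
      extra_here <- setdiff(lab, ref)
      stop(sprintf(
        "layer %d node labels differ from layer 1 (missing: %s; extra: %s)",
        i,
        if (length(missing_here)) paste(missing_here, collapse = ", ") else "none",
        if (length(extra_here)) paste(extra_here, collapse = ", ") else "none"
      ))
    }
    aligned[[i]] <- connectivity_layer(unclass(layers[[i]])[ref, ref, drop = FALSE], ref)
  }
  if (is.data.frame(network_map)) {
    nm <- as.character(network_map[[2]])
    names(nm) <- as.character(network_map[[1]])
    network_map <- nm
  }
  if (is.null(names(network_map))) {
    stop("`network_map` must be named by node label")
  }
  unmapped <- setdiff(ref, names(network_map))
  if (length(unmapped)) {
    stop("nodes without a network label: ", paste(unmapped, collapse = ", "))
  }
  network_labels <- network_map[ref]
  bad <- setdiff(unique(network_labels), networks)
  if (length(bad)) {
    stop("unknown network names: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      layers = lapply(aligned, function(l) {
        m <- unclass(l)
        class(m) <- NULL
        m
      }),
      node_labels = ref,
      network_labels = network_labels,
      n_nodes = length(ref),
      n_layers = length(layers)
    ),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> N = %d nodes, L = %d layers, networks: %s\n",
              x$n_nodes, x$n_layers,
              paste(sort(unique(x$network_labels)), collapse = " ")))
  invisible(x)
}

#' Pearson correlation matrix of ROI time series
#'
#' Columns are regions, rows are time points (one row per volume/TR). Any
#' region with zero temporal variance cannot be correlated and is reported
#' by name.
#'
#' @param ts Numeric matrix (T time points x N regions) with region labels as
#'   column names, or a data frame thereof.
#' @return N x N Pearson correlation matrix, diagonal 1.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (anyNA(ts)) stop("time series contain missing values")
  if (nrow(ts) < 3) stop("need at least 3 time points")
  if (ncol(ts) < 2) stop("need at least 2 regions")
  if (is.null(colnames(ts))) colnames(ts) <- paste0("n", seq_len(ncol(ts)))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts)
  # numerical guard: force exact symmetry and unit diagonal
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Off-diagonal correlations are clipped to +/-(1 - 1e-7) before `atanh` so
#' that perfectly (anti)correlated pairs map to large finite weights rather
#' than infinities, which the modularity optimizer cannot handle. The
#' diagonal is forced to zero (self-weight carries no information here).
#'
#' @param r_matrix Square symmetric matrix of correlations.
#' @return Matrix of z-values, zero diagonal.
#' @export
fisher_z <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  if (!isSymmetric(unname(r_matrix), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  lim <- 1 - 1e-7
  z <- atanh(pmin(pmax(r_matrix, -lim), lim))
  diag(z) <- 0
  z
}

#' Zero out negative weights
#'
#' Under global signal regression the meaning of negative correlations is
#' ambiguous, so the analysis is restricted to positive weighted networks:
#' negative entries and the diagonal are set to zero.
#'
#' @param z_matrix Square symmetric matrix (typically Fisher-z weights).
#' @param node_labels Optional node labels.
#' @return A [connectivity_layer()].
#' @export
positivize <- function(z_matrix, node_labels = NULL) {
  z_matrix <- as.matrix(z_matrix)
  if (!isSymmetric(unname(z_matrix), tol = 1e-10)) {
    stop("input matrix must be symmetric")
  }
  w <- pmax(z_matrix, 0)
  diag(w) <- 0
  connectivity_layer(w, node_labels)
}

#' FDR-thresholded positive connectivity layer
#'
#' Keeps only statistically significant connections. Each unique off-diagonal
#' correlation r is converted to a two-sided p-value through
#' `t = r * sqrt((T - 2) / (1 - r^2))` with `T - 2` degrees of freedom,
#' Benjamini-Hochberg correction is applied across the `N(N-1)/2` unique
#' pairs, and edges that do not survive at `alpha` — or are negative — are
#' zeroed. Surviving positive correlations are Fisher-z transformed.
#' Correction is per subject (per matrix); p-values are not pooled across
#' subjects.
#'
#' @param r_matrix Square symmetric correlation matrix.
#' @param n_timepoints Number of time points T the correlations were
#'   estimated from (must be >= 4).
#' @param alpha FDR level, in (0, 1]; the thresholded analysis of the
#'   pipeline uses 0.01.
#' @param node_labels Optional node labels.
#' @return A [connectivity_layer()] of Fisher-z weights.
#' @export
fdr_threshold <- function(r_matrix, n_timepoints, alpha = 0.01,
                          node_labels = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]")
  }
  if (n_timepoints < 4) stop("need at least 4 time points for the t-transform")
  r_matrix <- as.matrix(r_matrix)
  if (!isSymmetric(unname(r_matrix), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  n <- nrow(r_matrix)
  ut <- upper.tri(r_matrix)
  r <- pmin(pmax(r_matrix[ut], -(1 - 1e-12)), 1 - 1e-12)
  tval <- r * sqrt((n_timepoints - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df = n_timepoints - 2, lower.tail = FALSE)
  keep <- stats::p.adjust(p, method = "BH") <= alpha
  z <- fisher_z(r_matrix)
  zu <- z[ut]
  zu[!keep] <- 0
  out <- matrix(0, n, n)
  out[ut] <- zu
  out <- out + t(out)
  positivize(out, node_labels %||% rownames(r_matrix))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
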