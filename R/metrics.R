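#' Node flexibility
#'
#' Fraction of possible consecutive-layer transitions at which a node
#' changes community: (number of switches) / (L - 1).
#'
#' @param partition Integer N x L community assignment matrix (`L >= 2`).
#' @return Named numeric vector in `[0, 1]`, one value per node.
#' @export
node_flexibility <- function(partition) {
  partition <- as.matrix(partition)
  L <- ncol(partition)
  if (L < 2) stop("flexibility needs at least 2 layers")
  switches <- rowSums(partition[, -1, drop = FALSE] !=
                        partition[, -L, drop = FALSE])
  out <- switches / (L - 1)
  names(out) <- rownames(partition)
  out
}

#' Node promiscuity
#'
#' Fraction of all communities in which a node participates at least once
#' across layers. The denominator K is the number of distinct communities
#' in this partition; `total_communities` lets callers supply an
#' ensemble-wide K instead.
#'
#' @inheritParams node_flexibility
#' @param total_communities Denominator K; defaults to
#'   [count_modules()] of `partition`.
#' @return Named numeric vector in `(0, 1]`.
#' @export
node_promiscuity <- function(partition, total_communities = NULL) {
  partition <- as.matrix(partition)
  K <- total_communities %||% count_modules(partition)
  visited <- apply(partition, 1, function(g) length(unique(g)))
  out <- visited / K
  names(out) <- rownames(partition)
  out
}

# Shared switch bookkeeping: for each transition l -> l+1, movers are
# grouped by their ordered (source community, destination community) pair;
# a group of >= 2 nodes is a cohesive (mutual) move, a singleton group is a
# disjoint (independent) move. Community splits and merges are therefore
# cohesive by construction.
switch_events <- function(partition) {
  partition <- as.matrix(partition)
  N <- nrow(partition)
  L <- ncol(partition)
  if (L < 2) stop("switch classification needs at least 2 layers")
  events <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    src <- partition[, l]
    dst <- partition[, l + 1]
    movers <- which(src != dst)
    if (!length(movers)) {
      events[[l]] <- list()
      next
    }
    events[[l]] <- split(movers, paste(src[movers], dst[movers], sep = "->"))
  }
  events
}

#' Cohesion matrix and node cohesion strength
#'
#' `cohesion_matrix()` counts, for each node pair, the number of transitions
#' at which both nodes move together from one common community to another
#' common community (identical source -> destination). A node's cohesion
#' strength is its row sum — a raw, unbounded count of mutual switches.
#'
#' @inheritParams node_flexibility
#' @return `cohesion_matrix`: symmetric N x N integer matrix, zero diagonal.
#' @export
cohesion_matrix <- function(partition) {
  partition <- as.matrix(partition)
  N <- nrow(partition)
  M <- matrix(0L, N, N, dimnames = list(rownames(partition), rownames(partition)))
  for (groups in switch_events(partition)) {
    for (g in groups) {
      if (length(g) >= 2) {
        M[g, g] <- M[g, g] + 1L
        M[cbind(g, g)] <- M[cbind(g, g)] - 1L  # no self-pairs
      }
    }
  }
  M
}

#' @rdname cohesion_matrix
#' @return `node_cohesion_strength`: named numeric vector of row sums.
#' @export
node_cohesion_strength <- function(partition) {
  rowSums(cohesion_matrix(partition))
}

#' Node disjointedness
#'
#' Fraction of possible transitions at which a node switches community
#' alone: a switch counts as disjoint iff no other node makes the same
#' (source -> destination) move at that transition. Splits and merges of
#' whole subgroups are never disjoint.
#'
#' @inheritParams node_flexibility
#' @return Named numeric vector in `[0, 1]`.
#' @export
node_disjointedness <- function(partition) {
  partition <- as.matrix(partition)
  N <- nrow(partition)
  L <- ncol(partition)
  cnt <- integer(N)
  for (groups in switch_events(partition)) {
    for (g in groups) {
      if (length(g) == 1) cnt[g] <- cnt[g] + 1L
    }
  }
  out <- cnt / (L - 1)
  names(out) <- rownames(partition)
  out
}

#' Module allegiance matrix
#'
#' Entry (i, j) is the fraction of (layer, optimization) instances in which
#' nodes i and j are assigned to the same community. Computed over a single
#' partition's layers, a list of partitions, or a whole
#' `optimization_ensemble` (pooling all layer-by-rep pairs). Diagonal 1.
#'
#' @param partitions An N x L partition matrix, a list of such matrices, or
#'   an `optimization_ensemble`.
#' @return Symmetric N x N matrix with entries in `[0, 1]`, diagonal 1.
#' @export
allegiance <- function(partitions) {
  if (inherits(partitions, "optimization_ensemble")) {
    partitions <- lapply(partitions$results, `[[`, "partition")
  }
  if (is.matrix(partitions)) partitions <- list(partitions)
  if (!length(partitions)) stop("need at least one partition")
  N <- nrow(partitions[[1]])
  acc <- matrix(0, N, N)
  total <- 0
  for (p in partitions) {
    p <- as.matrix(p)
    for (l in seq_len(ncol(p))) {
      acc <- acc + outer(p[, l], p[, l], "==")
      total <- total + 1
    }
  }
  A <- acc / total
  dimnames(A) <- dimnames(partitions[[1]])[c(1, 1)]
  diag(A) <- 1
  A
}

#' Dynamic recruitment from a module allegiance matrix
#'
#' A node's recruitment is its mean allegiance to the other members of its
#' own predefined resting-state network (self excluded); network recruitment
#' averages over member nodes; global recruitment averages over all nodes.
#' A node whose network has no other member has undefined recruitment and is
#' excluded (NA) from the averages.
#'
#' @param allegiance_matrix N x N allegiance matrix.
#' @param network_labels Character vector (or named vector) of network
#'   membership, one per node, in node order.
#' @return List with `per_node` (named numeric), `per_network` (named
#'   numeric over networks), `global` (scalar).
#' @export
recruitment <- function(allegiance_matrix, network_labels) {
  N <- nrow(allegiance_matrix)
  if (length(network_labels) != N) {
    stop("`network_labels` must cover all nodes")
  }
  network_labels <- as.character(network_labels)
  per_node <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    peers <- which(network_labels == network_labels[i])
    peers <- setdiff(peers, i)
    if (length(peers)) per_node[i] <- mean(allegiance_matrix[i, peers])
  }
  names(per_node) <- rownames(allegiance_matrix) %||% names(network_labels)
  per_network <- tapply(per_node, network_labels, mean, na.rm = TRUE)
  per_network[is.nan(per_network)] <- NA_real_
  list(per_node = per_node,
       per_network = as.vector(per_network, mode = "numeric") |>
         stats::setNames(names(per_network)),
       global = mean(per_node, na.rm = TRUE))
}

GLOBAL_METRICS <- c("flexibility", "promiscuity", "cohesion_strength",
                    "disjointedness", "recruitment")

#' Summarize temporal metrics over an optimization ensemble
#'
#' Flexibility, promiscuity, cohesion strength and disjointedness are
#' computed per optimization run and averaged across the ensemble;
#' allegiance is pooled over all (layer, rep) instances and recruitment is
#' computed from that pooled matrix. Node values are then aggregated to the
#' seven predefined networks and to global means.
#'
#' @param ensemble An `optimization_ensemble` (or a single
#'   `modularity_result`).
#' @param network_labels Network membership per node, in node order.
#' @return Object of class `metric_set`: list with `per_node` (data frame:
#'   node, network, five metric columns), `per_network` (data frame),
#'   `global` (named numeric of the five metrics), `Q_mean`,
#'   `module_count_mean`, `n_reps`.
#' @export
summarize_metrics <- function(ensemble, network_labels) {
  if (inherits(ensemble, "modularity_result")) {
    ensemble <- structure(
      list(results = list(ensemble), mean_Q = ensemble$Q,
           mean_modules = count_modules(ensemble$partition), n_reps = 1L),
      class = "optimization_ensemble")
  }
  stopifnot(inherits(ensemble, "optimization_ensemble"))
  parts <- lapply(ensemble$results, `[[`, "partition")
  N <- nrow(parts[[1]])
  nodes <- rownames(parts[[1]]) %||% paste0("n", seq_len(N))
  if (length(network_labels) != N) stop("`network_labels` must cover all nodes")

  flex <- rowMeans(vapply(parts, node_flexibility, numeric(N)))
  prom <- rowMeans(vapply(parts, node_promiscuity, numeric(N)))
  cohe <- rowMeans(vapply(parts, node_cohesion_strength, numeric(N)))
  disj <- rowMeans(vapply(parts, node_disjointedness, numeric(N)))
  alle <- allegiance(parts)
  recr <- recruitment(alle, network_labels)

  per_node <- data.frame(
    node = nodes,
    network = as.character(network_labels),
    flexibility = unname(flex),
    promiscuity = unname(prom),
    cohesion_strength = unname(cohe),
    disjointedness = unname(disj),
    recruitment = unname(recr$per_node),
    stringsAsFactors = FALSE
  )
  per_network <- do.call(rbind, lapply(split(per_node, per_node$network), function(d) {
    data.frame(network = d$network[1],
               flexibility = mean(d$flexibility),
               promiscuity = mean(d$promiscuity),
               cohesion_strength = mean(d$cohesion_strength),
               disjointedness = mean(d$disjointedness),
               recruitment = mean(d$recruitment, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_network) <- NULL
  global <- c(flexibility = mean(per_node$flexibility),
              promiscuity = mean(per_node$promiscuity),
              cohesion_strength = mean(per_node$cohesion_strength),
              disjointedness = mean(per_node$disjointedness),
              recruitment = mean(per_node$recruitment, na.rm = TRUE))
  structure(
    list(per_node = per_node,
         per_network = per_network,
         global = global,
         allegiance = alle,
         Q_mean = ensemble$mean_Q,
         module_count_mean = ensemble$mean_modules,
         n_reps = ensemble$n_reps),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> %d nodes, %d reps; Q_mean = %.4f, modules = %.2f\n",
              nrow(x$per_node), x$n_reps, x$Q_mean, x$module_count_mean))
  print(round(x$global, 4))
  invisible(x)
}

#' Tidy long-format view of a metric set
#'
#' @param x A `metric_set`.
#' @param subject Optional subject id to prepend.
#' @return Data frame `subject, scope, unit, metric, value` where scope is
#'   node, network or global.
#' @export
metrics_long <- function(x, subject = NA) {
  stopifnot(inherits(x, "metric_set"))
  rows <- list()
  for (m in GLOBAL_METRICS) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, scope = "node", unit = x$per_node$node,
      metric = m, value = x$per_node[[m]], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, scope = "network", unit = x$per_network$network,
      metric = m, value = x$per_network[[m]], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, scope = "global", unit = "global",
      metric = m, value = unname(x$global[m]), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    subject = subject, scope = "global", unit = "global",
    metric = c("Q", "module_count"),
    value = c(x$Q_mean, x$module_count_mean), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
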