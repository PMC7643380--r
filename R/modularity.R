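#' Supra-modularity matrix of an ordinal multilayer network
#'
#' Builds the `NL x NL` matrix `B` whose within-layer diagonal blocks are
#' `A_l - gamma * k_l k_l' / (2 m_l)` (Newman-Girvan null model, with
#' `2 m_l` the total weight of layer l) and whose off-diagonal blocks couple
#' each node to itself in adjacent layers with weight `omega` (ordinal
#' coupling). The quality function is `Q = sum_ij B_ij delta(g_i, g_j) /
#' (2 mu)` with `2 mu = sum_l 2 m_l + 2 omega N (L - 1)` (total intralayer
#' strength plus total interlayer coupling strength).
#'
#' Supra-node order is layer-major: node i of layer l sits at index
#' `(l - 1) * N + i`.
#'
#' @param network A `multilayer_network`.
#' @param gamma Structural resolution parameter (> 0); larger values favour
#'   more, smaller communities. Default 1.
#' @param omega Temporal resolution (interlayer coupling) parameter (>= 0);
#'   larger values favour temporally consistent communities. Default 1.
#' @return List with elements `B` (dense matrix) and `twomu` (scalar).
#' @export
supra_modularity_matrix <- function(network, gamma = 1, omega = 1) {
  stopifnot(inherits(network, "multilayer_network"))
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("`omega` must be >= 0")
  N <- network$n_nodes
  L <- network$n_layers
  B <- matrix(0, N * L, N * L)
  twom_total <- 0
  for (l in seq_len(L)) {
    A <- network$layers[[l]]
    twom <- sum(A)
    if (twom <= 0) {
      stop(sprintf("layer %d is empty (total weight 0): null model undefined", l))
    }
    k <- rowSums(A)
    idx <- (l - 1) * N + seq_len(N)
    B[idx, idx] <- A - gamma * tcrossprod(k) / twom
    twom_total <- twom_total + twom
  }
  if (omega > 0 && L >= 2) {
    for (l in seq_len(L - 1)) {
      i1 <- (l - 1) * N + seq_len(N)
      i2 <- l * N + seq_len(N)
      B[cbind(i1, i2)] <- omega
      B[cbind(i2, i1)] <- omega
    }
  }
  twomu <- twom_total + 2 * omega * N * (L - 1)
  list(B = B, twomu = twomu)
}

#' Evaluate the multilayer modularity of a partition
#'
#' Direct, layer-by-layer evaluation of the quality function
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijlr} \left[(A_{ijl} - \gamma
#'   P_{ijl})\delta_{lr} + \delta_{ij}\,\omega_{jlr}\right]
#'   \delta(g_{il}, g_{jr})}
#' with `P_ijl = k_il k_jl / (2 m_l)` and `omega_jlr = omega` for
#' `|l - r| = 1` (ordinal coupling), zero otherwise. This evaluator is
#' independent of the optimizer's internal bookkeeping and serves as its
#' oracle: every optimizer run's reported Q must agree with it to 1e-10.
#'
#' @param network A `multilayer_network`.
#' @param partition Integer N x L matrix of community assignments `g_il`.
#' @inheritParams supra_modularity_matrix
#' @return Scalar Q.
#' @export
evaluate_Q <- function(network, partition, gamma = 1, omega = 1) {
  stopifnot(inherits(network, "multilayer_network"))
  partition <- as.matrix(partition)
  N <- network$n_nodes
  L <- network$n_layers
  if (nrow(partition) != N || ncol(partition) != L) {
    stop(sprintf("partition shape (%d x %d) does not match network (%d x %d)",
                 nrow(partition), ncol(partition), N, L))
  }
  total <- 0
  twomu <- 0
  for (l in seq_len(L)) {
    A <- network$layers[[l]]
    twom <- sum(A)
    if (twom <= 0) {
      stop(sprintf("layer %d is empty (total weight 0): null model undefined", l))
    }
    k <- rowSums(A)
    same <- outer(partition[, l], partition[, l], "==")
    total <- total + sum((A - gamma * tcrossprod(k) / twom)[same])
    twomu <- twomu + twom
  }
  if (L >= 2) {
    for (l in seq_len(L - 1)) {
      # each (j, l, l+1) pair appears twice in the ijlr sum (l,r and r,l)
      total <- total + 2 * omega * sum(partition[, l] == partition[, l + 1])
    }
    twomu <- twomu + 2 * omega * N * (L - 1)
  }
  total / twomu
}

#' Canonicalize community ids of a multilayer partition
#'
#' Relabels community ids to 1..K by order of first appearance scanning
#' node-major within layer 1, then layer 2, and so on, so that equivalent
#' partitions compare bit-stably.
#'
#' @param partition Integer N x L matrix.
#' @return Integer N x L matrix with ids 1..K.
#' @export
canonicalize_partition <- function(partition) {
  partition <- as.matrix(partition)
  v <- as.vector(partition)  # column-major: layer 1 nodes first
  ids <- unique(v)
  out <- matrix(match(v, ids), nrow(partition), ncol(partition))
  dimnames(out) <- dimnames(partition)
  out
}

#' Number of distinct modules in a partition
#' @param partition Integer N x L matrix.
#' @return Integer count of distinct community ids across all layers.
#' @export
count_modules <- function(partition) {
  length(unique(as.vector(as.matrix(partition))))
}

#' Maximize multilayer modularity with a generalized Louvain algorithm
#'
#' Louvain-style optimization on the supra-node graph: phase 1 sweeps
#' supra-nodes in random order and accepts strictly improving community
#' moves; phase 2 aggregates communities into super-nodes; the two phases
#' alternate until no improving move exists. Under `move_rule = "move"` the
#' best improving move is taken (ties broken by the seeded RNG); under
#' `"moverandw"` one improving move is chosen with probability proportional
#' to its modularity gain, which mitigates an abrupt-change pathology of the
#' greedy rule for ordinal interlayer coupling and is the rule used
#' throughout this pipeline.
#'
#' @inheritParams supra_modularity_matrix
#' @param seed Integer RNG seed; every run is reproducible given its seed.
#' @param move_rule `"moverandw"` (default) or `"move"`.
#' @param max_sweeps Cap on phase-1 sweeps per level before the run aborts
#'   with a diagnostic (default 1000).
#' @param .sm Precomputed [supra_modularity_matrix()] result, reused across
#'   ensemble restarts; leave NULL to build it from the network.
#' @return Object of class `modularity_result`: list with `partition`
#'   (canonicalized N x L integer matrix), `Q`, `gamma`, `omega`, `seed`,
#'   `move_rule`, `n_sweeps`.
#' @export
genlouvain_optimize <- function(network, gamma = 1, omega = 1, seed = 1,
                                move_rule = c("moverandw", "move"),
                                max_sweeps = 1000, .sm = NULL) {
  move_rule <- match.arg(move_rule)
  sm <- .sm %||% supra_modularity_matrix(network, gamma, omega)
  set.seed(seed)
  res <- genlouvain_cpp(sm$B, if (move_rule == "move") 0L else 1L,
                        as.integer(max_sweeps))
  N <- network$n_nodes
  L <- network$n_layers
  partition <- canonicalize_partition(matrix(res$membership, N, L))
  rownames(partition) <- network$node_labels
  structure(
    list(partition = partition,
         Q = res$q_num / sm$twomu,
         gamma = gamma, omega = omega,
         seed = seed, move_rule = move_rule,
         n_sweeps = res$n_sweeps),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result> Q = %.4f, %d modules (gamma = %g, omega = %g, seed = %d)\n",
              x$Q, count_modules(x$partition), x$gamma, x$omega, x$seed))
  invisible(x)
}

#' Repeated seeded modularity optimization
#'
#' The community detection algorithm is stochastic, so the pipeline runs it
#' `n_reps` times (default 100) and averages Q and all derived metrics over
#' the ensemble. Rep seeds are derived deterministically from `base_seed`,
#' so ensembles are bit-reproducible.
#'
#' @inheritParams genlouvain_optimize
#' @param n_reps Number of independent restarts (default 100).
#' @param base_seed Seed of the ensemble.
#' @return Object of class `optimization_ensemble`: list with `results`
#'   (list of `modularity_result`), `mean_Q`, `mean_modules`, `n_reps`,
#'   `gamma`, `omega`, `base_seed`.
#' @export
repeated_optimization <- function(network, gamma = 1, omega = 1,
                                  n_reps = 100, base_seed = 1,
                                  move_rule = c("moverandw", "move"),
                                  max_sweeps = 1000) {
  move_rule <- match.arg(move_rule)
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  seeds <- derive_seeds(base_seed, n_reps)
  sm <- supra_modularity_matrix(network, gamma, omega)
  results <- lapply(seeds, function(s) {
    genlouvain_optimize(network, gamma, omega, seed = s,
                        move_rule = move_rule, max_sweeps = max_sweeps,
                        .sm = sm)
  })
  qs <- vapply(results, `[[`, numeric(1), "Q")
  ks <- vapply(results, function(r) count_modules(r$partition), numeric(1))
  structure(
    list(results = results,
         mean_Q = mean(qs),
         mean_modules = mean(ks),
         n_reps = n_reps,
         gamma = gamma, omega = omega,
         base_seed = base_seed, move_rule = move_rule),
    class = "optimization_ensemble"
  )
}

#' @export
print.optimization_ensemble <- function(x, ...) {
  cat(sprintf("<optimization_ensemble> %d runs, mean Q = %.4f, mean modules = %.2f\n",
              x$n_reps, x$mean_Q, x$mean_modules))
  invisible(x)
}
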