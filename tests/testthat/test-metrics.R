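# Hand-written multilayer partitions with known switch tallies. Rows are
# nodes, columns are layers.

test_that("flexibility counts consecutive-layer switches over L - 1", {
  p <- pmat(1, 1, 2, 2,
            1, 2, 1, 2,
            3, 3, 3, 3, nrow = 3)
  f <- node_flexibility(p)
  expect_equal(unname(f), c(1 / 3, 1, 0))
  expect_error(node_flexibility(p[, 1, drop = FALSE]), "2 layers")
})

test_that("promiscuity is communities visited over total communities", {
  p <- pmat(1, 2, 1, 2,
            3, 3, 3, 3,
            1, 4, 2, 1, nrow = 3)  # K = 4
  pr <- node_promiscuity(p)
  expect_equal(unname(pr), c(2 / 4, 1 / 4, 3 / 4))
  expect_equal(unname(node_promiscuity(matrix(1L, 5, 3))), rep(1, 5))
  # ensemble-wide denominator can be supplied
  expect_equal(unname(node_promiscuity(p, total_communities = 8)),
               c(2 / 8, 1 / 8, 3 / 8))
})

test_that("a joint move is cohesive, a lone move is disjoint", {
  # nodes 1 and 2 move A(1) -> B(2) together at transition 1;
  # node 4 moves alone at transition 2; node 3 never moves.
  p <- pmat(1, 2, 2,
            1, 2, 2,
            1, 1, 1,
            3, 3, 1, nrow = 4)
  cm <- cohesion_matrix(p)
  expect_equal(cm[1, 2], 1L)
  expect_equal(sum(cm) - 2 * cm[1, 2], 0)
  expect_equal(unname(node_cohesion_strength(p)), c(1, 1, 0, 0))
  expect_equal(unname(node_disjointedness(p)), c(0, 0, 0, 1 / 2))
})

test_that("community splits and merges give cohesion > 0 and disjointedness = 0", {
  # split: community 1 = {1,2,3,4}; {1,2} -> B(4), {3,4} -> C(5)
  split_p <- pmat(1, 4,
                  1, 4,
                  1, 5,
                  1, 5,
                  2, 2,
                  3, 3, nrow = 6)
  expect_true(all(node_cohesion_strength(split_p)[1:4] > 0))
  expect_equal(unname(node_disjointedness(split_p)), rep(0, 6))

  # merge: all of community 2 = {4,5,6} joins community 1
  merge_p <- pmat(1, 1,
                  1, 1,
                  1, 1,
                  2, 1,
                  2, 1,
                  2, 1, nrow = 6)
  expect_true(all(node_cohesion_strength(merge_p)[4:6] > 0))
  expect_equal(unname(node_disjointedness(merge_p)), rep(0, 6))
  # no-switch partition: all zero
  expect_true(all(cohesion_matrix(matrix(1L, 4, 3)) == 0))
})

test_that("same (source, destination) at the same transition is required for cohesion", {
  # both nodes leave community 1 at transition 1 but to different targets
  p <- pmat(1, 2,
            1, 3,
            4, 4, nrow = 3)
  expect_true(all(cohesion_matrix(p) == 0))
  expect_equal(unname(node_disjointedness(p)), c(1, 1, 0))
})

test_that("every switch is classified at most once", {
  set.seed(17)
  for (rep in 1:20) {
    p <- matrix(sample.int(4, 8 * 4, replace = TRUE), 8, 4)
    switches <- (ncol(p) - 1) * node_flexibility(p)
    disjoint <- (ncol(p) - 1) * node_disjointedness(p)
    # cohesive switch count per node: transitions with a joint move
    cohesive <- vapply(seq_len(nrow(p)), function(i) {
      cnt <- 0
      for (l in seq_len(ncol(p) - 1)) {
        if (p[i, l] == p[i, l + 1]) next
        joint <- any(p[-i, l] == p[i, l] & p[-i, l + 1] == p[i, l + 1])
        if (joint) cnt <- cnt + 1
      }
      cnt
    }, numeric(1))
    expect_equal(disjoint + cohesive, switches)
    # flexibility 0 implies 1/K promiscuity and no classified switches
    frozen <- switches == 0
    if (any(frozen)) {
      expect_true(all(node_promiscuity(p)[frozen] == 1 / count_modules(p)))
      expect_true(all(node_cohesion_strength(p)[frozen] == 0))
      expect_true(all(node_disjointedness(p)[frozen] == 0))
    }
  }
})

test_that("allegiance pools layers and reps; constant partition gives 0/1 blocks", {
  # i, j share a community in 3 of 4 layers
  p <- pmat(1, 1, 1, 2,
            1, 1, 1, 3, nrow = 2)
  expect_equal(allegiance(p)[1, 2], 0.75)
  expect_equal(unname(diag(allegiance(p))), c(1, 1))

  const <- matrix(rep(c(1L, 1L, 2L, 2L, 3L), 3), 5, 3)
  A <- allegiance(const)
  expect_true(all(A %in% c(0, 1)))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0)

  # two reps pool to the average of the instances
  p2 <- pmat(1, 1, 1, 1,
             1, 1, 1, 1, nrow = 2)
  expect_equal(allegiance(list(p, p2))[1, 2], (3 + 4) / 8)
})

test_that("recruitment averages same-network allegiance, self excluded", {
  ones <- matrix(1, 4, 4)
  rec <- recruitment(ones, c("S", "S", "T", "T"))
  expect_equal(unname(rec$per_node), rep(1, 4))
  expect_equal(rec$global, 1)

  A <- matrix(0, 4, 4); diag(A) <- 1
  A[1, 2] <- A[2, 1] <- 0.5
  rec <- recruitment(A, c("S", "S", "T", "T"))
  expect_equal(rec$per_node[[1]], 0.5)
  expect_equal(rec$per_node[[3]], 0)

  # partition identical to the predefined networks: self-recruitment 1,
  # zero allegiance across networks
  const <- matrix(rep(rep(1:2, each = 3), 2), 6, 2)
  rec <- recruitment(allegiance(const), rep(c("DMN", "VIS"), each = 3))
  expect_equal(unname(rec$per_network), c(1, 1))

  # single-member network flagged missing and excluded from averages
  rec <- recruitment(ones, c("S", "S", "S", "LONE"))
  expect_true(is.na(rec$per_node[[4]]))
  expect_true(is.na(rec$per_network[["LONE"]]))
  expect_equal(rec$global, 1)
  expect_error(recruitment(ones, c("S", "S")), "cover")
})

test_that("summarize_metrics averages per rep then aggregates consistently", {
  pA <- pmat(1, 1, 2, 2,
             1, 1, 1, 1, nrow = 2)  # flexibilities 1/3, 0
  pB <- pmat(1, 2, 1, 2,
             1, 1, 1, 2, nrow = 2)  # flexibilities 1, 1/3
  mk_res <- function(p, q) structure(
    list(partition = p, Q = q, gamma = 1, omega = 1, seed = 1,
         move_rule = "moverandw", n_sweeps = 1L),
    class = "modularity_result")
  ens <- structure(list(results = list(mk_res(pA, 0.2), mk_res(pB, 0.4)),
                        mean_Q = 0.3, mean_modules = 2, n_reps = 2L),
                   class = "optimization_ensemble")
  ms <- summarize_metrics(ens, c("DMN", "DMN"))
  expect_equal(ms$per_node$flexibility, c((1 / 3 + 1) / 2, (0 + 1 / 3) / 2))
  expect_equal(ms$Q_mean, 0.3)
  # network and global rows recompute exactly from the per-node table
  expect_equal(ms$per_network$flexibility[ms$per_network$network == "DMN"],
               mean(ms$per_node$flexibility))
  expect_equal(unname(ms$global["flexibility"]), mean(ms$per_node$flexibility))
  # long view covers node, network and global scopes
  long <- metrics_long(ms, subject = "sub-001")
  expect_setequal(unique(long$scope), c("node", "network", "global"))
  expect_equal(long$value[long$metric == "Q"], 0.3)
})
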