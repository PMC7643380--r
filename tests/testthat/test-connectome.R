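test_that("correlation_matrix matches closed-form cases and rejects degenerate input", {
  t_axis <- seq_len(100)
  x <- sin(2 * pi * t_axis / 100)
  ts <- cbind(a = x, b = 2 * x + 5, c = -x,
              d = cos(2 * pi * t_axis / 100))
  r <- correlation_matrix(ts)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["a", "b"], 1.0)                  # identical up to affine map
  expect_equal(r["a", "c"], -1.0)                 # negation
  expect_lt(abs(r["a", "d"]), 1e-6)               # sampled sin/cos orthogonal
  expect_true(all(r >= -1 & r <= 1))

  ts_bad <- cbind(a = x, flatline = rep(2, 100))
  expect_error(correlation_matrix(ts_bad), "flatline")
})

test_that("correlation_matrix is invariant under positive affine rescaling", {
  set.seed(11)
  ts <- matrix(rnorm(50 * 4), 50, dimnames = list(NULL, letters[1:4]))
  r1 <- correlation_matrix(ts)
  ts2 <- ts
  ts2[, 2] <- 3.7 * ts2[, 2] - 12
  expect_equal(correlation_matrix(ts2), r1, tolerance = 1e-12)
})

test_that("fisher_z applies atanh off-diagonal, zero diagonal, clips r = 1", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.5, 0, -0.5, 1), 3)
  z <- fisher_z(r)
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)  # atanh(0.5)
  expect_equal(z[2, 3], -z[1, 2])                  # odd symmetry
  expect_equal(z[1, 3], 0)
  expect_equal(unname(diag(z)), rep(0, 3))
  r_extreme <- matrix(c(1, 1, 1, 1), 2)
  expect_true(all(is.finite(fisher_z(r_extreme))))
  expect_error(fisher_z(matrix(c(0, 0.2, 0.5, 0), 2)), "symmetric")
})

test_that("positivize zeroes negatives and the diagonal, and is idempotent", {
  z <- matrix(c(0.3, -0.2, 0.1,
                -0.2, 0.5, 0.4,
                0.1, 0.4, -0.9), 3)
  layer <- positivize(z)
  expect_s3_class(layer, "connectivity_layer")
  expect_equal(unname(diag(layer)), rep(0, 3))
  expect_equal(layer[1, 2], 0)
  expect_equal(layer[2, 3], 0.4)
  expect_equal(unclass(positivize(unclass(layer))), unclass(layer))

  all_neg <- matrix(-abs(rnorm(16)), 4); all_neg <- all_neg + t(all_neg); diag(all_neg) <- 0
  expect_true(all(unclass(positivize(all_neg)) == 0))
  expect_error(positivize(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("positivize after fisher_z preserves the nonpositive zero pattern", {
  set.seed(21)
  for (rep in 1:5) {
    r <- stats::cor(matrix(rnorm(30 * 8), 30))
    layer <- positivize(fisher_z(r))
    off <- upper.tri(r)
    expect_identical(unclass(layer)[off] == 0, r[off] <= 0)
  }
})

test_that("fdr_threshold matches a hand-rolled Benjamini-Hochberg oracle", {
  n_t <- 40
  set.seed(31)
  # near-null correlations plus one strong pair
  base <- matrix(rnorm(n_t * 6, sd = 1), n_t, 6)
  base[, 2] <- base[, 1] + rnorm(n_t, sd = 0.3)  # strong positive pair (1,2)
  r <- stats::cor(base)
  layer <- fdr_threshold(r, n_t, alpha = 0.01)

  # independent BH oracle on the same unique pairs
  ut <- upper.tri(r)
  rv <- r[ut]
  tv <- rv * sqrt((n_t - 2) / (1 - rv^2))
  pv <- 2 * pt(abs(tv), n_t - 2, lower.tail = FALSE)
  m <- length(pv)
  ord <- order(pv)
  thresh <- max(c(0, which(pv[ord] <= (seq_len(m) / m) * 0.01)))
  surviving <- logical(m)
  if (thresh > 0) surviving[ord[seq_len(thresh)]] <- TRUE
  expected_edges <- surviving & rv > 0
  expect_identical(unclass(layer)[ut] > 0, expected_edges)
  expect_true(layer[1, 2] > 0)

  # alpha = 1 disables the threshold entirely
  full <- fdr_threshold(r, n_t, alpha = 1)
  expect_equal(unclass(full), unclass(positivize(fisher_z(r))))
  # thresholded edge set is always a subset of the positive edge set
  expect_true(all(unclass(layer)[unclass(positivize(fisher_z(r))) == 0] == 0))
  expect_error(fdr_threshold(r, n_t, alpha = 0), "alpha")
})

test_that("assemble_multilayer aligns layers by node label and validates", {
  set.seed(41)
  n <- 5
  labels <- paste0("ROI_", 1:n)
  base <- matrix(runif(n^2), n); base <- (base + t(base)) / 2; diag(base) <- 0
  dimnames(base) <- list(labels, labels)
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- base[perm, perm]
  nm <- stats::setNames(rep(c("DMN", "VIS"), c(3, 2)), labels)

  net <- assemble_multilayer(list(connectivity_layer(base),
                                  connectivity_layer(shuffled)),
                             nm)
  expect_equal(net$n_layers, 2)
  # permuted layer realigned to layer-1 label order
  expect_equal(net$layers[[2]], unname(unclass(base)), ignore_attr = TRUE)

  dropped <- base[-1, -1]
  expect_error(assemble_multilayer(list(connectivity_layer(base),
                                        connectivity_layer(dropped)), nm),
               "ROI_1")
  expect_error(assemble_multilayer(list(connectivity_layer(base),
                                        connectivity_layer(base)),
                                   nm[-2]),
               "ROI_2")
  expect_error(assemble_multilayer(list(connectivity_layer(base)), nm),
               "at least 2")
})

test_that("time-series round trip: files -> layers -> multilayer network", {
  dir <- withr::local_tempdir()
  set.seed(51)
  part <- rep(1:2, each = 4)
  labels <- sprintf("ROI_%03d", 1:8)
  paths <- character(3)
  for (l in 1:3) {
    ts <- simulate_timeseries(part, n_timepoints = 120, mu_within = 0.7,
                              mu_between = 0.05, node_labels = labels)
    r <- correlation_matrix(ts)
    paths[l] <- file.path(dir, sprintf("occ%d.csv", l))
    write_matrix(positivize(fisher_z(r)), paths[l])
  }
  nm <- stats::setNames(rep(c("DMN", "VIS"), each = 4), labels)
  net <- load_subject_network(paths, nm)
  expect_equal(net$n_nodes, 8)
  expect_equal(net$n_layers, 3)
  # planted within-block correlation shows up as heavier within-block weight
  w <- net$layers[[1]]
  within <- mean(w[1:4, 1:4][upper.tri(matrix(0, 4, 4))])
  between <- mean(w[1:4, 5:8])
  expect_gt(within, between)
  expect_error(load_subject_network(c(paths, file.path(dir, "missing.csv")), nm),
               "missing")
})
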