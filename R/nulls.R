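#' Temporal null model: shuffle layer order
#'
#' Reorders the layers of a multilayer network by a uniformly random
#' permutation of occasions. Connectivity within each layer is untouched,
#' so any order-invariant per-layer statistic is preserved exactly, but
#' temporal dependence between consecutive layers is destroyed. The
#' identity permutation is admissible.
#'
#' @param network A `multilayer_network` with `L >= 2`.
#' @param seed Integer RNG seed.
#' @return A `multilayer_network` with permuted layers.
#' @export
temporal_null <- function(network, seed = 1) {
  stopifnot(inherits(network, "multilayer_network"))
  if (network$n_layers < 2) stop("temporal null needs at least 2 layers")
  set.seed(seed)
  perm <- sample.int(network$n_layers)
  out <- network
  out$layers <- network$layers[perm]
  attr(out, "layer_permutation") <- perm
  out
}

#' Nodal null model: permute within-layer edge weights
#'
#' Within each layer independently, the off-diagonal upper-triangle weights
#' are randomly permuted over node pairs and re-symmetrized. Each layer's
#' weight multiset, density, symmetry and zero diagonal are preserved
#' exactly, while community structure — which nodes the weight mass ties
#' together — is destroyed.
#'
#' @param network A `multilayer_network`.
#' @param seed Integer RNG seed.
#' @return A `multilayer_network` with rewired layers.
#' @export
nodal_null <- function(network, seed = 1) {
  stopifnot(inherits(network, "multilayer_network"))
  set.seed(seed)
  out <- network
  out$layers <- lapply(network$layers, function(A) {
    n <- nrow(A)
    ut <- upper.tri(A)
    w <- A[ut]
    B <- matrix(0, n, n, dimnames = dimnames(A))
    B[ut] <- sample(w)
    B + t(B)
  })
  out
}

#' Metric sets for an ensemble of null networks
#'
#' Draws `n_null` null realizations of a subject's multilayer network,
#' optimizes multilayer modularity `n_reps` times on each, and summarizes
#' the temporal metrics. Seeds fan out deterministically from `base_seed`
#' (one substream per null, one per rep), so the whole ensemble is
#' reproducible.
#'
#' @param network A `multilayer_network`.
#' @param kind `"temporal"` or `"nodal"`.
#' @param n_null Number of null networks (default 50).
#' @param n_reps Optimizations per null network (default 100).
#' @param base_seed Master seed for the ensemble.
#' @inheritParams genlouvain_optimize
#' @return List of `metric_set` objects, one per null network, with the
#'   null seeds as an attribute.
#' @export
null_ensemble <- function(network, kind = c("temporal", "nodal"),
                          n_null = 50, n_reps = 100, base_seed = 1,
                          gamma = 1, omega = 1,
                          move_rule = c("moverandw", "move")) {
  kind <- match.arg(kind)
  move_rule <- match.arg(move_rule)
  if (n_null < 1) stop("`n_null` must be >= 1")
  seeds <- derive_seeds(base_seed, 2L * n_null)
  draw_seeds <- seeds[seq_len(n_null)]
  opt_seeds <- seeds[n_null + seq_len(n_null)]
  out <- vector("list", n_null)
  for (i in seq_len(n_null)) {
    nl <- if (kind == "temporal") {
      temporal_null(network, draw_seeds[i])
    } else {
      nodal_null(network, draw_seeds[i])
    }
    ens <- repeated_optimization(nl, gamma = gamma, omega = omega,
                                 n_reps = n_reps, base_seed = opt_seeds[i],
                                 move_rule = move_rule)
    out[[i]] <- summarize_metrics(ens, network$network_labels)
  }
  attr(out, "kind") <- kind
  attr(out, "seeds") <- draw_seeds
  out
}

#' Average the global metrics of a list of metric sets
#'
#' Convenience for the per-subject null summary: the null metric values are
#' averaged across the `n_null` null networks, giving one null value per
#' subject per metric (so real and null group samples have equal length).
#'
#' @param metric_sets List of `metric_set` objects.
#' @return Named numeric vector: the five global metrics plus `Q` and
#'   `module_count`.
#' @export
average_global_metrics <- function(metric_sets) {
  g <- vapply(metric_sets, function(m) c(m$global, Q = m$Q_mean,
                                         module_count = m$module_count_mean),
              numeric(7))
  rowMeans(g)
}

#' Welch comparison of real versus null metric values
#'
#' Welch's two-sample t test (unequal variances, Satterthwaite degrees of
#' freedom) of per-subject real metric values against per-subject null
#' values, with the pooled-SD Cohen's d effect size. Effect sizes are read
#' against the conventional bands: d >= 0.2 small, >= 0.5 medium,
#' >= 0.8 large. When several metrics are tested, significance is assessed
#' at the Bonferroni-adjusted level alpha / n_comparisons.
#'
#' @param real_values Numeric vector, one value per subject.
#' @param null_values Numeric vector, one (averaged) null value per subject.
#' @param metric Metric name carried into the report.
#' @param alpha Family-wise alpha before adjustment (default 0.05).
#' @param n_comparisons Number of metrics in the family (default 1).
#' @return One-row data frame: metric, t, df, p, d, direction,
#'   effect_class, significant.
#' @export
compare_to_null <- function(real_values, null_values, metric = "metric",
                            alpha = 0.05, n_comparisons = 1) {
  real_values <- as.numeric(real_values)
  null_values <- as.numeric(null_values)
  if (length(real_values) < 2 || length(null_values) < 2) {
    stop("need at least 2 values per group")
  }
  if (stats::var(real_values) == 0 && stats::var(null_values) == 0) {
    stop("zero variance in both samples: Welch test undefined")
  }
  tt <- stats::t.test(real_values, null_values, var.equal = FALSE)
  n1 <- length(real_values); n2 <- length(null_values)
  sp <- sqrt(((n1 - 1) * stats::var(real_values) +
                (n2 - 1) * stats::var(null_values)) / (n1 + n2 - 2))
  d <- abs(mean(real_values) - mean(null_values)) / sp
  eff <- if (d >= 0.8) "large" else if (d >= 0.5) "medium" else
    if (d >= 0.2) "small" else "negligible"
  data.frame(
    metric = metric,
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    d = d,
    direction = sign(mean(real_values) - mean(null_values)),
    effect_class = eff,
    significant = tt$p.value < alpha / n_comparisons,
    stringsAsFactors = FALSE
  )
}
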