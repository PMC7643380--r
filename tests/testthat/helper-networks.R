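# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk.

# Multilayer network from a list of plain weight matrices. All nodes get the
# same network label unless `labels` is supplied.
make_multilayer <- function(layers, labels = NULL) {
  n <- nrow(layers[[1]])
  node_labels <- rownames(layers[[1]])
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  layers <- lapply(layers, function(m) {
    dimnames(m) <- list(node_labels, node_labels)
    connectivity_layer(m)
  })
  if (is.null(labels)) labels <- rep("FPCN", n)
  nm <- stats::setNames(labels, node_labels)
  if (length(layers) >= 2) {
    assemble_multilayer(layers, nm)
  } else {
    structure(list(layers = lapply(layers, unclass),
                   node_labels = node_labels, network_labels = nm,
                   n_nodes = n, n_layers = 1L),
              class = "multilayer_network")
  }
}

# Planted community network: L layers around a fixed membership vector.
planted_network <- function(membership, n_layers, mu_within = 0.6,
                            mu_between = 0.05, noise_sd = 0.02, seed = 1,
                            labels = NULL) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    unclass(layer_from_partition(membership, mu_within, mu_between, noise_sd))
  })
  make_multilayer(layers, labels)
}

# Random dense positive weighted multilayer network (no planted structure).
random_network <- function(n_nodes, n_layers, seed = 1) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    m <- matrix(stats::runif(n_nodes^2), n_nodes)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  make_multilayer(layers)
}

# Partition matrix helper: rows = nodes, columns = layers.
pmat <- function(..., nrow) matrix(c(...), nrow = nrow, byrow = TRUE)
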