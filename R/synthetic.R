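# sample() without the scalar-x surprise
resample <- function(x, size = 1) x[sample.int(length(x), size)]

#' Default Yeo-7 block sizes for a given parcellation size
#'
#' Block sizes proportional to the Schaefer-200/Yeo-7 convention
#' (FPCN 30, DMN 44, DAN 26, SVAN 24, LIMB 12, SM 34, VIS 30 at N = 200),
#' rescaled by largest remainder for other node counts.
#'
#' @param n_nodes Total number of nodes.
#' @return Named integer vector of 7 block sizes summing to `n_nodes`.
#' @export
yeo7_block_sizes <- function(n_nodes = 200) {
  ref <- c(FPCN = 30, DMN = 44, DAN = 26, SVAN = 24, LIMB = 12, SM = 34, VIS = 30)
  if (n_nodes == 200) return(ref)
  raw <- ref / 200 * n_nodes
  base <- floor(raw)
  rem <- n_nodes - sum(base)
  add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[add] <- base[add] + 1
  if (any(base < 1)) stop("n_nodes too small for 7 nonempty networks")
  base
}

#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Defaults emulate the cohort conditions the pipeline was designed for:
#' 150 subjects aged 64-83 (baseline mean 69.8), 200 cortical regions in 7
#' resting-state networks, 4 measurement occasions at 0/1/2/4 years.
#' Community switching between consecutive occasions happens at
#' `base_switch_prob` per node, increasing with age by `age_effect` per
#' year; a `cohesive_fraction` of switching events are executed as subgroup
#' moves (producing cohesion, not disjointedness). Edge weights live on the
#' Fisher-z scale: within-community pairs average `mu_within`,
#' between-community pairs `mu_between`, with Gaussian noise clipped at 0.
#' Cognitive T-scores (baseline M = 50, SD = 10 scaling) decline by
#' `cognitive_slope_mean` per year, more steeply with age by
#' `slope_age_effect`, with a `retest_bump` at every follow-up.
#'
#' @param n_subjects,n_nodes,n_layers Cohort dimensions.
#' @param network_sizes 7 block sizes summing to `n_nodes`.
#' @param mu_within,mu_between Mean edge weights (Fisher-z units),
#'   `mu_within > mu_between >= 0`.
#' @param noise_sd Edge-weight noise SD.
#' @param base_switch_prob Per-node switching probability per transition at
#'   mean age.
#' @param age_effect Increment to switch probability per year of age.
#' @param cohesive_fraction Share of switching events executed as subgroup
#'   moves.
#' @param occasion_times Years since baseline of the occasions.
#' @param cognitive_intercept,cognitive_slope_mean,slope_age_effect,slope_sd,retest_bump
#'   Cognition model parameters (T-score units).
#' @param seed Master RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 150,
                       n_nodes = 200,
                       n_layers = 4,
                       network_sizes = yeo7_block_sizes(n_nodes),
                       mu_within = 0.5,
                       mu_between = 0.1,
                       noise_sd = 0.1,
                       base_switch_prob = 0.4,
                       age_effect = 0.0036,
                       cohesive_fraction = 0.9,
                       occasion_times = c(0, 1, 2, 4),
                       cognitive_intercept = 50,
                       cognitive_slope_mean = -0.5,
                       slope_age_effect = -0.05,
                       slope_sd = 0.5,
                       retest_bump = 1.8,
                       seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_nodes = n_nodes, n_layers = n_layers,
              network_sizes = network_sizes, mu_within = mu_within,
              mu_between = mu_between, noise_sd = noise_sd,
              base_switch_prob = base_switch_prob, age_effect = age_effect,
              cohesive_fraction = cohesive_fraction,
              occasion_times = occasion_times,
              cognitive_intercept = cognitive_intercept,
              cognitive_slope_mean = cognitive_slope_mean,
              slope_age_effect = slope_age_effect, slope_sd = slope_sd,
              retest_bump = retest_bump, seed = seed)
  if (length(cfg$network_sizes) != 7 || any(cfg$network_sizes < 1)) {
    stop("`network_sizes` must be 7 positive block sizes")
  }
  if (sum(cfg$network_sizes) != n_nodes) {
    stop("`network_sizes` must sum to `n_nodes`")
  }
  if (!(mu_within > mu_between && mu_between >= 0)) {
    stop("need mu_within > mu_between >= 0")
  }
  probs <- c(base_switch_prob, cohesive_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(occasion_times) != n_layers) {
    stop("`occasion_times` must have one entry per layer")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Sample baseline ages
#'
#' Ages are drawn from a right-skewed Beta(2, 4.552) distribution rescaled
#' to an elderly cohort's baseline range [64, 83], with mean exactly 69.8
#' years.
#'
#' @param n Number of subjects.
#' @param seed RNG seed.
#' @return Numeric vector of ages in `[64, 83]`.
#' @export
sample_ages <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  m <- (69.8 - 64) / 19
  64 + 19 * stats::rbeta(n, 2, 2 * (1 - m) / m)
}

#' Evolve a community partition by one occasion
#'
#' Each node is independently flagged to switch with probability
#' `switch_prob`. Within each community, flagged nodes are executed either
#' as cohesive subgroup moves (a random subset of at least two flagged
#' nodes moves to one common target community) with probability
#' `cohesive_fraction`, or as disjoint lone moves. Targets are drawn among
#' the other existing community ids. A lone flagged straggler on a
#' cohesive event stays mutual by joining the previous subgroup's
#' destination (or recruiting an unflagged partner), so
#' `cohesive_fraction = 1` yields zero disjointedness wherever a community
#' has more than one member. Consumes the current RNG stream.
#'
#' @param prev Integer vector: previous occasion's community per node.
#' @param switch_prob Per-node switch probability.
#' @param cohesive_fraction Probability that an event is a subgroup move.
#' @return Integer vector: next occasion's community per node.
#' @export
evolve_partition <- function(prev, switch_prob, cohesive_fraction) {
  ids <- sort(unique(prev))
  if (length(ids) < 2) return(prev)  # nowhere to switch to
  nxt <- prev
  flagged <- which(stats::runif(length(prev)) < switch_prob)
  for (c_id in ids) {
    f <- intersect(flagged, which(prev == c_id))
    last_target <- NULL
    while (length(f) > 0) {
      cohesive <- stats::runif(1) < cohesive_fraction
      if (cohesive && length(f) >= 2) {
        size <- if (length(f) == 2) 2 else resample(2:length(f))
        grp <- resample(f, size)
        target <- resample(setdiff(ids, c_id))
        last_target <- target
      } else if (cohesive) {
        # single flagged straggler on a cohesive event: keep the move
        # mutual by reusing the previous subgroup's destination, or by
        # recruiting an unflagged same-community partner
        grp <- f
        if (!is.null(last_target)) {
          target <- last_target
        } else {
          partner <- setdiff(which(prev == c_id), f)
          target <- resample(setdiff(ids, c_id))
          if (length(partner)) grp <- c(grp, resample(partner))
        }
      } else {
        grp <- resample(f)
        target <- resample(setdiff(ids, c_id))
      }
      nxt[grp] <- target
      f <- setdiff(f, grp)
    }
  }
  nxt
}

#' Build a connectivity layer from a planted partition
#'
#' `weight(i, j) = max(0, mu_block + Normal(0, noise_sd))` with `mu_block`
#' equal to `mu_within` for same-community pairs and `mu_between`
#' otherwise; symmetric, zero diagonal. Negative noise excursions are
#' clipped at zero, matching the positive-network assumption of the
#' analysis. Consumes the current RNG stream.
#'
#' @param partition Integer vector of community labels per node.
#' @param mu_within,mu_between Mean edge weights (`mu_within > mu_between`).
#' @param noise_sd Gaussian noise SD.
#' @param node_labels Optional node labels.
#' @return A [connectivity_layer()].
#' @export
layer_from_partition <- function(partition, mu_within, mu_between,
                                 noise_sd = 0, node_labels = NULL) {
  if (mu_within <= mu_between) stop("need mu_within > mu_between")
  n <- length(partition)
  mu <- matrix(mu_between, n, n)
  same <- outer(partition, partition, "==")
  mu[same] <- mu_within
  ut <- upper.tri(mu)
  w <- matrix(0, n, n)
  noise <- if (noise_sd > 0) stats::rnorm(sum(ut), 0, noise_sd) else 0
  w[ut] <- pmax(0, mu[ut] + noise)
  w <- w + t(w)
  connectivity_layer(w, node_labels)
}

#' Simulate ROI time series with a planted block-correlation structure
#'
#' Latent-factor model: each node's signal mixes a global factor, its
#' community's factor and idiosyncratic noise so that expected Pearson
#' correlations are `tanh(mu_within)` within communities and
#' `tanh(mu_between)` between them — the time-series entry point of the
#' pipeline (correlation, Fisher z, positivize) then recovers weights near
#' `mu_within` / `mu_between`. Consumes the current RNG stream.
#'
#' @param partition Integer vector of community labels per node.
#' @param n_timepoints Number of time points (rows).
#' @inheritParams layer_from_partition
#' @return T x N numeric matrix with node labels as column names.
#' @export
simulate_timeseries <- function(partition, n_timepoints = 200,
                                mu_within = 0.5, mu_between = 0.1,
                                node_labels = NULL) {
  if (mu_within <= mu_between) stop("need mu_within > mu_between")
  n <- length(partition)
  rho_b <- tanh(mu_between)
  rho_w <- tanh(mu_within)
  g <- stats::rnorm(n_timepoints)
  ids <- sort(unique(partition))
  fac <- matrix(stats::rnorm(n_timepoints * length(ids)), n_timepoints)
  x <- sqrt(rho_b) * g %o% rep(1, n) +
    sqrt(rho_w - rho_b) * fac[, match(partition, ids)] +
    sqrt(1 - rho_w) * matrix(stats::rnorm(n_timepoints * n), n_timepoints)
  colnames(x) <- node_labels %||% sprintf("ROI_%03d", seq_len(n))
  x
}

#' Generate a synthetic longitudinal cohort
#'
#' Per subject: the baseline partition is the planted 7-network structure;
#' each later occasion evolves from the previous one by
#' [evolve_partition()] with a subject-specific switch probability
#' `clip(base_switch_prob + age_effect * (age_s - mean age), 0, 1)`; each
#' occasion's connectivity layer is drawn by [layer_from_partition()].
#' Cognitive scores follow
#' `intercept + slope_s * t + retest_bump * 1[t > 0] + Normal(0, 1)` with
#' `slope_s = cognitive_slope_mean + slope_age_effect * (age_s - mean) +
#' Normal(0, slope_sd)`, independently for the processing-speed and memory
#' domains. Ground-truth partitions are retained for every subject so the
#' generator and the metrics module can serve as mutual oracles.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort`: `networks` (list of
#'   `multilayer_network`), `truth` (list of N x L ground-truth partition
#'   matrices), `covariates` (data frame subject, age, gender, education,
#'   fd), `cognition` (long data frame subject, occasion, time, speed_T,
#'   memory_T), `network_labels`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  N <- config$n_nodes
  L <- config$n_layers
  node_labels <- sprintf("ROI_%03d", seq_len(N))
  network_labels <- rep(names(config$network_sizes), config$network_sizes)
  names(network_labels) <- node_labels
  planted <- rep(seq_along(config$network_sizes), config$network_sizes)

  seeds <- derive_seeds(config$seed, n + 1L)
  set.seed(seeds[n + 1L])
  ages <- sample_ages(n, seed = seeds[n + 1L])
  set.seed(seeds[n + 1L] + 1L)
  gender <- stats::rbinom(n, 1, 0.47)
  education <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  fd <- pmax(0.05, stats::rnorm(n, 0.2, 0.05))
  switch_prob <- pmin(pmax(
    config$base_switch_prob + config$age_effect * (ages - mean(ages)), 0), 1)

  subjects <- sprintf("sub-%03d", seq_len(n))
  networks <- vector("list", n)
  truth <- vector("list", n)
  cog_rows <- vector("list", n)

  for (s in seq_len(n)) {
    set.seed(seeds[s])
    part <- matrix(0L, N, L, dimnames = list(node_labels, NULL))
    part[, 1] <- planted
    for (l in seq_len(L - 1)) {
      part[, l + 1] <- evolve_partition(part[, l], switch_prob[s],
                                        config$cohesive_fraction)
    }
    layers <- lapply(seq_len(L), function(l) {
      layer_from_partition(part[, l], config$mu_within, config$mu_between,
                           config$noise_sd, node_labels)
    })
    networks[[s]] <- assemble_multilayer(layers, network_labels)
    truth[[s]] <- part

    tvec <- config$occasion_times
    sc <- vapply(c("speed", "memory"), function(dom) {
      slope <- config$cognitive_slope_mean +
        config$slope_age_effect * (ages[s] - mean(ages)) +
        stats::rnorm(1, 0, config$slope_sd)
      config$cognitive_intercept + slope * tvec +
        config$retest_bump * as.numeric(tvec > 0) +
        stats::rnorm(length(tvec))
    }, numeric(L))
    cog_rows[[s]] <- data.frame(subject = subjects[s],
                                occasion = seq_len(L) - 1L,
                                time = tvec,
                                speed_T = sc[, "speed"],
                                memory_T = sc[, "memory"],
                                stringsAsFactors = FALSE)
  }

  structure(
    list(networks = stats::setNames(networks, subjects),
         truth = stats::setNames(truth, subjects),
         covariates = data.frame(subject = subjects, age = ages,
                                 gender = gender, education = education,
                                 fd = fd, switch_prob = switch_prob,
                                 stringsAsFactors = FALSE),
         cognition = do.call(rbind, cog_rows),
         network_labels = network_labels,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes, %d layers (seed %d)\n",
              x$config$n_subjects, x$config$n_nodes, x$config$n_layers,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' Emits per-subject per-occasion matrix files, the node-to-network map,
#' the covariate/cognition table, and a `truth/` directory of ground-truth
#' partitions — the same delimited-text formats the real pipeline consumes.
#' Output is byte-deterministic given the cohort object.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$networks)) {
    net <- cohort$networks[[s]]
    for (l in seq_len(net$n_layers)) {
      write_matrix(round(net$layers[[l]], 8),
                   file.path(dir, sprintf("%s_occ%d.csv", s, l - 1)))
    }
    utils::write.table(cohort$truth[[s]],
                       file.path(dir, "truth", paste0(s, "_partition.csv")),
                       sep = ",", quote = FALSE, col.names = NA)
  }
  utils::write.table(
    data.frame(node_label = names(cohort$network_labels),
               network_name = unname(cohort$network_labels)),
    file.path(dir, "network_map.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  cov <- merge(cohort$cognition, cohort$covariates, by = "subject")
  cov <- cov[order(cov$subject, cov$occasion), ]
  utils::write.table(format(cov, digits = 10, trim = TRUE),
                     file.path(dir, "covariates.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
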