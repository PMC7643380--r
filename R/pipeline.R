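#' Optimize and summarize a whole cohort
#'
#' Runs [repeated_optimization()] and [summarize_metrics()] for every
#' subject in a cohort and gathers the global metrics (plus per-network
#' flexibility) into one subject-level table joined to the covariates.
#' Per-subject seeds fan out deterministically from `base_seed`. With
#' `use_truth = TRUE` the optimizer is bypassed and metrics are computed on
#' the generator's ground-truth partitions (Q is still evaluated on the
#' networks), which is how the generator and the metrics module audit each
#' other.
#'
#' @param cohort A `synthetic_cohort` (or a list with elements `networks`,
#'   `covariates`, `network_labels`).
#' @inheritParams repeated_optimization
#' @param use_truth Logical; score ground-truth partitions instead of
#'   optimizer output.
#' @return List with `metric_sets` (per subject) and `summary` (data
#'   frame: covariates plus global metrics, Q, module_count, and
#'   `flex_<NETWORK>` columns).
#' @export
compute_cohort_metrics <- function(cohort, gamma = 1, omega = 1,
                                   n_reps = 100, base_seed = 1,
                                   move_rule = c("moverandw", "move"),
                                   use_truth = FALSE) {
  move_rule <- match.arg(move_rule)
  subjects <- names(cohort$networks)
  seeds <- derive_seeds(base_seed, length(subjects))
  labels <- cohort$network_labels
  msets <- vector("list", length(subjects))
  names(msets) <- subjects
  for (i in seq_along(subjects)) {
    net <- cohort$networks[[i]]
    if (use_truth) {
      part <- cohort$truth[[i]]
      res <- structure(
        list(partition = canonicalize_partition(part),
             Q = evaluate_Q(net, part, gamma, omega),
             gamma = gamma, omega = omega, seed = NA_integer_,
             move_rule = "truth", n_sweeps = 0L),
        class = "modularity_result")
      msets[[i]] <- summarize_metrics(res, labels)
    } else {
      ens <- repeated_optimization(net, gamma = gamma, omega = omega,
                                   n_reps = n_reps, base_seed = seeds[i],
                                   move_rule = move_rule)
      msets[[i]] <- summarize_metrics(ens, labels)
    }
  }
  gl <- t(vapply(msets, function(m) c(m$global, Q = m$Q_mean,
                                      module_count = m$module_count_mean),
                 numeric(7)))
  nets <- sort(unique(as.character(labels)))
  fx <- t(vapply(msets, function(m) {
    v <- m$per_network$flexibility[match(nets, m$per_network$network)]
    stats::setNames(v, paste0("flex_", nets))
  }, numeric(length(nets))))
  summary <- data.frame(subject = subjects, gl, fx, stringsAsFactors = FALSE,
                        row.names = NULL)
  if (!is.null(cohort$covariates)) {
    summary <- merge(cohort$covariates, summary, by = "subject")
  }
  list(metric_sets = msets, summary = summary)
}

#' Null-model metric table for a whole cohort
#'
#' For each subject, draws `n_null` null networks of the requested kind,
#' optimizes each `n_reps` times, and averages the global metrics across
#' the nulls — yielding one null value per subject per metric, the same
#' shape as the real table, ready for [compare_to_null()].
#'
#' @inheritParams compute_cohort_metrics
#' @inheritParams null_ensemble
#' @return Data frame: subject plus the five global metrics, Q and
#'   module_count (null averages).
#' @export
cohort_null_metrics <- function(cohort, kind = c("temporal", "nodal"),
                                n_null = 50, n_reps = 100, base_seed = 1,
                                gamma = 1, omega = 1,
                                move_rule = c("moverandw", "move")) {
  kind <- match.arg(kind)
  move_rule <- match.arg(move_rule)
  subjects <- names(cohort$networks)
  seeds <- derive_seeds(base_seed + 1L, length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    ns <- null_ensemble(cohort$networks[[i]], kind = kind, n_null = n_null,
                        n_reps = n_reps, base_seed = seeds[i],
                        gamma = gamma, omega = omega, move_rule = move_rule)
    rows[[i]] <- as.data.frame(t(average_global_metrics(ns)))
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(subject = subjects, stringsAsFactors = FALSE), out)
}

#' Compare a cohort's real metrics against a null table
#'
#' Runs [compare_to_null()] for each of the five global multilayer metrics,
#' Bonferroni-adjusting the significance level for the family.
#'
#' @param real_summary,null_summary Subject-level tables from
#'   [compute_cohort_metrics()]`$summary` and [cohort_null_metrics()].
#' @param metrics Metric columns to compare.
#' @param alpha Family-wise alpha.
#' @return Data frame, one row per metric.
#' @export
compare_cohort_to_null <- function(real_summary, null_summary,
                                   metrics = GLOBAL_METRICS,
                                   alpha = 0.05) {
  stopifnot(all(metrics %in% names(real_summary)),
            all(metrics %in% names(null_summary)))
  out <- lapply(metrics, function(m) {
    compare_to_null(real_summary[[m]], null_summary[[m]], metric = m,
                    alpha = alpha, n_comparisons = length(metrics))
  })
  do.call(rbind, out)
}
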