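# Longitudinal cognition: per-subject change slopes (retest bump partialled
# out at cohort level) and change-change correlations between cognitive
# decline and flexibility (global + networks), raw and age-partialled.
source(file.path("analysis", "00_config.R"))

cohort <- generate_cohort(cohort_config())
metrics <- read.csv(file.path(RESULTS, "subject_metrics.csv"))

slopes <- data.frame(
  subject = names(change_slopes(cohort$cognition, "speed_T")),
  speed = unname(change_slopes(cohort$cognition, "speed_T")),
  memory = unname(change_slopes(cohort$cognition, "memory_T")))
write.csv(slopes, file.path(RESULTS, "cognitive_slopes.csv"), row.names = FALSE)
cat(sprintf("Change slopes (T-score/yr): speed %.2f +- %.2f, memory %.2f +- %.2f\n",
            mean(slopes$speed), sd(slopes$speed),
            mean(slopes$memory), sd(slopes$memory)))

ages <- stats::setNames(metrics$age, metrics$subject)
flex_cols <- c("flexibility", grep("^flex_", names(metrics), value = TRUE))
measures <- metrics[, c("subject", flex_cols)]
out <- lapply(c("speed", "memory"), function(dom) {
  sl <- stats::setNames(slopes[[dom]], slopes$subject)
  bc <- brain_cognition_correlation(measures, sl, age = ages,
                                    n_comparisons = length(flex_cols))
  bc$domain <- dom
  bc
})
bc <- do.call(rbind, out)
write.csv(bc, file.path(RESULTS, "brain_cognition_correlations.csv"),
          row.names = FALSE)
cat("\nChange-change correlations with flexibility:\n")
print(bc[bc$measure == "flexibility",
         c("domain", "r", "ci_lo", "ci_hi", "p", "partial_r", "significant")],
      digits = 2, row.names = FALSE)
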