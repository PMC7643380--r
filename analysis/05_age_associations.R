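# Group-level associations: each global metric (and network-specific
# flexibility) regressed on centered age with gender, education and head
# motion as nuisance covariates; metric intercorrelations with and without
# age partialled out.
source(file.path("analysis", "00_config.R"))

metrics <- read.csv(file.path(RESULTS, "subject_metrics.csv"))

global_metrics <- c("flexibility", "promiscuity", "cohesion_strength",
                    "disjointedness", "recruitment")
age_models <- do.call(rbind, lapply(global_metrics, function(m) {
  fit <- metric_age_regression(metrics, m, n_models = length(global_metrics))
  fit$outcome <- m
  fit
}))
write.csv(age_models, file.path(RESULTS, "age_models_global.csv"),
          row.names = FALSE)

net_cols <- grep("^flex_", names(metrics), value = TRUE)
net_models <- do.call(rbind, lapply(net_cols, function(m) {
  fit <- metric_age_regression(metrics, m, n_models = length(net_cols))
  fit$outcome <- m
  fit
}))
write.csv(net_models, file.path(RESULTS, "age_models_network_flexibility.csv"),
          row.names = FALSE)

age_rows <- age_models[age_models$term == "age", ]
cat("Age effects on the global metrics (alpha = .05/5):\n")
print(age_rows[, c("outcome", "estimate", "se", "p", "partial_eta_sq",
                   "significant")], digits = 3, row.names = FALSE)

cors <- metric_correlations(data.frame(Q = metrics$Q,
                                       recruitment = metrics$recruitment,
                                       flexibility = metrics$flexibility,
                                       age = metrics$age))
write.csv(cors, file.path(RESULTS, "metric_correlations.csv"),
          row.names = FALSE)
cat("\nIntercorrelations (raw and age-partialled):\n")
print(cors, digits = 2, row.names = FALSE)
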