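# Shared settings for the analysis drivers. The cohort is synthetic (the
# package's generator) at a desk-friendly scale; every step is seeded so
# the whole workflow is reproducible end to end.
library(longnet)

COHORT_SEED <- 11
N_SUBJECTS <- 40
N_NODES <- 56
N_REPS <- 10     # modularity optimizations per (subject | null) network
N_NULL <- 10     # null networks per subject and kind
RESULTS <- file.path("results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

cohort_config <- function() {
  sim_config(n_subjects = N_SUBJECTS, n_nodes = N_NODES, seed = COHORT_SEED)
}
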