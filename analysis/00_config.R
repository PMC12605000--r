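# Shared configuration for the analysis scripts. Every script sources this
# file, so the whole workflow is driven by one seed and one run directory;
# stages are cached under results/run/cache and recomputed only when their
# cache is deleted.

library(habitrad)

RESULTS <- file.path("results")                 # small text tables + figures
SCRATCH <- file.path("scratch")                 # bulky regenerable artifacts
RUN_DIR <- file.path(SCRATCH, "run")            # stage caches live here
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH, showWarnings = FALSE, recursive = TRUE)

# Cohort shaped like the study population: 110 patients, ~45% label
# prevalence, 80 on the first scanner (split 2:1 train:internal) and 30 on
# a second scanner serving as the external validation set.
analysis_config <- function(seed = 20260924) {
  pipeline_config(
    cohort = cohort_spec(n_patients = 110, prevalence = 50 / 110,
                         external_fraction = 30 / 110, seed = seed),
    preprocess = preprocess_spec(
      filters = c("original", "log-sigma-5-0-mm-3D", "wavelet-HHH",
                  "exponential", "lbp"),
      lbp_name = "lbp-2D"),
    harmonize = "none",      # ComBat path exists; see 04_fit_models.R
    icc = TRUE, icc_patients = 30L,
    boot = 500L,
    seed = seed)
}
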