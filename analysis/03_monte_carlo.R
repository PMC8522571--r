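#!/usr/bin/env Rscript
# The main Monte Carlo comparison: nine scenarios x six estimators,
# 400 replicate panels each (n = 800, T = 10, treatment from t = 6).
# Writes the per-estimator summary to results/study_summary.csv and a
# reproduction manifest per scenario to results/study_<id>.json.
# Runtime is roughly five minutes on one core; set REPS to thin it.

library(didconfound)
dir.create("results", showWarnings = FALSE)

REPS <- as.integer(Sys.getenv("REPS", "400"))
SEED <- 42

summaries <- lapply(scenario_ids(), function(id) {
  study <- run_study(id, n_reps = REPS, seed = SEED)
  study_write(study, json_path = sprintf("results/study_%s.json", id))
  cat(sprintf("scenario %-2s  true ATT %.2f  done (%d reps)\n",
              id, study$true_att, REPS))
  study$summary
})
res <- do.call(rbind, summaries)
write.csv(res, "results/study_summary.csv", row.names = FALSE)

cat("\nmean absolute percent bias by scenario and estimator:\n")
print(xtabs(mean_abs_pct_bias ~ scenario + estimator, res), digits = 3)
cat("\nKey patterns: misspecified adjustment (simple/CA under a time-varying",
    "\ncovariate effect) is badly biased; covariate-by-time adjustment (TVA)",
    "\nrecovers the effect everywhere except scenario 6, where the covariate",
    "\nis itself moved by treatment and adjusting for it removes the mediated",
    "\npart of the ATT. Matching regresses to the mean wherever the groups",
    "\ndiffer in the matching variable.\n")
cat("\nwrote results/study_summary.csv and per-scenario manifests\n")
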