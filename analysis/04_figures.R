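#!/usr/bin/env Rscript
# Dot charts of mean absolute percent bias and mean cluster-robust SE per
# estimator, faceted by scenario (run analysis/03_monte_carlo.R first).

library(didconfound)
suppressPackageStartupMessages(library(ggplot2))

res <- read.csv("results/study_summary.csv", colClasses = c(scenario = "character"))
res$estimator <- factor(res$estimator, levels = rev(did_estimators()))
dir.create("results", showWarnings = FALSE)

p_bias <- ggplot(res, aes(mean_abs_pct_bias, estimator)) +
  geom_point() +
  facet_wrap(~scenario, scales = "free_x") +
  labs(x = "mean absolute percent bias (%)", y = NULL) +
  theme_minimal()
ggsave("results/bias_by_scenario.png", p_bias, width = 9, height = 6, dpi = 150)

p_se <- ggplot(res, aes(mean_se, estimator)) +
  geom_point() +
  facet_wrap(~scenario, scales = "free_x") +
  labs(x = "mean cluster-robust SE", y = NULL) +
  theme_minimal()
ggsave("results/se_by_scenario.png", p_se, width = 9, height = 6, dpi = 150)

cat("wrote results/bias_by_scenario.png and results/se_by_scenario.png\n")
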