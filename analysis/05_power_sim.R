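#!/usr/bin/env Rscript
# Simulation-based design check: accuracy and credible-set coverage of the
# latent-class fit on data generated from known scenarios.
#  (a) a single-class scenario calibrated to the national fit scale;
#  (b) a two-class heterogeneous scenario, which exposes the weak
#      identifiability of N at three capture occasions.

suppressPackageStartupMessages(library(crc3s))
dir.create("results", showWarnings = FALSE)

cfg <- lcmcr_config(n_samples = 1000, burn_in = 20000, thinning = 50,
                    seed = 7)

cat("(a) single-class scenario, N = 18,000, lambda = (0.137, 0.073, 0.123):\n")
single <- crc_power_sim(18000, c(0.137, 0.073, 0.123), reps = 40,
                        config = cfg)
print(single)

cat("\n(b) two-class scenario, N = 10,000, 70% low-capture / 30% engaged:\n")
lam <- matrix(c(0.10, 0.08, 0.12, 0.35, 0.30, 0.40), 3, 2)
two <- crc_power_sim(10000, lam, reps = 40, weights = c(0.7, 0.3),
                     config = lcmcr_config(n_samples = 1000,
                                           burn_in = 20000, thinning = 50,
                                           seed = 42))
print(two)
cat("\nThe two-class scenario shows the systematic downward shrinkage and\n")
cat("under-coverage of N at k = 3 occasions discussed in the vignette.\n")

utils::write.csv(
  data.frame(scenario = c("single_class", "two_class"),
             true_N = c(18000, 10000),
             bias = c(single$bias, two$bias),
             rmse = c(single$rmse, two$rmse),
             mean_cs_width = c(single$mean_cs_width, two$mean_cs_width),
             coverage = c(single$coverage, two$coverage)),
  "results/power_simulation.csv", row.names = FALSE)
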