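#!/usr/bin/env Rscript

# Step 1: build the four registry-like scenarios and write a small
# simulated replicate set for each under results/scenarios/.
#
# Each scenario emulates the observed-count summary of one template
# entity (two large-count cancers, two near-zero-count cancers): 27
# areas, expected counts log-spaced inside the published count envelope
# and rescaled to its median, counts drawn from the Poisson log-normal
# random-effects model with the scenario's heterogeneity.

library(rarerates)

seed <- 20260920L
n_reps <- 25L
out_dir <- "results/scenarios"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (preset in c("cns", "ovary", "middle_ear", "trachea")) {
  p <- scenario_preset(preset)
  reps <- simulate_preset(preset, n_reps, seed = seed)
  e <- attr(reps, "expected")
  counts <- unlist(lapply(reps, function(r) r$table$observed))
  cat(sprintf(
    "%-11s E: median %8.1f range [%8.1f, %8.1f] | counts: median %6.1f max %6d zeros %4.1f%%\n",
    preset, median(e), min(e), max(e), median(counts), max(counts),
    100 * mean(counts == 0)))

  pdir <- file.path(out_dir, preset)
  dir.create(pdir, showWarnings = FALSE)
  for (r in reps[seq_len(min(5L, n_reps))])
    write_count_table(r$table,
                      file.path(pdir, sprintf("replicate%02d.csv",
                                              r$replicate)))
  write_report(list(preset = preset, mu0 = p$mu0, sigma0 = p$sigma0,
                    expected = e, seed = seed, n_reps = n_reps),
               file.path(pdir, "truth.json"), format = "json")
}

cat("\nScenario files under ", out_dir, "\n", sep = "")
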