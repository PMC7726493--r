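#!/usr/bin/env Rscript
# Generate the synthetic study: a 20,000-probe expression matrix for three
# compounds (BPA, BPF, BPS) plus control at four replicates each, with a
# 100-probe shared deregulated core and 50 private probes per compound, and
# concentration-response curves emulating ATP-depletion behaviour (two
# compounds with a half-maximal concentration in range, one never reaching
# 50% of control). Outputs go to results/data/.

library(txconcord)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_expression(sim_config(
  n_probes = 20000L, n_replicates = 4L,
  shared_de_count = 100L, private_de_count = 50L,
  effect_mean = 1.5, effect_sd = 0.25, effect_correlation = 0.5,
  noise_sd = 0.15, seed = 1L))

write_expression_matrix(sim$matrix,
                        file.path(out, "expression_matrix.tsv"),
                        file.path(out, "sample_sheet.csv"))
write_truth(sim$truth, file.path(out, "truth.json"))
print(sim$matrix)
cat(sprintf("truth: %d shared, %d private, %d null probes\n",
            sum(sim$truth$membership == "shared"),
            sum(grepl("^private_", sim$truth$membership)),
            sum(sim$truth$membership == "null")))

ic50s <- c(BPA = 130, BPF = 265, BPS = NA)   # uM; BPS stays above 50%
for (cmp in names(ic50s)) {
  cur <- generate_dose_response(dose_config(
    concentrations = c(0, 10, 50, 100, 250, 500),
    true_ic50 = ic50s[[cmp]], noise_sd = 5, n_replicates = 5L,
    seed = 10L + match(cmp, names(ic50s))))
  write_dose_curve(cur, file.path(out, sprintf("dose_%s.csv", cmp)))
  cat(sprintf("%s dose-response: responses %s%% of control\n", cmp,
              paste(round(cur$response), collapse = ", ")))
}
cat("wrote synthetic study to", out, "\n")
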