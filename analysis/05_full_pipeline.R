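#!/usr/bin/env Rscript
# Run the orchestrated end-to-end pipeline (DE -> Venn/overlap -> concordance
# -> PCA -> IC50 -> manifest) over the files written by 01_simulate.R, into
# results/pipeline/, and summarize the bundle.

library(txconcord)

cfg <- pipeline_config(
  matrix_path = "results/data/expression_matrix.tsv",
  samples_path = "results/data/sample_sheet.csv",
  dose_paths = c(BPA = "results/data/dose_BPA.csv",
                 BPF = "results/data/dose_BPF.csv",
                 BPS = "results/data/dose_BPS.csv"),
  control = "control", fc_threshold = 1.5, alpha = 0.05,
  pca_top_k = 1000L, seed = 1L, mc_reps = 2000L,
  out_dir = file.path("results", "pipeline"))

res <- run_pipeline(cfg)

cat("pipeline bundle:", paste(sort(list.files(cfg$out_dir)), collapse = ", "),
    "\n\n")
cat("DE calls per contrast:\n")
for (cmp in names(res$de))
  cat(sprintf("  %s: %d up, %d down\n", cmp,
              sum(res$de[[cmp]]$call == "up"),
              sum(res$de[[cmp]]$call == "down")))
cat(sprintf("\nPC1 explains %.1f%% of variance (top %d probes)\n",
            res$pca$percent_var[1], length(res$pca$probes)))
three <- res$overlap[res$overlap$k == 3 & res$overlap$defined, ]
if (nrow(three)) {
  cat("\nthree-way overlap ratios:\n")
  print(three[, c("direction", "n_sets", "observed", "expected", "ratio",
                  "p_exceed_mc")], row.names = FALSE)
}
cat("\nconcordance (Spearman R):\n")
print(round(res$concordance$R, 3))
cat("\nIC50 estimates:\n")
for (cmp in names(res$ic50)) {
  r <- res$ic50[[cmp]]
  cat(sprintf("  %s: %s\n", cmp,
              if (r$status == "estimated") sprintf("%.1f uM", r$ic50)
              else "not reached"))
}
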