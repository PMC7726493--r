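#!/usr/bin/env Rscript
# Call differential expression for each compound against the control group
# under the 1.5-fold / 5% FDR rule, and check recovery against the generator
# truth. Reads results/data/, writes per-compound DE tables and gene lists
# to results/de/.

library(txconcord)

em <- read_expression_matrix("results/data/expression_matrix.tsv",
                             "results/data/sample_sheet.csv")
truth <- read_truth("results/data/truth.json")
out <- file.path("results", "de")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

compounds <- setdiff(unique(em$samples$treatment), "control")
for (cmp in compounds) {
  de <- de_table(em, cmp, "control")
  write_de_table(de, file.path(out, sprintf("de_%s.tsv", cmp)))
  write_gene_list(de_probes(de, "up"), file.path(out, sprintf("up_%s.txt", cmp)))
  write_gene_list(de_probes(de, "down"),
                  file.path(out, sprintf("down_%s.txt", cmp)))
  true_de <- truth[[paste0("effect_", cmp)]] != 0
  called <- de$call != "ns"
  cat(sprintf(
    "%s vs control: %d up, %d down | sensitivity %.3f, empirical FDR %.3f\n",
    cmp, sum(de$call == "up"), sum(de$call == "down"),
    sum(called & true_de) / sum(true_de),
    if (sum(called)) sum(called & !true_de) / sum(called) else 0))
}
cat("wrote DE tables to", out, "\n")
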