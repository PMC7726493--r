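#!/usr/bin/env Rscript
# Quantify how concordantly the three compounds deregulate the transcriptome:
# Venn partition of up-/down-sets, pairwise and three-way overlap ratios
# (with a Monte-Carlo exceedance probability for the three-way overlaps), and
# the genome-wide Spearman concordance of log2 fold-change profiles.
# Reads results/de/, writes results/overlap/.

library(txconcord)

em <- read_expression_matrix("results/data/expression_matrix.tsv",
                             "results/data/sample_sheet.csv")
compounds <- setdiff(unique(em$samples$treatment), "control")
de <- lapply(compounds, function(cmp)
  read_de_table(file.path("results/de", sprintf("de_%s.tsv", cmp))))
names(de) <- compounds
N <- nrow(em$values)
out <- file.path("results", "overlap")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

up_sets <- lapply(de, de_probes, direction = "up")
down_sets <- lapply(de, de_probes, direction = "down")

for (dir_label in c("up", "down")) {
  sets <- if (dir_label == "up") up_sets else down_sets
  v <- venn_partition(sets, rownames(em$values))
  cat(sprintf("%s-set Venn regions (N = %d):\n", dir_label, N))
  print(v)
  tab <- overlap_table(sets, N)
  three <- tab[tab$k == 3 & tab$defined, ]
  if (nrow(three)) {
    sizes <- as.integer(strsplit(three$n_sets, ",")[[1]])
    mc <- monte_carlo_null(sizes[1], sizes[2], sizes[3], N = N,
                           reps = 10000L, seed = 42L,
                           observed = three$observed)
    cat(sprintf(
      "three-way %s overlap: observed %d, expected %.4f, ratio %.1f, MC p %s\n",
      dir_label, three$observed, three$expected, three$ratio,
      format_pval_floor(mc$p_exceed)))
  }
  utils::write.table(tab, file.path(out, sprintf("overlap_%s.tsv", dir_label)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cm <- pairwise_concordance(lapply(de, function(d) d$log2fc))
cat("genome-wide Spearman concordance of fold-change profiles:\n")
print(round(cm$R, 3))
cat("pairwise p-values:",
    paste(format_pval_floor(cm$p[upper.tri(cm$p)]), collapse = ", "), "\n")
utils::write.table(data.frame(condition = rownames(cm$R), round(cm$R, 4)),
                   file.path(out, "concordance_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote overlap and concordance tables to", out, "\n")
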