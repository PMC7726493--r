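#!/usr/bin/env Rscript
# Estimate IC50s from the percent-of-control concentration-response curves by
# the bracketing-segment line f(x) = a*x + b, reporting "not reached" when a
# compound never depletes the response below 50%. Reads results/data/, writes
# results/ic50.tsv.

library(txconcord)

files <- list.files("results/data", pattern = "^dose_.*\\.csv$",
                    full.names = TRUE)
rows <- lapply(files, function(f) {
  cmp <- sub("^dose_(.*)\\.csv$", "\\1", basename(f))
  r <- estimate_ic50(read_dose_curve(f))
  cat(sprintf("%s: %s\n", cmp,
              if (r$status == "estimated")
                sprintf("IC50 = %.1f uM (f(x) = %.3f x + %.1f)", r$ic50, r$a, r$b)
              else "IC50 not reached (response stays above 50% of control)"))
  data.frame(compound = cmp, status = r$status, ic50_uM = r$ic50,
             a = r$a, b = r$b)
})
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/ic50.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("wrote results/ic50.tsv\n")
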