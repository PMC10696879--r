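#!/usr/bin/env Rscript
# Dose-response analysis: per-peak logistic differential accessibility with
# pooled BH correction, gene-level quasipoisson dose models for ATAC gene
# scores and RNA, their coefficient comparison, and the 4PL viability fit.

suppressMessages(library(atacscreen))
dir.create("results", showWarnings = FALSE)

dr <- simulate_dose_response_dataset(sim_config(seed = 1))

da <- run_peak_da(dr$matrix, dr$design, min_frac = 0.01, alpha = 0.05)
write.table(da, "results/peak_da.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
planted <- names(dr$truth$betad)[dr$truth$betad != 0]
cat(sprintf("%d/%d peaks significant (padj < 0.05); power on planted: %.2f\n",
            sum(da$significant), nrow(da),
            mean(da$significant[da$peak %in% planted])))
cat(sprintf("opening: %d, closing: %d\n",
            sum(da$significant & da$direction == "opening"),
            sum(da$significant & da$direction == "closing")))

atac_fit <- fit_gene_dose_model(dr$atac_gene_scores, dr$design, "drugA",
                                dr$size_factors)
rna_fit <- fit_gene_dose_model(dr$rna, dr$design, "drugA", dr$size_factors)
write.table(rna_fit, "results/gene_dose_rna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(atac_fit, "results/gene_dose_atac.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cmp <- compare_atac_rna_coeffs(atac_fit, rna_fit)
cat(sprintf("ATAC vs RNA dose coefficients: r = %.3f, sign concordance %.2f (%d genes)\n",
            cmp$correlation, cmp$sign_concordance, cmp$n))

# viability: cells recovered per dose, thinned with dose per a 4PL curve
set.seed(1)
doses <- c(0.1, 1, 10, 100)
expected <- 20 + (400 - 20) / (1 + exp(1.2 * (log(doses) - log(5))))
counts <- rpois(length(doses), expected)
v <- tryCatch(fit_viability_4pl(counts, doses), error = function(e) NULL)
if (!is.null(v)) {
  cat(sprintf("4PL viability fit: ED50 = %.2f uM (b=%.2f, c=%.1f, d=%.1f)\n",
              v$e, v$b, v$c, v$d))
  write.table(data.frame(b = v$b, c = v$c, d = v$d, ed50 = v$e, sse = v$sse),
              "results/viability_4pl.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
} else cat("4PL viability fit did not converge on this draw\n")
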