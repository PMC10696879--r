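#!/usr/bin/env Rscript
# Motif-level analyses: per-motif logistic enrichment within trend classes,
# and elastic-net prediction of RNA dose coefficients from promoter motifs
# alone versus promoter plus distal co-accessible motifs.

suppressMessages(library(atacscreen))
dir.create("results", showWarnings = FALSE)

dr <- simulate_dose_response_dataset(sim_config(seed = 1))
da <- run_peak_da(dr$matrix, dr$design)

# motif enrichment within opening and closing DA classes
for (cl in c("opening", "closing")) {
  in_class <- rownames(dr$motifs) %in%
    da$peak[da$significant & da$direction == cl]
  if (!any(in_class) || all(in_class)) next
  mt <- motif_trend_regression(in_class, dr$motifs)
  write.table(mt, sprintf("results/motif_enrichment_%s.tsv", cl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s class: %d/%d motifs enriched (padj < 0.05)\n",
              cl, sum(mt$enriched), nrow(mt)))
}

# expression models: promoter-only vs promoter + distal features
rna_fit <- fit_gene_dose_model(dr$rna, dr$design, "drugA", dr$size_factors)
ft <- build_gene_features(dr$genes, dr$features, dr$motifs, dr$links,
                          threshold = 0.1, window = 500)
target <- setNames(rna_fit$beta_d, rna_fit$gene)
sig <- rna_fit$gene[!rna_fit$skipped & !is.na(rna_fit$padj) &
                      rna_fit$padj < 0.05]
em <- fit_expression_models(ft, target[sig], seed = 1)
cat(sprintf("variance explained: promoter %.3f, promoter+distal %.3f\n",
            em$r2_promoter, em$r2_full))
cat(sprintf("fold increase with distal features: %.2f (%d genes)\n",
            em$fold_increase, em$n_genes))
cf <- em$coef_full[grep("^dist_", rownames(em$coef_full)), , drop = FALSE]
top <- rownames(cf)[order(-abs(cf[, 1]))][1:3]
cat("top distal motifs by |coefficient|:", paste(top, collapse = ", "), "\n")
cat("planted distal motif:",
    names(which(dr$truth$motif_distal_effect != 0)), "\n")
write.table(data.frame(term = rownames(em$coef_full),
                       coef = em$coef_full[, 1]),
            "results/expression_model_coefficients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
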