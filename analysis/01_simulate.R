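#!/usr/bin/env Rscript
# Generate the synthetic study datasets (hashed nuclei, species mix,
# dose-response screen, trajectory) under the default study conditions and
# write them in the pipeline's exchange formats.

suppressMessages(library(atacscreen))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
cat("study conditions:", cfg$n_cells, "cells,", cfg$n_samples, "samples,",
    cfg$n_hashes, "hashes,", 100 * cfg$doublet_rate, "% doublets,",
    cfg$n_features, "features\n")

hx <- simulate_hash_experiment(cfg)
write_matrix_mtx(hx$hash_counts, "results/sim/hash_counts.mtx")
write.table(hx$truth, "results/sim/hash_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hx$qc, "results/sim/cell_qc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sm <- simulate_species_mix(cfg, collision_rate = 0.10)
write.table(sm$cells, "results/sim/species_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dr <- simulate_dose_response_dataset(cfg)
write_simulation(dr, "results/sim/dose_response")
write.table(dr$genes, "results/sim/dose_response/genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_matrix_mtx(dr$rna, "results/sim/dose_response/rna.mtx")

tj <- simulate_trajectory_dataset(cfg)
write_matrix_mtx(tj$matrix, "results/sim/trajectory.mtx")
write.table(tj$design, "results/sim/trajectory_design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("planted truth: ",
    sum(dr$truth$betad != 0), "dose-responsive peaks; ",
    sum(tj$truth$trend != "static"), "trajectory-dependent features\n")
cat("wrote results/sim/\n")
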