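#' Simulate a hashed single-nucleus ATAC experiment
#'
#' Generates hash UMI count vectors for singlet nuclei, doublets and
#' sub-threshold debris barcodes with planted ground truth. A singlet's
#' counts are a mixture of a point mass on its sample's hash and an ambient
#' (Dirichlet) profile; a doublet's counts are the sum of two singlet draws;
#' debris barcodes draw purely from the ambient profile and carry chromatin
#' fragment totals below the QC threshold so they feed background estimation.
#'
#' @param config a [sim_config()].
#' @return list with elements `hash_counts` (barcode x hash sparse matrix,
#'   cells then debris), `truth` (barcode, status singlet/heterotypic/
#'   homotypic/debris, sample, sample2), `debris_barcodes`, `ambient`
#'   (true ambient proportions), `qc` (per-barcode fragment totals and TSS
#'   enrichment) and `config`.
#' @export
simulate_hash_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  H <- cfg$n_hashes
  hashes <- sprintf("hash%02d", seq_len(H))
  samples <- sprintf("sample%02d", seq_len(cfg$n_samples))

  amb <- rgamma(H, shape = cfg$ambient_concentration)
  amb <- amb / sum(amb)

  n <- cfg$n_cells
  n_dbl <- round(cfg$doublet_rate * n)
  n_sng <- n - n_dbl
  b <- cfg$background_fraction

  draw_singlet <- function(s) {
    tot <- rnbinom(1, mu = cfg$mean_hash_umis, size = cfg$hash_nb_size)
    if (tot == 0) return(integer(H))
    pr <- b * amb
    pr[s] <- pr[s] + (1 - b)
    as.integer(rmultinom(1, tot, pr))
  }

  counts <- matrix(0L, n, H)
  lab1 <- sample(cfg$n_samples, n, replace = TRUE)
  lab2 <- rep(NA_integer_, n)
  status <- rep("singlet", n)
  if (n_dbl > 0) {
    idx <- seq_len(n_dbl)
    lab2[idx] <- sample(cfg$n_samples, n_dbl, replace = TRUE)
    status[idx] <- ifelse(lab1[idx] == lab2[idx], "homotypic", "heterotypic")
  }
  for (i in seq_len(n)) {
    counts[i, ] <- draw_singlet(lab1[i])
    if (!is.na(lab2[i])) counts[i, ] <- counts[i, ] + draw_singlet(lab2[i])
  }

  n_deb <- cfg$debris_multiplier * n
  deb_tot <- rpois(n_deb, cfg$mean_debris_umis)
  deb <- matrix(0L, n_deb, H)
  for (i in seq_len(n_deb))
    if (deb_tot[i] > 0) deb[i, ] <- as.integer(rmultinom(1, deb_tot[i], amb))

  cells <- sprintf("cell%05d", seq_len(n))
  debris <- sprintf("debris%05d", seq_len(n_deb))
  m <- rbind(counts, deb)
  dimnames(m) <- list(c(cells, debris), hashes)

  # chromatin QC covariates: real nuclei above, debris below, the filters
  qc <- data.frame(
    barcode = c(cells, debris),
    fragments = c(round(exp(rnorm(n, log(3000), 0.5))),
                  sample(10:400, n_deb, replace = TRUE)),
    tss_enrichment = c(pmax(0, rnorm(n, 8, 2)),
                       pmax(0, rnorm(n_deb, 2, 1))),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    barcode = c(cells, debris),
    status = c(status, rep("debris", n_deb)),
    sample = c(samples[lab1], rep(NA_character_, n_deb)),
    sample2 = c(ifelse(is.na(lab2), NA_character_, samples[lab2]),
                rep(NA_character_, n_deb)),
    stringsAsFactors = FALSE
  )

  log_stage("simulate_hash_experiment",
            sprintf("%d cells (%d doublets), %d debris barcodes, %d hashes",
                    n, n_dbl, n_deb, H))
  list(hash_counts = as_dgc(m), truth = truth, debris_barcodes = debris,
       ambient = setNames(amb, hashes), qc = qc, config = cfg)
}

#' Simulate a two-species barnyard experiment
#'
#' Cells are hashed human or mouse nuclei; planted collisions are barcodes
#' merging one nucleus of each species (and their hashes), so the observed
#' mixed-species fraction estimates the planted collision rate. Singlets
#' carry a small cross-species contamination so purity is high but not 1.
#'
#' @param config a [sim_config()]; half of the samples are assigned to each
#'   species.
#' @param collision_rate fraction of barcodes that are cross-species
#'   collisions.
#' @param contamination per-fragment probability of mapping to the other
#'   species in a singlet.
#' @return list with `cells` (barcode, human_frags, mouse_frags, species
#'   truth, collision truth), `hash_counts`, `hash_species` (hash -> species
#'   map) and `config`.
#' @export
simulate_species_mix <- function(config, collision_rate = 0.1,
                                 contamination = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  collision_rate <- check_prob(collision_rate, "collision_rate")
  if (cfg$n_samples < 2)
    stop_field("n_samples", "species mixing needs at least two samples")
  set.seed(cfg$seed + 1L)
  n <- cfg$n_cells
  H <- cfg$n_hashes
  hashes <- sprintf("hash%02d", seq_len(H))
  sp_of_sample <- rep(c("human", "mouse"), length.out = cfg$n_samples)
  b <- cfg$background_fraction
  amb <- rep(1 / H, H)

  hash_draw <- function(s) {
    tot <- rnbinom(1, mu = cfg$mean_hash_umis, size = cfg$hash_nb_size)
    if (tot == 0) return(integer(H))
    pr <- b * amb; pr[s] <- pr[s] + (1 - b)
    as.integer(rmultinom(1, tot, pr))
  }
  frag_draw <- function(species) {
    tot <- round(exp(rnorm(1, log(3000), 0.5)))
    other <- rbinom(1, tot, contamination)
    if (species == "human") c(human = tot - other, mouse = other)
    else c(human = other, mouse = tot - other)
  }

  n_col <- round(collision_rate * n)
  is_col <- c(rep(TRUE, n_col), rep(FALSE, n - n_col))
  hs <- which(sp_of_sample == "human")
  ms <- which(sp_of_sample == "mouse")
  hm <- matrix(0L, n, H)
  hu <- mo <- integer(n)
  species <- character(n)
  for (i in seq_len(n)) {
    if (is_col[i]) {
      s1 <- sample(hs, 1); s2 <- sample(ms, 1)
      f <- frag_draw("human") + frag_draw("mouse")
      hm[i, ] <- hash_draw(s1) + hash_draw(s2)
      species[i] <- "mixed"
    } else {
      s1 <- sample(cfg$n_samples, 1)
      f <- frag_draw(sp_of_sample[s1])
      hm[i, ] <- hash_draw(s1)
      species[i] <- sp_of_sample[s1]
    }
    hu[i] <- f["human"]; mo[i] <- f["mouse"]
  }
  barcodes <- sprintf("bc%05d", seq_len(n))
  dimnames(hm) <- list(barcodes, hashes)
  hash_species <- setNames(rep(NA_character_, H), hashes)
  hash_species[seq_len(cfg$n_samples)] <- sp_of_sample
  list(cells = data.frame(barcode = barcodes, human_frags = hu,
                          mouse_frags = mo, species = species,
                          collision = is_col, stringsAsFactors = FALSE),
       hash_counts = as_dgc(hm), hash_species = hash_species, config = cfg)
}

#' Simulate a dose-response accessibility dataset
#'
#' Per cell and feature, accessibility is Bernoulli with
#' `logit(p) = beta0 + beta_d * d + beta_f * (f - ln 3000) + beta_t * (t - 8)`
#' where `d` is log10(dose + delta), `f ~ Normal(ln 3000, 0.5^2)` is
#' log-fragments and `t ~ Normal(8, 2^2)` (truncated at 0) is TSS enrichment.
#' Gene-level RNA counts have log-mean linear in `d`; the gene dose
#' coefficients are driven by planted promoter and distal motif effects, the
#' distal ones routed through co-accessibility links with scores in `[0, 1]`
#' (only links >= 0.1 carry effect).
#'
#' @param config a [sim_config()].
#' @param drug drug label used in the design.
#' @return list with `matrix` (cell x feature binary sparse), `design`
#'   (DoseDesign data.frame), `features` (BED data.frame), `motifs`
#'   (peak x motif binary matrix), `genes` (gene, tss, promoter peak),
#'   `links` (peak_a, peak_b, score), `rna` and `atac_gene_scores`
#'   (cell x gene count matrices), `size_factors`, and `truth`.
#' @export
simulate_dose_response_dataset <- function(config, drug = "drugA") {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_genes > cfg$n_features)
    stop_field("n_genes", "must be <= n_features (promoter peaks)")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_cells
  p <- cfg$n_features
  cells <- sprintf("cell%05d", seq_len(n))
  peaks <- sprintf("peak%04d", seq_len(p))

  dose <- sample(c(0, cfg$dose_levels), n, replace = TRUE)
  ld <- log_dose(dose)
  f <- rnorm(n, log(3000), 0.5)
  t <- pmax(0, rnorm(n, 8, 2))
  beta0 <- runif(p, cfg$beta0_range[1], cfg$beta0_range[2])
  betad <- cfg$effect_sizes

  eta <- outer(ld$d, betad) +
    matrix(beta0, n, p, byrow = TRUE) +
    (cfg$beta_f * (f - log(3000)) + cfg$beta_t * (t - 8))
  x <- matrix(as.integer(runif(n * p) < plogis(eta)), n, p,
              dimnames = list(cells, peaks))

  design <- data.frame(cell = cells, drug = ifelse(dose == 0, "vehicle", drug),
                       dose = dose, vehicle = dose == 0,
                       d = ld$d, f = f, t = t,
                       replicate = sample(1:2, n, replace = TRUE),
                       stringsAsFactors = FALSE)
  attr(design, "dose_delta") <- ld$delta

  features <- data.frame(chrom = "chr1", start = (seq_len(p) - 1L) * 10000L,
                         end = (seq_len(p) - 1L) * 10000L + 501L,
                         name = peaks, stringsAsFactors = FALSE)

  motifs <- sprintf("motif%02d", seq_len(cfg$n_motifs))
  mm <- matrix(as.integer(runif(p * cfg$n_motifs) < 0.15), p, cfg$n_motifs,
               dimnames = list(peaks, motifs))

  # genes: gene g's TSS sits 100 bp inside peak g, so peak g is its promoter
  ng <- cfg$n_genes
  genes <- data.frame(gene = sprintf("gene%03d", seq_len(ng)),
                      chrom = "chr1",
                      tss = features$start[seq_len(ng)] + 100L,
                      promoter_peak = peaks[seq_len(ng)],
                      stringsAsFactors = FALSE)

  # co-accessibility links: each promoter peak to 4 random distal peaks
  distal_pool <- peaks[(ng + 1):p]
  links <- do.call(rbind, lapply(seq_len(ng), function(g) {
    tgt <- sample(distal_pool, 4)
    data.frame(peak_a = peaks[g], peak_b = tgt, score = runif(4),
               stringsAsFactors = FALSE)
  }))

  # planted motif -> expression effects: promoter motifs 1-2, distal motif 3
  eff_prom <- numeric(cfg$n_motifs); eff_prom[1:2] <- c(0.6, -0.6)
  eff_dist <- numeric(cfg$n_motifs); eff_dist[3] <- 1.5
  feat <- build_gene_features(genes, features, mm, links,
                              threshold = 0.1, window = 500)
  betad_gene <- as.numeric(feat$promoter %*% eff_prom +
                             feat$distal %*% eff_dist) +
    rnorm(ng, 0, 0.1)

  sf <- exp(rnorm(n, 0, 0.3))
  g0 <- runif(ng, log(1), log(5))
  mu_rna <- exp(outer(ld$d, betad_gene) + matrix(g0, n, ng, byrow = TRUE)) * sf
  rna <- matrix(rpois(n * ng, mu_rna), n, ng,
                dimnames = list(cells, genes$gene))
  # ATAC gene activity tracks the same dose effects with attenuation 0.6
  mu_ga <- exp(outer(ld$d, 0.6 * betad_gene) +
                 matrix(g0, n, ng, byrow = TRUE)) * sf
  gsc <- matrix(rpois(n * ng, mu_ga), n, ng,
                dimnames = list(cells, genes$gene))

  log_stage("simulate_dose_response_dataset",
            sprintf("%d cells x %d peaks, %d genes, %d motifs", n, p, ng,
                    cfg$n_motifs))
  list(matrix = as_dgc(x), design = design, features = features,
       motifs = mm, genes = genes, links = links,
       rna = as_dgc(rna), atac_gene_scores = as_dgc(gsc),
       size_factors = setNames(sf, cells),
       truth = list(beta0 = setNames(beta0, peaks),
                    betad = setNames(betad, peaks),
                    betad_gene = setNames(betad_gene, genes$gene),
                    motif_promoter_effect = setNames(eff_prom, motifs),
                    motif_distal_effect = setNames(eff_dist, motifs),
                    dose_delta = ld$delta),
       config = cfg)
}

#' Simulate a 1-D trajectory accessibility dataset
#'
#' Cells receive a latent trajectory position psi in `[0, 1]` correlated with
#' dose (`psi = clamp(dose_rank + Normal(0, 0.12))` with dose_rank the dose
#' index scaled to `[0, 1]`). Opening features have accessibility probability
#' increasing in psi, closing decreasing, dynamic a unimodal interior bump,
#' the remainder static. FRIP is
#' `0.3 + frip_dose_interaction * psi * dose_rank + Normal(0, frip_noise_sd)`.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (cell x feature binary sparse), `design`
#'   (cell, dose, vehicle, dose_rank, fragments, tss_enrichment, frip),
#'   `truth`
#'   (`psi` per cell, `trend` per feature) and `config`.
#' @export
simulate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 3L)
  n <- cfg$n_cells
  p <- cfg$n_features
  cells <- sprintf("cell%05d", seq_len(n))
  peaks <- sprintf("peak%04d", seq_len(p))

  lev <- c(0, cfg$dose_levels)
  di <- sample(length(lev), n, replace = TRUE)
  dose <- lev[di]
  dose_rank <- (di - 1) / (length(lev) - 1)
  psi <- pmin(1, pmax(0, dose_rank + rnorm(n, 0, 0.12)))

  fr <- c(opening = cfg$trajectory_fraction_opening,
          closing = cfg$trajectory_fraction_closing,
          dynamic = cfg$trajectory_fraction_dynamic)
  n_tr <- round(fr * p)
  trend <- rep("static", p)
  trend[seq_len(n_tr[1])] <- "opening"
  trend[n_tr[1] + seq_len(n_tr[2])] <- "closing"
  trend[n_tr[1] + n_tr[2] + seq_len(n_tr[3])] <- "dynamic"

  prob_fun <- function(cls, psi) {
    switch(cls,
           opening = plogis(-2 + 4 * psi),
           closing = plogis(2 - 4 * psi),
           dynamic = 0.1 + 0.6 * exp(-(psi - 0.5)^2 / (2 * 0.12^2)),
           static = rep(0.3, length(psi)))
  }
  pr <- vapply(trend, prob_fun, numeric(n), psi = psi)
  x <- matrix(as.integer(runif(n * p) < pr), n, p,
              dimnames = list(cells, peaks))

  frags <- round(exp(rnorm(n, log(3000), 0.5)))
  tss <- pmax(0, rnorm(n, 8, 2))
  frip <- 0.3 + cfg$frip_dose_interaction * psi * dose_rank +
    rnorm(n, 0, cfg$frip_noise_sd)
  frip <- pmin(0.99, pmax(0.01, frip))

  log_stage("simulate_trajectory_dataset",
            sprintf("%d cells x %d features (%d opening, %d closing, %d dynamic)",
                    n, p, n_tr[1], n_tr[2], n_tr[3]))
  list(matrix = as_dgc(x),
       design = data.frame(cell = cells, dose = dose, vehicle = dose == 0,
                           dose_rank = dose_rank, fragments = frags,
                           tss_enrichment = tss, frip = frip,
                           stringsAsFactors = FALSE),
       truth = list(psi = setNames(psi, cells),
                    trend = setNames(trend, peaks)),
       config = cfg)
}

#' Write a simulated dataset to disk in pipeline formats
#'
#' Emits the matrices as MatrixMarket + sidecars, tables as TSV and features
#' as BED, so fixtures double as format round-trip tests.
#'
#' @param sim result of [simulate_dose_response_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(outdir, "accessibility.mtx"),
    design = file.path(outdir, "design.tsv"),
    features = file.path(outdir, "features.bed")
  )
  write_matrix_mtx(sim$matrix, paths["matrix"])
  write.table(sim$design, paths["design"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(sim$features, paths["features"])
  if (!is.null(sim$motifs)) {
    paths["motifs"] <- file.path(outdir, "motifs.mtx")
    write_matrix_mtx(sim$motifs, paths["motifs"])
  }
  if (!is.null(sim$links)) {
    paths["links"] <- file.path(outdir, "links.tsv")
    write.table(sim$links, paths["links"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
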