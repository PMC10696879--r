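#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with validation. The defaults define
#' the study conditions used throughout the test-suite and the analysis
#' scripts: 2,000 nuclei from 8 hashed samples with roughly 100-fold
#' enrichment of the true hash over ambient background, 10% doublets, a
#' four-dose design plus vehicle, and planted dose effects on a subset of
#' features.
#'
#' `background_fraction` is the fraction of a singlet's hash UMIs drawn from
#' the ambient profile; with a near-uniform ambient over `n_hashes` hashes the
#' expected top/second hash ratio is `(1 - b) * n_hashes / b + 1`, so the
#' default 0.075 with 8 hashes gives the ~100-fold enrichment regime.
#'
#' @param n_cells number of real nuclei.
#' @param n_samples number of hashed samples (wells).
#' @param n_hashes number of hash barcodes (>= n_samples).
#' @param mean_hash_umis mean hash UMIs per nucleus (negative binomial).
#' @param hash_nb_size negative-binomial size (dispersion) of hash totals.
#' @param background_fraction fraction of a nucleus's hash UMIs drawn from
#'   the ambient profile, in `[0, 1]`.
#' @param ambient_concentration Dirichlet concentration of the ambient
#'   hash profile (1 = uniform prior).
#' @param doublet_rate fraction of barcodes that are doublets, in `[0, 1]`.
#' @param debris_multiplier debris barcodes per real nucleus (they feed
#'   background estimation).
#' @param mean_debris_umis mean hash UMIs per debris barcode.
#' @param n_features number of accessibility features (peaks/tiles).
#' @param dose_levels strictly increasing positive doses (uM); vehicle dose 0
#'   is always added.
#' @param effect_sizes per-feature dose coefficients (log-odds per unit
#'   log10-dose); default plants +2 on 10%, -2 on 10%, 0 elsewhere.
#' @param beta0_range range of per-feature baseline log-odds.
#' @param beta_f,beta_t coefficients of centered log-fragments and TSS
#'   enrichment in the generative accessibility model.
#' @param trajectory_fraction_opening,trajectory_fraction_closing,trajectory_fraction_dynamic
#'   fractions of features with each planted trajectory trend (sum <= 1;
#'   remainder static).
#' @param frip_dose_interaction coefficient of `psi * dose` in the FRIP model.
#' @param frip_noise_sd Gaussian noise sd of simulated FRIP values.
#' @param n_genes,n_motifs numbers of genes and motifs for the expression
#'   module.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000,
                       n_samples = 8,
                       n_hashes = 8,
                       mean_hash_umis = 200,
                       hash_nb_size = 5,
                       background_fraction = 0.075,
                       ambient_concentration = 1,
                       doublet_rate = 0.10,
                       debris_multiplier = 5,
                       mean_debris_umis = 20,
                       n_features = 500,
                       dose_levels = c(0.1, 1, 10, 100),
                       effect_sizes = NULL,
                       beta0_range = c(-2, 0),
                       beta_f = 0.25,
                       beta_t = 0.05,
                       trajectory_fraction_opening = 0.25,
                       trajectory_fraction_closing = 0.25,
                       trajectory_fraction_dynamic = 0.20,
                       frip_dose_interaction = 0.05,
                       frip_noise_sd = 0.02,
                       n_genes = 120,
                       n_motifs = 25,
                       seed = 1L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells"),
    n_samples = check_count(n_samples, "n_samples"),
    n_hashes = check_count(n_hashes, "n_hashes"),
    mean_hash_umis = check_pos(mean_hash_umis, "mean_hash_umis"),
    hash_nb_size = check_pos(hash_nb_size, "hash_nb_size"),
    background_fraction = check_prob(background_fraction,
                                     "background_fraction"),
    ambient_concentration = check_pos(ambient_concentration,
                                      "ambient_concentration"),
    doublet_rate = check_prob(doublet_rate, "doublet_rate"),
    debris_multiplier = check_count(debris_multiplier, "debris_multiplier"),
    mean_debris_umis = check_pos(mean_debris_umis, "mean_debris_umis"),
    n_features = check_count(n_features, "n_features"),
    dose_levels = dose_levels,
    effect_sizes = effect_sizes,
    beta0_range = beta0_range,
    beta_f = beta_f,
    beta_t = beta_t,
    trajectory_fraction_opening =
      check_prob(trajectory_fraction_opening, "trajectory_fraction_opening"),
    trajectory_fraction_closing =
      check_prob(trajectory_fraction_closing, "trajectory_fraction_closing"),
    trajectory_fraction_dynamic =
      check_prob(trajectory_fraction_dynamic, "trajectory_fraction_dynamic"),
    frip_dose_interaction = frip_dose_interaction,
    frip_noise_sd = check_pos(frip_noise_sd, "frip_noise_sd"),
    n_genes = check_count(n_genes, "n_genes"),
    n_motifs = check_count(n_motifs, "n_motifs"),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_hashes < cfg$n_samples)
    stop_field("n_hashes", "must be >= n_samples")
  if (any(dose_levels <= 0) || is.unsorted(dose_levels, strictly = TRUE))
    stop_field("dose_levels", "must be strictly increasing positive doses")
  if (!is.null(effect_sizes) && length(effect_sizes) != cfg$n_features)
    stop_field("effect_sizes",
               sprintf("length %d does not match n_features %d",
                       length(effect_sizes), cfg$n_features))
  if (is.null(effect_sizes)) {
    k <- max(1L, floor(cfg$n_features * 0.1))
    es <- numeric(cfg$n_features)
    es[seq_len(k)] <- 2
    es[k + seq_len(k)] <- -2
    cfg$effect_sizes <- es
  }
  tot <- cfg$trajectory_fraction_opening + cfg$trajectory_fraction_closing +
    cfg$trajectory_fraction_dynamic
  if (tot > 1)
    stop_field("trajectory_fraction_opening",
               "trend fractions must sum to at most 1")
  class(cfg) <- "sim_config"
  cfg
}
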