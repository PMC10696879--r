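#' Estimate the ambient hash background from debris barcodes
#'
#' The background profile is the mean hash UMI count vector over barcodes
#' that fell below the chromatin fragment QC threshold (nuclear debris),
#' normalized to proportions.
#'
#' @param hash_counts barcode x hash count matrix (dense or sparse).
#' @param debris_barcodes character vector of debris barcode ids (must be
#'   rows of `hash_counts`).
#' @return object of class `background_profile`: list with `proportions`
#'   (named, sums to 1) and `n_debris`.
#' @export
estimate_background <- function(hash_counts, debris_barcodes) {
  debris_barcodes <- intersect(debris_barcodes, rownames(hash_counts))
  if (length(debris_barcodes) == 0)
    stop("no debris barcodes found in the hash matrix; ",
         "lower the fragment threshold so some barcodes fall below it")
  sub <- hash_counts[debris_barcodes, , drop = FALSE]
  mean_counts <- Matrix::colSums(sub) / nrow(sub)
  tot <- sum(mean_counts)
  if (tot <= 0)
    stop("all debris barcodes have zero hash UMIs; ",
         "lower the fragment threshold so informative barcodes are included")
  structure(list(proportions = mean_counts / tot,
                 n_debris = nrow(sub)),
            class = "background_profile")
}

#' Chi-squared goodness-of-fit test of hash enrichment over background
#'
#' Tests a nucleus's hash UMI counts against the ambient background
#' proportions with the one-sample goodness-of-fit statistic
#' `sum((obs - exp)^2 / exp)`, `exp = proportion * total`, over hashes with
#' nonzero background proportion; the upper tail of the chi-squared
#' distribution with `(included hashes) - 1` degrees of freedom gives the
#' p-value. No continuity correction is applied. Observed counts on hashes
#' with zero background proportion are pooled into one extra category with
#' expected count 0: any mass there is infinite enrichment over background
#' (statistic `Inf`, p = 0).
#'
#' @param counts non-negative integer vector of hash UMI counts, total > 0.
#' @param background a `background_profile`.
#' @return list with `statistic`, `df` and `p`.
#' @export
chi2_enrichment_test <- function(counts, background) {
  stopifnot(inherits(background, "background_profile"))
  pr <- background$proportions
  if (length(counts) != length(pr))
    stop("counts and background cover different numbers of hashes")
  total <- sum(counts)
  if (total <= 0) stop("cell has zero total hash UMIs")
  nz <- pr > 0
  if (sum(nz) < 2)
    stop("background has fewer than 2 hashes with nonzero proportion; ",
         "goodness-of-fit test undefined")
  pooled <- sum(counts[!nz])
  expd <- pr[nz] * total
  stat <- sum((counts[nz] - expd)^2 / expd)
  df <- sum(nz) - 1L
  if (pooled > 0) {       # expected count 0 => infinite enrichment
    stat <- Inf
    df <- df + 1L
  }
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (wraps [stats::p.adjust()] with input validation).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hash enrichment score
#'
#' Ratio of the most abundant to the second most abundant hash UMI count in
#' a nucleus. When exactly one hash is observed the score is set to that
#' hash's count (avoiding infinite values); a tie for the top hash gives 1.
#'
#' @param counts non-negative hash UMI count vector.
#' @return a single numeric score (>= 1 whenever >= 2 hashes are observed).
#' @export
enrichment_score <- function(counts) {
  if (sum(counts) <= 0) stop("cell has zero total hash UMIs")
  srt <- sort(counts, decreasing = TRUE)
  if (sum(counts > 0) == 1) return(as.numeric(srt[1]))
  as.numeric(srt[1] / srt[2])
}

#' Assign nuclei to samples from hash counts
#'
#' A nucleus is called a singlet for its top hash when it has (1) at least
#' `min_umis` total hash UMIs, (2) a Benjamini-Hochberg adjusted chi-squared
#' enrichment p-value below `p_thresh` (adjusted jointly across all tested
#' nuclei in the run) and (3) an enrichment score of at least `alpha`
#' (`alpha >= 2` enforced). Nuclei failing only the enrichment-score
#' criterion are multiplets; all others are unassigned. The top hash is
#' tie-broken deterministically by hash order; a tie forces enrichment 1 and
#' hence a multiplet call.
#'
#' @param hash_counts barcode x hash count matrix.
#' @param background a `background_profile` from [estimate_background()].
#' @param min_umis minimum total hash UMIs (default 10).
#' @param p_thresh adjusted p-value threshold (default 0.05).
#' @param alpha minimum enrichment score (default 2; values below 2 are
#'   raised to 2).
#' @return data.frame with one row per barcode: cell, top_hash, second_hash,
#'   total_umis, chi2, p, padj, enrichment, call, alpha.
#' @export
assign_samples <- function(hash_counts, background, min_umis = 10,
                           p_thresh = 0.05, alpha = 2) {
  stopifnot(inherits(background, "background_profile"))
  if (alpha < 2) {
    log_stage("assign_samples", "alpha below 2 raised to the minimum of 2")
    alpha <- 2
  }
  m <- as.matrix(hash_counts)
  hashes <- colnames(m)
  n <- nrow(m)
  total <- rowSums(m)
  top_hash <- second_hash <- rep(NA_character_, n)
  enr <- chi2 <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (total[i] <= 0) next
    o <- order(-m[i, ], hashes)            # ties broken by hash id
    top_hash[i] <- hashes[o[1]]
    second_hash[i] <- hashes[o[2]]
    enr[i] <- enrichment_score(m[i, ])
    tst <- chi2_enrichment_test(m[i, ], background)
    chi2[i] <- tst$statistic
    p[i] <- tst$p
  }
  padj <- rep(NA_real_, n)
  tested <- !is.na(p)
  padj[tested] <- bh_adjust(p[tested])
  call <- rep("unassigned", n)
  labeled <- tested & total >= min_umis & padj < p_thresh
  call[labeled & enr < alpha] <- "multiplet"
  call[labeled & enr >= alpha] <- "singlet"
  log_stage("assign_samples",
            sprintf("%d barcodes: %d singlets, %d multiplets, %d unassigned",
                    n, sum(call == "singlet"), sum(call == "multiplet"),
                    sum(call == "unassigned")))
  data.frame(cell = rownames(m), top_hash = top_hash,
             second_hash = second_hash, total_umis = total,
             chi2 = chi2, p = p, padj = padj, enrichment = enr,
             call = call, alpha = alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a species-mixing experiment
#'
#' Chromatin collisions are barcodes with strictly less than `purity` of
#' their fragments on a single species; the report cross-tabulates them
#' against hash-based multiplet calls and scores hash label accuracy on
#' chromatin singlets.
#'
#' @param cells data.frame with barcode, human_frags, mouse_frags.
#' @param assignments output of [assign_samples()] for the same barcodes.
#' @param purity single-species fraction below which a barcode is a
#'   chromatin collision (strict inequality; default 0.90).
#' @param hash_species optional named map hash -> species ("human"/"mouse")
#'   used to score label accuracy.
#' @return list with the per-cell table, the collision/hash cross-tab,
#'   `collision_rate`, `hash_collision_recall` (fraction of chromatin
#'   collisions not called singlet by hash) and, when `hash_species` is
#'   given, `label_accuracy` on chromatin singlets.
#' @export
evaluate_species_mix <- function(cells, assignments, purity = 0.90,
                                 hash_species = NULL) {
  stopifnot(all(c("barcode", "human_frags", "mouse_frags") %in% names(cells)))
  tot <- cells$human_frags + cells$mouse_frags
  zero <- tot == 0
  if (any(zero))
    log_stage("evaluate_species_mix",
              sprintf("excluded %d zero-fragment cells", sum(zero)))
  cells <- cells[!zero, , drop = FALSE]
  tot <- tot[!zero]
  frac_max <- pmax(cells$human_frags, cells$mouse_frags) / tot
  collision <- frac_max < purity
  species <- ifelse(collision, "mixed",
                    ifelse(cells$human_frags >= cells$mouse_frags,
                           "human", "mouse"))
  idx <- match(cells$barcode, assignments$cell)
  call <- assignments$call[idx]
  tab <- table(chromatin = ifelse(collision, "collision", "singlet"),
               hash = call)
  out <- data.frame(cells, frac_max = frac_max, collision = collision,
                    species_call = species, hash_call = call,
                    stringsAsFactors = FALSE)
  res <- list(cells = out, crosstab = tab,
              collision_rate = mean(collision),
              hash_collision_recall =
                if (any(collision)) mean(call[collision] != "singlet")
                else NA_real_)
  if (!is.null(hash_species)) {
    sing <- !collision & call == "singlet"
    pred <- hash_species[assignments$top_hash[idx]]
    res$label_accuracy <- mean(pred[sing] == species[sing], na.rm = TRUE)
  }
  res
}
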