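#' Motif enrichment within an accessibility trend class
#'
#' For each motif, fits the univariate logistic model
#' `logit(P(in class)) = beta0 + beta_i M_i` predicting whether a peak has
#' the trend from the motif's presence, and tests `beta_i` with a two-
#' tailed Wald z-test. p-values are Benjamini-Hochberg adjusted across the
#' motifs of the family; a motif is enriched if `padj < alpha` and
#' `beta_i > 0`. Motifs present in all or in no peaks are inestimable and
#' skipped with a flag.
#'
#' @param in_class named logical (or 0/1) vector per peak: does the peak
#'   carry the trend?
#' @param motifs peak x motif binary matrix (rows matching `in_class`).
#' @param alpha adjusted-p threshold for the enriched flag (default 0.05).
#' @return data.frame with motif, beta, se, z, p, padj, skipped, enriched.
#' @export
motif_trend_regression <- function(in_class, motifs, alpha = 0.05) {
  y <- as.numeric(in_class)
  if (all(y == 1) || all(y == 0))
    stop("need at least one peak in the class and one outside it")
  m <- as.matrix(motifs)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    mj <- m[, j]
    if (all(mj == 1) || all(mj == 0))
      return(data.frame(motif = colnames(m)[j], beta = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    fit <- suppressWarnings(glm(y ~ mj, family = binomial(),
                                control = list(epsilon = 1e-14,
                                               maxit = 100)))
    wd <- glm_wald(fit)
    z <- unname(wd["mj", "est"] / wd["mj", "se"])
    data.frame(motif = colnames(m)[j], beta = unname(wd["mj", "est"]),
               se = unname(wd["mj", "se"]), z = z, p = 2 * pnorm(-abs(z)),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- NA_real_
  out$padj[!out$skipped] <- bh_adjust(out$p[!out$skipped])
  out$enriched <- !out$skipped & out$padj < alpha & out$beta > 0
  out
}

# distance (bp) from a TSS point to a 0-based half-open interval
tss_peak_distance <- function(tss, start, end) {
  pmax(0, pmax(start - tss, tss - (end - 1)))
}

#' Build promoter and distal motif features per gene
#'
#' A peak is a promoter peak when it lies within `window` bp of an
#' annotated TSS (inclusive). Genes without an accessible promoter peak are
#' excluded. Promoter features are binary: motif present in any promoter
#' peak of the gene. The distal feature for a motif is the highest
#' co-accessibility score (>= `threshold`) from any of the gene's promoter
#' peaks to a connected distal (non-promoter) peak carrying that motif,
#' else 0. Links are symmetrized; feature construction is order-invariant
#' in the links.
#'
#' @param genes data.frame with gene, chrom, tss (0-based position).
#' @param peaks BED-style data.frame of peaks (chrom, start, end, name).
#' @param motifs peak x motif binary matrix (rownames = peak names).
#' @param links data.frame with peak_a, peak_b, score in `[0, 1]`.
#' @param threshold minimum co-accessibility score for a connection
#'   (default 0.1).
#' @param window promoter window around the TSS in bp (default 500,
#'   inclusive).
#' @return object of class `gene_feature_table`: list with `genes`
#'   (retained gene table), `promoter` (gene x motif binary matrix),
#'   `distal` (gene x motif matrix with values in `{0} U [threshold, 1]`),
#'   `promoter_peaks` (per-gene list).
#' @export
build_gene_features <- function(genes, peaks, motifs, links,
                                threshold = 0.1, window = 500) {
  stopifnot(all(rownames(motifs) == peaks$name) ||
              all(peaks$name %in% rownames(motifs)))
  mm <- as.matrix(motifs)[peaks$name, , drop = FALSE]

  # global promoter labels: within `window` bp of any annotated TSS
  is_prom <- rep(FALSE, nrow(peaks))
  prom_of_gene <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    same <- peaks$chrom == genes$chrom[g]
    dd <- tss_peak_distance(genes$tss[g], peaks$start, peaks$end)
    hit <- same & dd <= window
    is_prom <- is_prom | hit
    prom_of_gene[[g]] <- peaks$name[hit]
  }
  keep <- lengths(prom_of_gene) > 0
  if (any(!keep))
    log_stage("build_gene_features",
              sprintf("dropped %d/%d genes without an accessible promoter",
                      sum(!keep), nrow(genes)))
  genes <- genes[keep, , drop = FALSE]
  prom_of_gene <- prom_of_gene[keep]

  # symmetric link lookup above threshold
  lk <- rbind(
    data.frame(a = links$peak_a, b = links$peak_b, s = links$score),
    data.frame(a = links$peak_b, b = links$peak_a, s = links$score))
  lk <- lk[lk$s >= threshold, , drop = FALSE]
  distal_names <- peaks$name[!is_prom]

  ng <- nrow(genes)
  nm <- ncol(mm)
  prom_feat <- matrix(0, ng, nm, dimnames = list(genes$gene, colnames(mm)))
  dist_feat <- matrix(0, ng, nm, dimnames = list(genes$gene, colnames(mm)))
  for (g in seq_len(ng)) {
    pp <- prom_of_gene[[g]]
    prom_feat[g, ] <- as.numeric(colSums(mm[pp, , drop = FALSE]) > 0)
    con <- lk[lk$a %in% pp & lk$b %in% distal_names, , drop = FALSE]
    if (nrow(con)) {
      for (j in seq_len(nm)) {
        has <- con$b[mm[con$b, j] == 1]
        if (length(has))
          dist_feat[g, j] <- max(con$s[con$b %in% has])
      }
    }
  }
  structure(list(genes = genes, promoter = prom_feat, distal = dist_feat,
                 promoter_peaks = setNames(prom_of_gene, genes$gene)),
            class = "gene_feature_table")
}

#' Elastic-net prediction of expression dose coefficients
#'
#' Fits two penalized linear models of the per-gene RNA dose coefficient:
#' promoter motif features alone, and promoter plus distal co-accessibility
#' features. Features are standardized; the penalty strength is chosen by
#' 5-fold cross-validation at mixing parameter `mixing` under a fixed seed.
#' Reports training R^2 (the headline variance explained), cross-validated
#' R^2, and the fold increase `R2_full / R2_promoter`.
#'
#' @param features a `gene_feature_table`.
#' @param target named per-gene dose coefficients (e.g. RNA `beta_d`);
#'   genes absent from the feature table are dropped.
#' @param mixing elastic-net mixing parameter (default 0.5).
#' @param seed seed for fold assignment.
#' @return list with `r2_promoter`, `r2_full`, `r2_cv_promoter`,
#'   `r2_cv_full`, `fold_increase`, `coef_promoter`, `coef_full`
#'   (promoter/distal coefficient tables), `n_genes`.
#' @export
fit_expression_models <- function(features, target, mixing = 0.5,
                                  seed = 1L) {
  stopifnot(inherits(features, "gene_feature_table"))
  genes <- intersect(features$genes$gene, names(target))
  if (length(genes) < 20)
    stop("need at least 20 genes with both features and a target")
  y <- target[genes]
  if (var(y) == 0) stop("target coefficients have zero variance")
  xp <- features$promoter[genes, , drop = FALSE]
  xd <- features$distal[genes, , drop = FALSE]
  colnames(xp) <- paste0("prom_", colnames(xp))
  colnames(xd) <- paste0("dist_", colnames(xd))
  xf <- cbind(xp, xd)

  fit_one <- function(x) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, y, alpha = mixing, nfolds = 5,
                            standardize = TRUE)
    pred <- as.numeric(predict(cv, newx = x, s = "lambda.min"))
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - sum((y - pred)^2) / sst
    cvm <- cv$cvm[cv$lambda == cv$lambda.min]
    list(r2 = r2, r2_cv = 1 - cvm / var(y),
         coef = as.matrix(coef(cv, s = "lambda.min")))
  }
  fp <- fit_one(xp)
  ff <- fit_one(xf)
  list(r2_promoter = fp$r2, r2_full = ff$r2,
       r2_cv_promoter = fp$r2_cv, r2_cv_full = ff$r2_cv,
       fold_increase = if (fp$r2 > 0) ff$r2 / fp$r2 else NA_real_,
       coef_promoter = fp$coef, coef_full = ff$coef,
       n_genes = length(genes))
}
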