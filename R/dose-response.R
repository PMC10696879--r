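#' Cells relevant for one drug's dose-response analysis
#'
#' The analysis set for drug D contains all cells treated with any dose of D
#' plus all vehicle-control cells.
#'
#' @param design DoseDesign data.frame (columns cell, drug, dose, vehicle,
#'   d, f, t).
#' @param drug drug label.
#' @return character vector of cell ids.
#' @export
subset_cells_for_drug <- function(design, drug) {
  treated <- design$cell[design$drug == drug & !design$vehicle]
  if (length(treated) == 0)
    stop(sprintf("no treated cells for drug '%s'", drug))
  c(treated, design$cell[design$vehicle])
}

# Wald table with the Fisher information evaluated at the converged
# coefficients (summary.glm uses the last IRLS working weights, one step
# behind the reported estimate)
glm_wald <- function(fit, quasi = FALSE) {
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  eta <- fit$family$linkfun(mu)
  w <- fit$family$mu.eta(eta)^2 / fit$family$variance(mu)
  vc <- tryCatch(solve(crossprod(X * w, X)),
                 error = function(e)    # separated fit: information singular
                   stats::vcov(fit))
  phi <- 1
  if (quasi)
    phi <- sum((fit$y - mu)^2 / fit$family$variance(mu)) / fit$df.residual
  cbind(est = coef(fit), se = sqrt(diag(vc) * phi))
}

# logistic fit with separation detection; returns coefficient row for `term`
wald_logit_fit <- function(y, covars, term = "d", cap = 15, maxit = 100) {
  df <- data.frame(y = y, covars)
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-14, maxit = maxit)))
  wd <- glm_wald(fit)
  est <- wd[term, "est"]
  se <- wd[term, "se"]
  z <- est / se
  flagged <- !fit$converged || abs(est) > cap
  list(beta = unname(est), se = unname(se), z = unname(z),
       p = unname(2 * pnorm(-abs(z))), flagged = flagged)
}

#' Dose-response differential accessibility per peak
#'
#' For each drug, cells are subset with [subset_cells_for_drug()]; peaks
#' accessible in fewer than `min_frac` of that set are excluded. Each
#' remaining peak is fit with the logistic model
#' `logit(Y) = beta0 + beta_d d + beta_f f + beta_t t` and the dose term
#' tested with a Wald z-test. Raw p-values are pooled across all drugs and
#' all analyzed peaks before a single Benjamini-Hochberg adjustment.
#' Non-converged or separated fits (`|beta_d| > 15` after 100 iterations)
#' are flagged and never called significant.
#'
#' @param x cell x peak binary matrix.
#' @param design DoseDesign data.frame.
#' @param drugs drug label(s); default all non-vehicle drugs in the design.
#' @param min_frac minimum accessible fraction of the analysis set
#'   (default 0.01).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return data.frame with peak, drug, beta_d, se, z, p, padj, n_cells,
#'   accessible_frac, flagged, significant, direction
#'   ("opening" iff beta_d > 0).
#' @export
run_peak_da <- function(x, design, drugs = NULL, min_frac = 0.01,
                        alpha = 0.05) {
  if (is.null(drugs))
    drugs <- setdiff(unique(design$drug[!design$vehicle]), NA)
  res <- lapply(drugs, function(dr) {
    cells <- subset_cells_for_drug(design, dr)
    sub <- x[cells, , drop = FALSE]
    dsub <- design[match(cells, design$cell), ]
    if (length(unique(dsub$d)) < 2)
      stop(sprintf("drug '%s' has fewer than 2 distinct dose values", dr))
    frac <- Matrix::colSums(sub) / nrow(sub)
    keep <- which(frac >= min_frac)
    log_stage("run_peak_da",
              sprintf("drug %s: %d cells, %d/%d peaks pass %.1f%% filter",
                      dr, nrow(sub), length(keep), ncol(sub),
                      100 * min_frac))
    covars <- dsub[, c("d", "f", "t")]
    rows <- lapply(keep, function(j) {
      ft <- wald_logit_fit(as.numeric(sub[, j]), covars)
      data.frame(peak = colnames(sub)[j], drug = dr, beta_d = ft$beta,
                 se = ft$se, z = ft$z, p = ft$p, n_cells = nrow(sub),
                 accessible_frac = frac[j], flagged = ft$flagged,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$padj <- bh_adjust(out$p)            # pooled across drugs and peaks
  out$significant <- !out$flagged & out$padj < alpha
  out$direction <- ifelse(out$beta_d > 0, "opening", "closing")
  out
}

#' Gene-level quasipoisson dose model
#'
#' Fits `ln(Y) = beta0 + beta_d d` per gene with a quasipoisson GLM
#' (log link, dispersion from Pearson residuals) and library size factors
#' as offsets. All-zero genes are skipped with a flag.
#'
#' @param y cell x gene count (or accessibility-score) matrix.
#' @param design DoseDesign data.frame covering the rows of `y`.
#' @param drug drug label ([subset_cells_for_drug()] defines the cells).
#' @param size_factors named positive size factors per cell.
#' @return data.frame with gene, beta_d, se, t, p, skipped; `padj` via BH
#'   over tested genes.
#' @export
fit_gene_dose_model <- function(y, design, drug, size_factors) {
  if (any(size_factors <= 0)) stop("size factors must be positive")
  cells <- subset_cells_for_drug(design, drug)
  sub <- y[cells, , drop = FALSE]
  d <- design$d[match(cells, design$cell)]
  off <- log(size_factors[cells])
  rows <- lapply(seq_len(ncol(sub)), function(j) {
    yj <- as.numeric(sub[, j])
    if (all(yj == 0))
      return(data.frame(gene = colnames(sub)[j], beta_d = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    fit <- suppressWarnings(
      glm(yj ~ d, family = quasipoisson(), offset = off,
          control = list(epsilon = 1e-14, maxit = 100)))
    wd <- glm_wald(fit, quasi = TRUE)
    tstat <- wd["d", "est"] / wd["d", "se"]
    data.frame(gene = colnames(sub)[j], beta_d = unname(wd["d", "est"]),
               se = unname(wd["d", "se"]), t = unname(tstat),
               p = unname(2 * pt(-abs(tstat), df = fit$df.residual)),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- NA_real_
  out$padj[!out$skipped] <- bh_adjust(out$p[!out$skipped])
  out
}

#' Compare ATAC and RNA dose coefficients
#'
#' Inner-joins gene-level dose coefficients from accessibility scores and
#' RNA counts on genes whose RNA dose term passes the significance filter,
#' reporting the Pearson correlation and sign concordance of the pairs.
#'
#' @param atac,rna results of [fit_gene_dose_model()].
#' @param rna_alpha adjusted-p threshold applied to the RNA results
#'   (default 0.05).
#' @return list with `pairs` (gene, beta_atac, beta_rna), `correlation`,
#'   `sign_concordance`, `n`.
#' @export
compare_atac_rna_coeffs <- function(atac, rna, rna_alpha = 0.05) {
  rna_sig <- rna[!rna$skipped & !is.na(rna$padj) & rna$padj < rna_alpha, ]
  shared <- intersect(atac$gene[!atac$skipped], rna_sig$gene)
  if (length(shared) == 0)
    stop("no shared genes pass the RNA significance filter")
  a <- atac$beta_d[match(shared, atac$gene)]
  r <- rna_sig$beta_d[match(shared, rna_sig$gene)]
  list(pairs = data.frame(gene = shared, beta_atac = a, beta_rna = r,
                          stringsAsFactors = FALSE),
       correlation = cor(a, r),
       sign_concordance = mean(sign(a) == sign(r)),
       n = length(shared))
}

#' Four-parameter log-logistic viability fit
#'
#' Fits `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))` to cells-per-dose
#' counts by nonlinear least squares. `c`/`d` are the lower/upper
#' asymptotes, `b` the steepness (positive for responses decreasing in
#' dose) and `e` the half-maximal effective dose (ED50); `f(e) = (c + d)/2`
#' by construction. Vehicle wells (dose 0) are excluded from the log-dose
#' fit; the upper asymptote absorbs the baseline.
#'
#' @param counts cells recovered per well.
#' @param doses matching doses (uM); at least 4 distinct positive doses.
#' @return list with `b`, `c`, `d`, `e` (ED50), `sse` and the `nls` fit.
#' @export
fit_viability_4pl <- function(counts, doses) {
  keep <- doses > 0
  counts <- counts[keep]; doses <- doses[keep]
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct positive doses")
  model <- function(p)
    p["c"] + (p["d"] - p["c"]) /
      (1 + exp(p["b"] * (log(doses) - log(p["e"]))))
  start <- c(b = 1, c = min(counts), d = max(counts),
             e = exp(mean(log(range(doses)))))
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(p) counts - model(p),
    lower = c(-Inf, -Inf, -Inf, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!fit$info %in% 1:4)
    stop("4PL fit failed to converge; last state: ",
         paste(names(fit$par), signif(fit$par, 6), sep = "=",
               collapse = ", "))
  p <- fit$par
  list(b = unname(p["b"]), c = unname(p["c"]), d = unname(p["d"]),
       e = unname(p["e"]), sse = sum(fit$fvec^2), fit = fit)
}
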