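#' Simulate doublets from random cell pairs
#'
#' Each simulated profile is the element-wise OR (binarized sum) of two
#' distinct observed cells sampled uniformly.
#'
#' @param x cell x feature binary matrix (>= 2 cells).
#' @param n_sim number of simulated doublets (default: number of cells).
#' @param seed integer seed.
#' @return binary matrix of `n_sim` simulated profiles over the same
#'   features, rownames `sim000001`, ...
#' @export
simulate_doublets <- function(x, n_sim = nrow(x), seed = 1L) {
  if (nrow(x) < 2) stop("need at least 2 cells to simulate doublets")
  if (n_sim < 1) stop("n_sim must be at least 1")
  set.seed(seed)
  a <- sample(nrow(x), n_sim, replace = TRUE)
  b <- sample(nrow(x) - 1L, n_sim, replace = TRUE)
  b <- ifelse(b >= a, b + 1L, b)           # distinct second member
  sim <- x[a, , drop = FALSE] + x[b, , drop = FALSE]
  sim@x[sim@x > 1] <- 1
  rownames(sim) <- sprintf("sim%06d", seq_len(n_sim))
  as_dgc(sim)
}

# brute-force k nearest neighbors of `query` rows among `ref` rows
# (Euclidean), self-matches excluded by the caller via index bookkeeping
knn_indices <- function(query, ref, k, exclude = NULL) {
  qn <- rowSums(query^2)
  rn <- rowSums(ref^2)
  out <- matrix(NA_integer_, nrow(query), k)
  block <- max(1L, floor(2e7 / nrow(ref)))
  for (s in seq(1, nrow(query), by = block)) {
    e <- min(s + block - 1L, nrow(query))
    d2 <- outer(qn[s:e], rn, "+") - 2 * tcrossprod(query[s:e, , drop = FALSE],
                                                   ref)
    for (i in seq_len(e - s + 1L)) {
      row <- d2[i, ]
      qi <- s + i - 1L
      if (!is.null(exclude)) row[exclude[qi]] <- Inf
      out[qi, ] <- order(row)[seq_len(k)]
    }
  }
  out
}

#' Score cells by simulated-doublet neighborhood fraction
#'
#' Transforms observed and simulated profiles with the IDF derived from
#' observed cells only, embeds them with a truncated SVD of the observed
#' matrix (default) or of the union, and scores each observed cell by the
#' fraction of simulated doublets among its `k` nearest neighbors
#' (Euclidean) in the reduced space (first component dropped; `dims = 49`
#' remaining by default).
#'
#' @param x observed cell x feature binary matrix.
#' @param sim simulated doublet matrix over the same features
#'   ([simulate_doublets()]).
#' @param dims number of components used for distances (default 49:
#'   50 computed, first dropped).
#' @param k neighborhood size; default `round(0.5 * sqrt(n_obs + n_sim))`.
#' @param basis `"observed"` (fit SVD on observed cells, project simulated;
#'   default) or `"union"` (fit on the concatenated matrix).
#' @return object of class `doublet_scores`: data.frame with cell, score in
#'   `[0, 1]`, rank (1 = highest score).
#' @export
score_doublets <- function(x, sim, dims = 49, k = NULL, basis = "observed") {
  if (ncol(x) != ncol(sim)) stop("feature spaces differ")
  n_obs <- nrow(x); n_sim <- nrow(sim)
  if (is.null(k)) k <- max(1L, round(0.5 * sqrt(n_obs + n_sim)))
  if (k >= n_obs + n_sim)
    stop("k must be smaller than the total number of points")
  basis <- match.arg(basis, c("observed", "union"))
  cs <- Matrix::colSums(x)
  idf <- ifelse(cs > 0, n_obs / cs, 0)   # IDF from observed cells only
  if (basis == "observed") {
    lsi <- tfidf_lsi(x, dims = dims + 1, drop_first = TRUE, idf = idf)
    emb_obs <- lsi$scores
    emb_sim <- project_lsi(lsi, sim)
  } else {
    lsi <- tfidf_lsi(rbind(x, sim), dims = dims + 1, drop_first = TRUE,
                     idf = idf)
    emb_obs <- lsi$scores[seq_len(n_obs), , drop = FALSE]
    emb_sim <- lsi$scores[n_obs + seq_len(n_sim), , drop = FALSE]
  }
  all_pts <- rbind(emb_obs, emb_sim)
  nn <- knn_indices(emb_obs, all_pts, k,
                    exclude = seq_len(n_obs))  # exclude self
  score <- rowMeans(matrix(nn > n_obs, nrow(nn), ncol(nn)))
  res <- data.frame(cell = rownames(x), score = score,
                    rank = rank(-score, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(res) <- c("doublet_scores", class(res))
  res
}

#' Remove the top fraction of doublet scores
#'
#' Deterministically removes exactly `ceiling(frac * n)` cells with the
#' highest scores; ties at the cutoff are broken by barcode order.
#'
#' @param scores a `doublet_scores` data.frame.
#' @param frac fraction to prune, in (0, 1) (default 0.10).
#' @return list with `pruned` and `retained` barcode vectors.
#' @export
prune_top_fraction <- function(scores, frac = 0.10) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  n <- nrow(scores)
  n_prune <- ceiling(frac * n)
  ord <- order(-scores$score, scores$cell)
  pruned <- scores$cell[ord[seq_len(n_prune)]]
  log_stage("prune_top_fraction",
            sprintf("removed %d/%d cells (top %.0f%% doublet scores)",
                    n_prune, n, 100 * frac))
  list(pruned = pruned, retained = setdiff(scores$cell, pruned))
}
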