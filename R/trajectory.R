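#' Learn a principal graph over an embedding
#'
#' A lightweight stand-in for external principal-graph learners: k-means
#' centroids joined by a minimum spanning tree over their Euclidean
#' distances, with every cell assigned to its nearest centroid. It preserves
#' exactly the properties the downstream pseudodose math consumes (node
#' assignment and geodesic distances) and can be swapped for an imported
#' node/edge table. The centroid count is deliberately modest: over-resolving
#' dense terminal regions makes the spanning tree zigzag through them,
#' inflating geodesic distances with spurious path length.
#'
#' @param embedding cell x component matrix with rownames.
#' @param n_centroids number of graph nodes (default 15).
#' @param seed integer seed for k-means.
#' @return object of class `principal_graph`: list with `nodes` (centroid
#'   coordinates), `graph` (weighted igraph), `edges` (from, to, length),
#'   `assignment` (named node index per cell).
#' @export
learn_principal_graph <- function(embedding, n_centroids = 15, seed = 1L) {
  if (n_centroids < 2 || n_centroids > nrow(embedding))
    stop("n_centroids must be in [2, number of cells]")
  if (all(apply(embedding, 2, function(z) diff(range(z)) == 0)))
    stop("degenerate embedding: all points identical")
  set.seed(seed)
  n_centroids <- min(n_centroids, nrow(unique(as.data.frame(embedding))))
  km <- kmeans(embedding, centers = n_centroids, nstart = 50,
               iter.max = 100)
  centers <- km$centers
  dm <- as.matrix(dist(centers))
  g_full <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                                weighted = TRUE)
  g <- igraph::mst(g_full)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length = igraph::E(g)$weight)
  assignment <- setNames(km$cluster, rownames(embedding))
  structure(list(nodes = centers, graph = g, edges = edges,
                 assignment = assignment),
            class = "principal_graph")
}

#' Pseudodose from geodesic distance to vehicle-dominated roots
#'
#' Root nodes are those where a strict majority of assigned cells are
#' vehicle-treated. Each cell's pseudodose is the minimum geodesic
#' (shortest-path) distance from its node to any root along the principal
#' graph. Cells are then grouped by 1-D k-means on pseudodose (default
#' k = 10) and each cell receives its group's mean value as the binned
#' pseudodose.
#'
#' @param graph a `principal_graph`.
#' @param vehicle named (or cell-ordered) logical vector: is each cell a
#'   vehicle control?
#' @param k number of pseudodose bins (default 10; reduced when fewer
#'   distinct values exist).
#' @param seed seed for the 1-D k-means.
#' @return data.frame with cell, node, psi (geodesic pseudodose), bin,
#'   psi_bin (bin mean). Attribute `roots` holds the root node indices.
#' @export
compute_pseudodose <- function(graph, vehicle, k = 10, seed = 1L) {
  stopifnot(inherits(graph, "principal_graph"))
  cells <- names(graph$assignment)
  if (!is.null(names(vehicle))) vehicle <- vehicle[cells]
  veh_frac <- tapply(vehicle, graph$assignment, mean)
  roots <- as.integer(names(veh_frac)[veh_frac > 0.5])
  if (length(roots) == 0)
    stop("no node has a vehicle majority; inspect the embedding or the ",
         "vehicle annotation before computing pseudodose")
  dmat <- igraph::distances(graph$graph, v = roots,
                            weights = igraph::E(graph$graph)$weight)
  node_psi <- apply(dmat, 2, min)
  psi <- unname(node_psi[graph$assignment])
  k_eff <- min(k, length(unique(psi)))
  set.seed(seed)
  km <- kmeans(psi, centers = k_eff, nstart = 10, iter.max = 100)
  # relabel bins in increasing pseudodose order
  ord <- order(km$centers)
  bin <- match(km$cluster, ord)
  psi_bin <- tapply(psi, bin, mean)[as.character(bin)]
  out <- data.frame(cell = cells, node = unname(graph$assignment),
                    psi = psi, bin = bin, psi_bin = unname(psi_bin),
                    stringsAsFactors = FALSE)
  attr(out, "roots") <- roots
  log_stage("compute_pseudodose",
            sprintf("%d roots, psi range [%.3f, %.3f], %d bins",
                    length(roots), min(psi), max(psi), k_eff))
  out
}

# split n cells into groups with sizes in [min_size, max_size]
chunk_sizes <- function(n, min_size, max_size) {
  g <- ceiling(n / max_size)
  base <- floor(n / g)
  sizes <- rep(base, g)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Aggregate cells into pseudodose groups
#'
#' Within each pseudodose bin, cells are sorted by pseudodose and chunked
#' into contiguous groups of at least `min_size` and at most `max_size`
#' cells; bins with fewer than `min_size` cells are merged with the nearest
#' adjacent bin before chunking. For each group j the output holds
#' `A[i, j]`, the number of cells in the group with feature i accessible,
#' the group mean pseudodose and the group's mean per-cell accessible
#' feature count S.
#'
#' @param x cell x feature binary matrix.
#' @param pseudodose data.frame from [compute_pseudodose()].
#' @param min_size,max_size group size bounds (defaults 50 and 100).
#' @return object of class `aggregate_accessibility`: list with `A`
#'   (feature x group counts), `psi` (group mean pseudodose), `S` (group
#'   cell-wise accessibility), `size`, `membership` (group per cell).
#' @export
aggregate_groups <- function(x, pseudodose, min_size = 50, max_size = 100) {
  if (nrow(x) < min_size)
    stop(sprintf("need at least %d cells to form aggregate groups",
                 min_size))
  pd <- pseudodose[match(rownames(x), pseudodose$cell), ]
  bins <- sort(unique(pd$bin))
  bin_n <- table(factor(pd$bin, levels = bins))
  # merge undersized bins with the nearest adjacent bin
  merged <- as.integer(bins)
  repeat {
    cnt <- tapply(rep(1, nrow(pd)), merged[match(pd$bin, bins)], sum)
    small <- names(cnt)[cnt < min_size]
    if (length(small) == 0) break
    s <- as.integer(small[1])
    others <- setdiff(unique(merged), s)
    tgt <- others[which.min(abs(others - s))]
    merged[merged == s] <- tgt
  }
  pd$group_bin <- merged[match(pd$bin, bins)]

  membership <- integer(nrow(pd))
  gid <- 0L
  for (gb in sort(unique(pd$group_bin))) {
    idx <- which(pd$group_bin == gb)
    idx <- idx[order(pd$psi[idx])]
    sizes <- chunk_sizes(length(idx), min_size, max_size)
    at <- 0L
    for (s in sizes) {
      gid <- gid + 1L
      membership[idx[at + seq_len(s)]] <- gid
      at <- at + s
    }
  }
  n_grp <- gid
  G <- Matrix::sparseMatrix(i = seq_len(nrow(pd)), j = membership, x = 1,
                            dims = c(nrow(pd), n_grp))
  A <- as.matrix(Matrix::t(x) %*% G)       # feature x group counts
  rownames(A) <- colnames(x)
  colnames(A) <- sprintf("group%03d", seq_len(n_grp))
  psi_g <- as.numeric(tapply(pd$psi, membership, mean))
  S_g <- as.numeric(tapply(Matrix::rowSums(x), membership, mean))
  size_g <- as.integer(table(factor(membership, levels = seq_len(n_grp))))
  log_stage("aggregate_groups",
            sprintf("%d cells -> %d groups (sizes %d-%d)", nrow(pd), n_grp,
                    min(size_g), max(size_g)))
  structure(list(A = A, psi = psi_g, S = S_g, size = size_g,
                 membership = setNames(membership, pd$cell)),
            class = "aggregate_accessibility")
}

# NB spline fit of grouped counts; Poisson fallback on failure
fit_nb_spline <- function(counts, psi, S, offset_log, spline_df = 2) {
  df <- data.frame(counts = counts, psi = psi, S = S)
  fml <- counts ~ splines::ns(psi, df = spline_df) +
    splines::ns(S, df = spline_df) + offset(offset_log)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(
      fml, data = df,
      control = glm.control(epsilon = 1e-10, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- suppressWarnings(glm(
      fml, data = df, family = poisson(),
      control = list(epsilon = 1e-10, maxit = 100)))
    attr(fit, "nb_fallback") <- TRUE
  }
  fit
}

#' Smooth grouped accessibility and classify trends
#'
#' Per feature, fits the negative-binomial log-link model
#' `ln(A) = beta0 + f(psi) + g(S)` with natural splines (default df = 2:
#' the trend families of interest -- monotone or single interior bump --
#' need one interior knot, and extra knots let terminal noise tilt the
#' smoothed tail across the opening/closing bin boundary) on the
#' group mean pseudodose and the group cell-wise accessibility, with
#' log(group size) as offset so predictions are per-cell rates. Predictions
#' are evaluated on a 100-point grid spanning the observed pseudodose
#' range, with S linearly interpolated from the group values at each grid
#' pseudodose so the smoothed curve follows the data manifold. Features
#' whose prediction argmax falls in bins
#' 1-20 are "closing", in bins 81-100 "opening", otherwise "dynamic";
#' features not in `da_peaks` are "static". Non-converging NB fits fall
#' back to Poisson with a flag.
#'
#' @param agg an `aggregate_accessibility`.
#' @param da_peaks character vector of differentially accessible feature
#'   names (trend classes are only assigned within this set).
#' @param grid_size prediction grid length (default 100).
#' @param spline_df natural-spline degrees of freedom for both smoothed
#'   covariates (default 2).
#' @return data.frame with peak, class, argmax_bin, nb_fallback, plus a
#'   `predictions` attribute (feature x grid matrix of per-cell rates).
#' @export
smooth_and_classify <- function(agg, da_peaks, grid_size = 100,
                                spline_df = 2) {
  stopifnot(inherits(agg, "aggregate_accessibility"))
  if (length(agg$psi) < 6)
    stop("need at least 6 groups for spline smoothing")
  grid <- seq(min(agg$psi), max(agg$psi), length.out = grid_size)
  feats <- rownames(agg$A)
  preds <- matrix(NA_real_, length(feats), grid_size,
                  dimnames = list(feats, NULL))
  cls <- rep("static", length(feats))
  argmax <- rep(NA_integer_, length(feats))
  fallback <- logical(length(feats))
  off <- log(agg$size)
  s_grid <- stats::approx(agg$psi, agg$S, xout = grid, rule = 2,
                          ties = mean)$y
  newdat <- data.frame(psi = grid, S = s_grid, offset_log = 0)
  for (i in seq_along(feats)) {
    fit <- fit_nb_spline(agg$A[i, ], agg$psi, agg$S, off, spline_df)
    fallback[i] <- isTRUE(attr(fit, "nb_fallback"))
    preds[i, ] <- predict(fit, newdata = newdat, type = "response")
    am <- which.max(preds[i, ])
    argmax[i] <- am
    if (feats[i] %in% da_peaks) {
      cls[i] <- if (am <= grid_size * 0.2) "closing"
      else if (am > grid_size * 0.8) "opening"
      else "dynamic"
    }
  }
  out <- data.frame(peak = feats, class = cls, argmax_bin = argmax,
                    nb_fallback = fallback, stringsAsFactors = FALSE)
  attr(out, "predictions") <- preds
  attr(out, "grid") <- grid
  out
}

#' FRIP-by-dose interaction test along a trajectory
#'
#' Full model: Gaussian regression of per-cell FRIP on a natural-spline
#' basis of binned pseudodose (df = 3) plus its interaction with dose;
#' reduced model: the spline alone. The likelihood-ratio statistic
#' `2 (ll_full - ll_reduced)` is referred to a chi-squared distribution
#' with df equal to the number of interaction terms. The spline main
#' effects appear in both models so they are properly nested.
#'
#' @param frip per-cell FRIP values.
#' @param psi_bin per-cell binned pseudodose.
#' @param d per-cell dose covariate (must vary).
#' @return list with `lrt`, `df`, `p`, `ll_full`, `ll_reduced` and both
#'   fits.
#' @export
fit_frip_interaction <- function(frip, psi_bin, d) {
  if (length(unique(d)) < 2)
    stop("dose is constant over cells: interaction inestimable")
  sp <- splines::ns(psi_bin, df = 3)
  full <- lm(frip ~ sp + sp:d)
  red <- lm(frip ~ sp)
  ll_f <- as.numeric(logLik(full))
  ll_r <- as.numeric(logLik(red))
  df <- length(coef(full)) - length(coef(red))
  lrt <- 2 * (ll_f - ll_r)
  list(lrt = lrt, df = df, p = pchisq(lrt, df = df, lower.tail = FALSE),
       ll_full = ll_f, ll_reduced = ll_r, full = full, reduced = red)
}

#' @importFrom stats poisson glm.control
NULL
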