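test_that("principal graph is a path on 1-D data and matches a brute MST", {
  set.seed(15)
  emb <- cbind(sort(runif(200, 0, 10)), 0)
  rownames(emb) <- sprintf("c%03d", 1:200)
  pg <- learn_principal_graph(emb, n_centroids = 8, seed = 2)
  deg <- igraph::degree(pg$graph)
  expect_equal(sort(unname(deg)), c(1, 1, rep(2, 6)))   # a path
  ref <- oracle_mst_edges(as.matrix(dist(pg$nodes)))
  got <- pg$edges[order(pmin(pg$edges$from, pg$edges$to),
                        pmax(pg$edges$from, pg$edges$to)), ]
  expect_equal(unname(cbind(pmin(got$from, got$to),
                            pmax(got$from, got$to))),
               unname(ref[, 1:2]))
  expect_equal(sum(got$length), sum(ref[, 3]), tolerance = 1e-10)

  # two well-separated clusters with 2 centroids: one linking edge
  emb2 <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
                matrix(rnorm(100, 10, 0.1), 50, 2))
  rownames(emb2) <- sprintf("c%03d", 1:100)
  pg2 <- learn_principal_graph(emb2, n_centroids = 2, seed = 1)
  expect_equal(nrow(pg2$edges), 1)
  expect_equal(pg2$edges$length, sqrt(2) * 10, tolerance = 0.5)

  pg2b <- learn_principal_graph(emb2, n_centroids = 2, seed = 1)
  expect_identical(pg2$assignment, pg2b$assignment)
  expect_error(learn_principal_graph(matrix(1, 10, 2), 2), "degenerate")
  expect_error(learn_principal_graph(emb2, 1), "n_centroids")
})

test_that("pseudodose is the geodesic distance to vehicle roots", {
  # path A-B-C with edge lengths 1 and 2; cells at each node
  assignment <- setNames(c(1, 1, 2, 3), c("v1", "v2", "m1", "m2"))
  pg <- path_graph(c(0, 1, 3), assignment)
  vehicle <- c(v1 = TRUE, v2 = TRUE, m1 = FALSE, m2 = FALSE)
  pd <- compute_pseudodose(pg, vehicle, k = 2)
  expect_equal(pd$psi[pd$cell == "m2"], 3)      # 1 + 2 along the path
  expect_equal(pd$psi[pd$cell == "v1"], 0)      # root cells at zero
  expect_error(compute_pseudodose(pg, !vehicle & FALSE, k = 2),
               "vehicle majority")
})

test_that("1-D k-means bins assign exact cluster means", {
  assignment <- setNames(rep(c(1, 2), each = 3), sprintf("c%d", 1:6))
  pg <- path_graph(c(0, 5), assignment)
  vehicle <- setNames(rep(c(TRUE, FALSE), each = 3), names(assignment))
  pd <- compute_pseudodose(pg, vehicle, k = 2)
  expect_setequal(unique(pd$psi_bin), c(0, 5))
  expect_equal(pd$psi_bin, pd$psi)
})

test_that("pseudodose is invariant under rigid rotation of the embedding", {
  set.seed(44)
  emb <- cbind(runif(300, 0, 10), rnorm(300, 0, 0.3))
  rownames(emb) <- sprintf("c%03d", 1:300)
  vehicle <- setNames(emb[, 1] < 2, rownames(emb))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pg1 <- learn_principal_graph(emb, n_centroids = 10, seed = 3)
  pg2 <- learn_principal_graph(emb %*% rot, n_centroids = 10, seed = 3)
  pd1 <- compute_pseudodose(pg1, vehicle)
  pd2 <- compute_pseudodose(pg2, vehicle)
  expect_equal(pd2$psi, pd1$psi, tolerance = 1e-6)
})

test_that("aggregation chunks bins into 50-100 cell groups", {
  set.seed(8)
  n <- 120
  m <- Matrix::Matrix(matrix(rbinom(n * 5, 1, 0.5), n, 5,
                             dimnames = list(sprintf("c%03d", 1:n),
                                             sprintf("f%d", 1:5))),
                      sparse = TRUE)
  pd <- data.frame(cell = rownames(m), node = 1,
                   psi = seq(0, 1, length.out = n),
                   bin = 1L, psi_bin = 0.5)
  agg <- aggregate_groups(m, pd)
  expect_equal(agg$size, c(60L, 60L))          # 120 -> two groups of 60
  expect_true(all(colSums(agg$A) <= agg$size * ncol(m)))
  # a feature accessible in every cell of a group counts the full group
  m2 <- m; m2[, 1] <- 1
  agg2 <- aggregate_groups(m2, pd)
  expect_equal(as.numeric(agg2$A["f1", ]), agg2$size)

  # an undersized bin is merged with its neighbor before chunking
  pd$bin <- rep(c(1L, 2L), c(40, 80))
  agg3 <- aggregate_groups(m, pd)
  expect_true(all(agg3$size >= 50 & agg3$size <= 100))
  expect_error(aggregate_groups(m[1:30, ], pd[1:30, ]), "at least 50")
})

test_that("trend classification follows the 20/80 bin rule", {
  set.seed(19)
  ng <- 24
  psi <- seq(0, 1, length.out = ng)
  size <- rep(80L, ng)
  S <- rep(100, ng) + rnorm(ng)
  mk <- function(p) rbinom(ng, size, p)
  A <- rbind(up = mk(plogis(-2 + 4 * psi)),
             down = mk(plogis(2 - 4 * psi)),
             bump = mk(0.1 + 0.6 * exp(-(psi - 0.5)^2 / 0.02)),
             flat = mk(0.3))
  agg <- structure(list(A = A, psi = psi, S = S, size = size,
                        membership = setNames(rep(1, ng),
                                              sprintf("c%d", 1:ng))),
                   class = "aggregate_accessibility")
  res <- smooth_and_classify(agg, da_peaks = c("up", "down", "bump"))
  expect_equal(res$class[res$peak == "up"], "opening")
  expect_equal(res$class[res$peak == "down"], "closing")
  expect_equal(res$class[res$peak == "bump"], "dynamic")
  expect_equal(res$class[res$peak == "flat"], "static")  # not DA
  preds <- attr(res, "predictions")
  expect_equal(dim(preds), c(4L, 100L))
})

test_that("NB spline fits match the independent reference", {
  set.seed(55)
  suppressMessages(library(splines))
  for (r in 1:20) {
    ng <- 30
    psi <- sort(runif(ng)); S <- 100 + 20 * runif(ng)
    size <- sample(50:100, ng, replace = TRUE)
    y <- rnbinom(ng, mu = size * plogis(-1 + 2 * psi), size = 5)
    if (sum(y > 0) < 8) next
    fit <- atacscreen:::fit_nb_spline(y, psi, S, log(size), spline_df = 3)
    if (isTRUE(attr(fit, "nb_fallback"))) next
    B <- cbind(ns(psi, df = 3), ns(S, df = 3))
    o <- oracle_nb(B, y, offset = log(size))
    expect_equal(unname(coef(fit)), o$coef, tolerance = 1e-6)
  }
})

test_that("FRIP interaction LRT is nested and needs dose variation", {
  set.seed(23)
  n <- 500
  psi <- runif(n)
  d <- sample(c(0, 0.5, 1), n, replace = TRUE)
  frip <- 0.3 + 0.05 * psi * d + rnorm(n, 0, 0.02)
  res <- fit_frip_interaction(frip, psi, d)
  expect_gte(res$ll_full, res$ll_reduced)
  expect_equal(res$df, 3)
  expect_lt(res$p, 0.01)          # planted interaction detected
  expect_error(fit_frip_interaction(frip, psi, rep(0, n)), "constant")
})
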