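test_that("motif trend regression recovers the 2x2 log odds ratio", {
  in_class <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  motif <- matrix(rep(c(1, 0), each = 10), ncol = 1,
                  dimnames = list(NULL, "m1"))
  res <- motif_trend_regression(in_class, motif)
  expect_equal(res$beta, log(16), tolerance = 1e-8)
  expect_error(motif_trend_regression(rep(TRUE, 20), motif),
               "one peak in the class")
  # inestimable motif (present everywhere) is skipped
  m2 <- cbind(motif, m2 = 1)
  res2 <- motif_trend_regression(in_class, m2)
  expect_true(res2$skipped[res2$motif == "m2"])
  expect_false(res2$skipped[res2$motif == "m1"])
})

test_that("motif logistic fits match the independent reference", {
  set.seed(61)
  for (r in 1:20) {
    np <- 120
    m <- matrix(rbinom(np, 1, 0.4), ncol = 1, dimnames = list(NULL, "m"))
    y <- rbinom(np, 1, plogis(-0.5 + 0.8 * m[, 1]))
    if (length(unique(y)) < 2) next
    res <- motif_trend_regression(y, m)
    o <- oracle_logistic(m, y)
    expect_equal(res$beta, o$coef[2], tolerance = 1e-6)
    expect_equal(res$z, o$z[2], tolerance = 1e-10)
  }
})

test_that("null motifs exceed |z| = 1.96 at roughly the nominal rate", {
  set.seed(71)
  hits <- replicate(400, {
    m <- matrix(rbinom(150, 1, 0.4), ncol = 1, dimnames = list(NULL, "m"))
    y <- rbinom(150, 1, 0.3)
    if (length(unique(y)) < 2 || length(unique(m[, 1])) < 2) return(NA)
    abs(motif_trend_regression(y, m)$z) > 1.96
  })
  rate <- mean(hits, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

feature_fixture <- function() {
  peaks <- data.frame(chrom = "chr1",
                      start = c(900, 5000, 8000, 20000),
                      end = c(1401, 5501, 8501, 20501),
                      name = c("prom", "distA", "distB", "far"))
  genes <- data.frame(gene = "g1", chrom = "chr1", tss = 1000)
  motifs <- matrix(c(1, 1, 0, 1,     # m1 in prom, distA, far
                     0, 0, 1, 0),    # m2 in distB only
                   nrow = 4,
                   dimnames = list(peaks$name, c("m1", "m2")))
  list(peaks = peaks, genes = genes, motifs = motifs)
}

test_that("distal feature takes the best motif-bearing connection", {
  fx <- feature_fixture()
  links <- data.frame(peak_a = c("prom", "prom", "prom"),
                      peak_b = c("distA", "distB", "far"),
                      score = c(0.3, 0.5, 0.8))
  ft <- build_gene_features(fx$genes, fx$peaks, fx$motifs, links)
  expect_equal(ft$promoter["g1", "m1"], 1)
  expect_equal(ft$promoter["g1", "m2"], 0)
  # m1 carried by distA (0.3) and far (0.8): best wins
  expect_equal(ft$distal["g1", "m1"], 0.8)
  expect_equal(ft$distal["g1", "m2"], 0.5)

  # below the 0.1 connection threshold the feature is 0
  weak <- data.frame(peak_a = "prom", peak_b = "distB", score = 0.05)
  ft2 <- build_gene_features(fx$genes, fx$peaks, fx$motifs, weak)
  expect_equal(ft2$distal["g1", "m2"], 0)

  # order invariance in the link table (including direction)
  rev_links <- links[c(3, 1, 2), ]
  rev_links[, 1:2] <- rev_links[, 2:1]
  ft3 <- build_gene_features(fx$genes, fx$peaks, fx$motifs, rev_links)
  expect_equal(ft3$distal, ft$distal)
})

test_that("promoter window is 500 bp inclusive around the TSS", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(1501, 1502), end = c(2001, 2002),
                      name = c("at500", "at501"))
  genes <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                      tss = c(1001, 1001))
  motifs <- matrix(1, 2, 1, dimnames = list(peaks$name, "m1"))
  links <- data.frame(peak_a = character(0), peak_b = character(0),
                      score = numeric(0))
  # gA's nearest peak starts exactly 500 bp away -> promoter;
  # gB keeps only the 501-bp-away peak after dropping at500
  ft <- build_gene_features(genes, peaks[1, ], motifs[1, , drop = FALSE],
                            links)
  expect_true("gA" %in% ft$genes$gene)
  ft2 <- build_gene_features(genes[1, ], peaks[2, ],
                             motifs[2, , drop = FALSE], links)
  expect_equal(nrow(ft2$genes), 0)   # 501 bp is outside the window
})

test_that("elastic-net models report R2 ratios and resist leakage", {
  set.seed(81)
  ng <- 100; nm <- 10
  prom <- matrix(rbinom(ng * nm, 1, 0.3), ng, nm,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 sprintf("m%02d", 1:nm)))
  dist0 <- matrix(0, ng, nm, dimnames = dimnames(prom))
  y <- setNames(as.numeric(prom %*% c(1, -1, rep(0, nm - 2))) +
                  rnorm(ng, 0, 0.3), rownames(prom))
  ft <- structure(list(genes = data.frame(gene = rownames(prom)),
                       promoter = prom, distal = dist0,
                       promoter_peaks = list()),
                  class = "gene_feature_table")
  em <- fit_expression_models(ft, y, seed = 2)
  expect_gt(em$r2_promoter, 0.5)
  expect_equal(em$fold_increase, em$r2_full / em$r2_promoter)

  # pure-noise distal features must not inflate cross-validated R2
  ft_noise <- ft
  ft_noise$distal <- matrix(runif(ng * nm), ng, nm,
                            dimnames = dimnames(prom))
  em_n <- fit_expression_models(ft_noise, y, seed = 2)
  expect_lt(em_n$r2_cv_full - em_n$r2_cv_promoter, 0.02)

  expect_error(fit_expression_models(ft, y[1:10]), "at least 20")
  expect_error(fit_expression_models(ft, setNames(rep(1, ng), names(y))),
               "zero variance")
})
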