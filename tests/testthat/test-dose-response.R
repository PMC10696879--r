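make_design <- function(d, drug = "A", f = NULL, t = NULL) {
  n <- length(d)
  data.frame(cell = sprintf("c%04d", seq_len(n)),
             drug = ifelse(d == min(d), "vehicle", drug),
             dose = ifelse(d == min(d), 0, 10^d),
             vehicle = d == min(d), d = d,
             f = if (is.null(f)) rep(log(3000), n) else f,
             t = if (is.null(t)) rep(8, n) else t,
             replicate = 1L, stringsAsFactors = FALSE)
}

test_that("drug subsets contain treated plus vehicle cells only", {
  des <- data.frame(cell = c("a", "b", "c", "d"),
                    drug = c("A", "B", "vehicle", "A"),
                    dose = c(1, 1, 0, 10),
                    vehicle = c(FALSE, FALSE, TRUE, FALSE),
                    d = c(0, 0, -2, 1), f = 8, t = 8, replicate = 1)
  expect_setequal(subset_cells_for_drug(des, "A"), c("a", "d", "c"))
  expect_error(subset_cells_for_drug(des, "C"), "no treated cells")
  veh_only <- des[des$vehicle, ]
  expect_error(subset_cells_for_drug(veh_only, "A"), "no treated cells")
})

test_that("saturated two-dose design recovers the 2x2 log odds ratio", {
  # accessibility 0.2 at d = 0 and 0.8 at d = 1, f and t constant
  n <- 500
  d <- rep(c(0, 1), each = n)
  y <- c(rep(c(1, 0), c(0.2 * n, 0.8 * n)),
         rep(c(1, 0), c(0.8 * n, 0.2 * n)))
  ft <- atacscreen:::wald_logit_fit(y, data.frame(d = d))
  expect_equal(ft$beta, log(16), tolerance = 1e-8)
})

test_that("peak filter, pooling and significance behave as specified", {
  set.seed(21)
  sim <- simulate_dose_response_dataset(
    sim_config(n_cells = 400, n_features = 60, n_genes = 20, seed = 13))
  # a peak accessible in < 1% of cells is excluded
  m <- sim$matrix
  rare <- "peak0060"
  m[, rare] <- 0
  m[1:3, rare] <- 1      # 0.75% < 1%
  res <- run_peak_da(m, sim$design, min_frac = 0.01)
  expect_false(rare %in% res$peak)
  expect_true(all(res$direction[res$beta_d > 0] == "opening"))
  expect_true(all(res$direction[res$beta_d < 0] == "closing"))

  # BH pooling across drugs equals BH on the concatenated p-vector
  des2 <- sim$design
  half <- seq_len(200)
  des2$drug[!des2$vehicle & seq_len(nrow(des2)) %in% half] <- "B"
  res2 <- run_peak_da(sim$matrix, des2, drugs = c("drugA", "B"))
  expect_equal(res2$padj, bh_adjust(res2$p), tolerance = 1e-12)
})

test_that("complete separation is flagged, not thrown", {
  n <- 60
  d <- rep(c(0, 1), each = n / 2)
  y <- as.integer(d > 0)          # perfectly separated
  m <- Matrix::Matrix(matrix(y, ncol = 1,
                             dimnames = list(sprintf("c%04d", 1:n), "pk")),
                      sparse = TRUE)
  des <- make_design(d)
  res <- run_peak_da(m, des, drugs = "A", min_frac = 0.01)
  expect_true(res$flagged)
  expect_false(res$significant)
})

test_that("gene dose model matches the two-group closed form and offsets", {
  n <- 400
  d <- rep(c(0, 1), each = n / 2)
  y <- rep(c(2, 8), each = n / 2)       # exact group means 2 and 8
  des <- make_design(d)
  ym <- matrix(y, ncol = 1, dimnames = list(des$cell, "g"))
  sf <- setNames(rep(1, n), des$cell)
  res <- fit_gene_dose_model(ym, des, "A", sf)
  expect_equal(res$beta_d, log(4), tolerance = 1e-8)
  res2 <- fit_gene_dose_model(ym, des, "A", sf * 2)
  expect_equal(res2$beta_d, res$beta_d, tolerance = 1e-10)

  ym0 <- cbind(ym, gz = 0)
  res3 <- fit_gene_dose_model(ym0, des, "A", sf)
  expect_true(res3$skipped[res3$gene == "gz"])
  expect_error(fit_gene_dose_model(ym, des, "A", sf * 0), "positive")
})

test_that("quasipoisson fits match the independent reference", {
  set.seed(33)
  for (r in 1:20) {
    n <- 150
    d <- runif(n, -2, 2)
    sf <- exp(rnorm(n, 0, 0.3))
    y <- rpois(n, sf * exp(0.5 + 0.4 * d))
    des <- make_design(d)
    ym <- matrix(y, ncol = 1, dimnames = list(des$cell, "g"))
    res <- fit_gene_dose_model(ym, des, "A", setNames(sf, des$cell))
    cells <- subset_cells_for_drug(des, "A")
    i <- match(cells, des$cell)
    o <- oracle_quasipoisson(matrix(d[i], ncol = 1), y[i], log(sf[i]))
    expect_equal(res$beta_d, o$coef[2], tolerance = 1e-6)
    expect_equal(res$t, o$t[2], tolerance = 1e-10)
  }
})

test_that("ATAC/RNA coefficient comparison joins on RNA-significant genes", {
  atac <- data.frame(gene = c("g1", "g2", "g3"), beta_d = c(1, -1, 0.5),
                     skipped = FALSE)
  rna <- data.frame(gene = c("g1", "g2", "g4"), beta_d = c(1, -1, 2),
                    skipped = FALSE, padj = c(0.01, 0.01, 0.2))
  cmp <- compare_atac_rna_coeffs(atac, rna)
  expect_equal(cmp$n, 2)
  expect_equal(cmp$correlation, 1)
  expect_equal(cmp$sign_concordance, 1)
  rna_far <- data.frame(gene = "g9", beta_d = 1, skipped = FALSE,
                        padj = 0.001)
  expect_error(compare_atac_rna_coeffs(atac, rna_far), "no shared genes")
})

test_that("4PL viability fit recovers noiseless parameters and midpoint", {
  doses <- c(0.1, 0.5, 2, 10, 50, 250)
  truth <- list(b = 1, c = 0, d = 100, e = 10)
  counts <- truth$c + (truth$d - truth$c) /
    (1 + exp(truth$b * (log(doses) - log(truth$e))))
  fit <- fit_viability_4pl(counts, doses)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
  expect_equal(fit$c, truth$c, tolerance = 1e-4)
  expect_equal(fit$d, truth$d, tolerance = 1e-6)
  expect_equal(fit$e, truth$e, tolerance = 1e-6)
  # f(e) = (c + d) / 2 by construction
  fe <- fit$c + (fit$d - fit$c) / (1 + exp(fit$b * (log(fit$e) -
                                                      log(fit$e))))
  expect_equal(fe, (fit$c + fit$d) / 2)
  # monotone decreasing data give positive steepness
  expect_gt(fit$b, 0)
  # vehicle (dose 0) rows are excluded rather than breaking the log
  fit2 <- fit_viability_4pl(c(110, counts), c(0, doses))
  expect_equal(fit2$e, truth$e, tolerance = 1e-4)
  expect_error(fit_viability_4pl(c(10, 20, 30), c(1, 2, 4)), "4 distinct")
})
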