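bg_uniform <- function(h) {
  structure(list(proportions = setNames(rep(1 / h, h),
                                        sprintf("hash%02d", seq_len(h))),
                 n_debris = 100L),
            class = "background_profile")
}

test_that("background estimation averages debris counts", {
  m <- matrix(c(1, 1, 3, 1, 10, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2", "cell1"), c("h1", "h2")))
  bg <- estimate_background(m, c("d1", "d2"))
  expect_equal(unname(bg$proportions), c(2 / 3, 1 / 3))
  bg1 <- estimate_background(m, "cell1")   # single barcode [10, 0]
  expect_equal(unname(bg1$proportions), c(1, 0))
  zero <- matrix(0, 2, 2, dimnames = list(c("z1", "z2"), c("h1", "h2")))
  expect_error(estimate_background(zero, c("z1", "z2")), "lower the fragment")
  expect_error(estimate_background(m, character(0)), "no debris")
})

test_that("chi-squared enrichment statistic matches the closed form", {
  bg <- bg_uniform(3)
  res <- chi2_enrichment_test(c(30, 5, 5), bg)
  expect_equal(res$statistic, 31.25)
  expect_equal(res$df, 2L)
  expect_equal(res$p, exp(-31.25 / 2), tolerance = 1e-12)

  # counts exactly proportional to background
  null <- chi2_enrichment_test(c(10, 10, 10), bg)
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)

  expect_error(chi2_enrichment_test(c(0, 0, 0), bg), "zero total")
  degenerate <- structure(list(proportions = c(1, 0), n_debris = 1L),
                          class = "background_profile")
  expect_error(chi2_enrichment_test(c(5, 5), degenerate), "fewer than 2")
})

test_that("chi-squared test agrees with the reference GOF on random vectors", {
  set.seed(31)
  for (r in 1:100) {
    h <- sample(3:10, 1)
    pr <- rgamma(h, 1); pr <- pr / sum(pr)
    bg <- structure(list(proportions = pr, n_debris = 10L),
                    class = "background_profile")
    x <- rmultinom(1, sample(20:200, 1), rgamma(h, 1))[, 1]
    if (sum(x) == 0) next
    res <- chi2_enrichment_test(x, bg)
    ref <- suppressWarnings(stats::chisq.test(x, p = pr))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("counts on zero-background hashes give infinite enrichment", {
  bg <- structure(list(proportions = c(0.5, 0.5, 0), n_debris = 5L),
                  class = "background_profile")
  res <- chi2_enrichment_test(c(3, 3, 10), bg)
  expect_identical(res$statistic, Inf)
  expect_equal(res$p, 0)
})

test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("enrichment score handles ratios, single-hash cells and ties", {
  expect_equal(enrichment_score(c(40, 20, 5)), 2)
  expect_equal(enrichment_score(c(50, 0, 0)), 50)  # single-hash rule
  expect_equal(enrichment_score(c(10, 10)), 1)
  expect_error(enrichment_score(c(0, 0)), "zero total")
})

test_that("sample assignment applies the three labeling criteria", {
  h <- 8
  bg <- bg_uniform(h)
  m <- rbind(
    nine  = c(9, rep(0, h - 1)),              # < 10 UMIs
    clean = c(100, rep(0, h - 1)),            # extreme enrichment
    even  = c(50, 50, rep(0, h - 2)),         # enrichment 1
    weak  = rep(2, h)                         # background-like
  )
  colnames(m) <- names(bg$proportions)
  res <- assign_samples(m, bg)
  expect_equal(res$call[res$cell == "nine"], "unassigned")
  expect_equal(res$call[res$cell == "clean"], "singlet")
  expect_equal(res$top_hash[res$cell == "clean"], "hash01")
  expect_equal(res$call[res$cell == "even"], "multiplet")
  expect_equal(res$call[res$cell == "weak"], "unassigned")
  expect_true(all(res$enrichment[res$total_umis > 0] >= 1, na.rm = TRUE))
  # alpha below the floor of 2 is raised
  res2 <- assign_samples(m, bg, alpha = 1)
  expect_equal(res2$alpha[1], 2)
  expect_equal(res2$call[res2$cell == "even"], "multiplet")
})

test_that("assignment is equivariant under hash permutation", {
  set.seed(77)
  h <- 6
  m <- matrix(rpois(20 * h, 5), 20, h,
              dimnames = list(sprintf("c%02d", 1:20),
                              sprintf("hash%02d", 1:h)))
  m[1:10, 3] <- m[1:10, 3] + 200
  bg <- bg_uniform(h)
  perm <- sample(h)
  bg_p <- structure(list(proportions = bg$proportions[perm],
                         n_debris = bg$n_debris),
                    class = "background_profile")
  r1 <- assign_samples(m, bg)
  r2 <- assign_samples(m[, perm], bg_p)
  expect_equal(r2$call, r1$call)
  expect_equal(r2$top_hash, r1$top_hash)
  expect_equal(r2$padj, r1$padj, tolerance = 1e-12)
})

test_that("species collisions use the strict 90% purity boundary", {
  cells <- data.frame(barcode = c("a", "b", "c"),
                      human_frags = c(95, 60, 90),
                      mouse_frags = c(5, 40, 10))
  asn <- data.frame(cell = c("a", "b", "c"),
                    top_hash = c("hash01", "hash01", "hash01"),
                    call = c("singlet", "multiplet", "singlet"),
                    stringsAsFactors = FALSE)
  res <- evaluate_species_mix(cells, asn,
                              hash_species = c(hash01 = "human"))
  expect_identical(res$cells$collision, c(FALSE, TRUE, FALSE))
  expect_identical(res$cells$species_call, c("human", "mixed", "human"))
  # exactly 90/10 stays a singlet: the inequality is strict
  expect_false(res$cells$collision[res$cells$barcode == "c"])
  expect_equal(res$label_accuracy, 1)
})
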