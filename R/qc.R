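# interval helpers (0-based half-open, non-overlapping sorted features)

# indices of features overlapped by [s, e) among features sorted by start
overlap_feature_range <- function(s, e, fstart, fend) {
  lo <- findInterval(s, fend) + 1L          # first feature with end > s
  hi <- findInterval(e - 1e-9, fstart)      # last feature with start < e
  if (lo > hi) integer(0) else lo:hi
}

#' Per-cell QC metrics from fragments
#'
#' Computes, per cell barcode: total fragments, FRIP (fraction of fragments
#' overlapping called peaks) and a TSS enrichment score defined as the mean
#' per-base insertion coverage in TSS +/- 50 bp divided by the mean per-base
#' insertion coverage in the two 100-bp flanks centered at +/- 1950 bp,
#' aggregated over all TSSs. Insertions are the two fragment end points.
#' This TSS score is a deliberate simplification of the external tooling
#' usually producing it; only its role as a filter covariate matters here.
#'
#' @param frags fragments data.frame ([read_fragments()] format).
#' @param tss BED-style data.frame of TSS positions (`start` is the TSS,
#'   0-based).
#' @param peaks BED-style data.frame of non-overlapping peaks.
#' @return data.frame with barcode, fragments, frip, tss_enrichment. Cells
#'   with zero fragments in peaks regions still appear; FRIP is NA only for
#'   cells absent from the fragments input.
#' @export
compute_cell_qc <- function(frags, tss, peaks) {
  if (nrow(tss) == 0) stop("empty TSS set: TSS enrichment undefined")
  barcodes <- sort(unique(frags$barcode))
  nfr <- tapply(frags$count, frags$barcode, sum)[barcodes]

  in_any <- function(pos_chrom, pos_s, pos_e, bed) {
    hit <- logical(length(pos_s))
    for (ch in unique(bed$chrom)) {
      b <- bed[bed$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      sel <- which(pos_chrom == ch)
      if (!length(sel)) next
      lo <- findInterval(pos_s[sel], b$end) + 1L
      hi <- findInterval(pos_e[sel] - 1e-9, b$start)
      hit[sel] <- lo <= hi
    }
    hit
  }
  inpeak <- in_any(frags$chrom, frags$start, frags$end, peaks)
  frip_n <- tapply(frags$count[inpeak], frags$barcode[inpeak], sum)
  frip <- as.numeric(frip_n[barcodes]) / as.numeric(nfr)
  frip[is.na(frip) & !is.na(nfr)] <- 0

  # insertion positions: fragment start and end - 1
  ins_pos <- c(frags$start, frags$end - 1)
  ins_chrom <- c(frags$chrom, frags$chrom)
  ins_bc <- c(frags$barcode, frags$barcode)
  ins_ct <- c(frags$count, frags$count)
  core <- data.frame(chrom = tss$chrom, start = tss$start - 50,
                     end = tss$start + 51)
  flank <- data.frame(chrom = rep(tss$chrom, 2),
                      start = c(tss$start - 2000, tss$start + 1901),
                      end = c(tss$start - 1900, tss$start + 2001))
  in_core <- in_any(ins_chrom, ins_pos, ins_pos + 1, core)
  in_flank <- in_any(ins_chrom, ins_pos, ins_pos + 1, flank)
  core_n <- tapply(ins_ct[in_core], ins_bc[in_core], sum)[barcodes]
  flank_n <- tapply(ins_ct[in_flank], ins_bc[in_flank], sum)[barcodes]
  core_n[is.na(core_n)] <- 0
  flank_n[is.na(flank_n)] <- 0
  core_w <- 101 * nrow(tss)
  flank_w <- 200 * nrow(tss)
  tss_enr <- (as.numeric(core_n) / core_w) / (as.numeric(flank_n) / flank_w)
  tss_enr[flank_n == 0 & core_n == 0] <- NA_real_

  data.frame(barcode = barcodes, fragments = as.numeric(nfr),
             frip = frip, tss_enrichment = tss_enr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells on fragment and TSS-enrichment thresholds
#'
#' Retains cells with `fragments >= min_frags` and
#' `tss_enrichment >= min_tss` (both thresholds inclusive). Sub-threshold
#' barcodes are returned as the debris set feeding hash background
#' estimation.
#'
#' @param qc data.frame with barcode, fragments, tss_enrichment.
#' @param min_frags minimum fragments per cell (default 500).
#' @param min_tss minimum TSS enrichment (default 3).
#' @return list with `retained` and `debris` barcode vectors.
#' @export
filter_cells <- function(qc, min_frags = 500, min_tss = 3) {
  keep <- qc$fragments >= min_frags & qc$tss_enrichment >= min_tss
  keep[is.na(keep)] <- FALSE
  log_stage("filter_cells",
            sprintf("%d/%d cells retained (frags >= %g, TSS >= %g)",
                    sum(keep), nrow(qc), min_frags, min_tss))
  list(retained = qc$barcode[keep], debris = qc$barcode[!keep])
}

#' Build a binarized cell-by-feature matrix from fragments
#'
#' Entry 1 iff at least one fragment of the cell overlaps the feature.
#' Features accessible in fewer than `min_cell_frac` of cells are removed.
#'
#' @param frags fragments data.frame.
#' @param features BED-style data.frame of non-overlapping features (500-bp
#'   tiles or fixed-width peaks).
#' @param min_cell_frac minimum fraction of cells a feature must be
#'   accessible in (default 0.005).
#' @return list with `matrix` (cell x feature binary dgCMatrix) and the
#'   retained `features`.
#' @export
build_binary_matrix <- function(frags, features, min_cell_frac = 0.005) {
  barcodes <- sort(unique(frags$barcode))
  bi <- match(frags$barcode, barcodes)
  ii <- integer(0); jj <- integer(0)
  feat_index <- seq_len(nrow(features))
  for (ch in unique(features$chrom)) {
    fsel <- which(features$chrom == ch)
    fo <- fsel[order(features$start[fsel])]
    fs <- features$start[fo]; fe <- features$end[fo]
    rsel <- which(frags$chrom == ch)
    for (r in rsel) {
      hits <- overlap_feature_range(frags$start[r], frags$end[r], fs, fe)
      if (length(hits)) {
        ii <- c(ii, rep(bi[r], length(hits)))
        jj <- c(jj, fo[hits])
      }
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(barcodes), nrow(features)),
                            dimnames = list(barcodes, features$name))
  m@x[] <- 1  # binarize duplicates
  m <- as_dgc(m)
  frac <- Matrix::colSums(m > 0) / nrow(m)
  keep <- frac >= min_cell_frac
  if (!any(keep)) stop("no features pass the accessibility fraction filter")
  log_stage("build_binary_matrix",
            sprintf("%d/%d features kept (>= %.3f%% of %d cells)",
                    sum(keep), nrow(features), 100 * min_cell_frac,
                    length(barcodes)))
  list(matrix = m[, keep, drop = FALSE],
       features = features[keep, , drop = FALSE])
}

#' TF-IDF transform and LSI embedding
#'
#' Computes `TF_ij = x_ij / rowsum_i`, `IDF_j = N / colsum_j`, transformed
#' value `log1p(1e4 * TF_ij) * log(IDF_j)` and a truncated SVD. A feature
#' present in every cell has `log(IDF) = 0` and vanishes. The sign of each
#' component is fixed by forcing its largest-magnitude feature loading
#' positive, making embeddings reproducible. An externally supplied IDF
#' vector is used verbatim (e.g. an IDF derived before doublet simulation).
#'
#' @param x cell x feature binary matrix (no all-zero rows).
#' @param dims number of singular components (default 50, capped at
#'   `min(dim(x))`).
#' @param drop_first drop the first component (depth-correlated)?
#' @param idf optional precomputed IDF vector (length `ncol(x)`).
#' @return object of class `lsi_embedding`: list with `scores`
#'   (cells x components), `d` (singular values, non-increasing), `v`
#'   (feature loadings), `idf`, `dropped_first`.
#' @export
tfidf_lsi <- function(x, dims = 50, drop_first = FALSE, idf = NULL) {
  rs <- Matrix::rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[which(rs == 0)[1]]
    stop(sprintf("cell '%s' has no accessible features", bad))
  }
  n <- nrow(x)
  if (is.null(idf)) {
    cs <- Matrix::colSums(x)
    idf <- ifelse(cs > 0, n / cs, 0)
  }
  if (length(idf) != ncol(x)) stop("idf length does not match feature count")
  tx <- tfidf_transform(x, idf)
  dims <- min(dims, nrow(tx), ncol(tx))
  sv <- svd(as.matrix(tx), nu = dims, nv = dims)
  d <- sv$d[seq_len(dims)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(dims)) {         # deterministic sign convention
    jmax <- which.max(abs(v[, k]))
    if (v[jmax, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  scores <- u %*% diag(d, dims)
  rownames(scores) <- rownames(x)
  rownames(v) <- colnames(x)
  keep <- if (drop_first) seq_len(dims)[-1] else seq_len(dims)
  structure(list(scores = scores[, keep, drop = FALSE],
                 d = d, v = v, idf = idf, dims = dims,
                 dropped_first = drop_first),
            class = "lsi_embedding")
}

# shared TF-IDF transform: log1p(1e4 * TF) * log(IDF)
tfidf_transform <- function(x, idf) {
  tf <- Matrix::Diagonal(x = 1 / Matrix::rowSums(x)) %*% x
  tx <- log1p(1e4 * tf)
  tx %*% Matrix::Diagonal(x = log(idf))
}

#' Project new profiles into an existing LSI basis
#'
#' Applies the embedding's stored IDF and TF-IDF transform to new rows and
#' projects them onto the feature loadings of the fitted SVD.
#'
#' @param lsi an `lsi_embedding`.
#' @param x new cell x feature matrix over the same features.
#' @return matrix of component scores matching `lsi$scores` columns.
#' @export
project_lsi <- function(lsi, x) {
  stopifnot(inherits(lsi, "lsi_embedding"))
  if (ncol(x) != nrow(lsi$v)) stop("feature spaces differ")
  tx <- tfidf_transform(x, lsi$idf)
  sc <- as.matrix(tx %*% lsi$v)
  keep <- if (lsi$dropped_first) seq_len(lsi$dims)[-1] else seq_len(lsi$dims)
  sc <- sc[, keep, drop = FALSE]
  rownames(sc) <- rownames(x)
  sc
}
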