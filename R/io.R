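#' Read a fragments file
#'
#' Reads a BED-like tab-separated fragments file with columns chrom, start,
#' end, barcode, count. Coordinates are 0-based half-open (BED convention).
#' Malformed lines and inverted coordinates are rejected with the offending
#' line number; barcodes outside an optional whitelist are dropped with a
#' logged count.
#'
#' @param path path to a (optionally gzip-compressed) fragments TSV.
#' @param whitelist optional character vector of barcodes to keep.
#' @return data.frame with columns chrom, start, end, barcode, count.
#' @export
read_fragments <- function(path, whitelist = NULL) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "numeric"),
                    col.names = c("chrom", "start", "end", "barcode", "count"),
                    quote = "", comment.char = "")
  bad <- which(!is.finite(raw$start) | !is.finite(raw$end) |
                 raw$start != floor(raw$start) | raw$end != floor(raw$end))
  if (length(bad))
    stop(sprintf("malformed fragment record at line %d", bad[1]))
  inv <- which(raw$start >= raw$end)
  if (length(inv))
    stop(sprintf("fragment with start >= end at line %d", inv[1]))
  badc <- which(raw$count < 1 | raw$count != floor(raw$count))
  if (length(badc))
    stop(sprintf("non-positive fragment count at line %d", badc[1]))
  if (!is.null(whitelist)) {
    keep <- raw$barcode %in% whitelist
    log_stage("read_fragments",
              sprintf("dropped %d/%d records outside whitelist",
                      sum(!keep), nrow(raw)))
    raw <- raw[keep, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write a fragments file
#'
#' @param frags data.frame as returned by [read_fragments()].
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode", "count") %in%
                  names(frags)))
  write.table(frags[, c("chrom", "start", "end", "barcode", "count")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a labeled sparse matrix as MatrixMarket plus sidecars
#'
#' Writes `<path>` in MatrixMarket coordinate format together with
#' `<path>.rownames` and `<path>.colnames` text sidecars holding the dimension
#' labels, one per line.
#'
#' @param m a matrix or Matrix with complete dimnames.
#' @param path output path for the MTX file.
#' @export
write_matrix_mtx <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column names")
  Matrix::writeMM(as_dgc(m), path)
  writeLines(rownames(m), paste0(path, ".rownames"))
  writeLines(colnames(m), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a labeled sparse matrix written by [write_matrix_mtx()]
#'
#' @param path path to the MTX file; sidecars `<path>.rownames` and
#'   `<path>.colnames` must exist.
#' @return a dgCMatrix with dimnames.
#' @export
read_matrix_mtx <- function(path) {
  m <- as_dgc(Matrix::readMM(path))
  rn <- readLines(paste0(path, ".rownames"))
  cn <- readLines(paste0(path, ".colnames"))
  if (length(rn) != nrow(m))
    stop(sprintf("row sidecar has %d names but matrix has %d rows",
                 length(rn), nrow(m)))
  if (length(cn) != ncol(m))
    stop(sprintf("column sidecar has %d names but matrix has %d columns",
                 length(cn), ncol(m)))
  dimnames(m) <- list(rn, cn)
  m
}

#' Read a sample sheet
#'
#' CSV with columns well, hash_barcode, sample, drug, dose, replicate and
#' optionally stimulation. Hash barcodes must be unique and dose 0 marks the
#' vehicle.
#'
#' @param path CSV path.
#' @return data.frame with a derived logical `vehicle` column.
#' @export
read_sample_sheet <- function(path) {
  ss <- read.table(path, sep = ",", header = TRUE, quote = "\"",
                   stringsAsFactors = FALSE)
  need <- c("well", "hash_barcode", "sample", "drug", "dose", "replicate")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$hash_barcode))
    stop("duplicated hash barcodes in sample sheet")
  if (any(ss$dose < 0)) stop("negative dose in sample sheet")
  ss$vehicle <- ss$dose == 0
  ss
}

#' Read/write BED3 feature files
#'
#' 0-based half-open intervals; the feature name is `chrom:start-end` unless a
#' fourth column is present.
#'
#' @param path BED path.
#' @return data.frame with chrom, start, end, name.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (any(bed$start >= bed$end)) stop("BED interval with start >= end")
  bed$name <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
  bed[, c("chrom", "start", "end", "name")]
}

#' @rdname read_bed
#' @param bed data.frame with chrom, start, end and optionally name.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  write.table(bed[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
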