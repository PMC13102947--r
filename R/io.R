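# locate triplet member, preferring the uncompressed file
.find_10x_file <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  .stopf("missing %s(.gz) in %s", base, dir)
}

.read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style Matrix Market triplet
#'
#' Loads `matrix.mtx(.gz)`, `features.tsv(.gz)` and `barcodes.tsv(.gz)` from
#' a directory. Orientation (genes x cells vs cells x genes) is
#' auto-detected from the header dimensions against the feature/barcode file
#' lengths; the returned matrix is always cells x genes. Duplicate gene
#' symbols are disambiguated deterministically in file order with `.1`, `.2`
#' suffixes (a warning is raised).
#'
#' @param dir Directory holding the triplet.
#' @return Sparse cells x genes integer count matrix with barcodes as
#'   rownames and gene symbols as colnames.
#' @export
read_10x <- function(dir) {
  mtx_path <- .find_10x_file(dir, "matrix.mtx")
  feat_path <- .find_10x_file(dir, "features.tsv")
  bc_path <- .find_10x_file(dir, "barcodes.tsv")

  if (grepl("\\.gz$", mtx_path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(.read_lines_maybe_gz(mtx_path), tmp)
    mtx_path <- tmp
  }
  m <- Matrix::readMM(mtx_path)
  if (any(m@x != round(m@x))) .stopf("matrix contains non-integer values")

  feat_lines <- .read_lines_maybe_gz(feat_path)
  feats <- do.call(rbind, strsplit(feat_lines, "\t", fixed = TRUE))
  symbols <- if (ncol(feats) >= 2) feats[, 2] else feats[, 1]
  barcodes <- .read_lines_maybe_gz(bc_path)

  if (nrow(m) == length(symbols) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # genes x cells dialect
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(symbols))) {
    .stopf("matrix dimensions %dx%d match neither %d features x %d barcodes nor its transpose",
           nrow(m), ncol(m), length(symbols), length(barcodes))
  }
  if (anyDuplicated(symbols)) {
    .warnf("%d duplicated gene symbol(s) suffixed .1, .2, ... in file order",
           sum(duplicated(symbols)))
    symbols <- make.unique(symbols, sep = ".")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(barcodes, symbols)
  m
}

#' Write a count matrix as a 10x-style triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (gene id and symbol columns) and
#' `barcodes.tsv` under `dir`, in the conventional genes x cells
#' orientation, optionally gzipped.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the triplet members.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir, gzip = FALSE) {
  if (is.null(dimnames(counts)) || is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must carry barcodes and gene symbols as dimnames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"))
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)

  write_member <- function(lines, base) {
    path <- file.path(dir, base)
    if (gzip) {
      con <- gzfile(paste0(path, ".gz"), "wt")
      writeLines(lines, con)
      close(con)
    } else {
      writeLines(lines, path)
    }
  }
  genes <- colnames(counts)
  write_member(paste(genes, genes, "Gene Expression", sep = "\t"), "features.tsv")
  write_member(rownames(counts), "barcodes.tsv")
  if (gzip) {
    write_member(readLines(mtx), "matrix.mtx")   # re-emit compressed
    file.remove(mtx)
    # writeLines above wrote matrix.mtx.gz; nothing else to do
  }
  invisible(dir)
}
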