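# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# allocate integer counts summing to n with proportions p (largest remainder)
.apportion <- function(p, n) {
  stopifnot(all(p >= 0), n >= 0)
  p <- p / sum(p)
  raw <- p * n
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

# cells x genes sparse matrix with dimnames, from a dense integer matrix
.as_count_matrix <- function(m, barcodes, genes) {
  dimnames(m) <- list(barcodes, genes)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

.is_count_matrix <- function(x) {
  methods::is(x, "Matrix") || is.matrix(x)
}

# deterministic write of a data.frame as TSV (UTF-8, header, no row names)
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}
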