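#' Read and write count matrices
#'
#' `readCounts` loads a count matrix from TSV/CSV (header row of gene ids,
#' first column of cell ids) or MatrixMarket coordinate format (`.mtx` plus
#' one id per line in the row- and column-name files). The returned matrix
#' always has cells in rows and genes in columns; set `genesAsRows = TRUE`
#' when the file stores genes in rows. Entries are validated to be
#' non-negative integers and ids to be unique. `writeCounts` is the inverse.
#'
#' @param path file to read or write.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`.
#' @param genesAsRows whether rows of the file are genes.
#' @param rowNamesFile,colNamesFile companion id files for `"mtx"`; default
#'   `<path>.rownames` / `<path>.colnames`.
#' @return `readCounts`: an integer matrix, cells x genes, with dimnames.
#' @export
readCounts <- function(path, format = c("tsv", "csv", "mtx"),
                       genesAsRows = FALSE,
                       rowNamesFile = paste0(path, ".rownames"),
                       colNamesFile = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    Y <- as.matrix(df)
  } else {
    Y <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rowNamesFile)
    cn <- readLines(colNamesFile)
    if (length(rn) != nrow(Y) || length(cn) != ncol(Y))
      stop("id files do not match the matrix dimensions")
    dimnames(Y) <- list(rn, cn)
  }
  if (genesAsRows) Y <- t(Y)
  bad <- which(Y < 0 | Y != floor(Y) | !is.finite(Y), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid (negative or non-integer) entries at: ",
         paste(sprintf("[%s, %s]", rownames(Y)[bad[, 1]],
                       colnames(Y)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  }
  if (anyDuplicated(rownames(Y))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(Y))) stop("duplicate gene ids")
  storage.mode(Y) <- "integer"
  Y
}

#' @rdname readCounts
#' @param Y count matrix, cells in rows, genes in columns, with dimnames.
#' @export
writeCounts <- function(Y, path, format = c("tsv", "csv", "mtx"),
                        genesAsRows = FALSE,
                        rowNamesFile = paste0(path, ".rownames"),
                        colNamesFile = paste0(path, ".colnames")) {
  format <- match.arg(format)
  out <- if (genesAsRows) t(Y) else Y
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(out, sparse = TRUE), path)
    writeLines(rownames(out), rowNamesFile)
    writeLines(colnames(out), colNamesFile)
  }
  invisible(path)
}

#' Filter lowly expressed genes
#'
#' Keeps genes having at least `minReads` reads in at least `minCells`
#' cells; the defaults implement the common "at least five reads in at
#' least five cells" rule.
#'
#' @param Y count matrix, cells x genes.
#' @param minReads,minCells filtering thresholds.
#' @return the filtered matrix.
#' @export
filterGenes <- function(Y, minReads = 5, minCells = 5) {
  if (minReads < 0 || minCells < 0) stop("thresholds must be non-negative")
  keep <- colSums(Y >= minReads) >= minCells
  if (!any(keep)) stop("all genes were filtered out")
  Y[, keep, drop = FALSE]
}

#' Select the most variable genes
#'
#' Ranks genes by the variance of `log(1 + count)` across cells and keeps
#' the top `nGenes`; ties are broken by column order.
#'
#' @param Y count matrix, cells x genes.
#' @param nGenes number of genes to keep (at most `ncol(Y)`).
#' @return the reduced matrix, original column order preserved.
#' @export
topVariableGenes <- function(Y, nGenes = 1000) {
  if (nGenes > ncol(Y)) stop("nGenes exceeds the number of genes")
  v <- apply(log1p(Y), 2, stats::var)
  keep <- sort(order(-v)[seq_len(nGenes)])
  Y[, keep, drop = FALSE]
}

#' Between-sample normalization baselines
#'
#' Normalizations used by the log-count PCA baseline (the ZINB factor model
#' itself is applied to raw counts; its cell intercept plays the role of a
#' scaling factor): `"TC"` divides each cell by its total count and rescales
#' by the mean total; `"FQ"` matches every cell's count distribution to the
#' mean quantile profile; `"TMM"` scales each cell by a weighted trimmed
#' mean of log-ratios against a reference cell (computed with
#' [edgeR::calcNormFactors()], factors normalized to geometric mean one).
#'
#' @param Y count matrix, cells x genes; no all-zero cell allowed.
#' @param method `"TC"`, `"FQ"`, or `"TMM"`.
#' @return real-valued matrix of normalized expression measures.
#' @export
normalizeCounts <- function(Y, method = c("TC", "FQ", "TMM")) {
  method <- match.arg(method)
  tot <- rowSums(Y)
  if (any(tot == 0)) stop("all-zero cells cannot be normalized")
  switch(method,
    TC = Y / tot * mean(tot),
    FQ = .fullQuantile(Y),
    TMM = {
      f <- edgeR::calcNormFactors(t(Y), method = "TMM")
      eff <- tot * f
      Y / eff * mean(eff)
    })
}

.fullQuantile <- function(Y) {
  n <- nrow(Y); J <- ncol(Y)
  sorted <- apply(Y, 1, sort)            # J x n, each column a sorted cell
  ref <- rowMeans(sorted)                # mean quantile profile
  out <- Y
  storage.mode(out) <- "double"
  for (i in seq_len(n)) {
    # each cell's sorted vector becomes the mean quantile profile exactly;
    # ties are broken by column order, as in standard full-quantile practice
    out[i, order(Y[i, ])] <- ref
  }
  out
}
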