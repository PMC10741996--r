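#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream stage assumes: unique, non-empty
#' gene and sample identifiers; all values finite; at least 3 genes and 3
#' samples (a forest with fewer than 2 predictors, or an enrichment walk
#' over fewer than 2 ranked genes, is meaningless).  Genes with zero
#' variance across samples are flagged in the `"zero_variance"` attribute:
#' they cannot serve as regression targets but are retained as predictors so
#' the gene universe stays stable.
#'
#' @param mat numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @return the matrix, invisibly, with a `"zero_variance"` attribute naming
#'   flagged genes.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression data must be a numeric matrix")
  }
  gid <- rownames(mat)
  sid <- colnames(mat)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix needs rownames (genes) and colnames (samples)")
  }
  if (any(!nzchar(gid))) stop("empty gene identifier at row ", which(!nzchar(gid))[1])
  if (any(!nzchar(sid))) stop("empty sample identifier at column ", which(!nzchar(sid))[1])
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifier: '", gid[duplicated(gid)][1], "'")
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifier: '", sid[duplicated(sid)][1], "'")
  }
  if (nrow(mat) < 3L) stop("need at least 3 genes, got ", nrow(mat))
  if (ncol(mat) < 3L) stop("need at least 3 samples, got ", ncol(mat))
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop("non-finite value at gene '", gid[bad[1]], "', sample '",
         sid[bad[2]], "'")
  }
  zv <- gid[apply(mat, 1L, function(x) max(x) - min(x)) == 0]
  if (length(zv)) {
    message(length(zv), " zero-variance gene(s) flagged (excluded as targets): ",
            paste(zv, collapse = ", "))
  }
  attr(mat, "zero_variance") <- zv
  invisible(mat)
}

#' Read a gene-by-sample expression matrix from a delimited text file
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column.  Lines starting with `#` are ignored, so tables written by
#' [write_expression()] round-trip.  Gzip-compressed files are decompressed
#' transparently.  Any missing or non-numeric cell is a hard error naming
#' its coordinates; values are never imputed, because variable importance
#' over silently imputed predictors would bias the rankings.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param transpose set `TRUE` for sample-major files (samples in rows);
#'   the returned matrix is always genes-by-samples.
#' @return a validated numeric matrix (see [validate_expression_matrix()]).
#' @export
read_expression <- function(path, delimiter = "\t", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                   comment.char = "#", quote = "", colClasses = "character",
                   na.strings = character(0), stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected gene ids in column 1 and >=1 sample column")
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", raw[bad[1], bad[2]], "' at gene '",
         ids[bad[1]], "' (row ", bad[1], "), sample '",
         colnames(raw)[bad[2]], "' (column ", bad[2] + 1L, ")")
  }
  dimnames(vals) <- list(ids, colnames(raw))
  if (transpose) vals <- t(vals)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV with a provenance header
#'
#' @param mat validated expression matrix.
#' @param path output path.
#' @param config_hash configuration fingerprint recorded in the header.
#' @return the path, invisibly.
#' @export
write_expression <- function(mat, path, config_hash = "none") {
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write_tsv_with_header(df, path, config_hash)
}

#' log2(TPM + 1) normalization
#'
#' Applies the standard log2(x + 1) transform to a non-negative TPM matrix.
#' Negative input is a hard error: already-logged data must not be
#' double-transformed silently.
#'
#' @param raw matrix of non-negative TPM values.
#' @return matrix of the same shape and dimnames with values `log2(x + 1)`.
#' @export
log2_tpm_transform <- function(raw) {
  if (!is.numeric(raw)) stop("expected a numeric matrix of TPM values")
  if (any(raw < 0, na.rm = TRUE)) {
    bad <- which(raw < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at [", bad[1], ",", bad[2],
         "]: input must be non-negative TPM, not already-logged data")
  }
  out <- log2(raw + 1)
  dimnames(out) <- dimnames(raw)
  out
}
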