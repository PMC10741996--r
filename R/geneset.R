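#' Construct a prior gene set
#'
#' @param name set name.
#' @param genes character vector of unique, non-empty gene identifiers.
#' @param tiers optional named character vector mapping a subset of `genes`
#'   to a confidence tier (`validated`, `screened` or `deduced`), mirroring
#'   the mixed-confidence structure of curated process-gene databases.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, tiers = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(genes) || length(genes) == 0L) {
    stop("a gene set needs at least one gene")
  }
  if (any(!nzchar(genes))) stop("empty gene identifier in set '", name, "'")
  if (anyDuplicated(genes)) {
    stop("duplicate gene '", genes[duplicated(genes)][1], "' in set '", name, "'")
  }
  if (!is.null(tiers)) {
    if (is.null(names(tiers)) || any(!names(tiers) %in% genes)) {
      stop("every tier key must be a member of the gene set")
    }
    ok <- tiers %in% c("validated", "screened", "deduced")
    if (!all(ok)) stop("unknown tier '", tiers[!ok][1],
                       "' (expected validated/screened/deduced)")
  }
  structure(list(name = name, genes = genes, tiers = tiers),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$genes), "genes\n")
  if (!is.null(x$tiers)) {
    print(table(factor(x$tiers, c("validated", "screened", "deduced"))))
  }
  invisible(x)
}

#' Read a gene set from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name`, `description`, then gene symbols.  Duplicate genes within a line
#' are collapsed with a warning; a line with no genes is an error.
#'
#' @param path GMT file path.
#' @param set_name which set to return.  May be omitted when the file holds
#'   a single set; with several sets it is required.
#' @param tiers_path optional 2-column TSV (gene, tier) assigning confidence
#'   tiers to members of the returned set.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, set_name = NULL, tiers_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names(fields) <- vapply(fields, `[[`, "", 1L)
  if (is.null(set_name)) {
    if (length(fields) > 1L) {
      stop("file holds ", length(fields), " sets (",
           paste(names(fields), collapse = ", "), "); give set_name")
    }
    set_name <- names(fields)[1L]
  }
  if (!set_name %in% names(fields)) {
    stop("set '", set_name, "' not found in ", path)
  }
  f <- fields[[set_name]]
  if (length(f) < 3L) stop("set '", set_name, "' has no genes")
  genes <- f[-(1:2)]
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("set '", set_name, "' has no genes")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("set '", set_name, "': collapsed duplicate gene(s): ",
            paste(dup, collapse = ", "))
    genes <- genes[!duplicated(genes)]
  }
  tiers <- NULL
  if (!is.null(tiers_path)) {
    tdf <- read.table(tiers_path, sep = "\t", header = FALSE,
                      col.names = c("gene", "tier"), comment.char = "#",
                      stringsAsFactors = FALSE)
    tdf <- tdf[tdf$gene %in% genes, , drop = FALSE]
    tiers <- stats::setNames(tdf$tier, tdf$gene)
  }
  gene_set(set_name, genes, tiers)
}

#' Restrict a gene set to the genes present in an expression matrix
#'
#' Enrichment is defined only over genes present in the ranking, so the
#' prior set must be intersected with the matrix universe before testing.
#' Dropped genes are reported; an intersection below `min_size` is an error
#' because enrichment over a near-empty set is undefined.
#'
#' @param set a [gene_set()].
#' @param mat expression matrix (or a character vector universe).
#' @param min_size minimum allowed intersection (default 5).
#' @return the restricted [gene_set()], original order preserved.
#' @export
restrict_to_universe <- function(set, mat, min_size = 5L) {
  universe <- if (is.character(mat)) mat else rownames(mat)
  keep <- set$genes %in% universe
  dropped <- set$genes[!keep]
  if (length(dropped)) {
    message("restrict_to_universe: dropped ", length(dropped),
            " gene(s) absent from the matrix: ",
            paste(dropped, collapse = ", "))
  }
  genes <- set$genes[keep]
  if (length(genes) < min_size) {
    stop("only ", length(genes), " prior gene(s) present in the matrix (minimum ",
         min_size, "): enrichment would be undefined")
  }
  tiers <- set$tiers
  if (!is.null(tiers)) tiers <- tiers[names(tiers) %in% genes]
  gene_set(set$name, genes, tiers)
}
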