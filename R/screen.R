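#' Configuration for the genome-wide screen
#'
#' @param alpha per-gene enrichment significance threshold (default 0.05,
#'   applied to the raw permutation p-value; BH-adjusted p-values are also
#'   emitted in the output table for reference but are not acted on).
#' @param rf an [rf_config()]; its `seed` field is ignored — per-target
#'   seeds are derived from `root_seed` and the gene identifier.
#' @param n_perm permutations per enrichment test (default 1000).
#' @param root_seed run-level seed.
#' @param target_genes optional subset of genes to screen (default: every
#'   gene in the matrix).
#' @param min_set_size minimum prior-set overlap with the matrix universe.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, rf = rf_config(), n_perm = 1000L,
                          root_seed = 1L, target_genes = NULL,
                          min_set_size = 5L) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1,
            inherits(rf, "rf_config"))
  structure(list(alpha = alpha, rf = rf, n_perm = as.integer(n_perm),
                 root_seed = as.integer(root_seed),
                 target_genes = target_genes,
                 min_set_size = as.integer(min_set_size)),
            class = "screen_config")
}

# fingerprint of everything that determines a per-gene record (the target
# subset does not belong here: subsetting must not invalidate a checkpoint)
.screen_hash <- function(config) {
  config_hash(list(alpha = config$alpha, rf = config$rf,
                   n_perm = config$n_perm, root_seed = config$root_seed))
}

.classify_mse <- function(p, es, alpha) {
  if (p < alpha && es > 0) "POSITIVE" else if (p < alpha && es < 0)
    "NEGATIVE" else "NONE"
}

#' Screen one target gene
#'
#' The four-step decision for a single gene: fit the per-target forest,
#' rank the N-1 predictors by each importance score, and test the prior set
#' (restricted to the predictor universe — the target itself is absent from
#' its own ranking) for enrichment in each ranking.  The permutation-score
#' result is classified by enrichment sign: `POSITIVE` (prior genes
#' concentrate among the most important predictors), `NEGATIVE` (they
#' concentrate among the least important — evidence *against* process
#' membership, possible because permutation importance can go negative), or
#' `NONE`.  The impurity-score result is a plain significance flag: the
#' method splits only the permutation-score set by sign.
#'
#' @param mat validated expression matrix.
#' @param gene target gene (nonzero variance).
#' @param prior prior [gene_set()], already restricted to the matrix
#'   universe.
#' @param config a [screen_config()].
#' @return a one-row data.frame: gene, es_mse, p_mse, es_purity, p_purity,
#'   mse_class, purity_hit.
#' @export
screen_gene <- function(mat, gene, prior, config = screen_config()) {
  rf_cfg <- config$rf
  rf_cfg$seed <- gene_seed(config$root_seed, gene, 0L)
  ranking <- fit_target_model(mat, gene, rf_cfg)
  res <- lapply(c(mse = "mse", purity = "purity"), function(sc) {
    ranked <- as_ranked_list(ranking, sc)
    gsea_test(ranked, prior, n_perm = config$n_perm,
              seed = gene_seed(config$root_seed, gene,
                               if (sc == "mse") 1L else 2L))
  })
  data.frame(gene = gene,
             es_mse = res$mse$es, p_mse = res$mse$p_value,
             es_purity = res$purity$es, p_purity = res$purity$p_value,
             mse_class = .classify_mse(res$mse$p_value, res$mse$es,
                                       config$alpha),
             purity_hit = res$purity$p_value < config$alpha,
             stringsAsFactors = FALSE)
}

#' Screen every eligible gene in the matrix
#'
#' Iterates [screen_gene()] over all target genes.  Zero-variance targets
#' are skipped with a message.  Per-gene seeds derive from the root seed and
#' the gene identifier, so results are independent of iteration order and
#' worker count.  When `checkpoint_path` is given, finished records are
#' streamed to disk and an interrupted run resumes without recomputation
#' (the checkpoint is keyed on a configuration fingerprint and discarded if
#' the configuration changed).
#'
#' @param mat validated expression matrix.
#' @param prior prior [gene_set()] (restricted to the universe internally).
#' @param config a [screen_config()].
#' @param checkpoint_path optional TSV path for streaming/resume.
#' @param workers number of parallel workers (forked; results identical to
#'   a serial run).
#' @return a data.frame of per-gene records (class `screen_table`), one row
#'   per eligible target, in matrix gene order, with BH-adjusted p-value
#'   columns `p_mse_adj`, `p_purity_adj` appended for reference.
#' @export
screen_all <- function(mat, prior, config = screen_config(),
                       checkpoint_path = NULL, workers = 1L) {
  validate_expression_matrix(mat)
  prior <- restrict_to_universe(prior, mat, config$min_set_size)
  targets <- config$target_genes %||% rownames(mat)
  stopifnot(all(targets %in% rownames(mat)))
  zv <- rownames(mat)[apply(mat, 1L, function(x) max(x) - min(x)) == 0]
  skip <- targets[targets %in% zv]
  for (g in skip) message("screen_all: skipping zero-variance target '", g, "'")
  targets <- setdiff(targets, skip)

  hash <- .screen_hash(config)
  done <- NULL
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    head1 <- readLines(checkpoint_path, n = 1L)
    if (grepl(paste0("config=", hash), head1, fixed = TRUE)) {
      done <- read.table(checkpoint_path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
      done <- done[done$gene %in% targets, , drop = FALSE]
      if (nrow(done)) {
        message("screen_all: resuming; ", nrow(done),
                " finished target(s) loaded from checkpoint")
      }
    } else {
      message("screen_all: checkpoint configuration differs; starting fresh")
      file.remove(checkpoint_path)
    }
  }
  todo <- setdiff(targets, done$gene)

  if (!is.null(checkpoint_path) && is.null(done)) {
    writeLines(c(tool_header(hash),
                 paste(c("gene", "es_mse", "p_mse", "es_purity", "p_purity",
                         "mse_class", "purity_hit"), collapse = "\t")),
               checkpoint_path)
  }

  run_one <- function(g) screen_gene(mat, g, prior, config)
  if (workers > 1L && length(todo) > 1L) {
    recs <- parallel::mclapply(todo, run_one, mc.cores = workers)
    fail <- vapply(recs, inherits, logical(1), "try-error")
    if (any(fail)) stop("screen failed for gene '", todo[fail][1], "'")
    if (!is.null(checkpoint_path)) {
      for (r in recs) {
        write.table(r, checkpoint_path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE, append = TRUE)
      }
    }
  } else {
    recs <- vector("list", length(todo))
    for (i in seq_along(todo)) {
      recs[[i]] <- run_one(todo[i])
      if (!is.null(checkpoint_path)) {
        write.table(recs[[i]], checkpoint_path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE, append = TRUE)
      }
    }
  }

  out <- rbind(done, do.call(rbind, recs))
  out <- out[match(targets, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out$p_mse_adj <- p.adjust(out$p_mse, method = "BH")
  out$p_purity_adj <- p.adjust(out$p_purity, method = "BH")
  attr(out, "alpha") <- config$alpha
  attr(out, "config_hash") <- hash
  class(out) <- c("screen_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the candidate gene sets and their final intersection
#'
#' Derives the four candidate sets from a screen table — permutation-score
#' positive and negative (mutually exclusive by enrichment sign), impurity
#' significant, and the differentially expressed genes — and intersects
#' them per the method's rule:
#' `final = mse_positive` \eqn{\cap} `purity` \eqn{\cap} `degs`.
#' The sign-negative set is excluded by construction, so
#' `final` \eqn{\cap} `mse_negative` is empty on every run (asserted).
#' A Venn-style count summary is reported.
#'
#' @param records a `screen_table` from [screen_all()].
#' @param degs character vector (or [gene_set()]) of differentially
#'   expressed genes between the consensus clusters.
#' @return an object of class `candidate_sets` with fields `mse_positive`,
#'   `mse_negative`, `purity`, `degs`, `final`.
#' @export
assemble_candidates <- function(records, degs) {
  if (inherits(degs, "gene_set")) degs <- degs$genes
  degs <- unique(as.character(degs))
  mse_positive <- records$gene[records$mse_class == "POSITIVE"]
  mse_negative <- records$gene[records$mse_class == "NEGATIVE"]
  purity <- records$gene[records$purity_hit]
  final <- intersect(intersect(mse_positive, purity), degs)
  stopifnot(length(intersect(mse_positive, mse_negative)) == 0L,
            length(intersect(final, mse_negative)) == 0L)
  out <- structure(list(mse_positive = mse_positive,
                        mse_negative = mse_negative,
                        purity = purity, degs = degs, final = final),
                   class = "candidate_sets")
  message(sprintf(paste0("candidate sets: %%IncMSE-positive %d, ",
                         "%%IncMSE-negative %d, IncNodePurity %d, DEGs %d; ",
                         "final intersection %d"),
                  length(mse_positive), length(mse_negative),
                  length(purity), length(degs), length(final)))
  out
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("<candidate_sets>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write candidate sets to a directory
#'
#' One plain gene list per derived set plus a Venn-style count summary TSV.
#'
#' @param cands a `candidate_sets`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_candidate_sets <- function(cands, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cands)) {
    writeLines(cands[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  counts <- data.frame(set = names(cands),
                       n = vapply(cands, length, integer(1)))
  write_tsv_with_header(counts, file.path(dir, "venn_counts.tsv"))
  invisible(dir)
}
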