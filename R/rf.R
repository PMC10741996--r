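#' Forest configuration for per-target importance models
#'
#' Defaults follow the method's stated settings: 500 unpruned regression
#' trees, every one of the N-1 predictor genes examined at each split
#' (bagged trees rather than random-subspace forests), bootstrap resampling
#' so out-of-bag permutation importance is defined.  `min_samples_leaf`
#' bounds tree growth (no post-pruning is applied, but unbounded depth is
#' still finite); 5 is the regression-tree convention.
#'
#' @param n_trees number of trees (default 500).
#' @param predictors_per_split `"all"` (default) or a positive integer
#'   capped at the number of predictors.  Full-feature bagging is the
#'   method's literal setting; a numeric cap is offered because it is
#'   computationally extreme at genome scale.
#' @param min_samples_leaf minimum in-bag cases per leaf (default 5).
#' @param bootstrap draw a bootstrap sample per tree (default `TRUE`).
#'   Without it there is no out-of-bag data and permutation importance is
#'   unavailable.
#' @param seed integer seed driving all resampling and permutation.
#' @param scale_importance report permutation importance as mean out-of-bag
#'   MSE increase divided by its standard error across trees (the
#'   conventional `%IncMSE`, default); `FALSE` reports the raw mean increase
#'   as a percentage of the unpermuted out-of-bag MSE.
#' @param permutation_repeats permutation passes per tree per predictor
#'   (default 1, the standard estimator).
#' @return an object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, predictors_per_split = "all",
                      min_samples_leaf = 5L, bootstrap = TRUE, seed = 1L,
                      scale_importance = TRUE, permutation_repeats = 1L) {
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L, min_samples_leaf >= 1L, permutation_repeats >= 1L)
  if (!identical(predictors_per_split, "all")) {
    predictors_per_split <- as.integer(predictors_per_split)
    stopifnot(predictors_per_split >= 1L)
  }
  structure(list(n_trees = n_trees,
                 predictors_per_split = predictors_per_split,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed),
                 scale_importance = isTRUE(scale_importance),
                 permutation_repeats = as.integer(permutation_repeats)),
            class = "rf_config")
}

#' Fit the per-target forest and score every predictor gene
#'
#' Regresses `target_gene` on the other N-1 genes with a bagged ensemble of
#' unpruned regression trees and returns both variable-importance vectors:
#'
#' * `pct_inc_mse` — for each tree, each predictor's column is permuted
#'   within that tree's out-of-bag samples and the increase in out-of-bag
#'   MSE recorded; the score is the mean increase across trees divided by
#'   its standard error (the raw mean when the standard error is zero, as
#'   for a predictor never split on, whose score is exactly 0).  Can be
#'   negative.
#' * `inc_node_purity` — the total decrease in node residual sum of squares
#'   over all splits on the predictor, divided by the number of trees;
#'   non-negative by construction.
#'
#' Results are bit-identical for identical `(matrix, target, config$seed)`
#' regardless of platform or worker count.
#'
#' @param mat validated expression matrix (genes x samples).
#' @param target_gene the dependent gene; must be present and have nonzero
#'   variance across samples.
#' @param config an [rf_config()].
#' @return an object of class `importance_ranking` with fields
#'   `target_gene`, `predictor_genes`, `pct_inc_mse`, `inc_node_purity`,
#'   `oob_mse`.
#' @export
fit_target_model <- function(mat, target_gene, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (!target_gene %in% rownames(mat)) {
    stop("target gene '", target_gene, "' not in the matrix")
  }
  # samples are put in canonical (sorted-identifier) order before fitting, so
  # the result depends on which samples are present, never on column order
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  y <- mat[target_gene, ]
  if (max(y) - min(y) == 0) {
    stop("target gene '", target_gene,
         "' has zero variance: its regression model is undefined")
  }
  predictors <- rownames(mat)[rownames(mat) != target_gene]
  X <- t(mat[predictors, , drop = FALSE])
  p <- ncol(X)
  mtry <- if (identical(config$predictors_per_split, "all")) p else
    min(config$predictors_per_split, p)
  core <- .rf_fit_importance(X, as.numeric(y), config$n_trees, mtry,
                             config$min_samples_leaf, config$bootstrap,
                             config$permutation_repeats,
                             as.numeric(config$seed))
  if (config$bootstrap) {
    mu <- core$perm_mean
    se <- core$perm_se
    if (config$scale_importance) {
      pct <- ifelse(se > 0, mu / se, mu)
    } else {
      pct <- if (is.finite(core$oob_mse) && core$oob_mse > 0)
        100 * mu / core$oob_mse else mu
    }
  } else {
    pct <- rep(NA_real_, p)
  }
  structure(list(target_gene = target_gene,
                 predictor_genes = predictors,
                 pct_inc_mse = stats::setNames(pct, predictors),
                 inc_node_purity = stats::setNames(core$inc_node_purity,
                                                   predictors),
                 oob_mse = core$oob_mse,
                 config = config),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking> target:", x$target_gene, "-",
      length(x$predictor_genes), "predictors, oob_mse =",
      format(x$oob_mse, digits = 4), "\n")
  invisible(x)
}

#' Ranked, scored gene list
#'
#' @param genes gene identifiers ordered by descending score (ties broken
#'   by gene identifier, so orderings are platform-independent).
#' @param scores scores in the same order; must be non-increasing.
#' @return an object of class `ranked_list`.
#' @export
ranked_list <- function(genes, scores) {
  stopifnot(length(genes) == length(scores), length(genes) >= 2L)
  if (anyDuplicated(genes)) stop("duplicate gene in ranked list")
  if (any(!is.finite(scores))) stop("non-finite score in ranked list")
  if (is.unsorted(rev(scores))) stop("scores must be non-increasing")
  structure(list(genes = as.character(genes), scores = as.numeric(scores)),
            class = "ranked_list")
}

#' Turn an importance ranking into a descending ranked list
#'
#' @param ranking an `importance_ranking` from [fit_target_model()].
#' @param score which importance score to rank by.
#' @return a [ranked_list()] over the N-1 predictor genes.
#' @export
as_ranked_list <- function(ranking, score = c("mse", "purity")) {
  score <- match.arg(score)
  s <- if (score == "mse") ranking$pct_inc_mse else ranking$inc_node_purity
  if (all(is.na(s))) {
    stop("no out-of-bag data (forest fitted with bootstrap = FALSE); ",
         "permutation importance is unavailable")
  }
  ord <- order(-s, ranking$predictor_genes, method = "radix")
  ranked_list(ranking$predictor_genes[ord], unname(s[ord]))
}

#' Serialize an importance ranking to TSV
#'
#' Columns: predictor, pct_inc_mse, inc_node_purity, rank_mse, rank_purity.
#'
#' @param ranking an `importance_ranking`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_importance_ranking <- function(ranking, path) {
  g <- ranking$predictor_genes
  rk <- function(s) match(g, g[order(-s, g, method = "radix")])
  df <- data.frame(predictor = g,
                   pct_inc_mse = unname(ranking$pct_inc_mse),
                   inc_node_purity = unname(ranking$inc_node_purity),
                   rank_mse = rk(ranking$pct_inc_mse),
                   rank_purity = rk(ranking$inc_node_purity))
  write_tsv_with_header(df, path, config_hash(ranking$config))
}
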