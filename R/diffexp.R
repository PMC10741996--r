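#' Configuration for the differential-expression stage
#'
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param padj_threshold adjusted-p cutoff (default 0.05).
#' @param test `"moderated"` (empirical-Bayes moderated t, default) or
#'   `"welch"`.
#' @param adjust multiple-testing adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @param prior_df prior degrees of freedom for the moderated test.
#'   `NULL` (default) estimates them from the data; an explicit value fixes
#'   the shrinkage strength (0 disables moderation, recovering the ordinary
#'   pooled t).
#' @return an object of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 1, padj_threshold = 0.05,
                      test = c("moderated", "welch"),
                      adjust = c("BH", "bonferroni"), prior_df = NULL) {
  stopifnot(lfc_threshold >= 0, padj_threshold > 0, padj_threshold < 1,
            is.null(prior_df) || prior_df >= 0)
  structure(list(lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold,
                 test = match.arg(test), adjust = match.arg(adjust),
                 prior_df = prior_df),
            class = "de_config")
}

# Method-of-moments fit of the scaled inverse-chi-square prior for gene
# variances: on the log scale, log s^2 ~ const + log F(df, d0), whose
# variance is trigamma(df/2) + trigamma(d0/2).  Solve for d0 by inverting
# the trigamma function; excess variance <= 0 means complete shrinkage
# (d0 = Inf).
.fit_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2L) return(list(d0 = Inf, s02 = mean(s2[pos], 1)))
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  excess <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) -
    trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    half_d0 <- stats::uniroot(function(x) trigamma(x) - excess,
                              lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group differential expression between consensus clusters
#'
#' Input values are assumed to be on the log2 scale already, so the log2
#' fold change is the plain difference of group means: group 1 minus group
#' 2, where cluster numbering follows [final_labels()] (cluster 1 is the
#' larger).  The default test is a moderated t: per-gene pooled
#' within-group variances are shrunk toward a common prior fitted by the
#' method of moments (scaled inverse-chi-square, trigamma inversion), and
#' the t statistic uses the shrunk variance with `df + d0` degrees of
#' freedom.  As the prior degrees of freedom go to zero the statistic
#' reverts to an ordinary pooled t; `test = "welch"` gives an unpooled
#' Welch test instead.  A gene with zero variance in both groups and equal
#' means gets p = 1 by convention.  Adjustment (BH by default) runs across
#' exactly the tested genes; a gene is significant iff
#' `|log2fc| > lfc_threshold` and `p_adj < padj_threshold`.
#'
#' @param mat validated expression matrix, values on a log2 scale.
#' @param labels two-group sample labels covering every column of `mat`;
#'   each group needs at least 3 samples.
#' @param config a [de_config()].
#' @return a data.frame (class `de_table`): gene, log2fc, p, p_adj,
#'   significant, direction; prior fit recorded in attributes `d0`, `s02`.
#' @export
differential_expression <- function(mat, labels, config = de_config()) {
  if (length(labels) != ncol(mat)) {
    stop("labels must cover all ", ncol(mat), " samples")
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("expected exactly 2 groups, got ", nlevels(f))
  n1 <- sum(f == levels(f)[1])
  n2 <- sum(f == levels(f)[2])
  if (min(n1, n2) < 3L) {
    stop("each group needs at least 3 samples (got ", n1, " and ", n2, ")")
  }
  x1 <- mat[, f == levels(f)[1], drop = FALSE]
  x2 <- mat[, f == levels(f)[2], drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  lfc <- m1 - m2
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  if (config$test == "moderated") {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    prior <- .fit_variance_prior(s2, df)
    if (!is.null(config$prior_df)) prior$d0 <- config$prior_df
    s2_tilde <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2)) else
      (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
    se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
    df_t <- df + prior$d0
  } else {
    prior <- list(d0 = NA_real_, s02 = NA_real_)
    se <- sqrt(v1 / n1 + v2 / n2)
    df_t <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  p <- ifelse(se > 0,
              2 * pt(-abs(lfc) / ifelse(se > 0, se, 1),
                     df = if (config$test == "moderated") df_t else
                       pmax(df_t, 1)),
              ifelse(lfc == 0, 1, 0))
  p_adj <- p.adjust(p, method = config$adjust)
  out <- data.frame(gene = rownames(mat), log2fc = unname(lfc),
                    p = unname(p), p_adj = unname(p_adj),
                    significant = unname(abs(lfc) > config$lfc_threshold &
                                           p_adj < config$padj_threshold),
                    direction = unname(ifelse(lfc >= 0, "up", "down")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  attr(out, "config") <- config
  class(out) <- c("de_table", class(out))
  out
}

#' Significant genes of a differential-expression table
#'
#' @param de a `de_table`.
#' @return character vector of significant gene identifiers.
#' @export
significant_genes <- function(de) {
  de$gene[de$significant]
}
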