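#' Configuration for resampled k-means consensus clustering
#'
#' Defaults follow the method's stated procedure: k-means with Euclidean
#' distance on 80% subsamples of the samples, drawn 1000 times, candidate
#' cluster numbers 2..6.
#'
#' @param k_range integer cluster numbers to evaluate (all >= 2).
#' @param n_resample number of subsampling rounds (>= 50).
#' @param subsample_fraction fraction of samples drawn (without
#'   replacement) per round, in (0, 1].
#' @param seed integer seed.
#' @param n_start k-means restarts per round, each from random initial
#'   centers.  Random (rather than deterministic) initialisation is
#'   essential here: the consensus diagnostics read cluster *instability*
#'   on weakly structured data as evidence against a candidate k.
#' @param delta_threshold relative CDF-area gain below which adding a
#'   cluster is considered uninformative (default 0.3, calibrated on
#'   simulations with a known cluster number: at strong separation the
#'   relative gain one step past the true k falls to about 0.25 or less
#'   while the gain up to the true k stays above 0.4).
#' @param contrast_threshold within-minus-between consensus contrast below
#'   which the chosen k is flagged low confidence (default 0.7, calibrated
#'   on structureless simulations, whose maximum contrast stays below about
#'   0.55, while genuinely clustered data approaches 1).
#' @return an object of class `consensus_config`.
#' @export
consensus_config <- function(k_range = 2:6, n_resample = 1000L,
                             subsample_fraction = 0.8, seed = 1L,
                             n_start = 1L, delta_threshold = 0.3,
                             contrast_threshold = 0.7) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 2L, n_resample >= 50L,
            subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(k_range = k_range, n_resample = as.integer(n_resample),
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed), n_start = as.integer(n_start),
                 delta_threshold = delta_threshold,
                 contrast_threshold = contrast_threshold),
            class = "consensus_config")
}

# stats::kmeans with n_start random restarts (random initial centers keep
# partitions of structureless data unstable across resamples, which is the
# signal the consensus diagnostics rely on); returns labels or NULL when
# k-means cannot form k clusters
.kmeans_restarts <- function(d, k, n_start) {
  km <- tryCatch(
    suppressWarnings(kmeans(d, centers = k, nstart = n_start,
                            iter.max = 50L)),
    error = function(e) NULL)
  if (is.null(km)) NULL else km$cluster
}

#' Consensus matrix for one cluster number
#'
#' Samples are clustered in the feature space of the supplied genes (rows of
#' `mat`).  Each round draws `subsample_fraction` of the samples without
#' replacement and partitions them with k-means; consensus entry (i, j) is
#' the fraction of rounds in which samples i and j were clustered together,
#' among the rounds in which both were drawn.  Pairs never drawn together
#' get 0 with a warning.  Rounds where k-means cannot fill k clusters are
#' discarded; more than 10% discards is an error.
#'
#' @param mat expression matrix already restricted to the feature genes
#'   (e.g. the prior set); samples in columns.
#' @param k number of clusters.
#' @param config a [consensus_config()].
#' @return a symmetric S x S matrix with unit diagonal and entries in
#'   \[0, 1\]; the number of discarded rounds is attached as attribute
#'   `"discarded"`.
#' @export
consensus_matrix <- function(mat, k, config = consensus_config()) {
  # resampling runs against the canonical (sorted-identifier) sample order,
  # so consensus entries depend only on sample identities, not column order
  canon <- order(colnames(mat))
  d <- t(mat[, canon, drop = FALSE])
  s <- nrow(d)
  msub <- floor(config$subsample_fraction * s)
  if (msub < k) stop("subsample of ", msub, " samples cannot form ", k,
                     " clusters")
  with_seed(config$seed + k, {
    co <- matrix(0, s, s)
    tog <- matrix(0, s, s)
    discarded <- 0L
    for (b in seq_len(config$n_resample)) {
      idx <- sample.int(s, msub)
      lab <- .kmeans_restarts(d[idx, , drop = FALSE], k, config$n_start)
      if (is.null(lab) || length(unique(lab)) < k) {
        discarded <- discarded + 1L
        next
      }
      ind <- matrix(0, s, k)
      ind[cbind(idx, lab)] <- 1
      co <- co + tcrossprod(ind)
      o <- numeric(s)
      o[idx] <- 1
      tog <- tog + tcrossprod(o)
    }
    if (discarded > 0.1 * config$n_resample) {
      stop(discarded, " of ", config$n_resample,
           " resampling rounds discarded (empty clusters); ",
           "k = ", k, " is not supportable on these data")
    }
    never <- tog == 0 & upper.tri(tog)
    if (any(never)) {
      warning(sum(never), " sample pair(s) never co-sampled; consensus 0 ",
              "assigned — increase n_resample or subsample_fraction")
    }
    cm <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cm) <- 1
    dimnames(cm) <- list(colnames(mat)[canon], colnames(mat)[canon])
    back <- match(colnames(mat), colnames(cm))
    cm <- cm[back, back]
    attr(cm, "discarded") <- discarded
    cm
  })
}

#' Choose the cluster number from CDF area and delta-area curves
#'
#' For each k the empirical CDF of the off-diagonal consensus entries is
#' evaluated on a fixed 100-bin grid and its area computed by the trapezoid
#' rule.  The delta area for the smallest k is that k's area; for larger k
#' it is the relative gain `(A(k) - A(k-1)) / A(k-1)`.  The advisory choice
#' is the smallest k whose successor's delta falls below
#' `config$delta_threshold`; both curves are returned so the user can
#' override.  When even the best k separates poorly (maximum within- minus
#' between-cluster consensus contrast below `config$contrast_threshold`)
#' the choice is flagged low confidence.
#'
#' @param matrices named list of consensus matrices, names = k.
#' @param config a [consensus_config()].
#' @return an object of class `k_selection`: data.frame `curve`
#'   (k, cdf_area, delta_area, contrast), `chosen_k`, `low_confidence`.
#' @export
select_k <- function(matrices, config = consensus_config()) {
  ks <- as.integer(names(matrices))
  stopifnot(!anyDuplicated(ks), all(diff(ks) > 0))
  grid <- seq(0, 1, length.out = 101L)
  areas <- vapply(matrices, function(m) {
    x <- m[upper.tri(m)]
    trapezoid_area(grid, vapply(grid, function(t) mean(x <= t), numeric(1)))
  }, numeric(1))
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  contrast <- vapply(seq_along(ks), function(i) {
    m <- matrices[[i]]
    lab <- final_labels(m, ks[i])
    same <- outer(lab, lab, "==") & upper.tri(m)
    diff_ <- !outer(lab, lab, "==") & upper.tri(m)
    w <- if (any(same)) mean(m[same]) else NA_real_
    b <- if (any(diff_)) mean(m[diff_]) else 0
    w - b
  }, numeric(1))
  if (length(ks) == 1L) {
    chosen <- ks
    delta <- NA_real_
  } else {
    below <- which(delta[-1] < config$delta_threshold)
    chosen <- if (length(below)) ks[min(below)] else ks[length(ks)]
  }
  low <- max(contrast, na.rm = TRUE) < config$contrast_threshold
  if (low) message("select_k: weak cluster structure (max consensus ",
                   "contrast < ", config$contrast_threshold,
                   "); chosen_k is low confidence")
  structure(list(curve = data.frame(k = ks, cdf_area = unname(areas),
                                    delta_area = unname(delta),
                                    contrast = contrast),
                 chosen_k = chosen, low_confidence = low),
            class = "k_selection")
}

#' Final sample labels from a consensus matrix
#'
#' Hierarchical clustering with average linkage on the dissimilarity
#' `1 - consensus`, cut at k clusters; labels are renumbered by descending
#' cluster size (ties broken by first sample occurrence), so cluster 1 is
#' always the largest.
#'
#' @param cm consensus matrix.
#' @param k number of clusters (at most the number of samples).
#' @return integer labels named by sample.
#' @export
final_labels <- function(cm, k) {
  s <- nrow(cm)
  if (k > s) stop("k = ", k, " exceeds the number of samples (", s, ")")
  hc <- hclust(as.dist(1 - cm), method = "average")
  cl <- cutree(hc, k = k)
  sizes <- tabulate(cl, nbins = k)
  first <- vapply(seq_len(k), function(j) which(cl == j)[1], integer(1))
  ord <- order(-sizes, first)
  out <- match(cl, ord)
  names(out) <- colnames(cm)
  out
}

#' Run consensus clustering across a range of cluster numbers
#'
#' Driver combining [consensus_matrix()], [select_k()] and
#' [final_labels()].
#'
#' @param mat expression matrix (all genes).
#' @param features feature [gene_set()] (or character vector) defining the
#'   clustering space; required, because the appropriate feature set is an
#'   analysis decision.
#' @param config a [consensus_config()].
#' @return an object of class `consensus_result`: `matrices` (per k),
#'   `selection`, `chosen_k`, `labels` (for the chosen k).
#' @export
consensus_cluster <- function(mat, features, config = consensus_config()) {
  fs <- restrict_to_universe(
    if (inherits(features, "gene_set")) features else
      gene_set("features", features), mat)
  sub <- mat[fs$genes, , drop = FALSE]
  matrices <- lapply(config$k_range, function(k)
    consensus_matrix(sub, k, config))
  names(matrices) <- config$k_range
  sel <- select_k(matrices, config)
  structure(list(matrices = matrices, selection = sel,
                 chosen_k = sel$chosen_k,
                 labels = final_labels(matrices[[as.character(sel$chosen_k)]],
                                       sel$chosen_k)),
            class = "consensus_result")
}
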