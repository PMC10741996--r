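# Independent oracles and tiny fixture builders shared across tests.
# Each oracle is a literal, unoptimised restatement of the definition,
# deliberately coded apart from the package's production path.

# Brute-force enrichment score: walk all N positions of the ranked list,
# accumulate the running sum, return the signed extreme of largest absolute
# value (positive on a tie).
es_oracle <- function(genes, scores, set_genes, weight = 1) {
  n <- length(genes)
  hit <- genes %in% set_genes
  w <- abs(scores)^weight
  denom <- sum(w[hit])
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) {
      acc + (if (denom > 0) w[i] / denom else 1 / sum(hit))
    } else {
      acc - 1 / (n - sum(hit))
    }
    running[i] <- acc
  }
  mx <- max(c(running, 0))
  mn <- min(c(running, 0))
  # the statistic's convention: a tie between the extremes resolves positive
  if (mx >= -mn - 1e-12) mx else mn
}

# Benjamini-Hochberg step-up, coded literally from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small deterministic expression matrix with named genes/samples
toy_matrix <- function(n_genes = 6, n_samples = 8, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("gene%02d", seq_len(n_genes)),
                                sprintf("smp%02d", seq_len(n_samples))))
    m
  })
}

# linear single-predictor fixture: target = 2*x1 + noise among background
linear_sim_matrix <- function(seed, n_bg = 50, s = 100, noise = 0.25) {
  set.seed(seed)
  X <- matrix(rnorm(s * n_bg), s, n_bg)
  y <- 2 * X[, 1] + rnorm(s, 0, noise)
  mat <- rbind(t(X), y)
  rownames(mat) <- c(sprintf("x%02d", seq_len(n_bg)), "target")
  colnames(mat) <- sprintf("s%03d", seq_len(s))
  mat
}

# two sample groups whose centroids sit `sep` within-group standard
# deviations apart in Euclidean distance (the shift is spread over the
# features so `sep` is the total separation, not a per-feature one)
separated_groups_matrix <- function(seed, n_feat = 20, per_group = 30,
                                    sep = 10) {
  set.seed(seed)
  truth <- rep(1:2, each = per_group)
  m <- matrix(rnorm(n_feat * 2 * per_group), n_feat, 2 * per_group) +
    (sep / sqrt(n_feat)) * outer(rep(1, n_feat), truth - 1)
  dimnames(m) <- list(sprintf("f%02d", seq_len(n_feat)),
                      sprintf("s%02d", seq_len(2 * per_group)))
  list(mat = m, truth = truth)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
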