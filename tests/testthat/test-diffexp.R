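planted_de_matrix <- function(seed, n_genes = 200, per_group = 30,
                              shift = 2, sigma = 0.3, n_shift = 10) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * per_group, 0, sigma), n_genes,
              2 * per_group,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(2 * per_group))))
  m[seq_len(n_shift), per_group + seq_len(per_group)] <-
    m[seq_len(n_shift), per_group + seq_len(per_group)] + shift
  list(mat = m, labels = rep(1:2, each = per_group),
       shifted = sprintf("g%03d", seq_len(n_shift)))
}

test_that("planted shifts are recovered exactly with no false positives", {
  for (s in 1:10) {
    px <- planted_de_matrix(seed = s)
    de <- differential_expression(px$mat, px$labels, de_config())
    expect_setequal(significant_genes(de), px$shifted)
    expect_true(all(de$direction[de$gene %in% px$shifted] == "down"))
  }
})

test_that("null data yields no significant genes", {
  hits <- vapply(1:10, function(s) {
    set.seed(s + 300)
    m <- matrix(rnorm(200 * 40), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("s%02d", 1:40)))
    sum(differential_expression(m, rep(1:2, each = 20),
                                de_config())$significant)
  }, numeric(1))
  expect_gte(sum(hits == 0), 8)
})

test_that("the fold-change filter overrides even tiny p-values", {
  set.seed(5)
  m <- matrix(rnorm(50 * 40, 0, 0.5), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40)))
  # strong but sub-threshold shift: lfc targeted just below 1
  m["g01", 21:40] <- rnorm(20, 0.99, 0.001)
  m["g01", 1:20] <- rnorm(20, 0, 0.001)
  de <- differential_expression(m, rep(1:2, each = 20), de_config())
  row <- de[de$gene == "g01", ]
  expect_lt(row$p_adj, 1e-6)
  expect_lt(abs(row$log2fc), 1)
  expect_false(row$significant)
})

test_that("swapping group labels flips effect signs but not inference", {
  px <- planted_de_matrix(seed = 9, n_genes = 80)
  a <- differential_expression(px$mat, px$labels, de_config())
  b <- differential_expression(px$mat, 3 - px$labels, de_config())
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(a$significant, b$significant)
  flip <- a$direction[a$log2fc != 0]
  expect_true(all(flip != b$direction[a$log2fc != 0]))
})

test_that("adjusted p-values match the literal step-up oracle", {
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  px <- planted_de_matrix(seed = 2, n_genes = 120)
  de <- differential_expression(px$mat, px$labels, de_config())
  expect_equal(de$p_adj, bh_oracle(de$p), tolerance = 1e-12)
})

test_that("the Welch variant matches t.test and moderation bridges to the pooled t", {
  px <- planted_de_matrix(seed = 4, n_genes = 40)
  welch <- differential_expression(px$mat, px$labels,
                                   de_config(test = "welch"))
  ref <- apply(px$mat, 1, function(x)
    t.test(x[px$labels == 1], x[px$labels == 2])$p.value)
  expect_equal(welch$p, unname(ref), tolerance = 1e-12)

  pooled_ref <- apply(px$mat, 1, function(x)
    t.test(x[px$labels == 1], x[px$labels == 2], var.equal = TRUE)$p.value)
  mod0 <- differential_expression(px$mat, px$labels,
                                  de_config(prior_df = 0))
  expect_equal(mod0$p, unname(pooled_ref), tolerance = 1e-10)

  # heavier moderation pulls p-values away from the unmoderated ones
  mod_strong <- differential_expression(px$mat, px$labels,
                                        de_config(prior_df = 50))
  expect_gt(max(abs(log10(mod_strong$p) - log10(mod0$p))), 0.01)
})

test_that("moderated inference agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(10)
  m <- matrix(rnorm(300 * 24), 300, 24,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:24)))
  # heteroscedastic genes so the prior fit is informative
  m <- m * rep(sqrt(rchisq(300, 5) / 5), 24)
  m[1:20, 13:24] <- m[1:20, 13:24] + 1.5
  lab <- rep(1:2, each = 12)
  mine <- differential_expression(m, lab, de_config())
  design <- stats::model.matrix(~ 0 + factor(lab))
  colnames(design) <- c("g1", "g2")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design),
    limma::makeContrasts(g1 - g2, levels = design)))
  expect_lt(max(abs(log10(mine$p) - log10(fit$p.value[, 1]))), 0.05)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 0.2)
})

test_that("degenerate inputs follow the stated conventions", {
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:12)))
  m[1, ] <- 4 # zero variance in both groups, equal means
  de <- differential_expression(m, rep(1:2, each = 6),
                                de_config(test = "welch"))
  expect_identical(de$p[1], 1)

  expect_error(differential_expression(m, rep(c(1, 2), c(10, 2)),
                                       de_config()), "at least 3")
  expect_error(differential_expression(m, rep(1:3, each = 4), de_config()),
               "2 groups")
})
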