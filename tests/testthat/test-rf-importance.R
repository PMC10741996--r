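test_that("fitting is deterministic in the seed and sensitive to it", {
  mat <- linear_sim_matrix(seed = 1, n_bg = 15, s = 40)
  a <- fit_target_model(mat, "target", rf_config(n_trees = 50L, seed = 7L))
  b <- fit_target_model(mat, "target", rf_config(n_trees = 50L, seed = 7L))
  expect_identical(a, b)
  c <- fit_target_model(mat, "target", rf_config(n_trees = 50L, seed = 8L))
  expect_false(identical(a$pct_inc_mse, c$pct_inc_mse))
})

test_that("sample column order does not change importance", {
  mat <- linear_sim_matrix(seed = 2, n_bg = 12, s = 40)
  a <- fit_target_model(mat, "target", rf_config(n_trees = 50L, seed = 3L))
  perm <- sample(ncol(mat))
  b <- fit_target_model(mat[, perm], "target",
                        rf_config(n_trees = 50L, seed = 3L))
  expect_identical(a$pct_inc_mse, b$pct_inc_mse)
  expect_identical(a$inc_node_purity, b$inc_node_purity)
})

test_that("the true linear driver ranks first by both importance scores", {
  hits_mse <- hits_pur <- 0
  for (s in 1:20) {
    mat <- linear_sim_matrix(seed = s)
    r <- fit_target_model(mat, "target", rf_config(n_trees = 100L, seed = s))
    hits_mse <- hits_mse + (names(which.max(r$pct_inc_mse)) == "x01")
    hits_pur <- hits_pur + (names(which.max(r$inc_node_purity)) == "x01")
  }
  expect_gte(hits_mse, 19)
  expect_gte(hits_pur, 19)
})

test_that("a predictor that can never be split on scores exactly zero", {
  mat <- linear_sim_matrix(seed = 4, n_bg = 10, s = 60)
  mat <- rbind(mat, flat = rep(3.14, ncol(mat))) # constant: no valid split
  r <- suppressMessages(
    fit_target_model(mat, "target", rf_config(n_trees = 100L, seed = 1L)))
  expect_identical(unname(r$pct_inc_mse["flat"]), 0)
  expect_identical(unname(r$inc_node_purity["flat"]), 0)
})

test_that("a duplicated target dominates the permutation importance", {
  # the leak is only distinguishable from the true driver when the target
  # carries real noise; at near-zero noise the driver is itself an almost
  # perfect predictor and the two must share importance instead
  for (s in 1:10) {
    mat <- linear_sim_matrix(seed = s, n_bg = 20, s = 60, noise = 1)
    mat <- rbind(mat, x_dup = mat["target", ])
    r <- fit_target_model(mat, "target", rf_config(n_trees = 100L, seed = s))
    expect_identical(names(which.max(r$pct_inc_mse)), "x_dup")
  }
})

test_that("identical informative predictors share importance and both stay on top", {
  for (s in 1:10) {
    mat <- linear_sim_matrix(seed = s, n_bg = 20, s = 60)
    single <- fit_target_model(mat, "target",
                               rf_config(n_trees = 100L, seed = s))
    twin <- fit_target_model(rbind(mat, x01b = mat["x01", ]), "target",
                             rf_config(n_trees = 100L, seed = s))
    rks <- rank(-twin$pct_inc_mse)[c("x01", "x01b")]
    expect_true(all(rks <= 2))
    expect_lt(twin$pct_inc_mse["x01"], single$pct_inc_mse["x01"])
    expect_lt(twin$pct_inc_mse["x01b"], single$pct_inc_mse["x01"])
  }
})

test_that("impurity importance is non-negative and permutation importance goes negative under the null", {
  for (s in 1:10) {
    set.seed(s)
    mat <- matrix(rnorm(30 * 50), 30, 50,
                  dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:50)))
    r <- fit_target_model(mat, "g01", rf_config(n_trees = 60L, seed = s))
    expect_true(all(r$inc_node_purity >= 0))
    expect_true(any(r$pct_inc_mse < 0))
  }
})

test_that("pure-noise targets centre permutation importance near zero", {
  ok <- 0
  for (s in 1:15) {
    set.seed(s + 2000)
    X <- matrix(rnorm(100 * 50), 100, 50)
    mat <- rbind(t(X), target = rnorm(100))
    rownames(mat) <- c(sprintf("x%02d", 1:50), "target")
    colnames(mat) <- sprintf("s%03d", 1:100)
    r <- fit_target_model(mat, "target", rf_config(n_trees = 100L, seed = s))
    ok <- ok + (abs(mean(r$pct_inc_mse)) <= 0.5)
  }
  expect_gte(ok, 13)
})

test_that("without bootstrap there is no out-of-bag permutation importance", {
  mat <- linear_sim_matrix(seed = 5, n_bg = 8, s = 30)
  r <- fit_target_model(mat, "target",
                        rf_config(n_trees = 30L, bootstrap = FALSE, seed = 1L))
  expect_true(all(is.na(r$pct_inc_mse)))
  expect_error(as_ranked_list(r, "mse"), "out-of-bag")
  expect_s3_class(as_ranked_list(r, "purity"), "ranked_list")
})

test_that("degenerate targets are rejected", {
  m <- toy_matrix(5, 6)
  m["gene02", ] <- 1
  expect_error(suppressMessages(fit_target_model(m, "gene02")),
               "zero variance")
  expect_error(fit_target_model(m, "nope"), "not in the matrix")
})

test_that("importance rankings agree with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(7)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(100, 0, 0.5)
  mat <- rbind(t(X), target = y)
  rownames(mat) <- c(sprintf("x%02d", 1:30), "target")
  colnames(mat) <- sprintf("s%03d", 1:100)
  mine <- fit_target_model(mat, "target", rf_config(n_trees = 500L, seed = 1L))
  rf <- randomForest::randomForest(X, y, ntree = 500, mtry = 30,
                                   nodesize = 5, importance = TRUE)
  imp <- randomForest::importance(rf)
  expect_gt(cor(mine$pct_inc_mse, imp[, 1], method = "spearman"), 0.5)
  expect_gt(cor(mine$inc_node_purity, imp[, 2], method = "spearman"), 0.5)
  expect_identical(names(which.max(mine$pct_inc_mse)), "x01")
  expect_identical(rownames(imp)[which.max(imp[, 1])], "1")
})

test_that("rankings serialize with both rank columns", {
  mat <- linear_sim_matrix(seed = 6, n_bg = 6, s = 30)
  r <- fit_target_model(mat, "target", rf_config(n_trees = 30L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_importance_ranking(r, path)
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_setequal(tab$predictor, r$predictor_genes)
  expect_identical(sort(tab$rank_mse), 1:6)
  top <- tab$predictor[tab$rank_mse == 1]
  expect_identical(top, names(which.max(r$pct_inc_mse)))
})
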