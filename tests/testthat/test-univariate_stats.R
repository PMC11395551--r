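# Fisher-LSD letters, fold change, hierarchical clustering.

test_that("LSD letters collapse equal groups and split far-separated ones", {
  vals <- rep(c(1, 2, 3), 4)
  grp <- rep(c("S1", "S2", "S3", "S4"), each = 3)
  res <- anova_lsd(vals, grp)
  expect_true(all(res$letters == "a"))

  set.seed(141)
  vals2 <- c(rnorm(3, 0, 1), rnorm(3, 100, 1))
  # the omnibus F is astronomically large here; its numerical warning is moot
  res2 <- suppressWarnings(anova_lsd(vals2, rep(c("lo", "hi"), each = 3)))
  expect_equal(sort(unname(res2$letters)), c("a", "b"))

  expect_error(suppressWarnings(anova_lsd(rep(1, 6), rep(c("a", "b"), each = 3))),
               "degenerate")
})

test_that("letter displays exactly encode the pairwise significance pattern", {
  set.seed(151)
  for (i in 1:25) {
    mu <- sample(c(0, 0, 1, 3), 4)
    vals <- rnorm(12, rep(mu, each = 3), 1)
    grp <- rep(paste0("G", 1:4), each = 3)
    res <- anova_lsd(vals, grp, alpha = 0.05)
    expect_true(audit_letters(as.list(res$letters), res$pairwise, 0.05),
                info = paste("design", i))
  }
})

test_that("protected LSD returns a single letter when the omnibus F is not significant", {
  set.seed(161)
  vals <- rnorm(12, 0, 1)
  grp <- rep(paste0("G", 1:4), each = 3)
  res <- anova_lsd(vals, grp, protected = TRUE)
  if (res$f_p_value > 0.05) expect_true(all(res$letters == "a"))
})

test_that("2^-ddCt fold change reproduces hand arithmetic", {
  expect_equal(ddct_fold_change(15, 15, 20, 20)$fold, 1)
  expect_equal(ddct_fold_change(14, 15, 20, 20)$fold, 2)  # ddCt = -1
  out <- ddct_fold_change(20, 15, 22, 15)
  expect_equal(out$delta_delta_ct, -2)
  expect_equal(out$fold, 4)
  # replicate averaging before differencing
  out2 <- ddct_fold_change(c(19, 21), c(15, 15), c(22, 22), c(15, 15))
  expect_equal(out2$fold, 4)
  # log identity
  expect_equal(log2(out$fold), -out$delta_delta_ct)
})

test_that("hierarchical clustering matches a brute-force agglomeration oracle", {
  set.seed(171)
  # identical rows merge first at height zero
  M <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 0, 2),
             d = c(-3, 5, 2, 0))
  h <- hca_cluster(M, k = 2, scale_rows = FALSE)
  expect_equal(h$heights[1], 0)
  expect_equal(h$clusters[["a"]], h$clusters[["b"]])

  for (i in 1:5) {
    X <- matrix(rnorm(20), 5, 4)
    h2 <- hca_cluster(X, k = 2, scale_rows = FALSE)
    expect_equal(h2$heights, oracle_merge_heights(X), tolerance = 1e-10)
    orc <- oracle_agglomerate(X, k = 2)
    expect_equal(rand_index(unname(h2$clusters), orc$partition), 1)
  }
  expect_error(hca_cluster(M, k = 10), "exceeds")
})

test_that("clustering is invariant under row permutation and exports Newick text", {
  set.seed(181)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("r", 1:6), NULL))
  h <- hca_cluster(X, k = 3)
  perm <- sample(6)
  h2 <- hca_cluster(X[perm, ], k = 3)
  expect_equal(sort(h$heights), sort(h2$heights), tolerance = 1e-10)
  expect_equal(rand_index(unname(h$clusters[rownames(X)]),
                          unname(h2$clusters[rownames(X)])), 1)
  expect_match(h$newick, "^\\(")
  tree <- ape::read.tree(text = h$newick)
  expect_setequal(tree$tip.label, rownames(X))
})
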