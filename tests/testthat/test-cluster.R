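# Feature matrices, Ward.D2 clustering, multiscale bootstrap support,
# cluster-defining features and permutation importance.

mk_stats <- function(keys, n_gained, n_lost, np = 4) {
  data.frame(key = keys, a = "x", b = "y",
             n_gained = n_gained, n_lost = n_lost,
             n_kept = pmax(np - n_gained - n_lost, 0), n_absent = 0,
             perc_gained = 100 * n_gained / np,
             perc_lost = 100 * n_lost / np,
             strict_gain = n_gained == np, strict_loss = n_lost == np,
             stringsAsFactors = FALSE)
}

test_that("feature matrix marks cancer-type perturbations per cohort", {
  stats_list <- list(
    X = mk_stats(c("a|b", "c|d"), c(3, 0), c(0, 2)),
    Y = mk_stats("a|b", 1, 0),
    Z = mk_stats("e|f", 2, 0))
  fm <- build_feature_matrix(stats_list, mode = "both", min_patients = 2)
  expect_equal(unname(fm$values[, "a|b:gain"]), c(1L, 0L, 0L))
  expect_equal(unname(fm$values[, "c|d:loss"]), c(1L, 0L, 0L))
  expect_equal(unname(fm$values[, "e|f:gain"]), c(0L, 0L, 1L))
  g <- build_feature_matrix(stats_list, mode = "gain", min_patients = 2)
  l <- build_feature_matrix(stats_list, mode = "loss", min_patients = 2)
  expect_equal(ncol(fm$values), ncol(g$values) + ncol(l$values))
  expect_error(build_feature_matrix(stats_list["X"]), "at least 2")
})

test_that("Ward clustering merges identical rows first and splits blocks", {
  X <- rbind(o1 = c(1, 1, 0, 0), o2 = c(1, 1, 0, 0), o3 = c(0, 0, 1, 1))
  d <- hclust_ward(X)
  expect_equal(d$members[[1]], c("o1", "o2"))
  expect_equal(d$height[1], 0)

  blocks <- rbind(
    a1 = c(rep(1, 10), rep(0, 10)), a2 = c(rep(1, 10), rep(0, 10)),
    b1 = c(rep(0, 10), rep(1, 10)), b2 = c(rep(0, 10), rep(1, 10)))
  db <- hclust_ward(blocks)
  k <- cut_dendrogram(db, 2)
  expect_equal(unname(k["a1"]), unname(k["a2"]))
  expect_equal(unname(k["b1"]), unname(k["b2"]))
  expect_true(k[["a1"]] != k[["b1"]])
  expect_error(hclust_ward(matrix(2, 2, 2)), "binary")
})

test_that("merge heights and memberships match a brute-force Ward.D2 oracle", {
  set.seed(44)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    X <- matrix(rbinom(n * 12, 1, 0.5), nrow = n,
                dimnames = list(letters[1:n], NULL))
    d <- hclust_ward(X)
    orc <- oracle_ward(X)
    expect_equal(d$height, orc$heights, tolerance = 1e-8)
    expect_identical(d$members, orc$members)
    # heights non-decreasing
    expect_true(all(diff(d$height) >= -1e-10))
  }
})

test_that("Ward clustering agrees with stats::hclust on tie-free data", {
  set.seed(50)
  repeat {
    X <- matrix(rbinom(5 * 40, 1, 0.5), nrow = 5,
                dimnames = list(letters[1:5], NULL))
    dm <- stats::dist(X)
    if (anyDuplicated(round(as.numeric(dm), 10)) == 0) break
  }
  ref <- stats::hclust(dm, method = "ward.D2")
  got <- hclust_ward(X)
  expect_equal(got$height, ref$height, tolerance = 1e-10)
})

test_that("clustering is invariant to object order", {
  set.seed(51)
  X <- matrix(rbinom(6 * 20, 1, 0.5), nrow = 6,
              dimnames = list(paste0("c", 1:6), NULL))
  d1 <- hclust_ward(X)
  perm <- sample(6)
  d2 <- hclust_ward(X[perm, , drop = FALSE])
  expect_identical(d1$members, d2$members)
  expect_equal(d1$height, d2$height, tolerance = 1e-10)
})

test_that("bootstrap support is reproducible and sane on planted blocks", {
  X <- rbind(
    a1 = c(rep(1, 15), rep(0, 15), 1, 0), a2 = c(rep(1, 15), rep(0, 15), 0, 1),
    a3 = c(rep(1, 15), rep(0, 15), 0, 0),
    b1 = c(rep(0, 15), rep(1, 15), 1, 0), b2 = c(rep(0, 15), rep(1, 15), 0, 1),
    b3 = c(rep(0, 15), rep(1, 15), 0, 0))
  bs1 <- multiscale_bootstrap(X, B = 100, seed = 9)
  bs2 <- multiscale_bootstrap(X, B = 100, seed = 9)
  expect_identical(bs1$bp_table, bs2$bp_table)
  sup <- bs1$support
  # the root has full support
  root <- sup[sup$size == 6, ]
  expect_equal(root$bp, 1)
  expect_equal(root$au, 1)
  # both planted blocks are recovered with high support
  blocks <- sup[sup$members %in% c("a1+a2+a3", "b1+b2+b3"), ]
  expect_equal(nrow(blocks), 2L)
  expect_true(all(blocks$au >= 0.95))
  expect_true(all(sup$bp >= 0 & sup$bp <= 1))
  expect_true(all(sup$au >= 0 & sup$au <= 1))
})

test_that("newick export writes a tree over the cohort labels", {
  X <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 1), c = c(0, 0, 1, 1),
             d = c(0, 1, 1, 0))
  d <- hclust_ward(X)
  f <- withr::local_tempfile()
  write_newick(d, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, rownames(X))
})

test_that("cluster-defining features split into exclusive and inclusive", {
  X <- rbind(o1 = c(1, 1, 1), o2 = c(1, 1, 1), o3 = c(0, 1, 1),
             o4 = c(0, 0, 1))
  colnames(X) <- c("f_excl", "f_incl", "f_all")
  de <- cluster_defining_edges(X, list(c("o1", "o2")))[[1]]
  expect_equal(de$exclusive, "f_excl")
  expect_setequal(de$inclusive, c("f_excl", "f_incl", "f_all"))
  expect_error(cluster_defining_edges(X, list("nope")), "unknown object")
})

test_that("permutation importance finds the separating feature", {
  set.seed(33)
  n <- 12
  labels <- rep(c("A", "B"), each = n / 2)
  hits <- 0
  for (s in 1:10) {
    X <- matrix(rbinom(n * 50, 1, 0.5), nrow = n,
                dimnames = list(paste0("o", 1:n),
                                sprintf("noise%02d", 1:50)))
    X <- cbind(X, signal = as.integer(labels == "A"))
    imp <- permutation_importance(X, labels, n_trees = 100, n_perm = 20,
                                  seed = s)
    if (imp$feature[1] == "signal") hits <- hits + 1
    # constant features have zero importance
    Xc <- cbind(X, flat = 1L)
    impc <- permutation_importance(Xc, labels, n_trees = 50, n_perm = 10,
                                   seed = s)
    expect_equal(impc$importance[impc$feature == "flat"], 0)
  }
  expect_gte(hits, 9)
})

test_that("label permutation shrinks importance toward the noise floor", {
  set.seed(77)
  n <- 12
  labels <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rbinom(n * 30, 1, 0.5), nrow = n,
              dimnames = list(paste0("o", 1:n), sprintf("n%02d", 1:30)))
  X <- cbind(X, signal = as.integer(labels == "A"))
  sig <- numeric(5)
  nullmax <- numeric(5)
  for (s in 1:5) {
    imp <- permutation_importance(X, labels, n_trees = 100, n_perm = 20,
                                  seed = s)
    sig[s] <- imp$importance[imp$feature == "signal"]
    shuffled <- sample(labels)
    impn <- permutation_importance(X, shuffled, n_trees = 100, n_perm = 20,
                                   seed = s)
    nullmax[s] <- max(impn$importance)
  }
  expect_gt(mean(sig), mean(nullmax))
})
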