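# Rewiring scores, greedy ranking, SMG association/enrichment and the
# paired size test.

test_that("rewiring scores follow the fraction-of-incident-edges rule", {
  net <- ppin(data.frame(a = c("v", "v", "w"), b = c("x", "y", "x")))
  rs <- rewiring_score(net, "v|x")
  v <- rs[rs$node == "v", ]
  expect_equal(v$rewiring_score, 0.5)
  expect_true(v$rewired)
  y <- rs[rs$node == "y", ]
  expect_equal(y$rewiring_score, 0)
  expect_false(y$rewired)
  # degree-1 node with its only edge perturbed: score 1 but not flagged
  x1 <- rewiring_score(ppin(data.frame(a = "p", b = "q")), "p|q")
  expect_equal(x1$rewiring_score, c(1, 1))
  expect_false(any(x1$rewired))
  expect_error(rewiring_score(net, "v|z"), "not in network")
})

test_that("greedy ranking reproduces the toy worked example", {
  toy <- toy9_network()
  r <- rank_nodes_greedy(toy, c("b|c", "c|d", "d|e"))
  rank_of <- function(n) r$rank[r$node == n]
  expect_equal(rank_of("c"), 3L)
  expect_equal(rank_of("b"), 1L)
  expect_equal(rank_of("d"), 1L)
  expect_equal(rank_of("e"), 1L)
  expect_true(all(r$rank[!r$node %in% c("b", "c", "d", "e")] == 0L))
  # attribution partitions the perturbed set
  expect_equal(sum(r$n_attributed), 3L)

  r1 <- rank_nodes_greedy(toy, "a|b")
  expect_equal(r1$rank[r1$node == "a"], 1L)
  expect_equal(r1$rank[r1$node == "b"], 1L)
  expect_equal(sum(r1$n_attributed), 1L)
})

test_that("greedy ranking matches an independent procedural oracle", {
  set.seed(17)
  for (i in 1:30) {
    g <- rand_ppin(sample(6:20, 1), sample(8:30, 1))
    k <- edge_keys(g)
    pert <- sample(k, sample.int(min(8, length(k)), 1))
    r <- rank_nodes_greedy(g, pert)
    orc <- oracle_rank_greedy(g, sort(pert))
    expect_equal(setNames(r$rank, r$node), orc[r$node])
    expect_equal(sum(r$n_attributed), length(pert))
    all_attr <- unlist(r$attributed_edges)
    expect_setequal(all_attr, pert)
    expect_false(anyDuplicated(all_attr) > 0)
  }
})

test_that("SMG association classifies first/second neighbors", {
  net <- ppin(data.frame(a = c("S", "x", "y", "u"),
                         b = c("x", "y", "z", "w")))
  cls <- smg_association(c("S|x", "x|y", "y|z", "u|w"), net, "S")
  got <- setNames(cls$smg_class, cls$key)
  expect_equal(unname(got["S|x"]), "smg_first_neighbor")
  expect_equal(unname(got["x|y"]), "smg_second_neighbor")
  expect_equal(unname(got["u|w"]), "smg_independent")
})

test_that("degree-matched sampling respects the band with nearest fallback", {
  net <- ppin(data.frame(
    a = c(rep("S", 5), rep("c1", 5), rep("c2", 5), rep("c3", 9)),
    b = c(paste0("x", 1:5), paste0("y", 1:5), paste0("z", 1:5),
          paste0("w", 1:9))))
  # S has degree 5; candidates c1, c2 have degree 5, c3 degree 9
  set.seed(1)
  for (i in 1:5) {
    m <- degree_matched_sample(net, "S")
    expect_true(m %in% c("c1", "c2"))
  }
  # empty band: unique nearest-degree candidate picked deterministically
  # (S has degree 4, x1 degree 2, everything else degree 1)
  net2 <- ppin(data.frame(a = c(rep("S", 4), "c"), b = c(paste0("x", 1:4), "x1")))
  expect_equal(degree_matched_sample(net2, "S"), "x1")
  set.seed(7)
  a <- degree_matched_sample(net, "S")
  set.seed(7)
  b <- degree_matched_sample(net, "S")
  expect_identical(a, b)
})

test_that("chi-squared on the SMG table matches the closed form", {
  t0 <- matrix(c(10, 90, 10, 90), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(t0, correct = FALSE))
  expect_equal(unname(ct$statistic), 0)
  expect_equal(ct$p.value, 1)
  t1 <- matrix(c(30, 70, 10, 90), nrow = 2, byrow = TRUE)
  ct1 <- suppressWarnings(stats::chisq.test(t1, correct = FALSE))
  expect_equal(unname(ct1$statistic), oracle_chi2(t1), tolerance = 1e-12)
  # row swap leaves the statistic unchanged
  ct2 <- suppressWarnings(stats::chisq.test(t1[2:1, ], correct = FALSE))
  expect_equal(unname(ct2$statistic), unname(ct1$statistic))
})

test_that("SMG enrichment test reports replicate p-values and degeneracy", {
  set.seed(30)
  g <- rand_ppin(20, 40)
  keys <- edge_keys(g)
  profs <- lapply(1:4, function(i) {
    k <- sample(keys, 25)
    structure(list(patient = paste0("P", i), cohort = "X",
                   codes = setNames(sample(c("10", "01", "11"), 25, TRUE,
                                           prob = c(.3, .3, .4)), k)),
              class = "patient_profile")
  })
  st <- edge_stats(cohort_profile(profs))
  smgs <- sample(g$nodes, 3)
  rep <- smg_enrichment_test(st, g, smgs, n_replicates = 20)
  expect_length(rep$p_replicates, 20)
  expect_true(all(rep$p_replicates >= 0 & rep$p_replicates <= 1))
  expect_equal(rep$p_value, stats::median(rep$p_replicates))
  # SMGs touching nothing: both columns empty on the SMG row is fine, but
  # an all-zero column margin flags the replicate as degenerate
  lonely <- ppin(data.frame(a = c("a", "b"), b = c("b", "c")), nodes = "L")
  st2 <- st[0, ]
  rep2 <- smg_enrichment_test(st2, lonely, "L", n_replicates = 5)
  expect_equal(rep2$degenerate, 1)
  expect_equal(rep2$p_value, 1)
})

test_that("paired size test is exact for small n and matches enumeration", {
  # constant unit differences, n = 10: fully tied ranks
  h <- rep(10, 10) + 1
  t <- rep(10, 10)
  res <- paired_size_test(h, t)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, oracle_wilcoxon_enum(h - t), tolerance = 1e-12)
  expect_equal(res$p_value, 2 / 2^10, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:10) {
    d <- round(stats::rnorm(sample(6:11, 1)), 1)
    d <- d[d != 0]
    if (length(d) < 2) next
    res <- paired_size_test(d, rep(0, length(d)))
    expect_equal(res$p_value, oracle_wilcoxon_enum(d), tolerance = 1e-12)
    # two-sided symmetry under negation
    resn <- paired_size_test(-d, rep(0, length(d)))
    expect_equal(res$p_value, resn$p_value, tolerance = 1e-12)
  }

  same <- paired_size_test(c(5, 5, 5), c(5, 5, 5))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
})

test_that("paired size test agrees with wilcox.test when ties are absent", {
  set.seed(2)
  x <- stats::rnorm(15)
  y <- stats::rnorm(15)
  res <- paired_size_test(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # large n: normal approximation
  x2 <- stats::rnorm(40)
  y2 <- stats::rnorm(40)
  res2 <- paired_size_test(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_equal(res2$p_value, ref2$p.value, tolerance = 1e-10)
})
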