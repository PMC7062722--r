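# Expression calling, major-isoform selection and condition-specific
# network construction.

test_that("mixture-based calls separate clear low/high components", {
  set.seed(1)
  low <- stats::rlnorm(500, log(0.2), 0.3)
  high <- stats::rlnorm(500, log(800), 0.5)
  vals <- matrix(c(low, high), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("s%02d", 1:10)))
  truth <- matrix(rep(c(FALSE, TRUE), each = 500), nrow = 100)
  meta <- data.frame(sample = colnames(vals), patient = colnames(vals),
                     condition = "tumor", cohort = "X")
  # one gene per transcript so gene abundance equals the drawn value
  ann <- annotation_set(rownames(vals), rownames(vals))
  expr <- expression_matrix(vals, meta)
  calls <- fit_expression_calls(expr, ann)
  expect_equal(calls$method, "gmm")
  agree <- mean(calls$expressed[rownames(vals), ] == truth)
  expect_gte(agree, 0.99)
})

test_that("all-zero matrices yield no expressed genes", {
  vals <- matrix(0, nrow = 10, ncol = 3,
                 dimnames = list(paste0("t", 1:10), paste0("s", 1:3)))
  meta <- data.frame(sample = colnames(vals), patient = colnames(vals),
                     condition = "healthy", cohort = "X")
  ann <- annotation_set(paste0("g", 1:10), paste0("t", 1:10))
  calls <- fit_expression_calls(expression_matrix(vals, meta), ann)
  expect_false(any(calls$expressed))
})

test_that("small datasets fall back to the abundance floor", {
  vals <- matrix(c(2.0, 0.5, 2.0, 0.5, 2.0, 0.5, 2.0, 0.5, 2.0, 0.5),
                 nrow = 5,
                 dimnames = list(paste0("t", 1:5), c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"), patient = c("p1", "p2"),
                     condition = "tumor", cohort = "X")
  ann <- annotation_set(paste0("g", 1:5), paste0("t", 1:5))
  calls <- fit_expression_calls(expression_matrix(vals, meta), ann)
  expect_equal(calls$method, "floor")
  expect_true(calls$expressed["g1", "s1"])   # abundance 2.0 >= 1.0
  expect_false(calls$expressed["g2", "s1"])  # abundance 0.5 <  1.0
})

test_that("transcript cut is inclusive at 0.1 and gated by the gene call", {
  vals <- matrix(c(0.1, 5.0, 0.0999), ncol = 1,
                 dimnames = list(c("tA", "tB", "tC"), "s1"))
  meta <- data.frame(sample = "s1", patient = "p1",
                     condition = "tumor", cohort = "X")
  ann <- annotation_set(c("gA", "gB", "gC"), c("tA", "tB", "tC"))
  expr <- expression_matrix(vals, meta)
  calls <- expression_calls(matrix(c(TRUE, FALSE, TRUE), ncol = 1,
                                   dimnames = list(c("gA", "gB", "gC"), "s1")))
  got <- expressed_transcripts(expr, calls, "s1", ann)
  expect_true("tA" %in% got)    # 0.1 inclusive
  expect_false("tB" %in% got)   # gene gate dominates
  expect_false("tC" %in% got)   # below the cut
  expect_error(expressed_transcripts(expr, calls, "nope", ann),
               "unknown sample")
})

test_that("major isoform follows expression with lexicographic tie-break", {
  fx <- isoform_switch_example()
  calls <- expression_calls(
    matrix(TRUE, nrow = 3, ncol = 2,
           dimnames = list(c("DST", "CALM1", "PPP1CB"), c("S_H", "S_T"))))
  h <- domain_state("DST", "S_H", fx$expr, calls, fx$annotations)
  expect_equal(h$major_transcript, "T_765")
  expect_length(h$domains, 0L)
  t <- domain_state("DST", "S_T", fx$expr, calls, fx$annotations)
  expect_equal(t$major_transcript, "T_364")
  expect_equal(t$domains, "PF13499")

  # tie at equal abundance picks the lexicographically smaller id
  vals <- matrix(c(2.0, 2.0), ncol = 1,
                 dimnames = list(c("T_a", "T_b"), "s1"))
  meta <- data.frame(sample = "s1", patient = "p1",
                     condition = "tumor", cohort = "X")
  ann <- annotation_set(c("G", "G"), c("T_a", "T_b"))
  cl <- expression_calls(matrix(TRUE, 1, 1, dimnames = list("G", "s1")))
  st <- domain_state("G", "s1", expression_matrix(vals, meta), cl, ann)
  expect_equal(st$major_transcript, "T_a")
})

test_that("isoform switch fixture gains its two DDI-supported edges", {
  fx <- isoform_switch_example()
  nets <- contextualize_cohort(fx$network, fx$annotations, fx$ddi, fx$expr)
  expect_equal(nrow(nets[["S_H"]]$edges), 0L)
  expect_setequal(edge_key(nets[["S_T"]]$edges$a, nets[["S_T"]]$edges$b),
                  c("CALM1|DST", "DST|PPP1CB"))
  expect_true(all(nets[["S_T"]]$reason == "ddi_supported"))
})

test_that("edges without any DDI evidence fall back to co-expression", {
  net <- ppin(data.frame(a = "A", b = "B"))
  ann <- annotation_set(c("A", "B"), c("tA", "tB"),
                        list(character(), character()))
  vals <- matrix(c(5, 5), ncol = 1, dimnames = list(c("tA", "tB"), "s1"))
  meta <- data.frame(sample = "s1", patient = "p1",
                     condition = "tumor", cohort = "X")
  expr <- expression_matrix(vals, meta)
  calls <- expression_calls(matrix(TRUE, 2, 1,
                                   dimnames = list(c("A", "B"), "s1")))
  cn <- build_condition_network(net, ann, ddi_map(), expr, calls, "s1")
  expect_equal(cn$reason, "no_ddi_evidence_fallback")
})

test_that("condition networks match the literal retention-rule oracle", {
  set.seed(99)
  for (i in 1:30) {
    inst <- rand_context_instance()
    cn <- build_condition_network(inst$net, inst$ann, inst$ddi, inst$expr,
                                  inst$calls, "s1")
    got <- sort(edge_key(cn$edges$a, cn$edges$b))
    expect_identical(got, oracle_condition_edges(inst))
    # subset property and expressed-endpoint invariant
    expect_true(all(got %in% edge_keys(inst$net)))
    expect_true(all(inst$expressed[unique(c(cn$edges$a, cn$edges$b))]))
  }
})

test_that("DDI pairs over unannotated domains change nothing; pairs over major
           domains never remove edges; silencing removes incident ones", {
  set.seed(5)
  inst <- rand_context_instance()
  base <- build_condition_network(inst$net, inst$ann, inst$ddi, inst$expr,
                                  inst$calls, "s1")
  # pairs over domains no transcript carries leave the network untouched
  inert <- ddi_map(c(inst$ddi_pairs$d1, "zz1", "zz2"),
                   c(inst$ddi_pairs$d2, "zz3", "zz4"))
  same <- build_condition_network(inst$net, inst$ann, inert, inst$expr,
                                  inst$calls, "s1")
  expect_identical(edge_key(same$edges$a, same$edges$b),
                   edge_key(base$edges$a, base$edges$b))
  # a pair linking the current major-isoform domains of an edge's two
  # expressed endpoints guarantees that edge's retention
  calls <- inst$calls
  for (i in seq_len(nrow(inst$net$edges))) {
    e1 <- inst$net$edges[i, ]
    if (!inst$expressed[[e1$a]] || !inst$expressed[[e1$b]]) next
    s_a <- domain_state(e1$a, "s1", inst$expr, calls, inst$ann)
    s_b <- domain_state(e1$b, "s1", inst$expr, calls, inst$ann)
    if (length(s_a$domains) == 0 || length(s_b$domains) == 0) next
    extra <- ddi_map(c(inst$ddi_pairs$d1, s_a$domains[1]),
                     c(inst$ddi_pairs$d2, s_b$domains[1]))
    more <- build_condition_network(inst$net, inst$ann, extra, inst$expr,
                                    calls, "s1")
    expect_true(edge_key(e1$a, e1$b) %in%
                  edge_key(more$edges$a, more$edges$b))
    break
  }

  on_genes <- names(inst$expressed)[inst$expressed]
  g0 <- on_genes[1L]
  silenced <- inst$expressed
  silenced[g0] <- FALSE
  calls2 <- expression_calls(matrix(silenced, ncol = 1,
                                    dimnames = list(names(silenced), "s1")))
  cn2 <- build_condition_network(inst$net, inst$ann, inst$ddi, inst$expr,
                                 calls2, "s1")
  k1 <- edge_key(base$edges$a, base$edges$b)
  k2 <- edge_key(cn2$edges$a, cn2$edges$b)
  incident <- base$edges$a == g0 | base$edges$b == g0
  expect_setequal(setdiff(k1, k2), k1[incident])
})
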