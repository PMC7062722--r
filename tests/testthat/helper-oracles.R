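# Independent brute-force oracles and random instance generators used by
# the unit and equivalence tests. These deliberately re-implement the
# rules as literal loops over plain data structures, not via the package
# internals.

edges_from_keys_df <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(a = character(), b = character()))
  }
  p <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(a = p[, 1], b = p[, 2], stringsAsFactors = FALSE)
}

mk_net <- function(keys) ppin(edges_from_keys_df(keys))

mk_profile <- function(patient, codes, cohort = "X") {
  structure(list(patient = patient, cohort = cohort, codes = codes),
            class = "patient_profile")
}

rand_ppin <- function(n_nodes, n_edges, prefix = "n") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  sel <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  ppin(data.frame(a = pairs[sel, 1L], b = pairs[sel, 2L],
                  stringsAsFactors = FALSE), nodes = nodes)
}

oracle_filter_nodes <- function(net, whitelist) {
  keep <- character()
  for (i in seq_len(nrow(net$edges))) {
    if (net$edges$a[i] %in% whitelist && net$edges$b[i] %in% whitelist) {
      keep <- c(keep, edge_key(net$edges$a[i], net$edges$b[i]))
    }
  }
  sort(keep)
}

# A random contextualization instance: annotated genes as network nodes,
# one sample, manual expression calls. Returns everything both the
# implementation and the oracle need.
rand_context_instance <- function(n_genes = 20L, n_edges = 40L,
                                  n_domains = 8L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  net <- rand_ppin(n_genes, n_edges, prefix = "g")
  n_tx <- sample(1:2, n_genes, replace = TRUE)
  tx_gene <- rep(genes, n_tx)
  tx_id <- unlist(lapply(seq_len(n_genes), function(i) {
    paste0(genes[i], ".t", seq_len(n_tx[i]))
  }))
  vocab <- sprintf("d%02d", seq_len(n_domains))
  domains <- lapply(tx_id, function(t) {
    k <- sample(0:2, 1L)
    if (k == 0L) character() else sample(vocab, k)
  })
  names(domains) <- tx_id
  ann <- annotation_set(tx_gene, tx_id, domains)
  n_pairs <- sample(0:10, 1L)
  ddi_pairs <- if (n_pairs == 0L) {
    data.frame(d1 = character(), d2 = character())
  } else {
    data.frame(d1 = sample(vocab, n_pairs, replace = TRUE),
               d2 = sample(vocab, n_pairs, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  ddi <- ddi_map(ddi_pairs$d1, ddi_pairs$d2)
  vals <- matrix(round(stats::runif(length(tx_id), 0, 5), 2), ncol = 1,
                 dimnames = list(tx_id, "s1"))
  vals[sample.int(length(vals), length(vals) %/% 3)] <- 0
  meta <- data.frame(sample = "s1", patient = "p1", condition = "tumor",
                     cohort = "X", stringsAsFactors = FALSE)
  expr <- expression_matrix(vals, meta)
  expressed <- matrix(stats::runif(n_genes) < 0.7, ncol = 1,
                      dimnames = list(genes, "s1"))
  calls <- expression_calls(expressed)
  list(net = net, ann = ann, ddi = ddi, ddi_pairs = ddi_pairs,
       expr = expr, calls = calls,
       genes = genes, tx_gene = tx_gene, tx_id = tx_id,
       domains = domains, expressed = expressed[, 1L])
}

# Literal re-implementation of the edge retention rule.
oracle_condition_edges <- function(inst, min_expr = 0.1) {
  pair_in <- function(x, y) {
    any((inst$ddi_pairs$d1 == x & inst$ddi_pairs$d2 == y) |
          (inst$ddi_pairs$d1 == y & inst$ddi_pairs$d2 == x))
  }
  sets_link <- function(s1, s2) {
    for (x in s1) for (y in s2) if (pair_in(x, y)) return(TRUE)
    FALSE
  }
  union_domains <- function(g) {
    out <- character()
    for (t in inst$tx_id[inst$tx_gene == g]) out <- c(out, inst$domains[[t]])
    unique(out)
  }
  major_domains <- function(g) {
    txs <- inst$tx_id[inst$tx_gene == g]
    v <- inst$expr$values[txs, "s1"]
    names(v) <- txs
    ok <- v[v >= min_expr]
    pool <- if (length(ok) > 0L) ok else v
    top <- sort(names(pool)[pool == max(pool)])[1L]
    inst$domains[[top]]
  }
  keep <- character()
  for (i in seq_len(nrow(inst$net$edges))) {
    a <- inst$net$edges$a[i]
    b <- inst$net$edges$b[i]
    if (!inst$expressed[[a]] || !inst$expressed[[b]]) next
    if (!sets_link(union_domains(a), union_domains(b))) {
      keep <- c(keep, edge_key(a, b))          # no evidence: fallback
    } else if (sets_link(major_domains(a), major_domains(b))) {
      keep <- c(keep, edge_key(a, b))
    }
  }
  sort(keep)
}

# Independent per-edge tally for cohort statistics.
oracle_edge_stats <- function(cohort) {
  np <- length(cohort$patients)
  out <- list()
  for (k in rownames(cohort$codes)) {
    row <- cohort$codes[k, ]
    out[[k]] <- c(n_gained = sum(row == "01"), n_lost = sum(row == "10"),
                  n_kept = sum(row == "11"), n_absent = sum(row == "00"),
                  perc_gained = 100 * sum(row == "01") / np,
                  perc_lost = 100 * sum(row == "10") / np)
  }
  out
}

# Independent straight-line version of the greedy ranking procedure.
oracle_rank_greedy <- function(net, perturbed) {
  nodes <- net$nodes
  nb <- lapply(nodes, function(v) {
    unique(c(net$edges$b[net$edges$a == v], net$edges$a[net$edges$b == v]))
  })
  names(nb) <- nodes
  pe <- do.call(rbind, strsplit(perturbed, "|", fixed = TRUE))
  incid <- function(v) perturbed[pe[, 1L] == v | pe[, 2L] == v]
  hood <- function(v) {
    s <- c(v, nb[[v]])
    perturbed[pe[, 1L] %in% s | pe[, 2L] %in% s]
  }
  I <- sapply(nodes, function(v) length(incid(v)))
  H <- sapply(nodes, function(v) length(hood(v)))
  deg <- sapply(nodes, function(v) length(nb[[v]]))
  elig <- nodes[deg >= 2 & I >= 1]
  elig <- elig[order(-I[elig], -H[elig], elig, method = "radix")]
  left <- perturbed
  got <- setNames(rep(0L, length(nodes)), nodes)
  for (v in elig) {
    s <- c(v, nb[[v]])
    le <- do.call(rbind, strsplit(left, "|", fixed = TRUE))
    if (is.null(le)) break
    take <- left[le[, 1L] %in% s | le[, 2L] %in% s]
    got[v] <- length(take)
    left <- setdiff(left, take)
  }
  for (e in left) {
    ends <- strsplit(e, "|", fixed = TRUE)[[1L]]
    ends <- ends[order(-I[ends], -H[ends], ends, method = "radix")]
    got[ends[1L]] <- got[ends[1L]] + 1L
  }
  rank <- got
  rank[I >= 1 & got == 0] <- 1L
  rank
}

# Ward.D2 agglomeration via the centroid/ESS closed form, with the same
# smallest-label tie-break as the implementation.
oracle_ward <- function(X) {
  labs <- rownames(X)
  clusters <- lapply(labs, identity)
  heights <- numeric(0)
  members <- list()
  ward_d <- function(ci, cj) {
    ni <- length(ci); nj <- length(cj)
    mi <- colMeans(X[ci, , drop = FALSE])
    mj <- colMeans(X[cj, , drop = FALSE])
    sqrt(2 * ni * nj / (ni + nj) * sum((mi - mj)^2))
  }
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- ward_d(clusters[[i]], clusters[[j]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])), method = "radix")
      cand <- list(d = d, i = i, j = j, key = key)
      if (is.null(best) || d < best$d - 1e-10 ||
          (abs(d - best$d) <= 1e-10 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- cand
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]),
                   method = "radix")
    heights <- c(heights, best$d)
    members[[length(members) + 1L]] <- merged
    clusters[[best$j]] <- NULL
    clusters[[best$i]] <- merged
  }
  list(heights = heights, members = members)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
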