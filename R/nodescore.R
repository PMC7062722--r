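# Node-level analysis: rewiring scores on the merged healthy/tumor
# network, the greedy neighbor-inclusive perturbation ranking, and the
# SMG (significantly mutated gene) association and enrichment tests.

check_perturbed <- function(net, perturbed) {
  perturbed <- unique(as.character(perturbed))
  missing <- setdiff(perturbed, edge_keys(net))
  if (length(missing) > 0L) {
    stop("perturbed edge(s) not in network: ",
         paste(missing, collapse = ", "))
  }
  perturbed
}

#' Node rewiring scores
#'
#' The rewiring score of a node is the fraction of its incident edges in
#' the merged (healthy-union-tumor) network that are perturbed. A node is
#' flagged as rewired when its score reaches 0.5 and it has at least two
#' interaction partners: a single perturbed edge on a degree-2 node means
#' half of its edges are perturbed, scoring exactly 0.5.
#'
#' @param merged A [ppin]: the union of a patient's (or cohort's) healthy
#'   and tumor networks.
#' @param perturbed Character vector of perturbed edge keys (subset of the
#'   merged network's edges).
#' @param nodes Nodes to score (default all; unknown nodes are an error).
#' @return Data.frame with columns `node`, `merged_degree`,
#'   `n_perturbed_incident`, `rewiring_score`, `rewired`.
#' @export
rewiring_score <- function(merged, perturbed, nodes = merged$nodes) {
  perturbed <- check_perturbed(merged, perturbed)
  deg <- node_degree(merged, nodes)
  pe <- edges_from_keys(perturbed)
  inc <- vapply(nodes, function(v) sum(pe$a == v | pe$b == v), integer(1))
  score <- ifelse(deg > 0L, inc / deg, 0)
  data.frame(
    node = nodes,
    merged_degree = as.integer(deg),
    n_perturbed_incident = as.integer(inc),
    rewiring_score = score,
    rewired = score >= 0.5 & deg >= 2L,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Greedy neighbor-inclusive perturbation ranking of nodes
#'
#' Ranks proteins by the number of perturbations they and their first
#' network neighbors are involved in, with exclusive attribution so that
#' each perturbed edge is credited to exactly one node:
#'
#' 1. For every node `v`, `I(v)` counts perturbed edges incident to `v`
#'    and `H(v)` counts perturbed edges incident to `v` or any neighbor.
#' 2. Eligible nodes (degree >= 2 and `I(v)` >= 1) are processed in order
#'    `I` descending, then `H` descending, then node id ascending.
#' 3. Each eligible node in turn is assigned every not-yet-attributed
#'    perturbed edge incident to it or a neighbor; its rank is the number
#'    assigned.
#' 4. A perturbed edge covered by no eligible node (for example an
#'    isolated perturbed edge between two degree-1 nodes) is attributed
#'    to its stronger endpoint (higher `I`, then higher `H`, then smaller
#'    id) so that attribution always partitions the perturbed edge set.
#' 5. Any node touching a perturbed edge that ends up with no assigned
#'    edges receives a participation rank of 1; untouched nodes rank 0.
#'
#' @param network A [ppin].
#' @param perturbed Character vector of perturbed edge keys.
#' @return Data.frame with columns `node`, `rank`, `n_attributed` and a
#'   list column `attributed_edges`; attribution partitions the perturbed
#'   edge set.
#' @export
rank_nodes_greedy <- function(network, perturbed) {
  perturbed <- check_perturbed(network, perturbed)
  nodes <- network$nodes
  adj <- adjacency_list(network)
  pe <- edges_from_keys(perturbed)
  incident <- function(v) perturbed[pe$a == v | pe$b == v]
  I <- vapply(nodes, function(v) length(incident(v)), integer(1))
  H <- vapply(nodes, function(v) {
    nb <- c(v, adj[[v]])
    sum(pe$a %in% nb | pe$b %in% nb)
  }, integer(1))
  deg <- node_degree(network)
  eligible <- nodes[deg >= 2L & I >= 1L]
  eligible <- eligible[order(-I[eligible], -H[eligible],
                             xtfrm_radix(eligible))]
  attributed <- rep(list(character()), length(nodes))
  names(attributed) <- nodes
  remaining <- perturbed
  for (v in eligible) {
    nb <- c(v, adj[[v]])
    re <- edges_from_keys(remaining)
    take <- remaining[re$a %in% nb | re$b %in% nb]
    if (length(take) > 0L) {
      attributed[[v]] <- take
      remaining <- setdiff(remaining, take)
    }
  }
  if (length(remaining) > 0L) {
    re <- edges_from_keys(remaining)
    for (idx in seq_along(remaining)) {
      ends <- c(re$a[idx], re$b[idx])
      ends <- ends[order(-I[ends], -H[ends], xtfrm_radix(ends))]
      v <- ends[1L]
      attributed[[v]] <- c(attributed[[v]], remaining[idx])
    }
  }
  n_attr <- lengths(attributed)
  rank <- n_attr
  rank[I >= 1L & n_attr == 0L] <- 1L
  data.frame(
    node = nodes,
    rank = as.integer(rank),
    n_attributed = as.integer(n_attr),
    attributed_edges = I(unname(attributed)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Classify edges by their relation to SMGs
#'
#' An edge is an SMG first neighbor when one endpoint is itself a
#' significantly mutated gene, an SMG second neighbor when an endpoint is
#' a network neighbor of an SMG, and SMG independent otherwise.
#'
#' @param edges Character vector of edge keys (or a two-column data.frame).
#' @param network A [ppin].
#' @param smgs Character vector of SMG node ids.
#' @return Data.frame with columns `key` and `smg_class`.
#' @export
smg_association <- function(edges, network, smgs) {
  if (is.data.frame(edges)) edges <- edge_key(edges[[1L]], edges[[2L]])
  ed <- edges_from_keys(edges)
  adj <- adjacency_list(network)
  smg_set <- intersect(smgs, network$nodes)
  nb_of_smg <- unique(c(smg_set,
                        unlist(adj[smg_set], use.names = FALSE)))
  first <- ed$a %in% smg_set | ed$b %in% smg_set
  second <- !first & (ed$a %in% nb_of_smg | ed$b %in% nb_of_smg)
  data.frame(
    key = edges,
    smg_class = ifelse(first, "smg_first_neighbor",
                       ifelse(second, "smg_second_neighbor",
                              "smg_independent")),
    stringsAsFactors = FALSE
  )
}

#' Degree-matched random node sample
#'
#' Draws, for each SMG present in the network, one non-SMG node of similar
#' degree (within `tolerance`, i.e. degree in
#' `[floor(d(1-tol)), ceiling(d(1+tol))]`), sampling without replacement
#' across the draw. When the band holds no candidate, the non-SMG node of
#' nearest degree is taken deterministically (ties by node id).
#'
#' @param network A [ppin].
#' @param smgs Character vector of SMG node ids.
#' @param tolerance Relative degree tolerance (default 0.10).
#' @return Character vector of matched node ids, one per SMG in the
#'   network.
#' @export
degree_matched_sample <- function(network, smgs, tolerance = 0.10) {
  smgs <- radix_sort(intersect(unique(smgs), network$nodes))
  candidates <- setdiff(network$nodes, smgs)
  if (length(candidates) == 0L) stop("all network nodes are SMGs")
  deg <- node_degree(network)
  out <- character(length(smgs))
  for (i in seq_along(smgs)) {
    d <- deg[[smgs[i]]]
    lo <- floor(d * (1 - tolerance))
    hi <- ceiling(d * (1 + tolerance))
    band <- candidates[deg[candidates] >= lo & deg[candidates] <= hi]
    if (length(band) > 0L) {
      pick <- band[sample.int(length(band), 1L)]
    } else {
      gap <- abs(deg[candidates] - d)
      pick <- radix_sort(candidates[gap == min(gap)])[1L]
    }
    out[i] <- pick
    candidates <- setdiff(candidates, pick)
    if (length(candidates) == 0L && i < length(smgs)) {
      stop("not enough non-SMG nodes to match all SMGs")
    }
  }
  out
}

chisq_2x2 <- function(tab) {
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}

#' SMG perturbation enrichment test
#'
#' Compares the proportion of perturbed edges among edges touching SMGs
#' against edges touching degree-matched random non-SMG nodes, with a
#' Pearson chi-squared test (no continuity correction, 1 df) on the 2x2
#' table. Because the matched set is random, the draw is repeated
#' `n_replicates` times; the median p-value and all replicates are
#' reported. An edge counts as perturbed when gained or lost in at least
#' `min_patients` patients of the cohort.
#'
#' @param stats An [edge_stats] table for the cohort.
#' @param network A [ppin] (the global or merged network the edges live in).
#' @param smgs Character vector of SMG node ids.
#' @param min_patients Perturbation threshold (default 2).
#' @param n_replicates Number of matched random draws (default 100).
#' @param tolerance Degree-matching tolerance passed to
#'   [degree_matched_sample].
#' @return List of class `smg_report`: `contingency` (first replicate's
#'   table), `chi2`, `p_value` (median over replicates), `p_replicates`,
#'   `degenerate` (fraction of replicates with a zero table margin, which
#'   score p = 1).
#' @export
smg_enrichment_test <- function(stats, network, smgs, min_patients = 2L,
                                n_replicates = 100L, tolerance = 0.10) {
  smg_set <- intersect(unique(smgs), network$nodes)
  perturbed <- stats$n_gained >= min_patients | stats$n_lost >= min_patients
  touch <- function(node_set) stats$a %in% node_set | stats$b %in% node_set
  row_for <- function(node_set) {
    t1 <- touch(node_set)
    c(perturbed = sum(t1 & perturbed), non_perturbed = sum(t1 & !perturbed))
  }
  smg_row <- row_for(smg_set)
  p_rep <- numeric(n_replicates)
  chi2_rep <- rep(NA_real_, n_replicates)
  first_tab <- NULL
  n_degenerate <- 0L
  for (r in seq_len(n_replicates)) {
    matched <- degree_matched_sample(network, smg_set, tolerance)
    tab <- rbind(smg = smg_row, matched = row_for(matched))
    if (is.null(first_tab)) first_tab <- tab
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p_rep[r] <- 1.0
      n_degenerate <- n_degenerate + 1L
    } else {
      ct <- chisq_2x2(tab)
      p_rep[r] <- ct$p.value
      chi2_rep[r] <- unname(ct$statistic)
    }
  }
  structure(
    list(contingency = first_tab,
         chi2 = chi2_rep[1L],
         p_value = stats::median(p_rep),
         p_replicates = p_rep,
         degenerate = n_degenerate / n_replicates),
    class = "smg_report"
  )
}

#' @export
print.smg_report <- function(x, ...) {
  cat("SMG enrichment: median p =", format(x$p_value, digits = 4),
      "over", length(x$p_replicates), "matched draws\n")
  print(x$contingency)
  invisible(x)
}
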