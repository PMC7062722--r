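# Canonical undirected edges and the global PPIN container.
#
# Edges are stored in canonical form: endpoint `a` precedes endpoint `b` in
# C-locale (byte) order, so that an undirected interaction has exactly one
# representation and edge sets can be compared as plain string sets.

radix_sort <- function(x) sort(x, method = "radix")

# Vectorized canonicalization. Byte order (radix) rather than locale
# collation, so results do not depend on LC_COLLATE.
canonicalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
    stop("edge endpoints must be non-empty strings")
  }
  lev <- radix_sort(unique(c(a, b)))
  ai <- match(a, lev)
  bi <- match(b, lev)
  swap <- ai > bi
  data.frame(
    a = ifelse(swap, b, a),
    b = ifelse(swap, a, b),
    self = ai == bi,
    stringsAsFactors = FALSE
  )
}

#' Canonical form of an undirected edge
#'
#' Orders the two endpoints of a protein-protein interaction so that every
#' undirected edge has a single representation (first endpoint smaller in
#' byte order). Self-loops are rejected: the perturbation codes downstream
#' are defined on distinct-endpoint edges only.
#'
#' @param u,v Node identifiers (single non-empty strings).
#' @return Character vector of length two, `c(a, b)` with `a < b`.
#' @examples
#' canonical_edge("B", "A")
#' @export
canonical_edge <- function(u, v) {
  if (length(u) != 1L || length(v) != 1L) {
    stop("u and v must be single node identifiers")
  }
  p <- canonicalize_pairs(u, v)
  if (p$self) stop("self-loop edge: '", u, "'")
  c(p$a, p$b)
}

#' Edge key string
#'
#' Collapses a canonical edge into a single `"a|b"` key used to index edge
#' sets and perturbation profiles.
#'
#' @param a Either the first endpoint, or a length-2 canonical edge.
#' @param b Second endpoint (omit when `a` is a length-2 edge).
#' @return Character vector of keys.
#' @export
edge_key <- function(a, b = NULL) {
  if (is.null(b)) {
    stopifnot(length(a) == 2L)
    b <- a[[2L]]
    a <- a[[1L]]
  }
  paste(a, b, sep = "|")
}

# Split keys back into a canonical two-column data.frame.
edges_from_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    a = vapply(parts, `[[`, character(1), 1L),
    b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' Construct a protein-protein interaction network
#'
#' A `ppin` is an undirected graph over opaque string node identifiers: a
#' deduplicated set of canonical edges plus the node set (the union of edge
#' endpoints and any isolated nodes supplied explicitly). The number of
#' edges is the network size.
#'
#' @param edges Two-column data.frame/matrix of endpoints, or `NULL` for an
#'   edgeless network.
#' @param nodes Optional additional (isolated) node identifiers.
#' @param drop_self_loops If `TRUE`, rows with identical endpoints are
#'   dropped with a warning; if `FALSE` (default) they are an error.
#' @return Object of class `ppin` with elements `nodes` (sorted character)
#'   and `edges` (canonical, deduplicated, sorted data.frame with columns
#'   `a`, `b`).
#' @examples
#' net <- ppin(data.frame(a = c("B", "A"), b = c("A", "C")))
#' ppin_size(net)
#' @export
ppin <- function(edges = NULL, nodes = NULL, drop_self_loops = FALSE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("edges must have two columns")
    p <- canonicalize_pairs(edges[[1L]], edges[[2L]])
    if (any(p$self)) {
      if (drop_self_loops) {
        warning(sum(p$self), " self-loop edge(s) dropped")
        p <- p[!p$self, , drop = FALSE]
      } else {
        stop("self-loop edge: '", p$a[p$self][1L], "'")
      }
    }
    key <- edge_key(p$a, p$b)
    p <- p[!duplicated(key), c("a", "b"), drop = FALSE]
    ed <- p[order(p$a, p$b, method = "radix"), , drop = FALSE]
    rownames(ed) <- NULL
  }
  all_nodes <- radix_sort(unique(c(ed$a, ed$b, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = ed), class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  cat("PPIN: ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Network size and edge keys
#'
#' `ppin_size()` returns the number of binary interactions in the network;
#' `edge_keys()` returns the canonical `"a|b"` key of every edge.
#'
#' @param net A `ppin`.
#' @return An integer count, or a character vector of keys.
#' @export
ppin_size <- function(net) nrow(net$edges)

#' @rdname ppin_size
#' @export
edge_keys <- function(net) edge_key(net$edges$a, net$edges$b)

#' Node degrees of a network
#'
#' @param net A `ppin`.
#' @param nodes Nodes to report (default all network nodes).
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(net, nodes = net$nodes) {
  cnt <- table(factor(c(net$edges$a, net$edges$b), levels = net$nodes))
  deg <- as.integer(cnt)
  names(deg) <- net$nodes
  if (any(!nodes %in% net$nodes)) {
    stop("unknown node(s): ", paste(setdiff(nodes, net$nodes), collapse = ", "))
  }
  deg[nodes]
}

# Named list: node -> character vector of neighbors.
adjacency_list <- function(net) {
  adj <- rep(list(character()), length(net$nodes))
  names(adj) <- net$nodes
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]
    b <- net$edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Restrict a network to a node whitelist
#'
#' Returns the induced subgraph on the whitelisted nodes: an edge is kept
#' if and only if both endpoints are on the whitelist. Used to restrict the
#' interactome to proteins with independent evidence of translation
#' (protein-abundance filtering).
#'
#' @param net A `ppin`.
#' @param whitelist Character vector of node identifiers to retain.
#' @return A `ppin` (empty whitelist gives an empty network).
#' @export
filter_nodes <- function(net, whitelist) {
  whitelist <- as.character(whitelist)
  keep <- net$edges$a %in% whitelist & net$edges$b %in% whitelist
  ppin(net$edges[keep, , drop = FALSE], nodes = intersect(net$nodes, whitelist))
}

#' Union of two networks
#'
#' Merges the node and edge sets of two networks; used to build the merged
#' healthy-plus-tumor network on which node rewiring scores are defined.
#'
#' @param x,y `ppin` objects.
#' @return A `ppin`.
#' @export
merge_networks <- function(x, y) {
  ppin(rbind(x$edges, y$edges), nodes = c(x$nodes, y$nodes))
}
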