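# Degree-preserving randomization of an undirected network by repeated
# double-edge swaps: two edges (a,b), (c,d) are replaced by (a,d), (c,b)
# (orientation chosen uniformly) whenever neither proposed edge is a
# self-loop or already present. Node degrees are exactly preserved.

#' Degree-preserving network randomization
#'
#' Randomizes a network by double-edge swaps until `n_swaps` swaps have
#' succeeded or the attempt budget (`max_attempts_factor` times the
#' target) is exhausted; in the latter case the current network is
#' returned with a warning and attribute `rewire_exhausted = TRUE`
#' (rigid graphs such as a triangle admit no valid swap and come back
#' unchanged). The node set and degree sequence are identical to the
#' input for every seed.
#'
#' @param network A [ppin] with at least 2 edges.
#' @param n_swaps Number of successful swaps, or `"auto"` for ten times
#'   the edge count.
#' @param max_attempts_factor Attempt budget multiplier (default 100).
#' @param seed Optional integer seed.
#' @return A randomized [ppin].
#' @export
degree_preserving_rewire <- function(network, n_swaps = "auto",
                                     max_attempts_factor = 100L,
                                     seed = NULL) {
  m <- ppin_size(network)
  if (m < 2L) stop("need at least 2 edges to rewire")
  if (identical(n_swaps, "auto")) n_swaps <- 10L * m
  n_swaps <- as.integer(n_swaps)
  stopifnot(n_swaps >= 0L)
  if (!is.null(seed)) set.seed(seed)
  a <- network$edges$a
  b <- network$edges$b
  present <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in edge_key(a, b)) assign(k, TRUE, envir = present)
  successes <- 0L
  attempts <- 0L
  budget <- max_attempts_factor * max(1L, n_swaps)
  exhausted <- FALSE
  while (successes < n_swaps) {
    if (attempts >= budget) {
      exhausted <- TRUE
      break
    }
    attempts <- attempts + 1L
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    # uniform orientation: either pair a_i with b_j, or a_i with a_j
    if (stats::runif(1) < 0.5) {
      n1 <- c(a[i], b[j]); n2 <- c(a[j], b[i])
    } else {
      n1 <- c(a[i], a[j]); n2 <- c(b[i], b[j])
    }
    if (n1[1L] == n1[2L] || n2[1L] == n2[2L]) next
    e1 <- canonical_edge(n1[1L], n1[2L])
    e2 <- canonical_edge(n2[1L], n2[2L])
    k1 <- edge_key(e1); k2 <- edge_key(e2)
    if (k1 == k2 ||
        exists(k1, envir = present) || exists(k2, envir = present)) next
    rm(list = c(edge_key(a[i], b[i]), edge_key(a[j], b[j])), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    a[i] <- e1[1L]; b[i] <- e1[2L]
    a[j] <- e2[1L]; b[j] <- e2[2L]
    successes <- successes + 1L
  }
  if (exhausted) {
    warning("attempt budget exhausted after ", successes,
            " successful swap(s)")
  }
  out <- ppin(data.frame(a = a, b = b, stringsAsFactors = FALSE),
              nodes = network$nodes)
  attr(out, "rewire_exhausted") <- exhausted
  attr(out, "n_swaps_done") <- successes
  out
}
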