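# Contextualization: reduce the global PPIN to one sample's
# condition-specific subnetwork at isoform/domain resolution.
#
# A gene counts as expressed in a sample when a two-component Gaussian
# mixture on pooled log2(gene abundance + 1) assigns its cell to the
# high-expression component; individual transcripts additionally need an
# abundance of at least `transcript_min_expr` (0.1 RSEM, inclusive). The
# domain content of a gene in a sample is that of its major (highest
# expressed) isoform. An edge survives contextualization when both
# endpoint genes are expressed and, where domain-domain interaction (DDI)
# evidence exists for the pair at all, the current major isoforms carry a
# linking domain pair; pairs without any possible DDI support fall back to
# co-expression.

#' Contextualization parameters
#'
#' @param transcript_min_expr Minimum transcript abundance (RSEM units) for
#'   an isoform to count as expressed; the boundary is inclusive. Default 0.1.
#' @param gmm_posterior_cut Posterior probability of the high-expression
#'   mixture component above which a gene is called expressed. Default 0.5.
#' @param gmm_floor Gene-level abundance floor (RSEM units) used when the
#'   mixture fit is unavailable or degenerate. Default 1.0.
#' @param gmm_max_iter,gmm_tol EM iteration cap and log-likelihood
#'   convergence tolerance.
#' @param seed Integer seed recorded with the configuration.
#' @return Object of class `context_config`.
#' @export
context_config <- function(transcript_min_expr = 0.1,
                           gmm_posterior_cut = 0.5,
                           gmm_floor = 1.0,
                           gmm_max_iter = 200L,
                           gmm_tol = 1e-6,
                           seed = 1L) {
  stopifnot(transcript_min_expr >= 0,
            gmm_posterior_cut > 0, gmm_posterior_cut < 1,
            gmm_floor >= 0, gmm_max_iter >= 1, gmm_tol > 0)
  structure(
    list(transcript_min_expr = transcript_min_expr,
         gmm_posterior_cut = gmm_posterior_cut,
         gmm_floor = gmm_floor,
         gmm_max_iter = as.integer(gmm_max_iter),
         gmm_tol = gmm_tol,
         seed = as.integer(seed)),
    class = "context_config"
  )
}

#' Gene-level abundance matrix
#'
#' Sums transcript values per gene. Transcripts absent from the annotation
#' are treated as single-isoform genes under their own identifier.
#'
#' @param expr An [expression_matrix].
#' @param annotations An [annotation_set].
#' @return Numeric matrix, genes by samples.
#' @export
gene_abundance <- function(expr, annotations) {
  g <- unname(annotations$gene_of_transcript[rownames(expr$values)])
  g[is.na(g)] <- rownames(expr$values)[is.na(g)]
  ab <- rowsum(expr$values, group = g, reorder = FALSE)
  ab[radix_sort(rownames(ab)), , drop = FALSE]
}

# Deterministic two-component EM on a numeric vector. Components returned
# with the higher-mean component second.
fit_gmm2 <- function(x, max_iter = 200L, tol = 1e-6) {
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  s0 <- max(stats::sd(x), 1e-3)
  if (!is.finite(s0)) s0 <- 1e-3
  sd2 <- c(s0, s0)
  w <- c(0.5, 0.5)
  if (mu[1] == mu[2]) {
    return(list(mu = mu, sd = sd2, w = w, converged = FALSE, degenerate = TRUE))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    g <- d2 / tot
    n2 <- sum(g)
    n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / length(x)
    mu <- c(sum((1 - g) * x) / n1, sum(g * x) / n2)
    sd2 <- pmax(sqrt(c(sum((1 - g) * (x - mu[1])^2) / n1,
                       sum(g * (x - mu[2])^2) / n2)), 1e-3)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sd2 <- rev(sd2); w <- rev(w)
  }
  degenerate <- abs(mu[2] - mu[1]) < 0.5 * max(sd2) || min(w) < 0.01
  list(mu = mu, sd = sd2, w = w, degenerate = degenerate)
}

gmm2_posterior_high <- function(fit, x) {
  d1 <- fit$w[1] * stats::dnorm(x, fit$mu[1], fit$sd[1])
  d2 <- fit$w[2] * stats::dnorm(x, fit$mu[2], fit$sd[2])
  tot <- d1 + d2
  out <- ifelse(tot < 1e-300, as.numeric(x > mean(fit$mu)), d2 / tot)
  out
}

#' Low-level expression call constructor
#'
#' Wraps a precomputed logical gene-by-sample matrix as an expression call
#' set, bypassing the mixture fit. Mainly useful for simulations and tests
#' where the expressed state is known.
#'
#' @param expressed Logical matrix, genes by samples.
#' @param method Label of the calling method.
#' @param threshold_used Log2-scale abundance threshold, if one applies.
#' @param fit Optional mixture fit parameters.
#' @return Object of class `expression_calls`.
#' @export
expression_calls <- function(expressed, method = "manual",
                             threshold_used = NA_real_, fit = NULL) {
  expressed <- as.matrix(expressed)
  stopifnot(is.logical(expressed))
  structure(
    list(expressed = expressed, method = method,
         threshold_used = threshold_used, fit = fit),
    class = "expression_calls"
  )
}

#' @export
print.expression_calls <- function(x, ...) {
  cat("ExpressionCallSet (", x$method, "): ", nrow(x$expressed), " genes x ",
      ncol(x$expressed), " samples, ",
      round(100 * mean(x$expressed), 1), "% expressed\n", sep = "")
  invisible(x)
}

#' Call genes expressed or not per sample
#'
#' Fits one two-component Gaussian mixture by EM on the pooled
#' `log2(gene abundance + 1)` values of the whole matrix (one fit per
#' cohort dataset), initialized at the 25th/75th percentiles with equal
#' weights. A gene is expressed in a sample when the posterior of the
#' higher-mean component exceeds `gmm_posterior_cut`. With fewer than 20
#' gene-by-sample observations, or when the fit degenerates (component
#' means closer than half the larger standard deviation, or a component
#' weight below 0.01), calling falls back to the abundance floor
#' `gmm_floor`.
#'
#' @param expr An [expression_matrix].
#' @param annotations An [annotation_set].
#' @param config A [context_config].
#' @return An [expression_calls] object covering every gene and sample of
#'   the matrix.
#' @export
fit_expression_calls <- function(expr, annotations,
                                 config = context_config()) {
  ab <- gene_abundance(expr, annotations)
  if (length(ab) == 0L) stop("empty expression matrix")
  x <- log2(ab + 1)
  if (length(x) < 20L) {
    return(expression_calls(ab >= config$gmm_floor, method = "floor",
                            threshold_used = log2(config$gmm_floor + 1)))
  }
  fit <- fit_gmm2(as.numeric(x), config$gmm_max_iter, config$gmm_tol)
  if (isTRUE(fit$degenerate)) {
    return(expression_calls(ab >= config$gmm_floor, method = "floor",
                            threshold_used = log2(config$gmm_floor + 1),
                            fit = fit))
  }
  post <- gmm2_posterior_high(fit, as.numeric(x))
  expressed <- matrix(post > config$gmm_posterior_cut,
                      nrow = nrow(x), dimnames = dimnames(x))
  thr <- tryCatch(
    stats::uniroot(function(v) gmm2_posterior_high(fit, v) -
                     config$gmm_posterior_cut,
                   lower = fit$mu[1], upper = fit$mu[2])$root,
    error = function(e) NA_real_)
  expression_calls(expressed, method = "gmm", threshold_used = thr, fit = fit)
}

# FALSE for genes outside the call matrix; error on unknown samples.
is_expressed <- function(calls, gene, sample) {
  if (!sample %in% colnames(calls$expressed)) {
    stop("unknown sample: '", sample, "'")
  }
  out <- rep(FALSE, length(gene))
  known <- gene %in% rownames(calls$expressed)
  out[known] <- calls$expressed[gene[known], sample]
  out
}

#' Expressed transcripts of one sample
#'
#' A transcript is expressed when its own abundance reaches
#' `transcript_min_expr` (inclusive) and its gene is called expressed.
#'
#' @param expr An [expression_matrix].
#' @param calls An [expression_calls].
#' @param sample Sample identifier.
#' @param annotations An [annotation_set].
#' @param config A [context_config].
#' @return Character vector of transcript ids.
#' @export
expressed_transcripts <- function(expr, calls, sample, annotations,
                                  config = context_config()) {
  if (!sample %in% colnames(expr$values)) {
    stop("unknown sample: '", sample, "'")
  }
  v <- expr$values[, sample]
  tx <- rownames(expr$values)
  g <- unname(annotations$gene_of_transcript[tx])
  g[is.na(g)] <- tx[is.na(g)]
  tx[v >= config$transcript_min_expr & is_expressed(calls, g, sample)]
}

#' Major-isoform domain state of one gene in one sample
#'
#' For an expressed gene, the major transcript is the expressed isoform
#' with the highest abundance (ties broken by the lexicographically
#' smallest transcript id); its domain set defines the gene's interaction
#' capability. If the gene is called expressed but no isoform reaches the
#' transcript cut, the highest-value isoform is taken as major. Genes with
#' no annotated transcripts behave as a single domain-free isoform.
#'
#' @param gene Gene identifier.
#' @param sample Sample identifier.
#' @param expr An [expression_matrix].
#' @param calls An [expression_calls].
#' @param annotations An [annotation_set].
#' @param config A [context_config].
#' @return List with `gene`, `sample`, `expressed`, `major_transcript`
#'   (`NA` when not expressed) and `domains`.
#' @export
domain_state <- function(gene, sample, expr, calls, annotations,
                         config = context_config()) {
  expressed <- is_expressed(calls, gene, sample)
  if (!expressed) {
    return(list(gene = gene, sample = sample, expressed = FALSE,
                major_transcript = NA_character_, domains = character()))
  }
  txs <- annotations$transcripts_of_gene[[gene]]
  if (is.null(txs) || length(txs) == 0L) {
    # unannotated gene: one virtual isoform without domains
    return(list(gene = gene, sample = sample, expressed = TRUE,
                major_transcript = NA_character_, domains = character()))
  }
  v <- rep(0, length(txs))
  names(v) <- txs
  present <- txs[txs %in% rownames(expr$values)]
  v[present] <- expr$values[present, sample]
  pass <- v[v >= config$transcript_min_expr]
  pool <- if (length(pass) > 0L) pass else v
  top <- radix_sort(names(pool)[pool == max(pool)])[1L]
  doms <- annotations$domains_of_transcript[[top]]
  if (is.null(doms)) doms <- character()
  list(gene = gene, sample = sample, expressed = TRUE,
       major_transcript = top, domains = doms)
}

# Domain states for many genes of one sample, as a named list.
domain_states <- function(genes, sample, expr, calls, annotations,
                          config = context_config()) {
  st <- lapply(genes, domain_state, sample = sample, expr = expr,
               calls = calls, annotations = annotations, config = config)
  names(st) <- genes
  st
}

# Union of domains over ALL annotated transcripts of each gene.
gene_domain_union <- function(annotations) {
  lapply(annotations$transcripts_of_gene, function(txs) {
    unique(unlist(annotations$domains_of_transcript[txs], use.names = FALSE))
  })
}

#' Per-edge DDI evidence of a network
#'
#' An edge has DDI evidence when some interacting domain pair links the
#' union of domains over all transcripts of one endpoint with that of the
#' other, i.e. some isoform combination could ever support the edge.
#'
#' @param global A [ppin].
#' @param annotations An [annotation_set].
#' @param ddi A [ddi_map].
#' @return Logical vector along the network's edges.
#' @export
edge_ddi_evidence <- function(global, annotations, ddi) {
  uni <- gene_domain_union(annotations)
  vapply(seq_len(nrow(global$edges)), function(i) {
    da <- uni[[global$edges$a[i]]]
    db <- uni[[global$edges$b[i]]]
    sets_interact(ddi, if (is.null(da)) character() else da,
                  if (is.null(db)) character() else db)
  }, logical(1))
}

# Core retention rule shared by contextualization and the synthetic truth
# table: both endpoints expressed, and where evidence exists the current
# domain sets must be linked by some DDI pair.
retained_edges <- function(global, ddi, expressed_genes, domains_of_gene,
                           evidence) {
  n <- nrow(global$edges)
  keep <- logical(n)
  reason <- character(n)
  expr_set <- expressed_genes
  for (i in seq_len(n)) {
    a <- global$edges$a[i]
    b <- global$edges$b[i]
    if (!(a %in% expr_set && b %in% expr_set)) next
    if (!evidence[i]) {
      keep[i] <- TRUE
      reason[i] <- "no_ddi_evidence_fallback"
    } else {
      da <- domains_of_gene[[a]]
      db <- domains_of_gene[[b]]
      if (sets_interact(ddi, if (is.null(da)) character() else da,
                        if (is.null(db)) character() else db)) {
        keep[i] <- TRUE
        reason[i] <- "ddi_supported"
      }
    }
  }
  data.frame(a = global$edges$a[keep], b = global$edges$b[keep],
             reason = reason[keep], stringsAsFactors = FALSE)
}

#' Build the condition-specific network of one sample
#'
#' Retains a global edge when both endpoint genes are expressed in the
#' sample and, if DDI evidence exists for the pair at all, some interacting
#' domain pair links the major isoforms' domain sets; edges whose endpoints
#' could never be linked by the DDI map are retained on co-expression alone
#' (`no_ddi_evidence_fallback`).
#'
#' @param global A [ppin] whose node ids coincide with gene ids.
#' @param annotations An [annotation_set].
#' @param ddi A [ddi_map].
#' @param expr An [expression_matrix].
#' @param calls An [expression_calls].
#' @param sample Sample identifier.
#' @param config A [context_config].
#' @param evidence Optional precomputed [edge_ddi_evidence] vector.
#' @return Object of class `condition_network`: `sample`, `patient`,
#'   `condition`, `cohort`, `edges` (data.frame `a`, `b`) and `reason`
#'   (retention reason per edge).
#' @export
build_condition_network <- function(global, annotations, ddi, expr, calls,
                                    sample, config = context_config(),
                                    evidence = NULL) {
  if (!sample %in% expr$meta$sample) stop("unknown sample: '", sample, "'")
  if (is.null(evidence)) {
    evidence <- edge_ddi_evidence(global, annotations, ddi)
  }
  expressed <- global$nodes[is_expressed(calls, global$nodes, sample)]
  states <- domain_states(expressed, sample, expr, calls, annotations, config)
  doms <- lapply(states, `[[`, "domains")
  ed <- retained_edges(global, ddi, expressed, doms, evidence)
  m <- expr$meta[expr$meta$sample == sample, ]
  structure(
    list(sample = sample, patient = m$patient[1L],
         condition = m$condition[1L], cohort = m$cohort[1L],
         edges = ed[, c("a", "b")], reason = ed$reason),
    class = "condition_network"
  )
}

#' @export
print.condition_network <- function(x, ...) {
  cat("ConditionNetwork [", x$sample, ", ", x$condition, "]: ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Contextualize every sample of a cohort
#'
#' Fits the expression calls once, precomputes per-edge DDI evidence once,
#' and builds one condition-specific network per sample of the matrix.
#'
#' @inheritParams build_condition_network
#' @return Named list of `condition_network` objects (by sample id), with
#'   the [expression_calls] attached as attribute `"calls"`.
#' @export
contextualize_cohort <- function(global, annotations, ddi, expr,
                                 config = context_config()) {
  calls <- fit_expression_calls(expr, annotations, config)
  evidence <- edge_ddi_evidence(global, annotations, ddi)
  nets <- lapply(expr$meta$sample, function(s) {
    build_condition_network(global, annotations, ddi, expr, calls, s,
                            config, evidence = evidence)
  })
  names(nets) <- expr$meta$sample
  attr(nets, "calls") <- calls
  nets
}

# ppin view of a condition network (for size tests and merging)
as_ppin <- function(x) {
  if (inherits(x, "ppin")) return(x)
  ppin(x$edges)
}
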