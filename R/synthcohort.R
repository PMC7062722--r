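# Synthetic data generator: global networks with gene/transcript/domain
# annotations and DDI support, paired healthy/tumor cohorts with planted
# perturbation events (gene silencing, gene activation, isoform switches
# that move DDI-bearing domains), per-patient noise and dropout, and full
# ground-truth tables computed by applying the package's own edge
# retention rule to the planted states.
#
# Planted DDI support uses gene-private anchor domains (one on the
# designated healthy-major isoform, and for switch genes one on the
# switch-target isoform) so that planted events have exactly the intended
# edgetic consequences; shared background domains carry no DDI pairs and
# only add annotation realism.

#' Synthetic cohort specification
#'
#' Defines the generator's study conditions: network size and model,
#' isoform and domain structure, DDI support density, cohort size, the
#' planted perturbation events, and the expression noise model
#' (log-normal baseline, multiplicative log-noise, dropout).
#'
#' @param n_genes,n_edges Global network size.
#' @param graph_model `"preferential_attachment"` or `"uniform_random"`.
#' @param transcripts_per_gene Integer range (length-2) of isoform counts.
#' @param n_domain_types Size of the shared background domain vocabulary.
#' @param ddi_support_fraction Fraction of global edges given DDI support;
#'   the remainder are retained on co-expression only.
#' @param n_patients Patients per cohort (one healthy/tumor pair each).
#' @param n_silenced,n_activated,n_switches Numbers of planted events when
#'   the explicit gene sets are `NULL`.
#' @param silenced_genes,activated_genes,switch_genes Optional explicit
#'   planted gene sets.
#' @param baseline_logmean,baseline_logsd Log-normal parameters of the
#'   expressed-gene abundance (RSEM-like units).
#' @param off_logmean,off_logsd,off_fraction Abundance level of
#'   non-expressed genes (capped below the transcript cut) and the
#'   fraction of genes kept off in both conditions.
#' @param minor_isoform_range Relative abundance range of non-major
#'   isoforms (keeps the major isoform dominant by a factor of 4 or more).
#' @param noise_sd Per-cell multiplicative log-noise standard deviation.
#' @param dropout_rate Probability of zeroing a non-planted transcript
#'   value.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_edges = 600L,
                           graph_model = c("preferential_attachment",
                                           "uniform_random"),
                           transcripts_per_gene = c(1L, 3L),
                           n_domain_types = 60L,
                           ddi_support_fraction = 0.7,
                           n_patients = 20L,
                           n_silenced = 10L, n_activated = 5L,
                           n_switches = 5L,
                           silenced_genes = NULL, activated_genes = NULL,
                           switch_genes = NULL,
                           baseline_logmean = log(100),
                           baseline_logsd = 0.5,
                           off_logmean = log(0.03), off_logsd = 0.5,
                           off_fraction = 0.3,
                           minor_isoform_range = c(0.05, 0.25),
                           noise_sd = 0.1, dropout_rate = 0.02,
                           seed = 1L) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_genes >= 2L, n_edges >= 1L,
            n_edges <= n_genes * (n_genes - 1) / 2,
            length(transcripts_per_gene) == 2L,
            transcripts_per_gene[1L] >= 1L,
            transcripts_per_gene[2L] >= transcripts_per_gene[1L],
            n_domain_types >= 1L,
            ddi_support_fraction >= 0, ddi_support_fraction <= 1,
            n_patients >= 1L,
            dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0,
            off_fraction >= 0, off_fraction < 1,
            max(minor_isoform_range) <= 0.25)
  structure(
    list(n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
         graph_model = graph_model,
         transcripts_per_gene = as.integer(transcripts_per_gene),
         n_domain_types = as.integer(n_domain_types),
         ddi_support_fraction = ddi_support_fraction,
         n_patients = as.integer(n_patients),
         n_silenced = as.integer(n_silenced),
         n_activated = as.integer(n_activated),
         n_switches = as.integer(n_switches),
         silenced_genes = silenced_genes,
         activated_genes = activated_genes,
         switch_genes = switch_genes,
         baseline_logmean = baseline_logmean,
         baseline_logsd = baseline_logsd,
         off_logmean = off_logmean, off_logsd = off_logsd,
         off_fraction = off_fraction,
         minor_isoform_range = minor_isoform_range,
         noise_sd = noise_sd, dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# simple undirected graph with an exact edge count over the gene names
simulate_graph <- function(genes, n_edges, model) {
  n <- length(genes)
  if (model == "uniform_random") {
    g <- igraph::sample_gnm(n, n_edges, directed = FALSE)
  } else {
    m0 <- max(1L, as.integer(round(n_edges / n)))
    g <- igraph::sample_pa(n, m = m0, directed = FALSE)
    g <- igraph::simplify(g)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  if (length(keys) > n_edges) {
    keys <- keys[sample.int(length(keys), n_edges)]
  } else if (length(keys) < n_edges) {
    all_pairs <- utils::combn(n, 2L)
    all_keys <- paste(all_pairs[1L, ], all_pairs[2L, ])
    avail <- setdiff(all_keys, keys)
    keys <- c(keys, sample(avail, n_edges - length(keys)))
  }
  ij <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  data.frame(a = genes[as.integer(ij[, 1L])],
             b = genes[as.integer(ij[, 2L])],
             stringsAsFactors = FALSE)
}

#' Simulate the global network, annotation and DDI map
#'
#' Generates the gene-level interaction graph, assigns each gene 1-3
#' isoforms with background domain content, selects the planted event
#' genes (silenced, activated, isoform switches) and the off-in-both
#' gene set, and constructs DDI support: a `ddi_support_fraction` of
#' edges get a domain pair linking the endpoints' healthy-major isoforms,
#' while each switch gene gets one designated incident "gain" edge whose
#' support runs through a domain carried only by the switch-target
#' isoform (so the edge appears upon the switch). Remaining edges carry
#' no DDI evidence and will be retained on co-expression alone.
#'
#' @param spec A [synthetic_spec].
#' @return Object of class `synthetic_global`: `network` ([ppin]),
#'   `annotations` ([annotation_set]), `ddi` ([ddi_map]) and `design`
#'   (planted sets, per-gene major/switch transcripts, off genes,
#'   supported and gain edge keys).
#' @export
simulate_global <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  ed <- simulate_graph(genes, spec$n_edges, spec$graph_model)
  network <- ppin(ed, nodes = genes)
  deg <- node_degree(network)
  adj <- adjacency_list(network)

  pick <- function(pool, n, what) {
    if (length(pool) < n) {
      stop("not enough candidate genes for planted ", what, " events")
    }
    if (n == 0L) character() else sample(pool, n)
  }
  connected <- genes[deg >= 1L]
  silenced <- spec$silenced_genes
  if (is.null(silenced)) silenced <- pick(connected, spec$n_silenced,
                                          "silencing")
  activated <- spec$activated_genes
  if (is.null(activated)) {
    activated <- pick(setdiff(connected, silenced), spec$n_activated,
                      "activation")
  }
  switch_genes <- spec$switch_genes
  if (is.null(switch_genes)) {
    pool2 <- setdiff(genes[deg >= 2L], c(silenced, activated))
    if (length(pool2) < spec$n_switches) {
      pool2 <- setdiff(connected, c(silenced, activated))
    }
    switch_genes <- pick(pool2, spec$n_switches, "isoform switch")
  }
  planted <- c(silenced, activated, switch_genes)
  if (anyDuplicated(planted)) {
    stop("planted gene sets must be disjoint")
  }
  stopifnot(all(planted %in% genes))
  n_off <- round(spec$off_fraction * spec$n_genes)
  off_genes <- pick(setdiff(genes, planted), n_off, "off-state")

  # isoforms: t1 is the designated healthy major; switch genes need >= 2
  tpg <- spec$transcripts_per_gene
  n_tx <- sample(seq(tpg[1L], tpg[2L]), spec$n_genes, replace = TRUE)
  names(n_tx) <- genes
  if (length(switch_genes) > 0L) {
    if (tpg[2L] < 2L) stop("isoform switches need transcripts_per_gene >= 2")
    n_tx[switch_genes] <- pmax(n_tx[switch_genes], 2L)
  }
  tx_gene <- rep(genes, n_tx)
  tx_id <- unlist(lapply(genes, function(g) {
    paste0(g, ".t", seq_len(n_tx[[g]]))
  }), use.names = FALSE)
  major_of_gene <- paste0(genes, ".t1")
  names(major_of_gene) <- genes
  switch_to <- paste0(switch_genes, ".t2")
  names(switch_to) <- switch_genes

  vocab <- sprintf("D%03d", seq_len(spec$n_domain_types))
  domains <- lapply(seq_along(tx_id), function(i) {
    k <- sample(0:2, 1L)
    if (k == 0L) character() else sample(vocab, k)
  })
  names(domains) <- tx_id

  # edge support: anchor domains are gene-private so planted events have
  # exactly the intended consequences and no accidental crosstalk
  keys <- edge_keys(network)
  n_support <- round(spec$ddi_support_fraction * length(keys))
  supported <- if (n_support > 0L) sample(keys, n_support) else character()
  gain_edges <- character(0)
  gain_gene <- character(0)
  for (g in switch_genes) {
    nbs <- adj[[g]]
    cand_keys <- edge_key(pmin_chr(g, nbs), pmax_chr(g, nbs))
    pref <- cand_keys[!nbs %in% c(planted, off_genes) &
                        !cand_keys %in% gain_edges]
    pool <- if (length(pref) > 0L) pref else
      cand_keys[!cand_keys %in% gain_edges]
    if (length(pool) == 0L) next
    ge <- pool[sample.int(length(pool), 1L)]
    gain_edges <- c(gain_edges, ge)
    gain_gene <- c(gain_gene, g)
    supported <- setdiff(supported, ge)
    # give the switch gene a supported (lost-on-switch) edge too
    others <- setdiff(cand_keys, ge)
    if (length(others) > 0L && !any(others %in% supported)) {
      supported <- c(supported, others[sample.int(length(others), 1L)])
    }
  }

  anchor_major <- function(g) paste0("AM.", g)
  anchor_switch <- function(g) paste0("AS.", g)
  d1 <- character(); d2 <- character()
  sup_ed <- edges_from_keys(supported)
  for (i in seq_len(nrow(sup_ed))) {
    a <- sup_ed$a[i]; b <- sup_ed$b[i]
    domains[[major_of_gene[[a]]]] <-
      unique(c(domains[[major_of_gene[[a]]]], anchor_major(a)))
    domains[[major_of_gene[[b]]]] <-
      unique(c(domains[[major_of_gene[[b]]]], anchor_major(b)))
    d1 <- c(d1, anchor_major(a)); d2 <- c(d2, anchor_major(b))
  }
  gain_ed <- edges_from_keys(gain_edges)
  for (i in seq_len(nrow(gain_ed))) {
    g <- gain_gene[i]
    nb <- setdiff(c(gain_ed$a[i], gain_ed$b[i]), g)
    domains[[switch_to[[g]]]] <-
      unique(c(domains[[switch_to[[g]]]], anchor_switch(g)))
    domains[[major_of_gene[[nb]]]] <-
      unique(c(domains[[major_of_gene[[nb]]]], anchor_major(nb)))
    d1 <- c(d1, anchor_switch(g)); d2 <- c(d2, anchor_major(nb))
  }

  annotations <- annotation_set(tx_gene, tx_id, domains[tx_id])
  ddi <- ddi_map(d1, d2)
  switch_events <- data.frame(
    gene = switch_genes,
    from = unname(major_of_gene[switch_genes]),
    to = unname(switch_to[switch_genes]),
    stringsAsFactors = FALSE
  )
  structure(
    list(network = network, annotations = annotations, ddi = ddi,
         design = list(
           genes = genes,
           major_of_gene = major_of_gene,
           off_genes = off_genes,
           silenced = silenced,
           activated = activated,
           switch_events = switch_events,
           gain_edges = gain_edges,
           supported_edges = supported)),
    class = "synthetic_global"
  )
}

#' @export
print.synthetic_global <- function(x, ...) {
  cat("Synthetic global: ", length(x$network$nodes), " genes, ",
      ppin_size(x$network), " edges; planted: ",
      length(x$design$silenced), " silenced, ",
      length(x$design$activated), " activated, ",
      nrow(x$design$switch_events), " switches\n", sep = "")
  invisible(x)
}

# Expected per-edge codes and causes under the planted states, computed
# with the package's own retention rule (an internal-consistency oracle).
truth_table <- function(global, silenced, activated, switch_events) {
  net <- global$network
  ann <- global$annotations
  ddi <- global$ddi
  des <- global$design
  genes <- des$genes
  expressed_h <- setdiff(genes, c(des$off_genes, activated))
  expressed_t <- setdiff(genes, c(des$off_genes, silenced))
  majors_h <- des$major_of_gene
  majors_t <- majors_h
  if (nrow(switch_events) > 0L) {
    majors_t[switch_events$gene] <- switch_events$to
  }
  evidence <- edge_ddi_evidence(net, ann, ddi)
  doms_for <- function(majors, expressed) {
    out <- lapply(majors[expressed], function(tx) {
      d <- ann$domains_of_transcript[[tx]]
      if (is.null(d)) character() else d
    })
    names(out) <- expressed
    out
  }
  eh <- retained_edges(net, ddi, expressed_h,
                       doms_for(majors_h, expressed_h), evidence)
  et <- retained_edges(net, ddi, expressed_t,
                       doms_for(majors_t, expressed_t), evidence)
  hk <- edge_key(eh$a, eh$b)
  tk <- edge_key(et$a, et$b)
  keys <- radix_sort(union(hk, tk))
  code <- rep(CODE_KEPT, length(keys))
  code[keys %in% setdiff(hk, tk)] <- CODE_LOST
  code[keys %in% setdiff(tk, hk)] <- CODE_GAINED
  ed <- edges_from_keys(keys)
  pert <- code != CODE_KEPT
  expr_genes <- c(silenced, activated)
  sw_genes <- switch_events$gene
  cause <- character(length(keys))
  switched <- character(length(keys))
  for (i in which(pert)) {
    ends <- c(ed$a[i], ed$b[i])
    if (any(ends %in% expr_genes)) {
      cause[i] <- "expression"
    } else {
      cause[i] <- "isoform_switch"
      switched[i] <- paste(intersect(ends, sw_genes), collapse = ",")
    }
  }
  structure(
    list(edge_codes = data.frame(key = keys, a = ed$a, b = ed$b,
                                 code = code, cause = cause,
                                 switched_endpoints = switched,
                                 stringsAsFactors = FALSE),
         silenced = silenced, activated = activated,
         switch_events = switch_events),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  tab <- table(x$edge_codes$code)
  cat("TruthTable: ", nrow(x$edge_codes), " edges (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Simulate a paired healthy/tumor cohort with planted events
#'
#' Draws, per patient, a healthy sample (expressed genes at log-normal
#' baseline with the designated major isoform dominant at least 4-fold;
#' off genes below the transcript cut) and a tumor sample where the
#' planted events are applied: silenced genes drop below both the
#' abundance floor and the transcript cut, activated genes switch on, and
#' isoform-switch genes move the dominant abundance to the switch-target
#' isoform. Per-cell multiplicative log-noise and dropout (never applied
#' to planted-event transcripts) follow. The accompanying truth table
#' holds the expected per-edge codes under the zero-noise states.
#'
#' @param global A [simulate_global] result.
#' @param spec The [synthetic_spec]; its planted gene sets must be among
#'   those prepared in `global` (defaults to the full prepared sets).
#' @param cohort Cohort label used in sample ids and metadata.
#' @param seed Integer seed (default derived from the spec seed).
#' @return List of class `synthetic_cohort`: `expr`
#'   ([expression_matrix]), `truth` (`truth_table`), `cohort`.
#' @export
simulate_cohort <- function(global, spec, cohort = "C1", seed = NULL) {
  stopifnot(inherits(global, "synthetic_global"),
            inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  des <- global$design
  silenced <- if (is.null(spec$silenced_genes)) des$silenced else
    spec$silenced_genes
  activated <- if (is.null(spec$activated_genes)) des$activated else
    spec$activated_genes
  sw_genes <- if (is.null(spec$switch_genes)) des$switch_events$gene else
    spec$switch_genes
  bad <- c(setdiff(silenced, des$silenced),
           setdiff(activated, des$activated),
           setdiff(sw_genes, des$switch_events$gene))
  if (length(bad) > 0L) {
    stop("planted gene(s) not prepared in the global design: ",
         paste(bad, collapse = ", "))
  }
  switch_events <- des$switch_events[des$switch_events$gene %in% sw_genes, ,
                                     drop = FALSE]
  ann <- global$annotations
  genes <- des$genes
  tx_of <- ann$transcripts_of_gene
  all_tx <- unlist(tx_of, use.names = FALSE)
  off_state <- function(n) {
    pmin(stats::rlnorm(n, spec$off_logmean, spec$off_logsd), 0.095)
  }
  expressed_draw <- function(g, major_tx) {
    txs <- tx_of[[g]]
    major <- stats::rlnorm(1, spec$baseline_logmean, spec$baseline_logsd)
    v <- major * stats::runif(length(txs), spec$minor_isoform_range[1L],
                              spec$minor_isoform_range[2L])
    names(v) <- txs
    v[major_tx] <- major
    v
  }
  majors_t <- des$major_of_gene
  majors_t[switch_events$gene] <- switch_events$to
  off_h <- c(des$off_genes, activated)
  off_t <- c(des$off_genes, silenced)

  np <- spec$n_patients
  patients <- sprintf("%s.P%02d", cohort, seq_len(np))
  sample_h <- paste0(patients, ".H")
  sample_t <- paste0(patients, ".T")
  vals <- matrix(0, nrow = length(all_tx), ncol = 2L * np,
                 dimnames = list(all_tx, c(rbind(sample_h, sample_t))))
  for (p in seq_len(np)) {
    for (g in genes) {
      txs <- tx_of[[g]]
      vals[txs, sample_h[p]] <- if (g %in% off_h) off_state(length(txs)) else
        expressed_draw(g, des$major_of_gene[[g]])
      vals[txs, sample_t[p]] <- if (g %in% off_t) off_state(length(txs)) else
        expressed_draw(g, majors_t[[g]])
    }
  }
  if (spec$noise_sd > 0) {
    vals <- vals * exp(stats::rnorm(length(vals), 0, spec$noise_sd))
  }
  if (spec$dropout_rate > 0) {
    planted_tx <- unlist(tx_of[c(silenced, activated, sw_genes)],
                         use.names = FALSE)
    mask <- matrix(stats::runif(length(vals)) < spec$dropout_rate,
                   nrow = nrow(vals))
    mask[rownames(vals) %in% planted_tx, ] <- FALSE
    vals[mask] <- 0
  }
  meta <- data.frame(
    sample = c(rbind(sample_h, sample_t)),
    patient = rep(patients, each = 2L),
    condition = rep(c("healthy", "tumor"), np),
    cohort = cohort,
    stage = NA_character_,
    stringsAsFactors = FALSE
  )
  expr <- expression_matrix(vals, meta)
  truth <- truth_table(global, silenced, activated, switch_events)
  structure(list(expr = expr, truth = truth, cohort = cohort, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort [", x$cohort, "]: ", sep = "")
  print(x$expr)
  invisible(x)
}

#' Simulate a multi-cohort design with shared and private perturbations
#'
#' Generates one global network and several cohorts organized into
#' groups: all cohorts share a small multi-cancer event set, cohorts of a
#' group share a group event set (the clustering signal), and each cohort
#' adds private events. All events are gene silencings, producing strict
#' edge losses at zero noise. The returned design matrix is the ground
#' truth for feature-matrix and clustering tests.
#'
#' @param spec Base [synthetic_spec] (network/expression parameters; its
#'   planted counts are ignored).
#' @param n_groups Number of cohort groups (>= 2 for clustering tests).
#' @param cohorts_per_group Cohorts per group; with fewer than 2 a
#'   warning is given since clusters cannot be validated.
#' @param n_shared_events Silenced genes shared by every cohort.
#' @param n_group_events Silenced genes shared within each group.
#' @param n_private_events Silenced genes private to each cohort.
#' @param n_patients Patients per cohort.
#' @param seed Integer seed (default the spec seed).
#' @return List of class `multicancer_sim`: `global`, `cohorts` (named
#'   list of `synthetic_cohort`), `groups` (named character cohort ->
#'   group), `design` (binary cohorts x expected-feature matrix) and
#'   `event_sets`.
#' @export
simulate_multicancer <- function(spec, n_groups = 2L, cohorts_per_group = 3L,
                                 n_shared_events = 5L, n_group_events = 30L,
                                 n_private_events = 2L, n_patients = 4L,
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), n_groups >= 2L)
  if (cohorts_per_group < 2L) {
    warning("fewer than 2 cohorts per group: cluster recovery cannot be ",
            "assessed on this design")
  }
  n_cohorts <- n_groups * cohorts_per_group
  total <- n_shared_events + n_groups * n_group_events +
    n_cohorts * n_private_events
  gspec <- spec
  gspec$n_silenced <- as.integer(total)
  gspec$n_activated <- 0L
  gspec$n_switches <- 0L
  gspec$silenced_genes <- NULL
  gspec$activated_genes <- character()
  gspec$switch_genes <- character()
  gspec$seed <- as.integer(seed)
  global <- simulate_global(gspec)
  pool <- global$design$silenced
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  shared <- take(n_shared_events)
  group_sets <- lapply(seq_len(n_groups), function(i) take(n_group_events))
  names(group_sets) <- paste0("grp", seq_len(n_groups))
  cohort_labels <- unlist(lapply(seq_len(n_groups), function(i) {
    paste0("grp", i, ".c", seq_len(cohorts_per_group))
  }), use.names = FALSE)
  groups <- rep(names(group_sets), each = cohorts_per_group)
  names(groups) <- cohort_labels
  cohorts <- vector("list", n_cohorts)
  names(cohorts) <- cohort_labels
  for (k in seq_len(n_cohorts)) {
    private <- take(n_private_events)
    cspec <- spec
    cspec$n_patients <- as.integer(n_patients)
    cspec$silenced_genes <- c(shared, group_sets[[groups[k]]], private)
    cspec$activated_genes <- character()
    cspec$switch_genes <- character()
    cohorts[[k]] <- simulate_cohort(global, cspec, cohort = cohort_labels[k],
                                    seed = as.integer(seed) + 100L + k)
  }
  feat_of <- function(truth) {
    ec <- truth$edge_codes
    pert <- ec$code %in% c(CODE_GAINED, CODE_LOST)
    paste0(ec$key[pert], ":",
           ifelse(ec$code[pert] == CODE_GAINED, "gain", "loss"))
  }
  feats <- lapply(cohorts, function(co) feat_of(co$truth))
  all_feats <- radix_sort(unique(unlist(feats, use.names = FALSE)))
  design <- matrix(0L, nrow = n_cohorts, ncol = length(all_feats),
                   dimnames = list(cohort_labels, all_feats))
  for (k in seq_len(n_cohorts)) design[k, feats[[k]]] <- 1L
  structure(
    list(global = global, cohorts = cohorts, groups = groups,
         design = design,
         event_sets = list(shared = shared, group = group_sets)),
    class = "multicancer_sim"
  )
}

#' @export
print.multicancer_sim <- function(x, ...) {
  cat("Multi-cohort simulation: ", length(x$cohorts), " cohorts in ",
      length(unique(x$groups)), " groups; ", ncol(x$design),
      " expected features\n", sep = "")
  invisible(x)
}
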