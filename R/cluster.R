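# Cohort clustering by perturbation signatures: binary feature matrices,
# Ward.D2 agglomeration with a fixed tie-break, multiscale bootstrap
# support (AU/BP), cluster-defining features and permutation importance.

#' Binary perturbation feature matrix over cohorts
#'
#' One row per cohort; one column per perturbed (edge, direction) feature,
#' named `"a|b:gain"` / `"a|b:loss"`. A cell is 1 when the edge-direction
#' is a cancer-type perturbation (perturbed in at least `min_patients`
#' patients) in that cohort. Gains and losses can be used separately or
#' concatenated. All-zero columns are dropped.
#'
#' @param profiles Named list (by cohort) of [cohort_profile] objects or
#'   [edge_stats] tables.
#' @param mode `"gain"`, `"loss"` or `"both"`.
#' @param min_patients Cancer-type perturbation threshold (default 2).
#' @return Object of class `feature_matrix`: a binary matrix `values`
#'   (cohorts x features) plus `mode` and `min_patients`.
#' @export
build_feature_matrix <- function(profiles, mode = c("both", "gain", "loss"),
                                 min_patients = 2L) {
  mode <- match.arg(mode)
  if (length(profiles) < 2L) stop("need at least 2 cohorts to build features")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be named by cohort label")
  }
  stats_list <- lapply(profiles, function(p) {
    if (inherits(p, "cohort_profile")) edge_stats(p) else p
  })
  dirs <- switch(mode, gain = "gain", loss = "loss", both = c("gain", "loss"))
  blocks <- lapply(dirs, function(dir) {
    col <- if (dir == "gain") "n_gained" else "n_lost"
    feats <- radix_sort(unique(unlist(lapply(stats_list, function(st) {
      st$key[st[[col]] >= min_patients]
    }), use.names = FALSE)))
    m <- matrix(0L, nrow = length(stats_list), ncol = length(feats),
                dimnames = list(names(stats_list),
                                if (length(feats)) paste0(feats, ":", dir)))
    for (i in seq_along(stats_list)) {
      st <- stats_list[[i]]
      hit <- st$key[st[[col]] >= min_patients]
      m[i, match(paste0(hit, ":", dir), colnames(m))] <- 1L
    }
    m
  })
  values <- do.call(cbind, blocks)
  dropped <- colSums(values) == 0L
  if (any(dropped)) {
    message(sum(dropped), " all-zero feature column(s) dropped")
    values <- values[, !dropped, drop = FALSE]
  }
  structure(list(values = values, mode = mode,
                 min_patients = as.integer(min_patients)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("FeatureMatrix (", x$mode, "): ", nrow(x$values), " cohorts x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

# Ward.D2 agglomeration (Lance-Williams on squared Euclidean distances,
# heights on the distance scale as in the R "ward.D2" convention).
# Deterministic tie-break: among minimal-distance pairs, the pair whose
# smallest-member labels sort first.
ward_engine <- function(X) {
  n <- nrow(X)
  labs <- rownames(X)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  stopifnot(n >= 2L)
  D2 <- as.matrix(stats::dist(X))^2
  diag(D2) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  cid <- -seq_len(n)             # hclust-style cluster codes per slot
  rep_lab <- labs                # smallest member label per slot
  members <- lapply(labs, identity)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merged_members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D2[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    cand <- which(sub <= mn + 1e-12 * max(1, abs(mn)), arr.ind = TRUE)
    # tie-break on the sorted pair of representative labels
    keys_a <- pmin_chr(rep_lab[idx[cand[, 1L]]], rep_lab[idx[cand[, 2L]]])
    keys_b <- pmax_chr(rep_lab[idx[cand[, 1L]]], rep_lab[idx[cand[, 2L]]])
    pick <- order(xtfrm_radix(keys_a), xtfrm_radix(keys_b))[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    height[s] <- sqrt(D2[i, j])
    merge[s, ] <- sort(c(cid[i], cid[j]))
    merged_members[[s]] <- radix_sort(c(members[[i]], members[[j]]))
    # Lance-Williams update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0L) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * D2[i, others] + (nj + nk) * D2[j, others] -
                 nk * D2[i, j]) / (ni + nj + nk)
      D2[i, others] <- newd
      D2[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    cid[i] <- s
    rep_lab[i] <- pmin_chr(rep_lab[i], rep_lab[j])
    members[[i]] <- merged_members[[s]]
  }
  list(merge = merge, height = height, labels = labs,
       members = merged_members)
}

# leaf order for hclust compatibility
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(k) {
    if (k < 0L) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' Ward.D2 hierarchical clustering of a binary feature matrix
#'
#' Agglomerative clustering with the Ward.D2 criterion on Euclidean
#' distances between cohort rows (distances, not squared, as in the R
#' `"ward.D2"` convention), with a deterministic tie-break (merge the
#' minimal-distance pair whose smallest member labels sort first) so the
#' result is invariant to row order.
#'
#' @param x A [build_feature_matrix] result or a binary matrix with
#'   rownames.
#' @return Object of class `ward_dendrogram`: hclust-style `merge` and
#'   `height`, `labels`, and `members` (the membership set of every
#'   internal cluster).
#' @export
hclust_ward <- function(x) {
  X <- fm_values(x)
  if (!all(X %in% c(0, 1))) stop("feature values must be binary (0/1)")
  if (nrow(X) < 2L) stop("need at least 2 objects to cluster")
  e <- ward_engine(X)
  structure(e, class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("Ward.D2 dendrogram over ", length(x$labels), " objects; ",
      "merge heights: ", paste(format(x$height, digits = 3),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert to a base hclust object
#'
#' @param x A `ward_dendrogram`.
#' @return A `stats::hclust` object (plottable, cuttable with
#'   [stats::cutree]).
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "ward_dendrogram"))
  structure(
    list(merge = x$merge, height = x$height, order = hclust_order(x$merge),
         labels = x$labels, method = "ward.D2",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Cut a dendrogram into k groups
#'
#' @param x A `ward_dendrogram`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_dendrogram <- function(x, k) stats::cutree(as_hclust(x), k = k)

#' Write a dendrogram as a newick tree
#'
#' Branch lengths derive from merge heights.
#'
#' @param x A `ward_dendrogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(ape::as.phylo(as_hclust(x)), file = path)
  invisible(path)
}

cluster_set_ids <- function(members) {
  vapply(members, paste, character(1), collapse = "\r")
}

#' Multiscale bootstrap support for dendrogram clusters
#'
#' Estimates, for every internal cluster of the Ward.D2 dendrogram, a
#' bootstrap probability (BP, plain resampling at scale 1) and an
#' approximately unbiased p-value (AU) from multiscale bootstrap
#' resampling: at each scale `r`, `B` replicates resample
#' `ceiling(n_features * r)` feature columns with replacement and the
#' clustering is recomputed; a cluster is recovered when an identical
#' membership set appears in the replicate. Per-scale recovery
#' frequencies `BP_r` (clipped to `[1/(2B), 1 - 1/(2B)]`) are fitted by
#' weighted least squares as
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` (weights inverse to the
#' delta-method variance of the probit-transformed frequency) and
#' `AU = 1 - pnorm(v - c)`. Only informative scales (frequency strictly
#' between 0 and 1) constrain the fit; clusters recovered always or never
#' at nearly every scale have no curvature information, so their AU falls
#' back to the plain recovery frequency at scale 1 with a
#' `degenerate_fit` flag. The root cluster is always recovered and has
#' BP = AU = 1.
#'
#' @param x A [build_feature_matrix] result or binary matrix.
#' @param dendrogram Optional precomputed [hclust_ward] result.
#' @param scales Resampling scales (default ten values 0.5 to 1.4).
#' @param B Bootstrap replicates per scale (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `cluster_support`: a data.frame `support` with
#'   columns `cluster`, `size`, `members`, `bp`, `au`, `v`, `c`,
#'   `fit_flag`, plus `bp_table` (clusters x scales recovery frequencies),
#'   `scales`, `B` and the `dendrogram`.
#' @export
multiscale_bootstrap <- function(x, dendrogram = NULL,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000L, seed = NULL) {
  stopifnot(B >= 10L, length(scales) >= 2L, all(scales > 0))
  if (!is.null(seed)) set.seed(seed)
  X <- fm_values(x)
  if (is.null(dendrogram)) dendrogram <- hclust_ward(x)
  orig_ids <- cluster_set_ids(dendrogram$members)
  nf <- ncol(X)
  nc <- length(orig_ids)
  counts <- matrix(0L, nrow = nc, ncol = length(scales),
                   dimnames = list(NULL, format(scales)))
  for (si in seq_along(scales)) {
    m <- max(1L, as.integer(ceiling(nf * scales[si])))
    for (b in seq_len(B)) {
      cols <- sample.int(nf, m, replace = TRUE)
      rep_ids <- cluster_set_ids(ward_engine(X[, cols, drop = FALSE])$members)
      counts[, si] <- counts[, si] + as.integer(orig_ids %in% rep_ids)
    }
  }
  freq <- counts / B
  clip <- function(p) pmin(pmax(p, 1 / (2 * B)), 1 - 1 / (2 * B))
  r1 <- which.min(abs(scales - 1))
  sq <- sqrt(scales)
  design <- cbind(v = sq, c = 1 / sq)
  au <- bp <- vv <- cc <- numeric(nc)
  flag <- character(nc)
  root <- which(lengths(dendrogram$members) == length(dendrogram$labels))
  for (k in seq_len(nc)) {
    bp[k] <- clip(freq[k, r1])
    if (k %in% root) {
      au[k] <- 1; bp[k] <- 1; vv[k] <- NA_real_; cc[k] <- NA_real_
      flag[k] <- "root"
      next
    }
    # only scales where the recovery frequency is informative constrain
    # the signed-distance/curvature fit; a cluster recovered always (or
    # never) at nearly every scale gives a singular fit and falls back to
    # its plain recovery frequency at scale 1
    use <- counts[k, ] > 0L & counts[k, ] < B
    if (sum(use) < 2L) {
      au[k] <- freq[k, r1]
      vv[k] <- NA_real_; cc[k] <- NA_real_
      flag[k] <- "degenerate_fit"
      next
    }
    bpr <- clip(freq[k, use])
    z <- stats::qnorm(1 - bpr)
    wts <- B * stats::dnorm(z)^2 / (bpr * (1 - bpr))
    fit <- tryCatch(stats::lm.wfit(design[use, , drop = FALSE], z, wts),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients) ||
        any(!is.finite(fit$coefficients))) {
      au[k] <- bp[k]
      vv[k] <- NA_real_; cc[k] <- NA_real_
      flag[k] <- "degenerate_fit"
    } else {
      vv[k] <- fit$coefficients[["v"]]
      cc[k] <- fit$coefficients[["c"]]
      au[k] <- 1 - stats::pnorm(vv[k] - cc[k])
      flag[k] <- ""
    }
  }
  support <- data.frame(
    cluster = seq_len(nc),
    size = lengths(dendrogram$members),
    members = vapply(dendrogram$members, paste, character(1),
                     collapse = "+"),
    bp = bp, au = au, v = vv, c = cc, fit_flag = flag,
    stringsAsFactors = FALSE
  )
  structure(
    list(support = support, bp_table = freq, scales = scales, B = B,
         dendrogram = dendrogram),
    class = "cluster_support"
  )
}

#' @export
print.cluster_support <- function(x, ...) {
  cat("Cluster support (B = ", x$B, ", ", length(x$scales),
      " scales):\n", sep = "")
  print(x$support[, c("cluster", "size", "members", "bp", "au")],
        row.names = FALSE)
  invisible(x)
}

#' Clusters passing an AU support threshold
#'
#' @param support A [multiscale_bootstrap] result.
#' @param au_min Minimum AU value (default 0.95, the usual selection rule).
#' @return Named list of member character vectors.
#' @export
supported_clusters <- function(support, au_min = 0.95) {
  sel <- support$support$au >= au_min
  out <- support$dendrogram$members[sel]
  names(out) <- support$support$members[sel]
  out
}

#' Features defining a cluster
#'
#' A feature defines a cluster exclusively when it is 1 for every member
#' and 0 for every non-member; the inclusive list only requires 1 for
#' every member (edges perturbed across all cohorts of the cluster).
#'
#' @param x A [build_feature_matrix] result or binary matrix.
#' @param clusters List of character vectors of member labels.
#' @return Named list (one element per cluster) of lists with `exclusive`
#'   and `inclusive` feature-id vectors.
#' @export
cluster_defining_edges <- function(x, clusters) {
  X <- fm_values(x)
  lapply(clusters, function(cl) {
    unknown <- setdiff(cl, rownames(X))
    if (length(unknown) > 0L) {
      stop("unknown object label(s): ", paste(unknown, collapse = ", "))
    }
    inside <- rownames(X) %in% cl
    all_in <- colSums(X[inside, , drop = FALSE]) == sum(inside)
    none_out <- colSums(X[!inside, , drop = FALSE]) == 0L
    list(exclusive = colnames(X)[all_in & none_out],
         inclusive = colnames(X)[all_in])
  })
}

#' Permutation importance of perturbation features
#'
#' Fits a bagged-trees classifier (a random forest with `mtry` equal to
#' the number of features) predicting the cluster labels from the binary
#' feature matrix, then scores every feature by the mean drop in
#' whole-sample prediction accuracy over `n_perm` within-column
#' permutations. Constant features score 0; ties rank by feature id.
#'
#' @param x A [build_feature_matrix] result or binary matrix.
#' @param labels Cluster assignment covering all rows (vector or named
#'   vector by row label); at least two classes.
#' @param n_trees Trees in the ensemble (default 200).
#' @param n_perm Permutations per feature (default 50).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `feature`, `importance`, `rank`,
#'   sorted by decreasing importance.
#' @export
permutation_importance <- function(x, labels, n_trees = 200L, n_perm = 50L,
                                   seed = NULL) {
  X <- fm_values(x)
  if (!is.null(names(labels))) labels <- labels[rownames(X)]
  stopifnot(length(labels) == nrow(X))
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two label classes")
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(X)))  # syntactic names for rf
  rf <- randomForest::randomForest(x = df, y = y, ntree = n_trees,
                                   mtry = ncol(df))
  base_acc <- mean(predict(rf, df) == y)
  imp <- numeric(ncol(df))
  n <- nrow(df)
  for (j in seq_len(ncol(df))) {
    big <- df[rep(seq_len(n), n_perm), , drop = FALSE]
    for (p in seq_len(n_perm)) {
      rows <- (p - 1L) * n + seq_len(n)
      big[rows, j] <- df[[j]][sample.int(n)]
    }
    pred <- predict(rf, big)
    acc <- vapply(seq_len(n_perm), function(p) {
      mean(pred[(p - 1L) * n + seq_len(n)] == y)
    }, numeric(1))
    imp[j] <- base_acc - mean(acc)
  }
  out <- data.frame(feature = colnames(X), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, xtfrm_radix(out$feature)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
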