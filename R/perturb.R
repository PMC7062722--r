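# Paired-network comparison into perturbation profiles, cohort
# aggregation, scope classification and cause attribution.
#
# Edge codes follow the two-character healthy/tumor presence convention:
#   "10" lost (healthy only), "01" gained (tumor only), "11" kept,
#   "00" absent (cohort level only, for edges unobserved in a patient).

CODE_LOST <- "10"
CODE_GAINED <- "01"
CODE_KEPT <- "11"
CODE_ABSENT <- "00"

#' Perturbation profile of one patient
#'
#' Compares the paired healthy and tumor condition networks of a patient:
#' edges present only in the healthy network are lost (`"10"`), edges
#' present only in the tumor network are gained (`"01"`), edges in both are
#' kept (`"11"`). The profile's domain is the union of the two edge sets,
#' so the absent code never occurs at patient level.
#'
#' @param healthy,tumor `condition_network` objects (or `ppin`s plus
#'   explicit ids) for the same patient.
#' @param patient,cohort Optional overrides when passing plain networks.
#' @return Object of class `patient_profile` with `patient`, `cohort` and
#'   `codes` (named character vector keyed by edge key).
#' @export
diff_networks <- function(healthy, tumor, patient = NULL, cohort = NULL) {
  get_field <- function(x, f, fallback) {
    if (inherits(x, "condition_network")) x[[f]] else fallback
  }
  cond_h <- get_field(healthy, "condition", "healthy")
  cond_t <- get_field(tumor, "condition", "tumor")
  if (!identical(cond_h, "healthy") || !identical(cond_t, "tumor")) {
    stop("diff_networks expects a healthy and a tumor network, in that order")
  }
  p_h <- get_field(healthy, "patient", patient)
  p_t <- get_field(tumor, "patient", patient)
  if (!is.null(p_h) && !is.null(p_t) && !identical(p_h, p_t)) {
    stop("mismatched patient ids: '", p_h, "' vs '", p_t, "'")
  }
  hk <- edge_key(healthy$edges$a, healthy$edges$b)
  tk <- edge_key(tumor$edges$a, tumor$edges$b)
  keys <- radix_sort(union(hk, tk))
  codes <- rep(CODE_KEPT, length(keys))
  names(codes) <- keys
  codes[setdiff(hk, tk)] <- CODE_LOST
  codes[setdiff(tk, hk)] <- CODE_GAINED
  structure(
    list(patient = if (is.null(p_h)) p_t else p_h,
         cohort = get_field(healthy, "cohort", cohort),
         codes = codes),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("PatientProfile [", x$patient, "]: ",
      sum(x$codes == CODE_LOST), " lost, ",
      sum(x$codes == CODE_GAINED), " gained, ",
      sum(x$codes == CODE_KEPT), " kept\n", sep = "")
  invisible(x)
}

#' Merge patient profiles into a cohort profile
#'
#' The cohort's edge universe is the union over patients; an edge
#' unobserved in a patient (absent from both of that patient's networks)
#' receives the code `"00"` there. Patient order follows the input order.
#'
#' @param profiles List of `patient_profile` objects sharing one cohort.
#' @param cohort Optional cohort label override.
#' @return Object of class `cohort_profile`: `cohort`, `patients`, and
#'   `codes`, a character matrix edges (rows, named by edge key) by
#'   patients.
#' @export
cohort_profile <- function(profiles, cohort = NULL) {
  stopifnot(length(profiles) >= 1L)
  patients <- vapply(profiles, `[[`, character(1), "patient")
  if (anyDuplicated(patients)) {
    stop("duplicate patient id: '", patients[duplicated(patients)][1L], "'")
  }
  cohorts <- unique(unlist(lapply(profiles, `[[`, "cohort")))
  cohorts <- cohorts[!is.na(cohorts)]
  if (is.null(cohort)) {
    cohort <- if (length(cohorts) > 0L) cohorts[1L] else NA_character_
  }
  if (length(cohorts) > 1L) {
    stop("profiles span more than one cohort: ",
         paste(cohorts, collapse = ", "))
  }
  keys <- radix_sort(unique(unlist(lapply(profiles, function(p) names(p$codes)),
                                   use.names = FALSE)))
  codes <- matrix(CODE_ABSENT, nrow = length(keys), ncol = length(patients),
                  dimnames = list(keys, patients))
  for (j in seq_along(profiles)) {
    pc <- profiles[[j]]$codes
    codes[names(pc), j] <- pc
  }
  structure(
    list(cohort = cohort, patients = patients, codes = codes),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("CohortProfile [", x$cohort, "]: ", nrow(x$codes), " edges x ",
      length(x$patients), " patients\n", sep = "")
  invisible(x)
}

#' Per-edge perturbation statistics of a cohort
#'
#' Counts, per edge, the patients in which it was gained, lost, kept or
#' absent, the corresponding percentages of the cohort (`perc_gained`,
#' `perc_lost`), and the strict flags (perturbed in every patient).
#'
#' @param cohort A [cohort_profile].
#' @return Data.frame with columns `key`, `a`, `b`, `n_gained`, `n_lost`,
#'   `n_kept`, `n_absent`, `perc_gained`, `perc_lost`, `strict_gain`,
#'   `strict_loss`, sorted by `perc_lost` then `perc_gained` (descending),
#'   then edge key.
#' @export
edge_stats <- function(cohort) {
  np <- length(cohort$patients)
  cnt <- function(code) rowSums(cohort$codes == code)
  n_gained <- cnt(CODE_GAINED)
  n_lost <- cnt(CODE_LOST)
  n_kept <- cnt(CODE_KEPT)
  n_absent <- cnt(CODE_ABSENT)
  ed <- edges_from_keys(rownames(cohort$codes))
  out <- data.frame(
    key = rownames(cohort$codes),
    a = ed$a, b = ed$b,
    n_gained = as.integer(n_gained),
    n_lost = as.integer(n_lost),
    n_kept = as.integer(n_kept),
    n_absent = as.integer(n_absent),
    perc_gained = 100 * n_gained / np,
    perc_lost = 100 * n_lost / np,
    strict_gain = n_gained == np,
    strict_loss = n_lost == np,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$perc_lost, -out$perc_gained,
                   xtfrm_radix(out$key)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# radix-order ranks for use inside order()
xtfrm_radix <- function(x) match(x, radix_sort(unique(x)))

#' Classify perturbation scope across cohorts
#'
#' A perturbed (edge, direction) "counts" in a cohort when it is perturbed
#' in at least `min_patients` patients there. Counting in two or more
#' cohorts makes it multi-cancer, in exactly one cohort cancer-specific;
#' perturbations never reaching `min_patients` anywhere are
#' patient-specific.
#'
#' @param stats_list Named list (by cohort label) of [edge_stats] tables.
#' @param min_patients Minimum patients per cohort for a cancer-type
#'   perturbation (default 2).
#' @return Data.frame with columns `key`, `direction` (`"gain"`/`"loss"`),
#'   `n_cohorts` (cohorts where it counts) and `scope`.
#' @export
classify_scope <- function(stats_list, min_patients = 2L) {
  if (min_patients < 1L) stop("min_patients must be >= 1")
  stopifnot(length(stats_list) >= 1L)
  acc <- list()
  for (cohort in names(stats_list)) {
    st <- stats_list[[cohort]]
    for (dir in c("gain", "loss")) {
      n <- if (dir == "gain") st$n_gained else st$n_lost
      sel <- n >= 1L
      if (any(sel)) {
        acc[[length(acc) + 1L]] <- data.frame(
          key = st$key[sel], direction = dir, n = n[sel],
          counts = n[sel] >= min_patients, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(key = character(), direction = character(),
                      n_cohorts = integer(), scope = character(),
                      stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, acc)
  grp <- paste(long$key, long$direction, sep = "\r")
  n_cohorts <- tapply(long$counts, grp, sum)
  u <- !duplicated(grp)
  out <- data.frame(
    key = long$key[u], direction = long$direction[u],
    n_cohorts = as.integer(n_cohorts[grp[u]]),
    stringsAsFactors = FALSE
  )
  out$scope <- ifelse(out$n_cohorts >= 2L, "multi_cancer",
                      ifelse(out$n_cohorts == 1L, "cancer_specific",
                             "patient_specific"))
  out <- out[order(xtfrm_radix(out$key), out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute a perturbed edge to expression change or isoform switch
#'
#' If either endpoint gene changes its expressed state between the healthy
#' and tumor samples the perturbation is caused by `expression` (a silenced
#' or activated protein product); otherwise both endpoints stay expressed
#' and the cause is an `isoform_switch`, with the switched endpoints being
#' those whose major transcript differs between conditions (possibly
#' both).
#'
#' @param a,b Canonical endpoints of the edge.
#' @param code The edge's perturbation code; must be `"01"` or `"10"`.
#' @param healthy_states,tumor_states Named lists of [domain_state]
#'   results covering genes `a` and `b` in each condition.
#' @return List with `cause` (`"expression"` or `"isoform_switch"`) and
#'   `switched_endpoints` (character subset of `c(a, b)`).
#' @export
attribute_cause <- function(a, b, code, healthy_states, tumor_states) {
  if (!code %in% c(CODE_GAINED, CODE_LOST)) {
    stop("cause attribution applies to gained or lost edges only")
  }
  st <- function(states, g) {
    s <- states[[g]]
    if (is.null(s)) stop("missing domain state for gene '", g, "'")
    s
  }
  expr_changed <- vapply(c(a, b), function(g) {
    st(healthy_states, g)$expressed != st(tumor_states, g)$expressed
  }, logical(1))
  if (any(expr_changed)) {
    return(list(cause = "expression", switched_endpoints = character()))
  }
  switched <- c(a, b)[vapply(c(a, b), function(g) {
    !identical(st(healthy_states, g)$major_transcript,
               st(tumor_states, g)$major_transcript)
  }, logical(1))]
  if (length(switched) == 0L) {
    stop("perturbed edge with unchanged expression and major isoforms: ",
         edge_key(a, b))
  }
  list(cause = "isoform_switch", switched_endpoints = switched)
}

#' Attribute all perturbed edges of a patient profile
#'
#' Convenience wrapper computing the domain states of every endpoint gene
#' in the patient's healthy and tumor samples and attributing each gained
#' or lost edge.
#'
#' @param profile A `patient_profile`.
#' @param healthy_sample,tumor_sample Sample ids of the pair.
#' @param expr An [expression_matrix].
#' @param calls An [expression_calls].
#' @param annotations An [annotation_set].
#' @param config A [context_config].
#' @return Data.frame with columns `patient`, `key`, `direction`, `cause`
#'   and `switched_endpoints` (comma-joined).
#' @export
attribute_profile_causes <- function(profile, healthy_sample, tumor_sample,
                                     expr, calls, annotations,
                                     config = context_config()) {
  pert <- profile$codes[profile$codes %in% c(CODE_GAINED, CODE_LOST)]
  if (length(pert) == 0L) {
    return(data.frame(patient = character(), key = character(),
                      direction = character(), cause = character(),
                      switched_endpoints = character(),
                      stringsAsFactors = FALSE))
  }
  ed <- edges_from_keys(names(pert))
  genes <- unique(c(ed$a, ed$b))
  hs <- domain_states(genes, healthy_sample, expr, calls, annotations, config)
  ts <- domain_states(genes, tumor_sample, expr, calls, annotations, config)
  res <- lapply(seq_along(pert), function(i) {
    ca <- attribute_cause(ed$a[i], ed$b[i], pert[[i]], hs, ts)
    data.frame(patient = profile$patient, key = names(pert)[i],
               direction = ifelse(pert[[i]] == CODE_GAINED, "gain", "loss"),
               cause = ca$cause,
               switched_endpoints = paste(ca$switched_endpoints,
                                          collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
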