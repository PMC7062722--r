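# End-to-end cohort analysis: contextualize every sample, diff the
# paired networks, aggregate the cohort profile, attribute causes and
# test the paired network sizes.

#' Analyze one cohort end to end
#'
#' Runs the full per-cohort pipeline: expression calls and
#' condition-specific networks for every sample, paired healthy/tumor
#' differencing into patient profiles, cohort aggregation and edge
#' statistics, cause attribution for every perturbed edge, and the paired
#' Wilcoxon test on network sizes.
#'
#' @param global A [ppin].
#' @param annotations An [annotation_set].
#' @param ddi A [ddi_map].
#' @param expr An [expression_matrix] holding one cohort's paired samples.
#' @param config A [context_config].
#' @return List of class `cohort_analysis`: `calls`, `networks`,
#'   `profiles` (per patient), `cohort` ([cohort_profile]), `stats`
#'   ([edge_stats] table), `causes` (per patient and perturbed edge) and
#'   `size_test` ([paired_size_test] result).
#' @export
analyze_cohort <- function(global, annotations, ddi, expr,
                           config = context_config()) {
  nets <- contextualize_cohort(global, annotations, ddi, expr, config)
  calls <- attr(nets, "calls")
  meta <- expr$meta
  patients <- unique(meta$patient)
  pair_of <- function(p, cond) {
    s <- meta$sample[meta$patient == p & meta$condition == cond]
    if (length(s) != 1L) {
      stop("patient '", p, "' lacks exactly one ", cond, " sample")
    }
    s
  }
  profiles <- vector("list", length(patients))
  causes <- vector("list", length(patients))
  sizes <- matrix(0L, nrow = length(patients), ncol = 2L,
                  dimnames = list(patients, c("healthy", "tumor")))
  for (i in seq_along(patients)) {
    sh <- pair_of(patients[i], "healthy")
    st <- pair_of(patients[i], "tumor")
    profiles[[i]] <- diff_networks(nets[[sh]], nets[[st]])
    causes[[i]] <- attribute_profile_causes(profiles[[i]], sh, st, expr,
                                            calls, annotations, config)
    sizes[i, ] <- c(nrow(nets[[sh]]$edges), nrow(nets[[st]]$edges))
  }
  names(profiles) <- patients
  cohort <- cohort_profile(profiles)
  structure(
    list(calls = calls,
         networks = nets,
         profiles = profiles,
         cohort = cohort,
         stats = edge_stats(cohort),
         causes = do.call(rbind, causes),
         sizes = as.data.frame(sizes),
         size_test = paired_size_test(sizes[, 1L], sizes[, 2L],
                                      cohort = cohort$cohort)),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis [", x$cohort$cohort, "]: ",
      length(x$profiles), " patients, ", nrow(x$stats), " profile edges (",
      sum(x$stats$n_gained > 0), " ever gained, ",
      sum(x$stats$n_lost > 0), " ever lost)\n", sep = "")
  print(x$size_test)
  invisible(x)
}
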