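# Small built-in example networks used in documentation and tests.

#' Nine-edge toy network
#'
#' The classic worked example for perturbation ranking: nodes a-i with
#' edges a-b, a-d, b-c, b-h, c-d, d-e, d-f, f-g and h-i (9 edges over 9
#' nodes). With edges b-c, c-d and d-e marked perturbed, the greedy
#' neighbor-inclusive ranking gives node c a rank of 3 and nodes b, d and
#' e a rank of 1 each.
#'
#' @return A [ppin] with 9 nodes and 9 edges.
#' @examples
#' toy <- toy9_network()
#' rank_nodes_greedy(toy, c("b|c", "c|d", "d|e"))
#' @export
toy9_network <- function() {
  ppin(data.frame(
    a = c("a", "a", "b", "b", "c", "d", "d", "f", "h"),
    b = c("b", "d", "c", "h", "d", "e", "f", "g", "i"),
    stringsAsFactors = FALSE
  ))
}

#' Isoform-switch mechanism example
#'
#' A minimal three-gene fixture reproducing the canonical isoform-switch
#' gain mechanism: in the healthy sample the DST gene's major isoform
#' carries no domains, while in the tumor sample the dominant isoform
#' switches to one carrying the domain PF13499, which interacts with the
#' domains exposed by CALM1 and PPP1CB. Contextualizing both samples and
#' diffing them yields exactly the two gained edges DST-CALM1 and
#' DST-PPP1CB, each attributed to an isoform switch in DST.
#'
#' @return List with `network`, `annotations`, `ddi` and `expr`
#'   (an [expression_matrix] with one patient's paired samples).
#' @examples
#' fx <- isoform_switch_example()
#' nets <- contextualize_cohort(fx$network, fx$annotations, fx$ddi, fx$expr)
#' diff_networks(nets[["S_H"]], nets[["S_T"]])
#' @export
isoform_switch_example <- function() {
  network <- ppin(data.frame(
    a = c("DST", "DST"),
    b = c("CALM1", "PPP1CB"),
    stringsAsFactors = FALSE
  ))
  annotations <- annotation_set(
    gene = c("DST", "DST", "CALM1", "PPP1CB"),
    transcript = c("T_765", "T_364", "T_CALM1", "T_PPP1CB"),
    domains = list(character(), "PF13499", "X1", "X2")
  )
  ddi <- ddi_map(c("PF13499", "PF13499"), c("X1", "X2"))
  vals <- matrix(
    c(8.0, 0.05,   # T_765: healthy major, tumor minor
      0.05, 8.0,   # T_364: tumor major (carries PF13499)
      5.0, 5.0,    # T_CALM1
      5.0, 5.0),   # T_PPP1CB
    nrow = 4, byrow = TRUE,
    dimnames = list(c("T_765", "T_364", "T_CALM1", "T_PPP1CB"),
                    c("S_H", "S_T"))
  )
  meta <- data.frame(
    sample = c("S_H", "S_T"),
    patient = "P1",
    condition = c("healthy", "tumor"),
    cohort = "EX",
    stringsAsFactors = FALSE
  )
  list(network = network, annotations = annotations, ddi = ddi,
       expr = expression_matrix(vals, meta))
}
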